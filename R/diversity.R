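#' Harmonic numbers
#'
#' `H_n = 1 + 1/2 + ... + 1/n`, the normalising constant of the
#' Watterson estimator for a sample of `n + 1` sequences.
#'
#' @param n Vector of positive integers.
#' @return Numeric vector of `H_n` values.
#' @export
harmonic_number <- function(n) {
  if (!length(n)) return(numeric())
  if (any(is.na(n)) || any(n < 1L) || any(n != floor(n))) {
    stop("n must be a positive integer")
  }
  cumsum(1 / seq_len(max(n)))[n]
}

#' Depth-corrected per-site diversity (beta statistic)
#'
#' `beta = S / (L * H_{round(D) - 1})`: the Watterson-style relative
#' diversity of a contig, with the read depth `D` standing in for the
#' (unknown) number of sampled haplotypes. `beta_t` uses the strict SNP
#' count over the whole contig (`S_t`, `L_t`); `beta_n` and `beta_s` use
#' the non-synonymous and synonymous counts over the putative coding
#' length (`S_n`/`S_s`, `L_c`). Because the correction is conditioned on
#' coverage depth rather than the actual number of haplotypes, beta is a
#' relative -- not an absolute -- diversity measure.
#'
#' `D` is rounded half-up to the nearest integer before forming the
#' harmonic number; `harmonic_terms = "digamma"` switches to the
#' continuous generalisation `H_x = digamma(x + 1) + gamma` for
#' sensitivity analysis.
#'
#' @param S Number of SNPs (vector).
#' @param L Sequence length in bp (vector, `>= 1`; `NA` or 0 gives
#'   `NA`).
#' @param D Average fold coverage (vector).
#' @param min_cov Minimum coverage for beta to be defined (default 6,
#'   avoiding biases from weakly expressed, weakly covered contigs).
#' @param harmonic_terms `"round"` (default) or `"digamma"`.
#' @return Numeric vector of beta values; `NA` where undefined
#'   (`D < min_cov`, `round(D) - 1 < 1`, or missing/zero `L`).
#' @export
beta_stat <- function(S, L, D, min_cov = 6,
                      harmonic_terms = c("round", "digamma")) {
  harmonic_terms <- match.arg(harmonic_terms)
  n <- max(length(S), length(L), length(D))
  S <- rep_len(S, n); L <- rep_len(L, n); D <- rep_len(D, n)
  if (any(S < 0, na.rm = TRUE)) stop("S must be non-negative")
  out <- rep(NA_real_, n)
  if (harmonic_terms == "round") {
    m <- floor(D + 0.5) - 1          # round half-up, then D - 1 terms
    ok <- !is.na(D) & D >= min_cov & m >= 1 & !is.na(L) & L >= 1 &
      !is.na(S)
    if (any(ok)) out[ok] <- S[ok] / (L[ok] * harmonic_number(m[ok]))
  } else {
    ok <- !is.na(D) & D >= min_cov & (D - 1) > 0 & !is.na(L) & L >= 1 &
      !is.na(S)
    H <- digamma(D[ok]) - digamma(1)  # H_{D-1}, continuous
    out[ok] <- S[ok] / (L[ok] * H)
  }
  out
}

#' Per-contig diversity table
#'
#' One row per contig with average coverage `>= min_cov`, combining
#' strict SNP counts, coding-region classification and the beta
#' statistics. SNP calls must carry their `coding_class` (apply
#' [classify_snps()] first) for `S_n`/`S_s` to be populated; contigs
#' without a best-hit annotation get `L_c = NA` and undefined
#' `beta_n`/`beta_s`.
#'
#' @param alignments List of [multiple_alignment()] objects.
#' @param calls A `snp_calls` data frame; the strict flag selects the
#'   SNPs counted.
#' @param annotations Optional `ortholog_annotation_set` or
#'   [annotation_table()] data frame supplying coding lengths.
#' @param min_cov Coverage threshold for inclusion (default 6).
#' @param harmonic_terms Passed to [beta_stat()].
#' @return Data frame of class `contig_diversity`: `contig_id`, `S_t`,
#'   `S_n`, `S_s`, `L_t`, `L_c`, `D`, `beta_t`, `beta_n`, `beta_s`.
#' @export
diversity_table <- function(alignments, calls, annotations = NULL,
                            min_cov = 6,
                            harmonic_terms = c("round", "digamma")) {
  harmonic_terms <- match.arg(harmonic_terms)
  alignments <- .as_alignment_list(alignments)
  strict <- calls[calls$passes_strict, , drop = FALSE]
  ann <- NULL
  if (!is.null(annotations)) {
    ann <- if (inherits(annotations, "ortholog_annotation_set")) {
      annotation_table(annotations)
    } else {
      annotations
    }
  }
  rows <- lapply(alignments, function(aln) {
    D <- average_coverage(aln)
    if (D < min_cov) return(NULL)
    id <- aln$contig_id
    mine <- strict[strict$contig_id == id, , drop = FALSE]
    L_c <- if (!is.null(ann) && id %in% ann$query_id) {
      ann$coding_length[match(id, ann$query_id)]
    } else {
      NA_integer_
    }
    data.frame(
      contig_id = id,
      S_t = nrow(mine),
      S_n = if (is.na(L_c)) NA_integer_
            else sum(mine$coding_class == "non_synonymous"),
      S_s = if (is.na(L_c)) NA_integer_
            else sum(mine$coding_class == "synonymous"),
      L_t = unpadded_length(aln),
      L_c = L_c,
      D = D,
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    tab <- data.frame(contig_id = character(), S_t = integer(),
                      S_n = integer(), S_s = integer(), L_t = integer(),
                      L_c = integer(), D = numeric(), beta_t = numeric(),
                      beta_n = numeric(), beta_s = numeric(),
                      stringsAsFactors = FALSE)
    class(tab) <- c("contig_diversity", "data.frame")
    return(tab)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$beta_t <- beta_stat(tab$S_t, tab$L_t, tab$D, min_cov,
                          harmonic_terms)
  tab$beta_n <- beta_stat(tab$S_n, tab$L_c, tab$D, min_cov,
                          harmonic_terms)
  tab$beta_s <- beta_stat(tab$S_s, tab$L_c, tab$D, min_cov,
                          harmonic_terms)
  class(tab) <- c("contig_diversity", "data.frame")
  tab
}

#' Mean and median of each beta statistic
#'
#' Summaries are computed per statistic over the contigs where that
#' statistic is individually defined (non-`NA`), matching the reporting
#' convention for depth-thresholded diversity tables.
#'
#' @param div A `contig_diversity` data frame from [diversity_table()].
#' @return Data frame with `statistic`, `n`, `mean`, `median`.
#' @export
diversity_summary <- function(div) {
  do.call(rbind, lapply(c("beta_t", "beta_n", "beta_s"), function(st) {
    v <- div[[st]]
    v <- v[!is.na(v)]
    data.frame(statistic = st, n = length(v),
               mean = if (length(v)) mean(v) else NA_real_,
               median = if (length(v)) stats::median(v) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' Coding-region SNP rates per kilobase
#'
#' Counts strict non-synonymous and synonymous SNPs and expresses them
#' per 1,000 bp of putative coding sequence, where the denominator is
#' the summed coding length of the regions containing at least one
#' strict SNP (the same convention as the overall per-kb SNP rate).
#'
#' @param calls A `snp_calls` data frame with `coding_class` filled (see
#'   [classify_snps()]).
#' @param annotations An `ortholog_annotation_set` or
#'   [annotation_table()] data frame.
#' @return List of class `coding_rate_summary`; see
#'   [coding_rate_from_counts()].
#' @export
coding_rate_summary <- function(calls, annotations) {
  ann <- if (inherits(annotations, "ortholog_annotation_set")) {
    annotation_table(annotations)
  } else {
    annotations
  }
  strict <- calls[calls$passes_strict, , drop = FALSE]
  # A region enters the denominator when a strict SNP falls inside it;
  # positional membership (not coding_class) decides, so truncated-codon
  # "unassigned" calls inside the region still qualify it.
  regions <- NULL
  if (inherits(annotations, "ortholog_annotation_set")) {
    regions <- lapply(annotations, putative_coding_region)
  }
  pos_in_region <- vapply(seq_len(nrow(strict)), function(i) {
    if (!is.null(regions)) {
      reg <- regions[[strict$contig_id[i]]]
      if (is.null(reg)) return(FALSE)
      any(reg$intervals$start <= strict$position[i] &
            strict$position[i] <= reg$intervals$end)
    } else {
      strict$coding_class[i] %in% c("synonymous", "non_synonymous")
    }
  }, logical(1))
  with_snps <- unique(strict$contig_id[pos_in_region])
  coding_bp <- sum(ann$coding_length[ann$query_id %in% with_snps],
                   na.rm = TRUE)
  coding_rate_from_counts(
    n_non_synonymous = sum(strict$coding_class == "non_synonymous"),
    n_synonymous = sum(strict$coding_class == "synonymous"),
    coding_bp = coding_bp,
    n_regions_with_snps = length(with_snps)
  )
}

#' Assemble coding SNP rates from already-tallied counts
#'
#' @param n_non_synonymous,n_synonymous SNP counts by class.
#' @param coding_bp Summed putative coding length (bp) of regions with at
#'   least one counted SNP.
#' @param n_regions_with_snps Optional count of those regions.
#' @return List of class `coding_rate_summary` with the inputs plus
#'   `non_synonymous_per_kb` and `synonymous_per_kb` (`NA` when the
#'   denominator is zero).
#' @export
coding_rate_from_counts <- function(n_non_synonymous, n_synonymous,
                                    coding_bp,
                                    n_regions_with_snps = NA_integer_) {
  rate <- function(n) if (coding_bp > 0) 1000 * n / coding_bp else NA_real_
  structure(list(
    n_non_synonymous = n_non_synonymous,
    n_synonymous = n_synonymous,
    coding_bp = coding_bp,
    n_regions_with_snps = n_regions_with_snps,
    non_synonymous_per_kb = rate(n_non_synonymous),
    synonymous_per_kb = rate(n_synonymous)
  ), class = "coding_rate_summary")
}

#' @export
print.coding_rate_summary <- function(x, ...) {
  cat(sprintf(
    "<coding_rate_summary> %d non-syn / %d syn SNPs in %d coding bp\n",
    x$n_non_synonymous, x$n_synonymous, x$coding_bp))
  cat(sprintf("  %.2f non-synonymous, %.2f synonymous per kb\n",
              x$non_synonymous_per_kb, x$synonymous_per_kb))
  invisible(x)
}

#' Correlation of contig diversity with species-hit breadth
#'
#' Pearson product-moment correlation between `beta_t` and the number of
#' protein databases hit (0--3), with the usual t-distributed two-sided
#' p-value. A negative correlation indicates that lineage-specific genes
#' (few databases hit) are the more diverse ones.
#'
#' @param div A `contig_diversity` data frame from [diversity_table()].
#' @param profile Output of [species_hit_profile()].
#' @return List with `r`, `p`, `n`; `r`/`p` are `NA` with a `reason`
#'   when fewer than 3 pairs are available or either variable is
#'   constant.
#' @export
beta_hitcount_correlation <- function(div, profile) {
  idx <- match(div$contig_id, profile$query_id)
  ok <- !is.na(idx) & !is.na(div$beta_t)
  x <- div$beta_t[ok]
  y <- profile$n_databases_hit[idx[ok]]
  if (length(x) < 3L) {
    return(list(r = NA_real_, p = NA_real_, n = length(x),
                reason = "fewer than 3 paired observations"))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = length(x),
                reason = "zero variance"))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
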