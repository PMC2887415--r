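#' Call SNPs column-by-column from contig multiple alignments
#'
#' Each padded column of each alignment is analysed independently. A
#' column is a SNP candidate when (a) the consensus character at that
#' column is not a pad and (b) at least two distinct nucleotide alleles
#' (`A,C,G,T`) are present among the covering reads. Reads showing a pad
#' or `N` at the column contribute neither to allele counts nor to the
#' column coverage used by the criteria.
#'
#' Two published criteria are evaluated for every candidate:
#' * **loose** -- each of the two most common alleles is seen in at least
#'   `loose_min_reads` reads (default 2); designed to maximise discovery
#'   of rare alleles.
#' * **strict** -- column coverage is at least `strict_min_cov` (default
#'   6x) and the minority allele accounts for at least `strict_min_frac`
#'   (default 25%) of the covering reads; designed to minimise false
#'   positives from sequencing error.
#'
#' Every strict call is also a loose call at the default thresholds.
#' Columns with three or more alleles yield a single call based on the
#' two most common alleles; ties are broken alphabetically for
#' determinism.
#'
#' @param alignments A [multiple_alignment()] or list thereof.
#' @param criterion Which calls to return: `"loose"`, `"strict"`, or
#'   `"any"` (all candidate columns, with both criterion flags).
#' @param strict_min_frac Minimum minority-allele fraction for the strict
#'   criterion.
#' @param strict_min_cov Minimum column coverage for the strict criterion.
#' @param loose_min_reads Minimum reads per top-two allele for the loose
#'   criterion.
#' @return A data frame of class `snp_calls` with one row per call:
#'   `contig_id`, `column` (1-based padded), `position` (1-based
#'   unpadded), allele counts `n_A..n_T`, `coverage` (non-gap non-`N`
#'   reads), `major_allele`, `minor_allele`, `major_count`, `minor_count`,
#'   `passes_loose`, `passes_strict`, `substitution_class`
#'   (transition/transversion of the major/minor pair) and `coding_class`
#'   (`"unassigned"` until [classify_snps()] is applied).
#' @export
call_snps <- function(alignments, criterion = c("loose", "strict", "any"),
                      strict_min_frac = 0.25, strict_min_cov = 6L,
                      loose_min_reads = 2L) {
  criterion <- match.arg(criterion)
  alignments <- .as_alignment_list(alignments)
  rows <- lapply(alignments, .call_snps_one, strict_min_frac,
                 strict_min_cov, loose_min_reads)
  calls <- do.call(rbind, c(rows, list(.empty_snp_calls())))
  calls <- switch(criterion,
    loose = calls[calls$passes_loose, , drop = FALSE],
    strict = calls[calls$passes_strict, , drop = FALSE],
    any = calls
  )
  rownames(calls) <- NULL
  class(calls) <- c("snp_calls", "data.frame")
  calls
}

.empty_snp_calls <- function() {
  data.frame(contig_id = character(), column = integer(),
             position = integer(), n_A = integer(), n_C = integer(),
             n_G = integer(), n_T = integer(), coverage = integer(),
             major_allele = character(), minor_allele = character(),
             major_count = integer(), minor_count = integer(),
             passes_loose = logical(), passes_strict = logical(),
             substitution_class = character(), coding_class = character(),
             stringsAsFactors = FALSE)
}

.call_snps_one <- function(aln, strict_min_frac, strict_min_cov,
                           loose_min_reads) {
  m <- .alignment_counts(aln)[c("A", "C", "G", "T"), , drop = FALSE]
  cons <- .consensus_chars(aln)
  cov <- colSums(m)
  n_alleles <- colSums(m > 0L)
  cand <- which(cons != "-" & n_alleles >= 2L)
  if (!length(cand)) return(NULL)
  unpadded_pos <- cumsum(cons != "-")     # 1-based position of each column
  bases <- c("A", "C", "G", "T")
  out <- lapply(cand, function(j) {
    cnt <- m[, j]
    ord <- order(-cnt, bases)             # alphabetical tie-break
    major <- bases[ord[1]]; minor <- bases[ord[2]]
    data.frame(
      contig_id = aln$contig_id, column = j,
      position = unpadded_pos[j],
      n_A = cnt[["A"]], n_C = cnt[["C"]], n_G = cnt[["G"]],
      n_T = cnt[["T"]], coverage = cov[[j]],
      major_allele = major, minor_allele = minor,
      major_count = cnt[[major]], minor_count = cnt[[minor]],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  out$passes_loose <- out$major_count >= loose_min_reads &
    out$minor_count >= loose_min_reads
  out$passes_strict <- out$coverage >= strict_min_cov &
    out$minor_count / out$coverage >= strict_min_frac
  out$substitution_class <- classify_substitution(out$major_allele,
                                                  out$minor_allele)
  out$coding_class <- "unassigned"
  out
}

#' Classify a base substitution as transition or transversion
#'
#' Transitions exchange purines (`A<->G`) or pyrimidines (`C<->T`); all
#' other substitutions are transversions. Of the six unordered base pairs,
#' two are transitions and four transversions.
#'
#' @param base1,base2 Character vectors of distinct bases in `A,C,G,T`
#'   (recycled to a common length).
#' @return Character vector of `"transition"` / `"transversion"`.
#' @export
classify_substitution <- function(base1, base2) {
  n <- max(length(base1), length(base2))
  base1 <- rep_len(toupper(base1), n)
  base2 <- rep_len(toupper(base2), n)
  ok <- base1 %in% c("A", "C", "G", "T") & base2 %in% c("A", "C", "G", "T")
  if (any(!ok)) stop("bases must be in A,C,G,T")
  if (any(base1 == base2)) stop("bases must differ")
  purine <- c("A", "G")
  same_family <- (base1 %in% purine) == (base2 %in% purine)
  ifelse(same_family, "transition", "transversion")
}

#' Detect multi-column variant regions in a contig alignment
#'
#' Implements the assembler-style grouping rule for co-occurring
#' polymorphisms: a padded column is *polymorphic* when at least two
#' character states over `A,C,G,T,-` (pads count as a state, `N` does
#' not) are each supported by at least `min_support` reads. Polymorphic
#' columns are chained while at most `max_gap` non-polymorphic columns
#' separate consecutive ones. Chains of a single column (isolated SNPs)
#' are not reported.
#'
#' The variants of a region are the distinct padded strings spanned by
#' reads that fully cover the region; only strings supported by at least
#' `min_support` such reads are counted, and regions retaining fewer than
#' two supported variants are dropped. Base qualities are not used.
#'
#' @param alignments A [multiple_alignment()] or list thereof.
#' @param max_gap Maximum run of non-polymorphic columns inside a region.
#' @param min_support Minimum reads per character state and per spanning
#'   variant string.
#' @return Data frame with one row per region: `contig_id`,
#'   `start_column`/`end_column` (1-based padded, inclusive), `length_bp`
#'   (unpadded span), `n_polymorphic_columns`, `n_variants`, and a
#'   list-column `support` of named read counts per variant string.
#' @export
detect_variant_regions <- function(alignments, max_gap = 11L,
                                   min_support = 2L) {
  alignments <- .as_alignment_list(alignments)
  out <- lapply(alignments, .variant_regions_one, max_gap, min_support)
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(contig_id = character(), start_column = integer(),
                      end_column = integer(), length_bp = integer(),
                      n_polymorphic_columns = integer(),
                      n_variants = integer(),
                      support = I(list()), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.variant_regions_one <- function(aln, max_gap, min_support) {
  m <- .alignment_counts(aln)[c("A", "C", "G", "T", "-"), , drop = FALSE]
  poly <- which(colSums(m >= min_support) >= 2L)
  if (length(poly) < 2L) return(NULL)
  chain_id <- cumsum(c(1L, diff(poly) - 1L > max_gap))
  cons <- .consensus_chars(aln)
  starts <- aln$reads$start
  ends <- starts + nchar(aln$reads$seq)
  rows <- lapply(split(poly, chain_id), function(cols) {
    if (length(cols) < 2L) return(NULL)
    s <- min(cols); e <- max(cols)
    span <- which(starts <= s - 1L & ends >= e)   # reads covering [s, e]
    if (!length(span)) return(NULL)
    strs <- substring(aln$reads$seq[span], s - starts[span], e - starts[span])
    tab <- table(strs)
    tab <- tab[tab >= min_support]
    if (length(tab) < 2L) return(NULL)
    sup <- as.integer(tab); names(sup) <- names(tab)
    data.frame(contig_id = aln$contig_id, start_column = s, end_column = e,
               length_bp = sum(cons[s:e] != "-"),
               n_polymorphic_columns = length(cols),
               n_variants = length(sup), support = I(list(sup)),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Dataset-level SNP discovery summary
#'
#' Counts calls under one criterion and expresses the SNP rate per 1,000
#' bases of the contigs in which at least one such SNP was found (the
#' same denominator convention used for published per-kb EST SNP rates).
#'
#' @param alignments List of [multiple_alignment()] objects the calls came
#'   from.
#' @param calls A `snp_calls` data frame (see [call_snps()]).
#' @param criterion `"strict"` or `"loose"`; selects calls by their flags.
#' @return An object of class `snp_rate_summary`; see
#'   [snp_rate_from_counts()] for the fields.
#' @export
snp_rate_summary <- function(alignments, calls,
                             criterion = c("strict", "loose")) {
  criterion <- match.arg(criterion)
  alignments <- .as_alignment_list(alignments)
  keep <- if (criterion == "strict") calls$passes_strict else calls$passes_loose
  calls <- calls[keep, , drop = FALSE]
  lens <- vapply(alignments, unpadded_length, numeric(1))
  names(lens) <- vapply(alignments, `[[`, character(1), "contig_id")
  with_snps <- unique(calls$contig_id)
  snp_rate_from_counts(
    n_snps = nrow(calls),
    transitions = sum(calls$substitution_class == "transition"),
    transversions = sum(calls$substitution_class == "transversion"),
    bp_in_contigs_with_snps = sum(lens[with_snps]),
    n_contigs_with_snps = length(with_snps)
  )
}

#' Assemble a SNP-rate summary from already-tallied counts
#'
#' The arithmetic core of [snp_rate_summary()], exposed so that published
#' count tables can be turned into per-kb rates directly.
#'
#' @param n_snps Total SNP count.
#' @param transitions,transversions Substitution-class counts; must sum to
#'   `n_snps`.
#' @param bp_in_contigs_with_snps Summed unpadded length (bp) of contigs
#'   containing at least one counted SNP.
#' @param n_contigs_with_snps Optional count of those contigs.
#' @return An object of class `snp_rate_summary`: the inputs plus
#'   `snps_per_kb` (`NA` when the denominator is zero) and
#'   `transversion_fraction`.
#' @export
snp_rate_from_counts <- function(n_snps, transitions, transversions,
                                 bp_in_contigs_with_snps,
                                 n_contigs_with_snps = NA_integer_) {
  if (transitions + transversions != n_snps) {
    stop("transitions + transversions must equal n_snps")
  }
  structure(list(
    n_snps = n_snps,
    transitions = transitions,
    transversions = transversions,
    transversion_fraction = if (n_snps > 0) transversions / n_snps
                            else NA_real_,
    n_contigs_with_snps = n_contigs_with_snps,
    bp_in_contigs_with_snps = bp_in_contigs_with_snps,
    snps_per_kb = if (bp_in_contigs_with_snps > 0) {
      1000 * n_snps / bp_in_contigs_with_snps
    } else {
      NA_real_
    }
  ), class = "snp_rate_summary")
}

#' @export
print.snp_rate_summary <- function(x, ...) {
  cat(sprintf("<snp_rate_summary> %d SNPs (%d ts / %d tv, %.0f%% tv)\n",
              x$n_snps, x$transitions, x$transversions,
              100 * x$transversion_fraction))
  cat(sprintf("  in %s contigs spanning %d bp: %.2f SNPs per kb\n",
              ifelse(is.na(x$n_contigs_with_snps), "?",
                     x$n_contigs_with_snps),
              x$bp_in_contigs_with_snps, x$snps_per_kb))
  invisible(x)
}
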