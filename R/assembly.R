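#' Assembly-level summary statistics
#'
#' Counts, length statistics and coverage statistics for a unigene set
#' (contigs plus singletons). A unigene is a contig or an unassembled
#' singleton EST; `n_unigenes = n_contigs + n_singletons` always holds.
#' The median of an even-sized set is the mean of the two central values.
#'
#' @param contigs Contig sequences: a data frame with columns
#'   `id`/`sequence` (see [read_fasta()]) or a character vector.
#' @param singletons Singleton sequences, same forms as `contigs`.
#' @param alignments Optional list of [multiple_alignment()] objects for
#'   the contigs; when given, mean and median fold coverage are reported.
#' @return An object of class `assembly_summary` (a named list).
#' @export
assembly_summary <- function(contigs, singletons, alignments = NULL) {
  clen <- .seq_lengths(contigs)
  slen <- .seq_lengths(singletons)
  ulen <- c(clen, slen)
  cov <- if (!is.null(alignments)) {
    vapply(.as_alignment_list(alignments), average_coverage, numeric(1))
  } else {
    numeric()
  }
  total <- sum(ulen)
  structure(list(
    n_contigs = length(clen),
    n_singletons = length(slen),
    n_unigenes = length(ulen),
    mean_contig_length = .mean_or_na(clen),
    median_contig_length = .median_or_na(clen),
    mean_singleton_length = .mean_or_na(slen),
    median_singleton_length = .median_or_na(slen),
    mean_unigene_length = .mean_or_na(ulen),
    median_unigene_length = .median_or_na(ulen),
    total_bp = total,
    singleton_bp_fraction = if (total > 0) sum(slen) / total else NA_real_,
    mean_contig_coverage = .mean_or_na(cov),
    median_contig_coverage = .median_or_na(cov)
  ), class = "assembly_summary")
}

.seq_lengths <- function(x) {
  if (is.null(x)) return(integer())
  if (is.data.frame(x)) return(nchar(x$sequence))
  if (is.character(x)) return(nchar(x))
  if (is.numeric(x)) return(as.integer(x))
  stop("expected a data frame, character vector or lengths")
}

.mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
.median_or_na <- function(x) if (length(x)) stats::median(x) else NA_real_

#' @export
print.assembly_summary <- function(x, ...) {
  cat(sprintf("<assembly_summary> %d unigenes = %d contigs + %d singletons\n",
              x$n_unigenes, x$n_contigs, x$n_singletons))
  cat(sprintf("  contig length mean/median: %.1f / %.1f bp\n",
              x$mean_contig_length, x$median_contig_length))
  cat(sprintf("  singleton length mean/median: %.1f / %.1f bp\n",
              x$mean_singleton_length, x$median_singleton_length))
  cat(sprintf("  total %d bp (%.1f%% in singletons)\n", x$total_bp,
              100 * x$singleton_bp_fraction))
  if (!is.na(x$mean_contig_coverage)) {
    cat(sprintf("  contig coverage mean/median: %.2fx / %.2fx\n",
                x$mean_contig_coverage, x$median_contig_coverage))
  }
  invisible(x)
}

#' Group contigs into coverage bins
#'
#' Bins are left-closed, right-open, except the last which is closed on
#' both sides, matching the usual histogram convention for coverage
#' distributions. Contigs with coverage outside the binned range are
#' excluded with a warning.
#'
#' @param alignments List of [multiple_alignment()] objects.
#' @param bin_edges Strictly increasing numeric vector of bin edges
#'   (length >= 2).
#' @return Data frame with one row per bin: `bin_low`, `bin_high`,
#'   `n_contigs`, `mean_length` (mean unpadded contig length, `NA` for
#'   empty bins).
#' @export
coverage_histogram <- function(alignments, bin_edges) {
  alignments <- .as_alignment_list(alignments)
  if (length(bin_edges) < 2L) stop("need at least two bin edges")
  if (any(diff(bin_edges) <= 0)) stop("bin edges must be strictly increasing")
  cov <- vapply(alignments, average_coverage, numeric(1))
  len <- vapply(alignments, unpadded_length, numeric(1))
  # rightmost.closed maps cov == last edge into the last bin
  idx <- findInterval(cov, bin_edges, rightmost.closed = TRUE)
  out <- idx < 1L | idx > length(bin_edges) - 1L
  if (any(out)) {
    warning(sum(out), " contig(s) outside the binned coverage range excluded")
    cov <- cov[!out]; len <- len[!out]; idx <- idx[!out]
  }
  nb <- length(bin_edges) - 1L
  data.frame(
    bin_low = bin_edges[seq_len(nb)],
    bin_high = bin_edges[seq_len(nb) + 1L],
    n_contigs = vapply(seq_len(nb), function(b) sum(idx == b), integer(1)),
    mean_length = vapply(seq_len(nb), function(b) {
      if (any(idx == b)) mean(len[idx == b]) else NA_real_
    }, numeric(1))
  )
}
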