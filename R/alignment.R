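#' Construct a contig multiple alignment
#'
#' A `multiple_alignment` holds the padded read layout of one contig as
#' produced during assembly: a padded consensus row and, for each read, its
#' 0-based start offset in padded coordinates together with its padded
#' sequence. Pads are `-`. All column-wise analysis (SNP calling, variant
#' regions) operates in padded coordinates; lengths and coverage are
#' denominated in unpadded (pad-free) consensus base pairs.
#'
#' @param contig_id Contig identifier.
#' @param consensus Padded consensus string over `A,C,G,T,N,-`.
#' @param reads Data frame with columns `read_id`, `start` (0-based offset
#'   of the read in padded consensus coordinates) and `seq` (padded read
#'   string over `A,C,G,T,N,-`).
#' @return An object of class `multiple_alignment`.
#' @export
multiple_alignment <- function(contig_id, consensus, reads) {
  stopifnot(is.character(contig_id), length(contig_id) == 1L,
            is.character(consensus), length(consensus) == 1L)
  consensus <- toupper(consensus)
  if (nchar(consensus) < 1L) {
    stop("contig '", contig_id, "': zero-length consensus")
  }
  if (grepl("[^ACGTN-]", consensus)) {
    stop("contig '", contig_id, "': invalid character in consensus")
  }
  reads <- as.data.frame(reads, stringsAsFactors = FALSE)
  stopifnot(all(c("read_id", "start", "seq") %in% names(reads)))
  reads$start <- as.integer(reads$start)
  reads$seq <- toupper(reads$seq)
  if (any(grepl("[^ACGTN-]", reads$seq))) {
    bad <- reads$read_id[grepl("[^ACGTN-]", reads$seq)][1]
    stop("contig '", contig_id, "': invalid character in read '", bad, "'")
  }
  L <- nchar(consensus)
  ends <- reads$start + nchar(reads$seq)
  if (any(reads$start < 0L) || any(ends > L)) {
    bad <- reads$read_id[reads$start < 0L | ends > L][1]
    stop("contig '", contig_id, "': read '", bad,
         "' exceeds consensus bounds")
  }
  aln <- structure(
    list(contig_id = contig_id, consensus = consensus, reads = reads),
    class = "multiple_alignment"
  )
  cov <- colSums(.alignment_counts(aln))
  if (any(cov == 0L)) {
    warning("contig '", contig_id, "': ", sum(cov == 0L),
            " column(s) covered by no read")
  }
  aln
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat("<multiple_alignment> contig", x$contig_id, "--",
      nchar(x$consensus), "padded /", unpadded_length(x),
      "unpadded bp,", nrow(x$reads), "reads,",
      sprintf("%.2fx", average_coverage(x)), "coverage\n")
  invisible(x)
}

# Character count matrix: rows A,C,G,T,N,'-', one column per padded column.
# Counts are over reads covering the column; pads in reads count under '-'.
.alignment_counts <- function(aln) {
  L <- nchar(aln$consensus)
  bases <- c("A", "C", "G", "T", "N", "-")
  m <- matrix(0L, nrow = 6L, ncol = L, dimnames = list(bases, NULL))
  for (i in seq_len(nrow(aln$reads))) {
    chars <- strsplit(aln$reads$seq[i], "", fixed = TRUE)[[1]]
    cols <- aln$reads$start[i] + seq_along(chars)
    for (b in bases) {
      hit <- cols[chars == b]
      if (length(hit)) m[b, hit] <- m[b, hit] + 1L
    }
  }
  m
}

.consensus_chars <- function(aln) strsplit(aln$consensus, "", fixed = TRUE)[[1]]

#' Unpadded consensus length of a contig
#'
#' @param aln A [multiple_alignment()].
#' @return Number of non-pad consensus characters (bp).
#' @export
unpadded_length <- function(aln) {
  nchar(gsub("-", "", aln$consensus, fixed = TRUE))
}

#' Unpadded consensus sequence (the contig's unigene sequence)
#'
#' @param aln A [multiple_alignment()].
#' @export
consensus_sequence <- function(aln) {
  gsub("-", "", aln$consensus, fixed = TRUE)
}

#' Character profile of one padded alignment column
#'
#' @param aln A [multiple_alignment()].
#' @param column 1-based padded column index.
#' @return Named integer vector of counts over `A,C,G,T,N,-` among reads
#'   covering the column. Counts sum to the number of covering reads.
#' @export
column_profile <- function(aln, column) {
  L <- nchar(aln$consensus)
  if (!is.numeric(column) || length(column) != 1L || column < 1L ||
      column > L) {
    stop("column index out of range [1, ", L, "]")
  }
  .alignment_counts(aln)[, as.integer(column)]
}

#' Average fold coverage of a contig
#'
#' Total non-gap read characters (`N` included) divided by the unpadded
#' consensus length.
#'
#' @param aln A [multiple_alignment()].
#' @return Fold coverage as a double.
#' @export
average_coverage <- function(aln) {
  len <- unpadded_length(aln)
  if (len == 0L) stop("contig '", aln$contig_id, "': zero unpadded length")
  nongap <- sum(nchar(gsub("-", "", aln$reads$seq, fixed = TRUE)))
  nongap / len
}

#' Columns where the read majority disagrees with the consensus row
#'
#' The consensus row of the alignment file is trusted throughout the
#' package; this check reports the padded columns where the most common
#' read character (pads included) differs from the consensus. Ties that
#' include the consensus character are not reported.
#'
#' @param aln A [multiple_alignment()].
#' @return Integer vector of 1-based padded column indices.
#' @export
consensus_discrepancies <- function(aln) {
  m <- .alignment_counts(aln)
  cons <- .consensus_chars(aln)
  top <- apply(m, 2L, max)
  cons_count <- m[cbind(match(cons, rownames(m)), seq_along(cons))]
  which(cons_count < top)
}
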