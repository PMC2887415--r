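#' @keywords internal
.HIT_COLUMNS <- c("qseqid", "sseqid", "db", "evalue", "bitscore",
                  "qstart", "qend", "sstart", "send", "frame",
                  "qlen", "slen", "qseq_aln", "sseq_aln")

#' Read translated-search hits
#'
#' Two tabular dialects are supported:
#' * `"extended"` (default) -- a 14-column TSV with a required header:
#'   `qseqid sseqid db evalue bitscore qstart qend sstart send frame qlen
#'   slen qseq_aln sseq_aln`. Coordinates are 1-based inclusive; `qstart`
#'   and `qend` are nucleotide positions on the query (with
#'   `qstart > qend` for reverse frames), `sstart`/`send` are subject
#'   residue positions, and `qseq_aln`/`sseq_aln` are the gapped
#'   translated-query and subject alignment rows.
#' * `"standard"` -- the classic 12-column tabular output (`qseqid sseqid
#'   pident length mismatch gapopen qstart qend sstart send evalue
#'   bitscore`, no header). Frame, lengths and alignment rows are absent;
#'   downstream gap-aware computations degrade with a warning.
#'
#' No e-value filtering is applied at read time.
#'
#' @param path Path to the hits file.
#' @param dialect `"extended"` or `"standard"`.
#' @param db Database label to assign when the dialect carries none.
#' @return Data frame of hit records in the extended column layout
#'   (missing fields `NA` for the standard dialect).
#' @export
read_hits <- function(path, dialect = c("extended", "standard"), db = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("hits file not found: ", path)
  if (dialect == "extended") {
    hits <- utils::read.delim(path, stringsAsFactors = FALSE,
                              colClasses = "character")
    if (!identical(names(hits), .HIT_COLUMNS)) {
      stop("'", path, "': expected header columns ",
           paste(.HIT_COLUMNS, collapse = " "))
    }
    for (col in c("evalue", "bitscore")) hits[[col]] <- as.numeric(hits[[col]])
    for (col in c("qstart", "qend", "sstart", "send", "frame",
                  "qlen", "slen")) {
      v <- suppressWarnings(as.integer(hits[[col]]))
      if (anyNA(v) && !all(is.na(hits[[col]]))) {
        stop("'", path, "' line ", which(is.na(v))[1] + 1L,
             ": unparsable ", col)
      }
      hits[[col]] <- v
    }
    .validate_hits(hits, path)
    hits
  } else {
    hits <- utils::read.delim(path, header = FALSE,
                              stringsAsFactors = FALSE)
    if (ncol(hits) != 12L) {
      stop("'", path, "': standard tabular dialect needs 12 columns, got ",
           ncol(hits))
    }
    names(hits) <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                     "gapopen", "qstart", "qend", "sstart", "send",
                     "evalue", "bitscore")
    out <- data.frame(
      qseqid = hits$qseqid, sseqid = hits$sseqid,
      db = if (is.null(db)) NA_character_ else db,
      evalue = hits$evalue, bitscore = hits$bitscore,
      qstart = hits$qstart, qend = hits$qend,
      sstart = hits$sstart, send = hits$send,
      frame = NA_integer_, qlen = NA_integer_, slen = NA_integer_,
      qseq_aln = NA_character_, sseq_aln = NA_character_,
      stringsAsFactors = FALSE
    )
    out
  }
}

.validate_hits <- function(hits, path = "<hits>") {
  if (any(hits$evalue < 0, na.rm = TRUE)) {
    stop("'", path, "': negative e-value")
  }
  bad_frame <- !is.na(hits$frame) & !(abs(hits$frame) %in% 1:3)
  if (any(bad_frame)) {
    stop("'", path, "' line ", which(bad_frame)[1] + 1L,
         ": frame must be in -3..-1, 1..3")
  }
  has_rows <- !is.na(hits$qseq_aln) & !is.na(hits$sseq_aln)
  uneq <- has_rows & nchar(hits$qseq_aln) != nchar(hits$sseq_aln)
  if (any(uneq)) {
    stop("'", path, "' line ", which(uneq)[1] + 1L,
         ": gapped alignment rows of unequal length")
  }
  # non-gap query residues must consume exactly the spanned nucleotides
  nres <- nchar(gsub("-", "", hits$qseq_aln[has_rows], fixed = TRUE))
  span <- abs(hits$qend[has_rows] - hits$qstart[has_rows]) + 1L
  mism <- 3L * nres != span
  if (any(mism)) {
    stop("'", path, "' line ", which(has_rows)[which(mism)[1]] + 1L,
         ": query span does not equal 3 x non-gap query residues")
  }
  invisible(hits)
}

#' Write hits in the extended tabular dialect
#'
#' @param hits Data frame of hit records (see [read_hits()]).
#' @param path Output path.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(hits[, .HIT_COLUMNS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Select best-hit records per query (and per database)
#'
#' Records with `evalue >= e_cutoff` are discarded. For each query (and
#' database label, when present) the best subject is the one with the
#' lowest e-value over its HSPs, ties broken by highest bit score, then
#' lexicographically smallest subject id. All retained HSPs of the best
#' subject are returned, so multi-HSP hits stay intact for downstream
#' region merging.
#'
#' @param hits Data frame of hit records.
#' @param e_cutoff E-value cutoff (exclusive; hits at the cutoff are
#'   discarded).
#' @param exclude_self Drop records with `qseqid == sseqid` before
#'   selection (used for unigene-vs-unigene searches, where the trivial
#'   self-match is vacuous).
#' @return Data frame of the winning subjects' HSPs (possibly empty).
#' @export
best_hits <- function(hits, e_cutoff = 1e-5, exclude_self = FALSE) {
  hits <- hits[hits$evalue < e_cutoff, , drop = FALSE]
  if (exclude_self) hits <- hits[hits$qseqid != hits$sseqid, , drop = FALSE]
  if (!nrow(hits)) return(hits)
  grp <- paste(hits$qseqid, hits$db, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(hits)), grp), function(idx) {
    sub <- hits[idx, , drop = FALSE]
    stats <- do.call(rbind, lapply(split(seq_along(idx), sub$sseqid),
      function(k) {
        data.frame(sseqid = sub$sseqid[k[1]], e = min(sub$evalue[k]),
                   bits = max(sub$bitscore[k]), stringsAsFactors = FALSE)
      }))
    best <- stats[order(stats$e, -stats$bits, stats$sseqid), ][1, "sseqid"]
    idx[sub$sseqid == best]
  }), use.names = FALSE)
  out <- hits[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' One-row-per-query table of best-hit subjects
#'
#' Convenience wrapper over [best_hits()] for graph building: collapses
#' the winning HSPs to a `(qseqid, db, sseqid)` table.
#'
#' @inheritParams best_hits
#' @return Data frame with columns `qseqid`, `db`, `sseqid`.
#' @export
best_hit_table <- function(hits, e_cutoff = 1e-5, exclude_self = FALSE) {
  bh <- best_hits(hits, e_cutoff = e_cutoff, exclude_self = exclude_self)
  unique(bh[, c("qseqid", "db", "sseqid")])
}
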