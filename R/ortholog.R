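#' Ortholog hit ratio for one query against its best-hit subject
#'
#' The ortholog hit ratio estimates how much of a reference protein a
#' unigene has recovered: the number of non-gap characters of the query
#' in the hit region, counted in residue (codon) units on the translated
#' query row, divided by the subject length in residues. HSPs of the same
#' subject are merged by taking the union of the query nucleotide
#' positions their non-gap residues occupy, so overlapping HSPs are
#' counted once and duplicating an HSP never changes the ratio. A
#' gapless HSP covering the whole subject gives exactly 1.0; ratios above
#' 1.0 indicate query insertions relative to the subject.
#'
#' When alignment rows are absent (standard 12-column input) the residue
#' count degrades to `(|qend - qstart| + 1) / 3` per HSP, with a warning,
#' i.e. alignment gaps can no longer be subtracted.
#'
#' @param hsps Data frame of hit records for a single query and a single
#'   subject (as returned by [best_hits()] filtered to one query).
#' @return An object of class `ortholog_annotation`: a list with
#'   `query_id`, `subject_id`, `db`, `subject_length`, `query_length`,
#'   `frame` (dominant frame), `frame_conflict`, `n_residues` (size of
#'   the merged non-gap query region, residues), `ortholog_hit_ratio`,
#'   and `intervals` (merged query nucleotide intervals, 1-based
#'   inclusive, with per-interval frame).
#' @export
ortholog_hit_ratio <- function(hsps) {
  stopifnot(nrow(hsps) >= 1L)
  if (length(unique(hsps$qseqid)) != 1L ||
      length(unique(hsps$sseqid)) != 1L) {
    stop("hsps must belong to a single query/subject pair")
  }
  slen <- hsps$slen[1]
  if (is.na(slen) || slen == 0L) stop("subject length missing or zero")
  pos_by_frame <- list()
  for (i in seq_len(nrow(hsps))) {
    p <- .hsp_query_positions(hsps$qstart[i], hsps$qend[i], hsps$frame[i],
                              hsps$qseq_aln[i])
    key <- as.character(hsps$frame[i])
    pos_by_frame[[key]] <- union(pos_by_frame[[key]], p)
  }
  sizes <- vapply(pos_by_frame, length, integer(1))
  dominant <- names(pos_by_frame)[which.max(sizes)]
  all_pos <- sort(unique(unlist(pos_by_frame)))
  n_res <- length(all_pos) / 3
  intervals <- do.call(rbind, lapply(names(pos_by_frame), function(f) {
    iv <- .positions_to_intervals(pos_by_frame[[f]])
    iv$frame <- suppressWarnings(as.integer(f))
    iv
  }))
  intervals <- intervals[order(intervals$start), , drop = FALSE]
  rownames(intervals) <- NULL
  structure(list(
    query_id = hsps$qseqid[1],
    subject_id = hsps$sseqid[1],
    db = hsps$db[1],
    subject_length = slen,
    query_length = hsps$qlen[1],
    frame = suppressWarnings(as.integer(dominant)),
    frame_conflict = length(pos_by_frame) > 1L,
    n_residues = n_res,
    ortholog_hit_ratio = n_res / slen,
    intervals = intervals
  ), class = "ortholog_annotation")
}

#' @export
print.ortholog_annotation <- function(x, ...) {
  cat(sprintf(
    "<ortholog_annotation> %s -> %s (%s): %.1f residues / %d = ratio %.3f%s\n",
    x$query_id, x$subject_id, x$db, x$n_residues, x$subject_length,
    x$ortholog_hit_ratio, if (x$frame_conflict) " [frame conflict]" else ""))
  invisible(x)
}

# Query nucleotide positions (1-based, plus strand) occupied by the
# non-gap residues of one HSP. For reverse frames qstart > qend and the
# alignment walks the plus strand downward.
.hsp_query_positions <- function(qstart, qend, frame, qseq_aln) {
  if (is.na(qseq_aln)) {
    warning("alignment row absent; counting the full query span ",
            "(gaps cannot be subtracted)", call. = FALSE)
    return(seq(min(qstart, qend), max(qstart, qend)))
  }
  chars <- strsplit(qseq_aln, "", fixed = TRUE)[[1]]
  r <- seq_len(sum(chars != "-")) - 1L   # 0-based non-gap residue ranks
  if (is.na(frame) || frame > 0L) {
    starts <- qstart + 3L * r
    if (max(starts) + 2L != qend) {
      stop("HSP coordinates inconsistent with alignment row for query span ",
           qstart, "-", qend)
    }
  } else {
    starts <- qstart - 3L * r - 2L
    if (min(starts) != qend) {
      stop("HSP coordinates inconsistent with alignment row for query span ",
           qstart, "-", qend)
    }
  }
  as.integer(sort(c(starts, starts + 1L, starts + 2L)))
}

.positions_to_intervals <- function(pos) {
  pos <- sort(unique(pos))
  if (!length(pos)) {
    return(data.frame(start = integer(), end = integer()))
  }
  brk <- c(0L, which(diff(pos) > 1L), length(pos))
  data.frame(start = pos[brk[-length(brk)] + 1L], end = pos[brk[-1L]])
}

#' Annotate unigenes with their best-subject hit regions
#'
#' Applies the e-value cutoff, selects each query's best subject within
#' one database via [best_hits()], and computes the ortholog hit ratio
#' and merged hit region for every annotated query.
#'
#' @param hits Data frame of hit records (extended dialect).
#' @param db Database label to annotate against; required when `hits`
#'   spans several databases.
#' @param e_cutoff E-value cutoff passed to [best_hits()].
#' @return A named list of [ortholog_hit_ratio()] annotations (class
#'   `ortholog_annotation_set`), indexed by query id. Convert with
#'   [annotation_table()].
#' @export
annotate_unigenes <- function(hits, db = NULL, e_cutoff = 1e-5) {
  if (!is.null(db)) hits <- hits[hits$db == db, , drop = FALSE]
  if (length(unique(hits$db)) > 1L) {
    stop("hits span several databases; pass db = <label>")
  }
  bh <- best_hits(hits, e_cutoff = e_cutoff)
  anns <- lapply(split(bh, bh$qseqid), ortholog_hit_ratio)
  structure(anns, class = "ortholog_annotation_set")
}

#' Flatten an annotation set to a data frame
#'
#' @param annotations An `ortholog_annotation_set` (see
#'   [annotate_unigenes()]) or list of `ortholog_annotation` objects.
#' @return Data frame with one row per annotated query: `query_id`,
#'   `subject_id`, `db`, `subject_length`, `frame`, `frame_conflict`,
#'   `n_residues`, `ortholog_hit_ratio`, `coding_length` (L_c, nt).
#' @export
annotation_table <- function(annotations) {
  rows <- lapply(annotations, function(a) {
    cr <- putative_coding_region(a)
    data.frame(query_id = a$query_id, subject_id = a$subject_id,
               db = a$db, subject_length = a$subject_length,
               frame = a$frame, frame_conflict = a$frame_conflict,
               n_residues = a$n_residues,
               ortholog_hit_ratio = a$ortholog_hit_ratio,
               coding_length = cr$coding_length,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Putative coding region of an annotated unigene
#'
#' The merged hit region of the best subject is taken as a conservative
#' estimate of the unigene's coding sequence. When HSPs disagree on
#' frame, only the frame with the largest merged region is kept and the
#' region is flagged.
#'
#' @param annotation An `ortholog_annotation` (see
#'   [ortholog_hit_ratio()]).
#' @return List with `intervals` (query nt intervals, 1-based inclusive),
#'   `frame`, `flagged` (frame conflict dropped some HSPs) and
#'   `coding_length` (total nt, `L_c`).
#' @export
putative_coding_region <- function(annotation) {
  iv <- annotation$intervals
  keep <- if (is.na(annotation$frame)) is.na(iv$frame)
          else !is.na(iv$frame) & iv$frame == annotation$frame
  iv <- iv[keep, , drop = FALSE]
  list(intervals = iv[, c("start", "end")],
       frame = annotation$frame,
       flagged = annotation$frame_conflict,
       coding_length = sum(iv$end - iv$start + 1L))
}
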