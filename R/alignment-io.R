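#' Read contig multiple alignments from the tabular layout format
#'
#' The layout format is plain text with one block per contig, blocks
#' separated by blank lines:
#' ```
#' CO <contig_id> <padded_consensus>
#' RD <read_id> <start_0based> <padded_read>
#' RD ...
#' ```
#' Pads are `-`. The format round-trips bit-exactly through
#' [write_contig_alignment()].
#'
#' @param path Path to a layout file.
#' @return List of [multiple_alignment()] objects.
#' @export
read_contig_alignment <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  alns <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur)) return(NULL)
    reads <- do.call(rbind, cur$reads)
    multiple_alignment(
      cur$contig_id, cur$consensus,
      data.frame(read_id = reads[, 1L], start = as.integer(reads[, 2L]),
                 seq = reads[, 3L], stringsAsFactors = FALSE)
    )
  }
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(trimws(line))) {
      a <- flush(cur)
      if (!is.null(a)) alns[[length(alns) + 1L]] <- a
      cur <- NULL
      next
    }
    tok <- strsplit(trimws(line), "[ \t]+")[[1]]
    if (tok[1] == "CO") {
      if (!is.null(cur)) {
        a <- flush(cur)
        if (!is.null(a)) alns[[length(alns) + 1L]] <- a
      }
      if (length(tok) != 3L) stop("line ", i, ": malformed CO record")
      cur <- list(contig_id = tok[2], consensus = tok[3], reads = list())
    } else if (tok[1] == "RD") {
      if (is.null(cur)) stop("line ", i, ": RD record before any CO record")
      if (length(tok) != 4L || is.na(suppressWarnings(as.integer(tok[3])))) {
        stop("line ", i, ": malformed RD record")
      }
      cur$reads[[length(cur$reads) + 1L]] <- tok[2:4]
    } else {
      stop("line ", i, ": unknown record type '", tok[1], "'")
    }
  }
  a <- flush(cur)
  if (!is.null(a)) alns[[length(alns) + 1L]] <- a
  alns
}

#' Write contig multiple alignments in the tabular layout format
#'
#' @param alignments A [multiple_alignment()] or list thereof.
#' @param path Output path.
#' @seealso [read_contig_alignment()]
#' @export
write_contig_alignment <- function(alignments, path) {
  alignments <- .as_alignment_list(alignments)
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(alignments)) {
    aln <- alignments[[k]]
    writeLines(paste("CO", aln$contig_id, aln$consensus), con)
    for (i in seq_len(nrow(aln$reads))) {
      writeLines(paste("RD", aln$reads$read_id[i], aln$reads$start[i],
                       aln$reads$seq[i]), con)
    }
    if (k < length(alignments)) writeLines("", con)
  }
  invisible(path)
}

.as_alignment_list <- function(x) {
  if (inherits(x, "multiple_alignment")) return(list(x))
  stopifnot(is.list(x), all(vapply(x, inherits, logical(1),
                                   "multiple_alignment")))
  x
}

#' Read contig multiple alignments from an ACE assembly file
#'
#' Minimal reader for CAP3-style ACE files: `CO` records introduce a padded
#' consensus (pads `*`), `AF` records give each read's 1-based padded
#' offset and orientation, and `RD` records give the padded read sequence.
#' Base-quality (`BQ`) and quality-clip (`QA`/`DS`) sections are skipped;
#' reads are used at their full padded length. Pads are converted to `-`
#' and offsets to the 0-based convention of [multiple_alignment()].
#'
#' Reads whose `AF` offset places part of the read outside the consensus
#' (assembler overhang) are trimmed to the consensus bounds.
#'
#' @param path Path to an ACE file.
#' @return List of [multiple_alignment()] objects.
#' @export
read_ace <- function(path) {
  if (!file.exists(path)) stop("ACE file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  i <- 1L
  n <- length(lines)
  read_seq_block <- function(i) {
    seq <- character()
    while (i <= n && nzchar(trimws(lines[i]))) {
      seq <- c(seq, trimws(lines[i]))
      i <- i + 1L
    }
    list(seq = paste(seq, collapse = ""), next_line = i)
  }
  contigs <- list()
  cur <- NULL
  while (i <= n) {
    tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(tok) == 0L || !nzchar(tok[1])) { i <- i + 1L; next }
    if (tok[1] == "CO") {
      if (!is.null(cur)) contigs[[length(contigs) + 1L]] <- cur
      blk <- read_seq_block(i + 1L)
      cur <- list(contig_id = tok[2], consensus = chartr("*", "-", blk$seq),
                  af = list(), rd = list())
      i <- blk$next_line
    } else if (tok[1] == "AF") {
      cur$af[[tok[2]]] <- as.integer(tok[4])
      i <- i + 1L
    } else if (tok[1] == "RD") {
      blk <- read_seq_block(i + 1L)
      cur$rd[[tok[2]]] <- chartr("*", "-", blk$seq)
      i <- blk$next_line
    } else if (tok[1] == "BQ") {
      blk <- read_seq_block(i + 1L)
      i <- blk$next_line
    } else {
      i <- i + 1L
    }
  }
  if (!is.null(cur)) contigs[[length(contigs) + 1L]] <- cur
  lapply(contigs, function(co) {
    ids <- names(co$rd)
    L <- nchar(co$consensus)
    rows <- lapply(ids, function(id) {
      off <- co$af[[id]]
      if (is.null(off)) stop("ACE contig '", co$contig_id,
                             "': read '", id, "' has no AF record")
      start <- off - 1L           # ACE offsets are 1-based
      seq <- co$rd[[id]]
      if (start < 0L) {           # clip assembler overhang
        seq <- substring(seq, 1L - start)
        start <- 0L
      }
      if (start + nchar(seq) > L) seq <- substring(seq, 1L, L - start)
      data.frame(read_id = id, start = start, seq = seq,
                 stringsAsFactors = FALSE)
    })
    multiple_alignment(co$contig_id, co$consensus, do.call(rbind, rows))
  })
}
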