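#' Read a FASTA file of unigene or protein sequences
#'
#' Reads a (wrapped or unwrapped) FASTA file and returns one record per
#' entry. Nucleotide sequences are uppercased and `U` is mapped to `T`;
#' protein sequences are uppercased only.
#'
#' @param path Path to a FASTA file.
#' @param type `"dna"` (default) or `"protein"`. Controls alphabet
#'   validation and the `U -> T` mapping.
#' @return A data frame with columns `id` (first whitespace-delimited token
#'   of the header) and `sequence`.
#' @export
read_fasta <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  if (file.size(path) == 0) {
    return(data.frame(id = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("malformed FASTA in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  if (any(!nzchar(ids))) {
    stop("malformed FASTA header (empty id) at record ",
         which(!nzchar(ids))[1], " of '", path, "'")
  }
  empty <- which(!nzchar(seqs))
  if (length(empty)) {
    stop("empty sequence for record '", ids[empty[1]], "' (record ",
         empty[1], ", near line ", .fasta_record_line(path, empty[1]),
         ") in '", path, "'")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id '", ids[anyDuplicated(ids)], "' in '",
         path, "'")
  }
  if (type == "dna") {
    seqs <- chartr("U", "T", seqs)
    bad <- grepl("[^ACGTN]", seqs)
    if (any(bad)) {
      stop("non-nucleotide characters in record '", ids[which(bad)[1]],
           "' of '", path, "'")
    }
  }
  data.frame(id = unname(ids), sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

# Line number of the n-th '>' header, for error messages only.
.fasta_record_line <- function(path, n) {
  heads <- grep("^>", readLines(path, warn = FALSE))
  if (n <= length(heads)) heads[n] else NA_integer_
}

#' Write sequences to a FASTA file
#'
#' @param records Data frame with columns `id` and `sequence` (as returned
#'   by [read_fasta()]), or a named character vector.
#' @param path Output path.
#' @param width Line-wrap width in characters.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (is.character(records)) {
    records <- data.frame(id = names(records), sequence = unname(records),
                          stringsAsFactors = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[i]), con)
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
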