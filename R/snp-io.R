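#' Write SNP calls as a TSV table
#'
#' The on-disk table uses 0-based unpadded positions (column `position0`);
#' the in-memory representation is 1-based. This writer is the single
#' point where that conversion happens for the tabular output.
#'
#' @param calls A `snp_calls` data frame (see [call_snps()]).
#' @param path Output path.
#' @export
write_snp_tsv <- function(calls, path) {
  out <- as.data.frame(calls)
  out$position0 <- out$position - 1L
  cols <- c("contig_id", "position0", "major_allele", "minor_allele",
            "n_A", "n_C", "n_G", "n_T", "coverage", "passes_loose",
            "passes_strict", "substitution_class", "coding_class")
  utils::write.table(out[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read SNP calls written by [write_snp_tsv()]
#'
#' @param path Path to the TSV file.
#' @return A `snp_calls` data frame with 1-based `position`.
#' @export
read_snp_tsv <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  out$position <- out$position0 + 1L
  out$position0 <- NULL
  class(out) <- c("snp_calls", "data.frame")
  out
}

#' Write SNP calls as a minimal VCF 4.2 file
#'
#' One record per call: `CHROM` is the contig id, `POS` the 1-based
#' unpadded position, `REF` the consensus base at the column and `ALT`
#' the minor allele (or the major allele when the consensus equals the
#' minor). Allele depths and criterion flags are carried in `INFO`.
#'
#' @param calls A `snp_calls` data frame.
#' @param alignments The [multiple_alignment()] list the calls came from
#'   (used to recover consensus bases).
#' @param path Output path.
#' @export
write_snp_vcf <- function(calls, alignments, path) {
  alignments <- .as_alignment_list(alignments)
  names(alignments) <- vapply(alignments, `[[`, character(1), "contig_id")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=estpop",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Non-gap non-N read depth at column\">",
    "##INFO=<ID=AC,Number=R,Type=Integer,Description=\"Read counts for REF and ALT alleles\">",
    "##INFO=<ID=LOOSE,Number=0,Type=Flag,Description=\"Passes loose criterion\">",
    "##INFO=<ID=STRICT,Number=0,Type=Flag,Description=\"Passes strict criterion\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  ), con)
  counts <- as.matrix(as.data.frame(calls)[, c("n_A", "n_C", "n_G", "n_T")])
  colnames(counts) <- c("A", "C", "G", "T")
  for (i in seq_len(nrow(calls))) {
    aln <- alignments[[calls$contig_id[i]]]
    if (is.null(aln)) stop("no alignment for contig '", calls$contig_id[i], "'")
    ref <- .consensus_chars(aln)[calls$column[i]]
    alt <- if (calls$minor_allele[i] == ref) calls$major_allele[i]
           else calls$minor_allele[i]
    ac_ref <- if (ref %in% colnames(counts)) counts[i, ref] else 0L
    info <- paste0(
      "DP=", calls$coverage[i],
      ";AC=", ac_ref, ",", counts[i, alt],
      if (calls$passes_loose[i]) ";LOOSE" else "",
      if (calls$passes_strict[i]) ";STRICT" else ""
    )
    writeLines(paste(calls$contig_id[i], calls$position[i], ".", ref, alt,
                     ".", "PASS", info, sep = "\t"), con)
  }
  invisible(path)
}
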