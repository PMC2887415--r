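.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

.revcomp <- function(x) {
  paste(rev(.COMPLEMENT[strsplit(x, "", fixed = TRUE)[[1]]]), collapse = "")
}

.translate_codon <- function(codon) {
  if (grepl("N", codon, fixed = TRUE)) return(NA_character_)
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Classify one SNP as synonymous, non-synonymous or noncoding
#'
#' The SNP position (1-based, unpadded query/unigene coordinates) is
#' tested against the putative coding region. Outside every interval the
#' class is `"noncoding"`. Inside, the codon containing the position is
#' reconstructed on the frame's codon lattice (anchored at the interval
#' start for forward frames, at the interval end for reverse frames,
#' where codons are read on the reverse complement), the two alleles are
#' substituted in turn, and the translations are compared under the
#' standard genetic code. A codon truncated at a region edge, or one
#' containing `N`, yields `"unassigned"`.
#'
#' @param position 1-based unpadded position on the query sequence.
#' @param allele1,allele2 The two alleles observed at the position
#'   (plus-strand bases; order is irrelevant).
#' @param coding_region A region from [putative_coding_region()], or an
#'   `ortholog_annotation` (converted internally), or `NULL` for an
#'   unannotated unigene (returns `"unassigned"`).
#' @param query_sequence The unigene (unpadded consensus) sequence.
#' @return One of `"synonymous"`, `"non_synonymous"`, `"noncoding"`,
#'   `"unassigned"`.
#' @export
classify_snp <- function(position, allele1, allele2, coding_region,
                         query_sequence) {
  if (is.null(coding_region)) return("unassigned")
  if (inherits(coding_region, "ortholog_annotation")) {
    coding_region <- putative_coding_region(coding_region)
  }
  iv <- coding_region$intervals
  hit <- which(iv$start <= position & position <= iv$end)
  if (!length(hit)) return("noncoding")
  s <- iv$start[hit[1]]; e <- iv$end[hit[1]]
  frame <- coding_region$frame
  if (is.na(frame)) return("unassigned")
  if (frame > 0L) {
    codon_start <- s + 3L * ((position - s) %/% 3L)
    codon_end <- codon_start + 2L
  } else {
    codon_end <- e - 3L * ((e - position) %/% 3L)
    codon_start <- codon_end - 2L
  }
  if (codon_start < s || codon_end > e ||
      codon_end > nchar(query_sequence)) {
    return("unassigned")
  }
  codon <- substring(query_sequence, codon_start, codon_end)
  off <- position - codon_start + 1L
  c1 <- codon; substring(c1, off, off) <- toupper(allele1)
  c2 <- codon; substring(c2, off, off) <- toupper(allele2)
  if (frame < 0L) {
    c1 <- .revcomp(c1)
    c2 <- .revcomp(c2)
  }
  aa1 <- .translate_codon(c1)
  aa2 <- .translate_codon(c2)
  if (is.na(aa1) || is.na(aa2)) return("unassigned")
  if (aa1 == aa2) "synonymous" else "non_synonymous"
}

#' Fill the coding class of SNP calls from best-hit annotations
#'
#' Maps every call onto its unigene's putative coding region (contig
#' unpadded coordinates are the query coordinates: the unigene is the
#' query) and classifies it with [classify_snp()]. Calls in unigenes
#' without an annotation stay `"unassigned"`.
#'
#' @param calls A `snp_calls` data frame (see [call_snps()]).
#' @param annotations An `ortholog_annotation_set` (see
#'   [annotate_unigenes()]).
#' @param unigenes Unigene sequences: a named character vector or a
#'   data frame with columns `id` and `sequence`.
#' @return `calls` with `coding_class` filled in.
#' @export
classify_snps <- function(calls, annotations, unigenes) {
  seqs <- .as_named_sequences(unigenes)
  regions <- lapply(annotations, putative_coding_region)
  cls <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    id <- calls$contig_id[i]
    region <- regions[[id]]
    if (is.null(region)) {
      cls[i] <- "unassigned"
      next
    }
    if (!id %in% names(seqs)) {
      stop("no sequence available for annotated unigene '", id, "'")
    }
    cls[i] <- classify_snp(calls$position[i], calls$major_allele[i],
                           calls$minor_allele[i], region, seqs[[id]])
  }
  calls$coding_class <- cls
  calls
}

.as_named_sequences <- function(x) {
  if (is.data.frame(x)) {
    out <- x$sequence
    names(out) <- x$id
    return(out)
  }
  stopifnot(is.character(x), !is.null(names(x)))
  x
}

#' Per-query species-hit flags across protein databases
#'
#' For each query, records whether it has at least one hit below the
#' e-value cutoff in each database.
#'
#' @param queries Character vector of all query (unigene) ids, including
#'   those with no hits.
#' @param hits Data frame of hit records with a `db` column.
#' @param e_cutoff E-value cutoff (exclusive).
#' @param databases Database labels to profile; defaults to the sorted
#'   labels present in `hits`.
#' @return Data frame with one row per query: `query_id`, one logical
#'   column per database, and `n_databases_hit`.
#' @export
species_hit_profile <- function(queries, hits, e_cutoff = 1e-5,
                                databases = NULL) {
  if (is.null(databases)) databases <- sort(unique(hits$db))
  hits <- hits[hits$evalue < e_cutoff & hits$db %in% databases, ,
               drop = FALSE]
  out <- data.frame(query_id = queries, stringsAsFactors = FALSE)
  for (db in databases) {
    out[[db]] <- queries %in% hits$qseqid[hits$db == db]
  }
  out$n_databases_hit <- rowSums(as.matrix(out[, databases, drop = FALSE]))
  out
}

#' Venn-region counts of a species-hit profile
#'
#' Tallies queries by the exact combination of databases hit. Queries
#' hitting no database are reported under the empty combination `"none"`.
#' When a `classes` vector is given (e.g. high-coverage contig /
#' low-coverage contig / singleton), per-class counts are added.
#'
#' @param profile Output of [species_hit_profile()].
#' @param classes Optional named character vector mapping query id to a
#'   class label.
#' @return Data frame with `combination` (database labels joined by
#'   `+`), `n`, and one count column per class level if `classes` is
#'   given.
#' @export
venn_counts <- function(profile, classes = NULL) {
  dbs <- setdiff(names(profile), c("query_id", "n_databases_hit"))
  flags <- as.matrix(profile[, dbs, drop = FALSE])
  combo <- apply(flags, 1L, function(f) {
    if (!any(f)) "none" else paste(dbs[f], collapse = "+")
  })
  tab <- table(combo)
  out <- data.frame(combination = names(tab), n = as.integer(tab),
                    stringsAsFactors = FALSE)
  if (!is.null(classes)) {
    cls <- classes[profile$query_id]
    for (lv in sort(unique(stats::na.omit(as.character(cls))))) {
      out[[paste0("n_", lv)]] <- vapply(out$combination, function(cb) {
        sum(combo == cb & !is.na(cls) & cls == lv)
      }, integer(1), USE.NAMES = FALSE)
    }
  }
  out[order(-out$n), , drop = FALSE]
}

#' Coverage classes for unigenes (high/low contig, singleton)
#'
#' Contigs at or above the median contig coverage are `"high_coverage"`,
#' those below are `"low_coverage"`; singletons (coverage 1.0 by
#' definition) form their own class.
#'
#' @param alignments List of [multiple_alignment()] objects (the
#'   contigs).
#' @param singleton_ids Character vector of singleton unigene ids.
#' @return Named character vector of class labels, indexed by unigene id.
#' @export
unigene_coverage_classes <- function(alignments, singleton_ids = character()) {
  alignments <- .as_alignment_list(alignments)
  cov <- vapply(alignments, average_coverage, numeric(1))
  ids <- vapply(alignments, `[[`, character(1), "contig_id")
  med <- stats::median(cov)
  cls <- ifelse(cov < med, "low_coverage", "high_coverage")
  names(cls) <- ids
  c(cls, stats::setNames(rep("singleton", length(singleton_ids)),
                         singleton_ids))
}

#' Mean ortholog hit ratio by coverage stratum
#'
#' Stratifies annotated unigenes into contigs below the median contig
#' coverage, contigs at or above it, and singletons, and reports the
#' mean ortholog hit ratio per stratum. Completeness of assembly is
#' expected to increase with coverage, so the above-median stratum
#' should not trail the below-median one on well-behaved data.
#'
#' @param annotations Data frame from [annotation_table()] (or an
#'   annotation set, converted internally).
#' @param alignments List of [multiple_alignment()] objects (contigs).
#' @param singleton_ids Character vector of singleton unigene ids.
#' @return Data frame with `stratum`, `n`, `mean_ratio`.
#' @export
ohr_by_stratum <- function(annotations, alignments,
                           singleton_ids = character()) {
  if (inherits(annotations, "ortholog_annotation_set")) {
    annotations <- annotation_table(annotations)
  }
  cls <- unigene_coverage_classes(alignments, singleton_ids)
  strata <- c("low_coverage", "high_coverage", "singleton")
  ann_cls <- cls[annotations$query_id]
  do.call(rbind, lapply(strata, function(s) {
    r <- annotations$ortholog_hit_ratio[!is.na(ann_cls) & ann_cls == s]
    data.frame(stratum = s, n = length(r),
               mean_ratio = if (length(r)) mean(r) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

#' Mean ortholog hit ratio by subject-length bin
#'
#' Completeness of gene discovery typically decreases with the length of
#' the reference protein; this summarises that trend.
#'
#' @param annotations Data frame from [annotation_table()] (or an
#'   annotation set).
#' @param bin_edges Strictly increasing subject-length bin edges
#'   (residues); left-closed, right-open, last bin closed.
#' @return Data frame with `bin_low`, `bin_high`, `n`, `mean_ratio`.
#' @export
ohr_by_subject_length <- function(annotations, bin_edges) {
  if (inherits(annotations, "ortholog_annotation_set")) {
    annotations <- annotation_table(annotations)
  }
  if (any(diff(bin_edges) <= 0)) stop("bin edges must be strictly increasing")
  idx <- findInterval(annotations$subject_length, bin_edges,
                      rightmost.closed = TRUE)
  nb <- length(bin_edges) - 1L
  do.call(rbind, lapply(seq_len(nb), function(b) {
    r <- annotations$ortholog_hit_ratio[idx == b]
    data.frame(bin_low = bin_edges[b], bin_high = bin_edges[b + 1L],
               n = length(r),
               mean_ratio = if (length(r)) mean(r) else NA_real_)
  }))
}
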