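#' Build the best-hit association graph over unigenes and proteins
#'
#' Each unigene is a node; each reference protein that is some unigene's
#' best hit is a node namespaced by its database label (`db:protein`).
#' Undirected edges connect each unigene to its best same-species
#' unigene match and to its best protein hit per database. Self-matches
#' are suppressed and each unigene contributes at most one edge per
#' relation, so the graph encodes single-linkage similarity at the
#' best-hit level.
#'
#' @param unigene_ids Character vector of all unigene ids (no-hit
#'   unigenes become isolated nodes).
#' @param unigene_best Optional data frame with columns
#'   `qseqid`/`sseqid`: each unigene's best unigene match (see
#'   [best_hit_table()] with `exclude_self = TRUE`). Targets must be in
#'   `unigene_ids`.
#' @param protein_best Optional named list of data frames (one per
#'   database label) with columns `qseqid`/`sseqid`: each unigene's best
#'   protein hit in that database.
#' @return An [igraph::graph] with vertex attributes `type`
#'   (`"unigene"`/`"protein"`) and edge attribute `relation`.
#' @export
build_association_graph <- function(unigene_ids, unigene_best = NULL,
                                    protein_best = list()) {
  stopifnot(!anyDuplicated(unigene_ids))
  edges <- list()
  if (!is.null(unigene_best) && nrow(unigene_best)) {
    ub <- unigene_best[unigene_best$qseqid != unigene_best$sseqid, ,
                       drop = FALSE]
    if (anyDuplicated(ub$qseqid)) {
      stop("unigene_best: more than one best match for a query")
    }
    missing <- setdiff(c(ub$qseqid, ub$sseqid), unigene_ids)
    if (length(missing)) {
      stop("unigene_best refers to unknown unigene(s): ",
           paste(utils::head(missing, 3), collapse = ", "))
    }
    if (nrow(ub)) {
      edges[["unigene"]] <- data.frame(from = ub$qseqid, to = ub$sseqid,
                                       relation = "best_unigene",
                                       stringsAsFactors = FALSE)
    }
  }
  if (length(protein_best)) {
    stopifnot(!is.null(names(protein_best)),
              all(nzchar(names(protein_best))))
    for (db in names(protein_best)) {
      pb <- protein_best[[db]]
      if (!nrow(pb)) next
      if (anyDuplicated(pb$qseqid)) {
        stop("protein_best[['", db, "']]: more than one best hit ",
             "for a query")
      }
      missing <- setdiff(pb$qseqid, unigene_ids)
      if (length(missing)) {
        stop("protein_best[['", db, "']] refers to unknown unigene(s): ",
             paste(utils::head(missing, 3), collapse = ", "))
      }
      edges[[db]] <- data.frame(from = pb$qseqid,
                                to = paste0(db, ":", pb$sseqid),
                                relation = paste0("best_", db),
                                stringsAsFactors = FALSE)
    }
  }
  edges <- do.call(rbind, edges)
  protein_nodes <- if (!is.null(edges)) {
    unique(edges$to[grepl(":", edges$to, fixed = TRUE)])
  } else {
    character()
  }
  vertices <- data.frame(
    name = c(unigene_ids, protein_nodes),
    type = c(rep("unigene", length(unigene_ids)),
             rep("protein", length(protein_nodes))),
    stringsAsFactors = FALSE
  )
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        relation = character(), stringsAsFactors = FALSE)
  }
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = vertices)
}

#' Cluster unigenes as connected components of the association graph
#'
#' Unigenes in the same connected component form a cluster. Protein
#' nodes connect unigenes but are not counted as members; components
#' containing only protein nodes are dropped.
#'
#' @param graph Graph from [build_association_graph()].
#' @return Object of class `cluster_report`: list with `clusters` (list
#'   of unigene-id character vectors, largest first), `n_clusters`,
#'   `n_singleton_clusters`, and `membership` (named integer vector,
#'   cluster index per unigene).
#' @export
cluster_unigenes <- function(graph) {
  comp <- igraph::components(graph)
  type <- igraph::vertex_attr(graph, "type")
  name <- igraph::vertex_attr(graph, "name")
  is_uni <- type == "unigene"
  clusters <- split(name[is_uni], comp$membership[is_uni])
  clusters <- clusters[order(-lengths(clusters),
                             vapply(clusters, min, character(1)))]
  names(clusters) <- NULL
  membership <- rep(seq_along(clusters), lengths(clusters))
  names(membership) <- unlist(clusters)
  structure(list(
    clusters = clusters,
    n_clusters = length(clusters),
    n_singleton_clusters = sum(lengths(clusters) == 1L),
    membership = membership
  ), class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf(
    "<cluster_report> %d clusters over %d unigenes (%d singleton clusters",
    x$n_clusters, length(x$membership), x$n_singleton_clusters))
  if (x$n_clusters > 0) {
    cat(sprintf(", largest %d members", length(x$clusters[[1]])))
  }
  cat(")\n")
  invisible(x)
}

#' Composition of one cluster
#'
#' Breaks a cluster down into contigs vs singletons and, per database,
#' the members whose hits are confined to that database ("only" hits),
#' the pattern characteristic of contamination families such as
#' unassembled rRNA.
#'
#' @param report A `cluster_report` from [cluster_unigenes()].
#' @param kind Named character vector mapping unigene id to
#'   `"contig"`/`"singleton"`.
#' @param profile Optional [species_hit_profile()] data frame for
#'   per-database "only" counts.
#' @param which_cluster Index of the cluster to describe (default 1, the
#'   largest).
#' @return List with `size`, `n_contigs`, `n_singletons` and, when a
#'   profile is given, a data frame `only_hits` with per-database counts
#'   split by member kind.
#' @export
cluster_composition <- function(report, kind, profile = NULL,
                                which_cluster = 1L) {
  members <- report$clusters[[which_cluster]]
  k <- kind[members]
  out <- list(size = length(members),
              n_contigs = sum(!is.na(k) & k == "contig"),
              n_singletons = sum(!is.na(k) & k == "singleton"))
  if (!is.null(profile)) {
    dbs <- setdiff(names(profile), c("query_id", "n_databases_hit"))
    idx <- match(members, profile$query_id)
    flags <- as.matrix(profile[idx, dbs, drop = FALSE])
    out$only_hits <- do.call(rbind, lapply(dbs, function(db) {
      only <- !is.na(idx) & flags[, db] &
        rowSums(flags, na.rm = TRUE) == 1L
      data.frame(db = db,
                 n_only = sum(only),
                 contigs_only = sum(only & !is.na(k) & k == "contig"),
                 singletons_only = sum(only & !is.na(k) & k == "singleton"),
                 stringsAsFactors = FALSE)
    }))
  }
  out
}

#' Write a cluster report to TSV and JSON summaries
#'
#' @param report A `cluster_report` from [cluster_unigenes()].
#' @param tsv_path Path for the member table (`cluster_id`, `member`).
#' @param json_path Optional path for a JSON summary (`n_clusters`,
#'   `n_singleton_clusters`, `largest_cluster_size`).
#' @export
write_cluster_report <- function(report, tsv_path, json_path = NULL) {
  tab <- data.frame(
    cluster_id = rep(seq_along(report$clusters),
                     lengths(report$clusters)),
    member = unlist(report$clusters),
    stringsAsFactors = FALSE
  )
  utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      n_clusters = report$n_clusters,
      n_singleton_clusters = report$n_singleton_clusters,
      largest_cluster_size = if (report$n_clusters > 0) {
        length(report$clusters[[1]])
      } else {
        0L
      }
    ), json_path, auto_unbox = TRUE)
  }
  invisible(tsv_path)
}
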