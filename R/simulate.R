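#' Configuration for the synthetic EST assembly generator
#'
#' Defaults describe a pooled population EST study on a 454-style
#' platform: ~400 bp reads, per-contig depth following a lognormal
#' expression distribution with median 3.3x and mean ~10x, a low
#' substitution error rate, and K = 16 population haplotypes.
#'
#' `theta` is the population-scaled per-site mutation rate in the
#' Watterson sense: a site segregates among the K haplotypes with
#' probability `theta * H_{K-1}`, so `theta` is what a depth-corrected
#' diversity statistic should recover. At a segregating site the derived
#' allele is carried by `k` of the K haplotypes, with `k` drawn from the
#' neutral frequency spectrum (`P(k) proportional to 1/k`,
#' `allele_freq_model = "sfs"`) or fixed at `K/2`
#' (`allele_freq_model = "balanced"`, a 50/50 site).
#'
#' @param seed Integer RNG seed; identical seeds give identical output.
#' @param n_genes Number of genes (transcripts) to simulate.
#' @param n_haplotypes Number of population haplotypes K.
#' @param theta Per-site scaled mutation rate (see above).
#' @param allele_freq_model `"sfs"` or `"balanced"`.
#' @param protein_length_mean,protein_length_sd,protein_length_min
#'   Reference protein length distribution (residues; truncated normal).
#' @param utr5_length,utr3_length,utr_sd UTR length distributions (nt;
#'   truncated normal, rounded, floor 0).
#' @param depth_meanlog,depth_sdlog Lognormal per-contig depth
#'   distribution (defaults give median 3.3x, mean ~10x).
#' @param read_length_mean,read_length_sd,read_length_min Read length
#'   distribution (nt); reads are clamped to the transcript length.
#' @param full_length_reads When `TRUE` every read spans its whole
#'   transcript, giving exactly uniform coverage (used for calibration
#'   studies).
#' @param error_rate Per-base iid substitution error probability.
#' @param singleton_fraction Probability that a gene is represented by a
#'   single unassembled read (a singleton unigene) instead of a contig.
#' @param db Database label attached to the truth-derived hit records.
#' @param rrna_family Optional list (`n_reads`, `divergence`, and
#'   optionally `length`, `subject_id`, `db`) planting a high-diversity
#'   unassemblable read family whose members all hit one protein hub --
#'   the structural signature of rRNA contamination picked up by
#'   association-graph clustering.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 200L,
                       n_haplotypes = 16L,
                       theta = 0.002,
                       allele_freq_model = c("sfs", "balanced"),
                       protein_length_mean = 250,
                       protein_length_sd = 80,
                       protein_length_min = 60,
                       utr5_length = 60,
                       utr3_length = 120,
                       utr_sd = 20,
                       depth_meanlog = log(3.3),
                       depth_sdlog = 1.49,
                       read_length_mean = 400,
                       read_length_sd = 50,
                       read_length_min = 100,
                       full_length_reads = FALSE,
                       error_rate = 0.001,
                       singleton_fraction = 0.35,
                       db = "bmori",
                       rrna_family = NULL) {
  allele_freq_model <- match.arg(allele_freq_model)
  stopifnot(n_genes >= 1L, n_haplotypes >= 2L, theta >= 0, theta <= 1,
            error_rate >= 0, error_rate <= 1,
            singleton_fraction >= 0, singleton_fraction <= 1,
            protein_length_min >= 1, read_length_min >= 1,
            depth_sdlog >= 0, protein_length_sd >= 0, utr_sd >= 0,
            read_length_sd >= 0)
  if (theta * harmonic_number(n_haplotypes - 1L) >= 1) {
    stop("infeasible config: theta * H_{K-1} >= 1 (every site would ",
         "segregate)")
  }
  structure(as.list(environment()), class = "sim_config")
}

.BASES <- c("A", "C", "G", "T")

.rnorm_int <- function(n, mean, sd, min) {
  pmax(as.integer(round(stats::rnorm(n, mean, sd))), as.integer(min))
}

.random_protein <- function(len) {
  aas <- setdiff(unique(unname(Biostrings::GENETIC_CODE)), "*")
  paste(c("M", sample(aas, len - 1L, replace = TRUE)), collapse = "")
}

# Back-translate a protein with uniformly chosen synonymous codons and
# append a stop codon.
.backtranslate <- function(protein) {
  code <- Biostrings::GENETIC_CODE
  by_aa <- split(names(code), unname(code))
  aas <- strsplit(protein, "", fixed = TRUE)[[1]]
  codons <- vapply(aas, function(a) {
    opts <- by_aa[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1), USE.NAMES = FALSE)
  stop_codon <- by_aa[["*"]][sample.int(3L, 1L)]
  paste(c(codons, stop_codon), collapse = "")
}

.translate_nt <- function(nt) {
  n_cod <- nchar(nt) %/% 3L
  codons <- substring(nt, 3L * seq_len(n_cod) - 2L, 3L * seq_len(n_cod))
  paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

# Hit record for a unigene that covers transcript window
# [w0 + 1, w0 + wl] (0-based offset w0): the HSP spans the full codons
# of the CDS that lie inside the window, in unigene coordinates.
# NULL when no full codon is covered.
.window_hit <- function(unigene_id, protein_id, db, w0, wl, uni_seq,
                        protein, cds_start, P) {
  cds_res_end <- cds_start + 3L * P - 1L
  a <- max(w0 + 1L, cds_start)
  b <- min(w0 + wl, cds_res_end)
  if (b < a + 2L) return(NULL)
  i_lo <- as.integer(ceiling((a - cds_start) / 3))
  i_hi <- as.integer(floor((b - cds_start - 2L) / 3))
  if (i_hi < i_lo) return(NULL)
  qstart <- (cds_start + 3L * i_lo) - w0
  qend <- (cds_start + 3L * i_hi + 2L) - w0
  n_res <- i_hi - i_lo + 1L
  data.frame(
    qseqid = unigene_id, sseqid = protein_id, db = db,
    evalue = 1e-120, bitscore = round(2 * n_res),
    qstart = qstart, qend = qend, sstart = i_lo + 1L, send = i_hi + 1L,
    frame = ((qstart - 1L) %% 3L) + 1L, qlen = wl, slen = P,
    qseq_aln = .translate_nt(substring(uni_seq, qstart, qend)),
    sseq_aln = substring(protein, i_lo + 1L, i_hi + 1L),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic population-level EST assembly with known truth
#'
#' Simulates a reference proteome with coding transcripts (UTR + CDS +
#' UTR), plants segregating sites among K haplotypes, samples reads with
#' per-contig depth variation and iid substitution errors, and emits the
#' objects every pipeline stage consumes -- contig multiple alignments
#' (true read placements; no assembler is run, so the analysis is tested
#' in isolation from assembler behaviour), unigene and protein
#' sequences, truth-derived hit records with correct frames and subject
#' lengths, and truth tables keyed to all of them.
#'
#' Reads of a contig are placed with chained random offsets so that
#' consecutive reads overlap; the contig is the covered transcript
#' window, and all unigene-level coordinates (alignments, hit records,
#' `unigene_position` in the site truth table) are relative to that
#' window. The contig consensus carries the majority allele at each
#' planted site (ties favour the ancestral base); alignments contain no
#' pads since errors are substitution-only.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, all outputs are also
#'   written as text files (see [write_simulation()]).
#' @return List of class `est_simulation`: `config`, `alignments` (list
#'   of [multiple_alignment()], contigs only), `unigenes` (data frame
#'   `id`/`sequence`/`kind`), `proteins` (data frame `id`/`sequence`),
#'   `hits` (extended-dialect data frame), and `truth` (list of data
#'   frames `genes`, `sites`, `reads`).
#' @export
simulate_est <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  K <- cfg$n_haplotypes
  p_seg <- cfg$theta * harmonic_number(K - 1L)
  min_overlap <- 30L

  plens <- .rnorm_int(cfg$n_genes, cfg$protein_length_mean,
                      cfg$protein_length_sd, cfg$protein_length_min)
  u5s <- .rnorm_int(cfg$n_genes, cfg$utr5_length, cfg$utr_sd, 0L)
  u3s <- .rnorm_int(cfg$n_genes, cfg$utr3_length, cfg$utr_sd, 0L)

  alignments <- list()
  unigenes <- list()
  proteins <- list()
  hits <- list()
  t_genes <- list()
  t_sites <- list()
  t_reads <- list()

  for (g in seq_len(cfg$n_genes)) {
    gene_id <- sprintf("g%04d", g)
    protein_id <- paste0("p_", gene_id)
    P <- plens[g]
    protein <- .random_protein(P)
    cds <- .backtranslate(protein)              # 3P + 3 nt incl. stop
    u5 <- u5s[g]; u3 <- u3s[g]
    tx <- paste0(paste(sample(.BASES, u5, replace = TRUE), collapse = ""),
                 cds,
                 paste(sample(.BASES, u3, replace = TRUE), collapse = ""))
    L <- nchar(tx)
    tx_chars <- strsplit(tx, "", fixed = TRUE)[[1]]
    cds_start <- u5 + 1L
    if (cfg$read_length_min > L) {
      stop("infeasible config: minimum read length (", cfg$read_length_min,
           ") exceeds transcript length (", L, ") for gene ", gene_id)
    }

    # --- planted segregating sites ------------------------------------
    site_pos <- which(stats::runif(L) < p_seg)
    n_sites <- length(site_pos)
    anc <- tx_chars[site_pos]
    der <- vapply(anc, function(b) sample(setdiff(.BASES, b), 1L),
                  character(1), USE.NAMES = FALSE)
    k_der <- if (n_sites == 0L) {
      integer()
    } else if (cfg$allele_freq_model == "balanced") {
      rep(K %/% 2L, n_sites)
    } else {
      ks <- seq_len(K - 1L)
      sample(ks, n_sites, replace = TRUE, prob = 1 / ks)
    }
    carriers <- lapply(k_der, function(k) sample.int(K, k))

    # consensus-level sequence: majority allele at each site
    cons_chars <- tx_chars
    maj_der <- k_der > K / 2
    cons_chars[site_pos[maj_der]] <- der[maj_der]

    # --- reads (chained placement so consecutive reads overlap) -------
    singleton <- stats::runif(1) < cfg$singleton_fraction
    depth <- stats::rlnorm(1, cfg$depth_meanlog, cfg$depth_sdlog)
    draw_len <- function() {
      if (cfg$full_length_reads) L
      else min(L, .rnorm_int(1L, cfg$read_length_mean,
                             cfg$read_length_sd, cfg$read_length_min))
    }
    read_rows <- list()
    total_bases <- 0
    covered_end <- 0L
    first_start <- 0L
    i <- 0L
    repeat {
      i <- i + 1L
      rl <- draw_len()
      if (i == 1L) {
        s0 <- if (cfg$full_length_reads) 0L
              else sample.int(L - rl + 1L, 1L) - 1L
        first_start <- s0
      } else {
        lo <- max(first_start, covered_end - rl)
        hi <- min(L - rl, covered_end - min_overlap)
        if (hi < lo) hi <- lo
        s0 <- lo + sample.int(hi - lo + 1L, 1L) - 1L
      }
      hap <- sample.int(K, 1L)
      chars <- tx_chars[(s0 + 1L):(s0 + rl)]
      if (n_sites) {
        inside <- which(site_pos > s0 & site_pos <= s0 + rl)
        for (j in inside) {
          if (hap %in% carriers[[j]]) chars[site_pos[j] - s0] <- der[j]
        }
      }
      if (cfg$error_rate > 0) {
        err <- which(stats::runif(rl) < cfg$error_rate)
        for (e in err) chars[e] <- sample(setdiff(.BASES, chars[e]), 1L)
      }
      read_rows[[i]] <- list(read_id = sprintf("%s_r%03d", gene_id, i),
                             start = s0, seq = paste(chars, collapse = ""),
                             hap = hap)
      total_bases <- total_bases + rl
      covered_end <- max(covered_end, s0 + rl)
      if (singleton) break
      span <- covered_end - first_start
      if (i >= 2L && total_bases >= depth * span) break
    }

    unigene_id <- if (singleton) paste0("sgl_", gene_id)
                  else paste0("ctg_", gene_id)
    kind <- if (singleton) "singleton" else "contig"
    w0 <- first_start
    wl <- covered_end - first_start

    if (singleton) {
      uni_seq <- read_rows[[1L]]$seq            # the read, errors and all
    } else {
      uni_seq <- paste(cons_chars[(w0 + 1L):(w0 + wl)], collapse = "")
      reads_df <- data.frame(
        read_id = vapply(read_rows, `[[`, character(1), "read_id"),
        start = vapply(read_rows, `[[`, integer(1), "start") - w0,
        seq = vapply(read_rows, `[[`, character(1), "seq"),
        stringsAsFactors = FALSE
      )
      alignments[[length(alignments) + 1L]] <-
        multiple_alignment(unigene_id, uni_seq, reads_df)
    }

    hit <- .window_hit(unigene_id, protein_id, cfg$db, w0, wl, uni_seq,
                       protein, cds_start, P)
    if (!is.null(hit)) hits[[length(hits) + 1L]] <- hit

    unigenes[[length(unigenes) + 1L]] <- data.frame(
      id = unigene_id, sequence = uni_seq, kind = kind,
      stringsAsFactors = FALSE
    )
    proteins[[length(proteins) + 1L]] <- data.frame(
      id = protein_id, sequence = protein, stringsAsFactors = FALSE
    )
    t_genes[[length(t_genes) + 1L]] <- data.frame(
      gene_id = gene_id, unigene_id = unigene_id, kind = kind,
      transcript_length = L, protein_id = protein_id, protein_length = P,
      utr5 = u5, cds_start = cds_start,
      cds_res_end = cds_start + 3L * P - 1L,
      window_start = w0 + 1L, window_end = w0 + wl,
      stringsAsFactors = FALSE
    )
    if (n_sites) {
      in_window <- site_pos > w0 & site_pos <= w0 + wl
      uni_pos <- ifelse(in_window, site_pos - w0, NA_integer_)
      in_hit <- rep(FALSE, n_sites)
      true_class <- rep(NA_character_, n_sites)
      if (!is.null(hit)) {
        in_hit <- !is.na(uni_pos) & uni_pos >= hit$qstart &
          uni_pos <= hit$qend
        for (j in which(in_hit)) {
          c_start_u <- hit$qstart +
            3L * ((uni_pos[j] - hit$qstart) %/% 3L)
          c_start <- c_start_u + w0                   # transcript coords
          codon <- paste(cons_chars[c_start:(c_start + 2L)],
                         collapse = "")
          off <- site_pos[j] - c_start + 1L
          c1 <- codon; substring(c1, off, off) <- anc[j]
          c2 <- codon; substring(c2, off, off) <- der[j]
          true_class[j] <-
            if (Biostrings::GENETIC_CODE[[c1]] ==
                Biostrings::GENETIC_CODE[[c2]]) "synonymous"
            else "non_synonymous"
        }
      }
      t_sites[[length(t_sites) + 1L]] <- data.frame(
        gene_id = gene_id, unigene_id = unigene_id, position = site_pos,
        unigene_position = uni_pos, ancestral = anc, derived = der,
        derived_count = k_der, derived_freq = k_der / K,
        consensus_allele = cons_chars[site_pos],
        in_hit_region = in_hit, true_class = true_class,
        stringsAsFactors = FALSE
      )
    }
    t_reads[[length(t_reads) + 1L]] <- data.frame(
      read_id = vapply(read_rows, `[[`, character(1), "read_id"),
      gene_id = gene_id, unigene_id = unigene_id,
      haplotype = vapply(read_rows, `[[`, integer(1), "hap"),
      start = vapply(read_rows, `[[`, integer(1), "start") + 1L,
      length = nchar(vapply(read_rows, `[[`, character(1), "seq")),
      stringsAsFactors = FALSE
    )
  }

  # --- optional unassemblable high-diversity family -------------------
  if (!is.null(cfg$rrna_family)) {
    rr <- cfg$rrna_family
    rr_len <- if (is.null(rr$length)) 1200L else as.integer(rr$length)
    rr_db <- if (is.null(rr$db)) "herato" else rr$db
    rr_subj <- if (is.null(rr$subject_id)) "rrna_hub" else rr$subject_id
    base <- sample(.BASES, rr_len, replace = TRUE)
    hub_res <- rr_len %/% 3L
    aas <- setdiff(unique(unname(Biostrings::GENETIC_CODE)), "*")
    hub_prot <- paste(sample(aas, hub_res, replace = TRUE), collapse = "")
    proteins[[length(proteins) + 1L]] <- data.frame(
      id = rr_subj, sequence = hub_prot, stringsAsFactors = FALSE
    )
    for (i in seq_len(rr$n_reads)) {
      chars <- base
      mut <- which(stats::runif(rr_len) < rr$divergence)
      for (m in mut) chars[m] <- sample(setdiff(.BASES, chars[m]), 1L)
      uid <- sprintf("sgl_rrna%03d", i)
      unigenes[[length(unigenes) + 1L]] <- data.frame(
        id = uid, sequence = paste(chars, collapse = ""),
        kind = "singleton", stringsAsFactors = FALSE
      )
      hits[[length(hits) + 1L]] <- data.frame(
        qseqid = uid, sseqid = rr_subj, db = rr_db,
        evalue = 1e-30, bitscore = 120,
        qstart = 1L, qend = 3L * hub_res, sstart = 1L, send = hub_res,
        frame = 1L, qlen = rr_len, slen = hub_res,
        qseq_aln = hub_prot, sseq_aln = hub_prot, stringsAsFactors = FALSE
      )
    }
  }

  sim <- structure(list(
    config = cfg,
    alignments = alignments,
    unigenes = do.call(rbind, unigenes),
    proteins = do.call(rbind, proteins),
    hits = do.call(rbind, hits),
    truth = list(
      genes = do.call(rbind, t_genes),
      sites = if (length(t_sites)) do.call(rbind, t_sites) else
        data.frame(gene_id = character(), unigene_id = character(),
                   position = integer(), unigene_position = integer(),
                   ancestral = character(), derived = character(),
                   derived_count = integer(), derived_freq = numeric(),
                   consensus_allele = character(),
                   in_hit_region = logical(), true_class = character(),
                   stringsAsFactors = FALSE),
      reads = do.call(rbind, t_reads)
    )
  ), class = "est_simulation")
  if (!is.null(out_dir)) write_simulation(sim, out_dir)
  sim
}

#' @export
print.est_simulation <- function(x, ...) {
  cat(sprintf(
    "<est_simulation> %d unigenes (%d contigs, %d singletons), %d planted sites\n",
    nrow(x$unigenes), length(x$alignments),
    sum(x$unigenes$kind == "singleton"), nrow(x$truth$sites)))
  invisible(x)
}

#' Replace truth hits by partial HSPs with drawn completeness
#'
#' Emulates incomplete transcript discovery: each contig's hit is
#' replaced by an HSP covering a random subject prefix or suffix whose
#' relative length (the completeness) is drawn from
#' `completeness_range`, coupled negatively to subject length so that
#' longer reference proteins are recovered less completely -- the trend
#' seen in real assemblies. The resulting ortholog hit ratio equals the
#' drawn completeness up to one-residue quantisation (and up to the
#' residues actually contained in the contig).
#'
#' Uses the current RNG state; call `set.seed()` first for
#' reproducibility.
#'
#' @param sim An `est_simulation` from [simulate_est()].
#' @param completeness_range Length-2 numeric range for the drawn
#'   completeness.
#' @return `sim` with modified `hits` and an extra truth table
#'   `completeness` (`unigene_id`, `drawn`, `achieved`,
#'   `subject_length`).
#' @export
truncate_hits <- function(sim, completeness_range = c(0.2, 1.0)) {
  stopifnot(inherits(sim, "est_simulation"),
            length(completeness_range) == 2L,
            completeness_range[1] > 0, completeness_range[2] <= 1,
            completeness_range[1] <= completeness_range[2])
  genes <- sim$truth$genes
  ctg <- genes[genes$kind == "contig", , drop = FALSE]
  ctg <- ctg[ctg$unigene_id %in% sim$hits$qseqid, , drop = FALSE]
  if (!nrow(ctg)) return(sim)
  u <- stats::runif(nrow(ctg))
  r <- (rank(ctg$protein_length, ties.method = "average") - 0.5) /
    nrow(ctg)
  v <- (u + (1 - r)) / 2                       # anti-coupled to length
  drawn <- completeness_range[1] + diff(completeness_range) * v
  achieved <- numeric(nrow(ctg))
  for (i in seq_len(nrow(ctg))) {
    gid <- ctg$unigene_id[i]
    row <- which(sim$hits$qseqid == gid & sim$hits$db == sim$config$db)
    if (length(row) != 1L) next
    h <- sim$hits[row, ]
    P <- ctg$protein_length[i]
    avail <- h$send - h$sstart + 1L
    k <- max(1L, min(avail, as.integer(round(drawn[i] * P))))
    achieved[i] <- k / P
    if (stats::runif(1) < 0.5) {               # subject prefix
      sstart <- h$sstart; send <- h$sstart + k - 1L
      qstart <- h$qstart; qend <- h$qstart + 3L * k - 1L
    } else {                                   # subject suffix
      sstart <- h$send - k + 1L; send <- h$send
      qend <- h$qend; qstart <- h$qend - 3L * k + 1L
    }
    uni <- sim$unigenes$sequence[sim$unigenes$id == gid]
    sim$hits[row, c("qstart", "qend", "sstart", "send")] <-
      list(qstart, qend, sstart, send)
    sim$hits$frame[row] <- ((qstart - 1L) %% 3L) + 1L
    sim$hits$qseq_aln[row] <- .translate_nt(substring(uni, qstart, qend))
    sim$hits$sseq_aln[row] <- substring(
      sim$proteins$sequence[sim$proteins$id == ctg$protein_id[i]],
      sstart, send)
    sim$hits$bitscore[row] <- round(2 * k)
  }
  sim$truth$completeness <- data.frame(
    unigene_id = ctg$unigene_id, drawn = drawn, achieved = achieved,
    subject_length = ctg$protein_length, stringsAsFactors = FALSE
  )
  sim
}

#' Write a simulation to plain-text files
#'
#' Emits `alignments.txt` (layout format), `unigenes.fasta`,
#' `proteins.fasta`, `hits.tsv` (extended dialect), the truth tables as
#' TSV, and `config.json`.
#'
#' @param sim An `est_simulation`.
#' @param dir Output directory (created if needed).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_contig_alignment(sim$alignments, file.path(dir, "alignments.txt"))
  write_fasta(sim$unigenes, file.path(dir, "unigenes.fasta"))
  write_fasta(sim$proteins, file.path(dir, "proteins.fasta"))
  write_hits(sim$hits, file.path(dir, "hits.tsv"))
  for (nm in names(sim$truth)) {
    utils::write.table(sim$truth[[nm]],
                       file.path(dir, paste0("truth_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  cfg <- unclass(sim$config)
  cfg$rrna_family <- if (is.null(cfg$rrna_family)) NULL
                     else as.list(cfg$rrna_family)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, null = "null")
  invisible(dir)
}
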