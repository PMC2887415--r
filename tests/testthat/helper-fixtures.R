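# Shared fixtures and independent test-side oracles.

# Alignment from equal-length read strings all starting at column 1.
make_aln <- function(consensus, reads, contig_id = "c1",
                     starts = rep(0L, length(reads)),
                     ids = sprintf("r%02d", seq_along(reads))) {
  multiple_alignment(contig_id, consensus,
                     data.frame(read_id = ids, start = starts,
                                seq = reads, stringsAsFactors = FALSE))
}

# Random padded alignment; the first read spans the whole consensus so
# no column is uncovered.
random_alignment <- function(id = "c1", min_len = 20L, max_len = 60L) {
  len <- sample(min_len:max_len, 1L)
  cons <- sample(c("A", "C", "G", "T", "A", "C", "G", "T", "-"), len,
                 replace = TRUE)
  if (all(cons == "-")) cons[1] <- "A"
  alphabet <- c("A", "C", "G", "T", "A", "C", "G", "T", "N", "-")
  n_reads <- sample(3:12, 1L)
  rows <- lapply(seq_len(n_reads), function(i) {
    if (i == 1L) {
      s <- 0L; l <- len
    } else {
      s <- sample(0:(len - 5L), 1L)
      l <- sample(5:(len - s), 1L)
    }
    data.frame(read_id = sprintf("%s_r%d", id, i), start = s,
               seq = paste(sample(alphabet, l, replace = TRUE),
                           collapse = ""),
               stringsAsFactors = FALSE)
  })
  multiple_alignment(id, paste(cons, collapse = ""), do.call(rbind, rows))
}

# Brute-force SNP caller: re-derives every column profile by scanning
# reads one character at a time. Deliberately naive and independent of
# the package's vectorised path.
brute_force_snps <- function(aln, strict_min_frac = 0.25,
                             strict_min_cov = 6, loose_min_reads = 2) {
  cons <- strsplit(aln$consensus, "")[[1]]
  bases <- c("A", "C", "G", "T")
  out <- list()
  unpadded <- 0L
  for (col in seq_along(cons)) {
    if (cons[col] != "-") unpadded <- unpadded + 1L
    counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
    for (i in seq_len(nrow(aln$reads))) {
      s <- aln$reads$start[i]
      l <- nchar(aln$reads$seq[i])
      if (col > s && col <= s + l) {
        ch <- substr(aln$reads$seq[i], col - s, col - s)
        if (ch %in% bases) counts[ch] <- counts[ch] + 1L
      }
    }
    if (cons[col] == "-") next
    if (sum(counts > 0L) < 2L) next
    ord <- order(-counts, bases)
    major <- bases[ord[1]]; minor <- bases[ord[2]]
    cov <- sum(counts)
    out[[length(out) + 1L]] <- data.frame(
      column = col, position = unpadded, major = major, minor = minor,
      coverage = cov,
      loose = counts[major] >= loose_min_reads &
        counts[minor] >= loose_min_reads,
      strict = cov >= strict_min_cov &
        counts[minor] / cov >= strict_min_frac,
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(column = integer(), position = integer(),
                      major = character(), minor = character(),
                      coverage = integer(), loose = logical(),
                      strict = logical(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Union-find with path compression; independent oracle for connected
# components.
union_find_partition <- function(nodes, from, to) {
  parent <- seq_along(nodes)
  idx <- function(x) match(x, nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  fi <- idx(from); ti <- idx(to)
  for (k in seq_along(fi)) {
    a <- find(fi[k]); b <- find(ti[k])
    if (a != b) parent[a] <- b
  }
  vapply(seq_along(nodes), find, integer(1))
}

# Canonical form of a partition: sorted list of sorted member vectors.
canonical_partition <- function(members, groups) {
  p <- lapply(split(members, groups), sort)
  names(p) <- NULL
  p[order(vapply(p, `[`, character(1), 1L))]
}

# Extended-dialect hit record with sane defaults for hand fixtures.
make_hit <- function(qseqid = "q1", sseqid = "s1", db = "bmori",
                     evalue = 1e-20, bitscore = 100, qstart = 1L,
                     qend = 30L, sstart = 1L, send = 10L, frame = 1L,
                     qlen = 100L, slen = 10L,
                     qseq_aln = strrep("M", 10L),
                     sseq_aln = strrep("M", 10L)) {
  data.frame(qseqid = qseqid, sseqid = sseqid, db = db, evalue = evalue,
             bitscore = bitscore, qstart = qstart, qend = qend,
             sstart = sstart, send = send, frame = frame, qlen = qlen,
             slen = slen, qseq_aln = qseq_aln, sseq_aln = sseq_aln,
             stringsAsFactors = FALSE)
}
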