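test_that("hit files round-trip and malformed rows are rejected", {
  sim <- simulate_est(sim_config(seed = 3, n_genes = 8))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hits(sim$hits, f)
  back <- read_hits(f)
  expect_equal(back, sim$hits)

  bad <- sim$hits[1, ]
  bad$sseq_aln <- paste0(bad$sseq_aln, "MM")
  write_hits(bad, f)
  expect_error(read_hits(f), "unequal length")

  writeLines(c("qseqid\tsseqid", "a\tb"), f)
  expect_error(read_hits(f), "expected header columns")
})

test_that("standard 12-column tabular input is accepted with degraded fields", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("q1\ts1\t98.5\t100\t1\t0\t1\t300\t1\t100\t1e-30\t200", f)
  hits <- read_hits(f, dialect = "standard", db = "bmori")
  expect_equal(hits$qseqid, "q1")
  expect_equal(hits$db, "bmori")
  expect_true(is.na(hits$qseq_aln))
})

test_that("best_hits applies the cutoff and deterministic tie-breaks", {
  hits <- rbind(
    make_hit(sseqid = "s1", evalue = 1e-10),
    make_hit(sseqid = "s2", evalue = 1e-8)
  )
  expect_equal(unique(best_hits(hits)$sseqid), "s1")

  # e >= cutoff is discarded: nothing at 1e-4, nor exactly at 1e-5
  expect_equal(nrow(best_hits(make_hit(evalue = 1e-4))), 0L)
  expect_equal(nrow(best_hits(make_hit(evalue = 1e-5))), 0L)
  expect_equal(nrow(best_hits(make_hit(evalue = 0.9e-5))), 1L)

  # equal e-values: higher bit score wins
  hits <- rbind(
    make_hit(sseqid = "s1", evalue = 1e-10, bitscore = 50),
    make_hit(sseqid = "s2", evalue = 1e-10, bitscore = 60)
  )
  expect_equal(unique(best_hits(hits)$sseqid), "s2")

  # equal e-value and bits: lexicographically smaller subject id
  hits <- rbind(
    make_hit(sseqid = "sB", evalue = 1e-10, bitscore = 50),
    make_hit(sseqid = "sA", evalue = 1e-10, bitscore = 50)
  )
  expect_equal(unique(best_hits(hits)$sseqid), "sA")

  # all HSPs of the winning subject are retained
  hits <- rbind(
    make_hit(sseqid = "s1", evalue = 1e-10, qstart = 1, qend = 30),
    make_hit(sseqid = "s1", evalue = 1e-7, qstart = 100, qend = 129,
             sstart = 50, send = 59, slen = 100),
    make_hit(sseqid = "s2", evalue = 1e-8)
  )
  expect_equal(nrow(best_hits(hits)), 2L)

  # self-match exclusion keeps the next best non-self subject
  hits <- rbind(
    make_hit(qseqid = "u1", sseqid = "u1", evalue = 1e-50),
    make_hit(qseqid = "u1", sseqid = "u2", evalue = 1e-20)
  )
  expect_equal(best_hit_table(hits, exclude_self = TRUE)$sseqid, "u2")
})

test_that("ortholog hit ratio counts non-gap query residues per subject residue", {
  # gapless HSP covering all of a 100-residue subject
  full <- make_hit(qstart = 1, qend = 300, sstart = 1, send = 100,
                   qlen = 400, slen = 100,
                   qseq_aln = strrep("M", 100), sseq_aln = strrep("M", 100))
  ann <- ortholog_hit_ratio(full)
  expect_identical(ann$ortholog_hit_ratio, 1.0)
  expect_equal(ann$intervals$start, 1L)
  expect_equal(ann$intervals$end, 300L)

  # 90 query residues + 10 query gaps against a 100-residue subject
  gapped <- make_hit(qstart = 1, qend = 270, sstart = 1, send = 100,
                     qlen = 400, slen = 100,
                     qseq_aln = paste0(strrep("M", 45), strrep("-", 10),
                                       strrep("L", 45)),
                     sseq_aln = strrep("A", 100))
  expect_equal(ortholog_hit_ratio(gapped)$ortholog_hit_ratio, 0.9)

  # two disjoint HSPs of 30 and 20 residues over a 100-residue subject
  two <- rbind(
    make_hit(qstart = 1, qend = 90, sstart = 1, send = 30, slen = 100,
             qseq_aln = strrep("M", 30), sseq_aln = strrep("M", 30)),
    make_hit(qstart = 100, qend = 159, sstart = 41, send = 60, slen = 100,
             qseq_aln = strrep("M", 20), sseq_aln = strrep("M", 20))
  )
  expect_equal(ortholog_hit_ratio(two)$ortholog_hit_ratio, 0.5)

  # duplicating an HSP never changes the ratio (union idempotence)
  expect_equal(ortholog_hit_ratio(rbind(two, two[1, ]))$ortholog_hit_ratio,
               0.5)

  # overlap counted once
  over <- rbind(
    make_hit(qstart = 1, qend = 90, sstart = 1, send = 30, slen = 100,
             qseq_aln = strrep("M", 30), sseq_aln = strrep("M", 30)),
    make_hit(qstart = 61, qend = 120, sstart = 21, send = 40, slen = 100,
             qseq_aln = strrep("M", 20), sseq_aln = strrep("M", 20))
  )
  expect_equal(ortholog_hit_ratio(over)$ortholog_hit_ratio, 0.4)
})

test_that("reverse-frame HSPs resolve to plus-strand intervals", {
  rev <- make_hit(qstart = 29, qend = 15, frame = -2L, sstart = 1,
                  send = 5, qlen = 30, slen = 10,
                  qseq_aln = strrep("M", 5), sseq_aln = strrep("M", 5))
  ann <- ortholog_hit_ratio(rev)
  expect_equal(ann$frame, -2L)
  expect_equal(ann$intervals$start, 15L)
  expect_equal(ann$intervals$end, 29L)
  expect_equal(ann$ortholog_hit_ratio, 0.5)
})

test_that("putative coding region converts coordinates and handles conflicts", {
  # HSP at query nt 10..309 in frame +1 -> one 300 nt region
  hit <- make_hit(qstart = 10, qend = 309, sstart = 1, send = 100,
                  slen = 120, qseq_aln = strrep("M", 100),
                  sseq_aln = strrep("M", 100))
  cr <- putative_coding_region(ortholog_hit_ratio(hit))
  expect_equal(cr$intervals$start, 10L)
  expect_equal(cr$intervals$end, 309L)
  expect_equal(cr$coding_length, 300L)
  expect_false(cr$flagged)

  # conflicting frames: the larger union wins and the region is flagged
  conflict <- rbind(
    make_hit(qstart = 1, qend = 90, sstart = 1, send = 30, slen = 100,
             qseq_aln = strrep("M", 30), sseq_aln = strrep("M", 30)),
    make_hit(qstart = 200, qend = 214, frame = 2L, sstart = 60, send = 64,
             slen = 100, qseq_aln = strrep("M", 5), sseq_aln = strrep("M", 5))
  )
  ann <- ortholog_hit_ratio(conflict)
  expect_true(ann$frame_conflict)
  cr <- putative_coding_region(ann)
  expect_equal(cr$frame, 1L)
  expect_equal(cr$coding_length, 90L)
  expect_true(cr$flagged)
})

test_that("SNPs classify as synonymous, non-synonymous, noncoding or unassigned", {
  region <- list(intervals = data.frame(start = 1L, end = 3L), frame = 1L)
  # GGA -> GGG at codon position 3: both glycine
  expect_equal(classify_snp(3L, "A", "G", region, "GGA"), "synonymous")
  # ATG -> ATA: Met -> Ile
  expect_equal(classify_snp(3L, "G", "A", region, "ATG"), "non_synonymous")
  # outside every interval
  expect_equal(classify_snp(10L, "A", "C", region, "GGAACCGGTT"), "noncoding")
  # no annotation at all
  expect_equal(classify_snp(3L, "A", "G", NULL, "GGA"), "unassigned")
  # codon truncated at the region edge
  trunc <- list(intervals = data.frame(start = 10L, end = 308L), frame = 1L)
  expect_equal(classify_snp(308L, "A", "G", trunc, strrep("A", 400)),
               "unassigned")
  # codon containing N
  expect_equal(classify_snp(3L, "A", "G", region, "GNA"), "unassigned")
})

test_that("reverse-frame SNPs are classified on the reverse complement", {
  region <- list(intervals = data.frame(start = 15L, end = 29L), frame = -2L)
  qseq <- paste0(strrep("A", 26), "CAT")   # plus-strand codon 27..29 = CAT
  # CAT|rev-comp ATG (Met) vs CAC|rev-comp GTG (Val)
  expect_equal(classify_snp(29L, "T", "C", region, qseq), "non_synonymous")
  # synonymous on the minus strand: TAA vs CAA reverse-complement to
  # TTA and TTG, both leucine
  qseq2 <- paste0(strrep("A", 26), "TAA")
  expect_equal(classify_snp(27L, "T", "C", region, qseq2), "synonymous")
})

test_that("classify_snps joins calls to annotations by unigene", {
  aln <- make_aln("GGATT", c(rep("GGATT", 4), rep("GGGTT", 3)),
                  contig_id = "u1")
  calls <- call_snps(aln, "any")     # A/G at position 3
  hits <- make_hit(qseqid = "u1", qstart = 1, qend = 3, sstart = 1,
                   send = 1, slen = 1, qlen = 5, qseq_aln = "G",
                   sseq_aln = "G")
  anns <- annotate_unigenes(hits)
  out <- classify_snps(calls, anns, c(u1 = "GGATT"))
  expect_equal(out$coding_class, "synonymous")  # GGA vs GGG

  # unannotated unigene stays unassigned
  out2 <- classify_snps(calls, annotate_unigenes(make_hit(qseqid = "zz")),
                        c(u1 = "GGATT"))
  expect_equal(out2$coding_class, "unassigned")
})

test_that("species hit profiles and Venn counts conserve queries", {
  hits <- rbind(
    make_hit(qseqid = "q1", db = "bmori"),
    make_hit(qseqid = "q1", db = "herato"),
    make_hit(qseqid = "q1", db = "dmel"),
    make_hit(qseqid = "q2", db = "bmori"),
    make_hit(qseqid = "q3", db = "herato"),
    make_hit(qseqid = "q3", db = "dmel"),
    make_hit(qseqid = "q4", db = "bmori", evalue = 1e-3)  # above cutoff
  )
  prof <- species_hit_profile(paste0("q", 1:5), hits)
  expect_equal(prof$n_databases_hit, c(3, 1, 2, 0, 0))

  vn <- venn_counts(prof)
  expect_equal(sum(vn$n), 5L)
  expect_equal(vn$n[vn$combination == "none"], 2L)
  expect_equal(vn$n[vn$combination == "bmori+dmel+herato"], 1L)
  expect_equal(vn$n[vn$combination == "dmel+herato"], 1L)
  expect_equal(sum(vn$n[vn$combination != "none"]),
               sum(prof$n_databases_hit > 0))

  cls <- c(q1 = "contig", q2 = "singleton", q3 = "contig",
           q4 = "singleton", q5 = "contig")
  vc <- venn_counts(prof, cls)
  expect_equal(vc$n_contig + vc$n_singleton, vc$n)
})

test_that("mean hit ratio stratifies by median contig coverage", {
  cons <- strrep("A", 90)
  low <- make_aln(cons, rep(cons, 2), contig_id = "lowc")    # 2x
  high <- make_aln(cons, rep(cons, 10), contig_id = "highc") # 10x
  anns <- data.frame(
    query_id = c("lowc", "highc", "sg1"),
    subject_id = "s", db = "bmori", subject_length = 100L,
    frame = 1L, frame_conflict = FALSE, n_residues = 30,
    ortholog_hit_ratio = c(0.2, 0.6, 0.4),
    coding_length = 90L, stringsAsFactors = FALSE
  )
  strat <- ohr_by_stratum(anns, list(low, high), singleton_ids = "sg1")
  expect_equal(strat$mean_ratio[strat$stratum == "low_coverage"], 0.2)
  expect_equal(strat$mean_ratio[strat$stratum == "high_coverage"], 0.6)
  expect_equal(strat$mean_ratio[strat$stratum == "singleton"], 0.4)
})

test_that("deeper coverage strata reach higher completeness on simulated data", {
  sim <- simulate_est(sim_config(seed = 5, n_genes = 300,
                                 singleton_fraction = 0.2))
  anns <- annotate_unigenes(sim$hits, db = "bmori")
  strat <- ohr_by_stratum(anns, sim$alignments,
                          sim$unigenes$id[sim$unigenes$kind == "singleton"])
  hi <- strat$mean_ratio[strat$stratum == "high_coverage"]
  lo <- strat$mean_ratio[strat$stratum == "low_coverage"]
  sgl <- strat$mean_ratio[strat$stratum == "singleton"]
  expect_gte(hi, lo)
  expect_lt(sgl, hi)     # single reads recover the least of a transcript

  # subject-length stratification: single-read unigenes discover less of
  # longer proteins
  bins <- ohr_by_subject_length(anns, c(0, 200, 300, 1000))
  expect_equal(sum(bins$n), nrow(annotation_table(anns)))
})
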