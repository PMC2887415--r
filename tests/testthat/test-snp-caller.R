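test_that("loose and strict criteria follow the published rules", {
  # column 1: {A:5, C:3}, consensus A -> loose and strict
  # (minor 3/8 = 0.375 >= 0.25, coverage 8 >= 6)
  aln <- make_aln("AT", c(rep("AT", 5), rep("CT", 3)))
  calls <- call_snps(aln, "any")
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$column, 1L)
  expect_equal(calls$major_allele, "A")
  expect_equal(calls$minor_allele, "C")
  expect_equal(calls$coverage, 8L)
  expect_true(calls$passes_loose)
  expect_true(calls$passes_strict)

  # {A:9, C:1}: minor < 2 reads fails loose; 0.1 < 0.25 fails strict
  aln <- make_aln("AT", c(rep("AT", 9), "CT"))
  calls <- call_snps(aln, "any")
  expect_equal(nrow(calls), 1L)
  expect_false(calls$passes_loose)
  expect_false(calls$passes_strict)
  expect_equal(nrow(call_snps(aln, "loose")), 0L)

  # {A:8}: one allele, no candidate at all
  aln <- make_aln("AT", rep("AT", 8))
  expect_equal(nrow(call_snps(aln, "any")), 0L)

  # consensus pad: {A:2, C:2} under '-' is never a SNP
  aln <- make_aln("A-T", c("AAT", "AAT", "ACT", "ACT"))
  calls <- call_snps(aln, "any")
  expect_false(2L %in% calls$column)
})

test_that("coverage excludes pads and N, and minor ties break alphabetically", {
  # column 2: A x3, T x3, N x1, - x1 -> coverage 6, minor 3/6 strict
  aln <- make_aln("AAT", c(rep("AAT", 3), rep("ATT", 3), "ANT", "A-T"))
  calls <- call_snps(aln, "any")
  row <- calls[calls$column == 2L, ]
  expect_equal(row$coverage, 6L)
  expect_true(row$passes_strict)

  # {A:3, C:3}: tie for major/minor resolved alphabetically
  aln <- make_aln("AT", c(rep("AT", 3), rep("CT", 3)))
  row <- call_snps(aln, "any")
  expect_equal(row$major_allele, "A")
  expect_equal(row$minor_allele, "C")

  # tri-allelic {A:4, C:3, G:2}: one call on the top two alleles
  aln <- make_aln("AT", c(rep("AT", 4), rep("CT", 3), rep("GT", 2)))
  row <- call_snps(aln, "any")
  expect_equal(nrow(row), 1L)
  expect_equal(c(row$major_allele, row$minor_allele), c("A", "C"))
  expect_equal(row$coverage, 9L)
})

test_that("unpadded positions skip pad columns", {
  aln <- make_aln("A-CT", c("A-CT", "A-GT", "A-GT", "A-CT"))
  calls <- call_snps(aln, "any")
  expect_equal(calls$column, 3L)
  expect_equal(calls$position, 2L)
})

test_that("substitution classes enumerate to 2 transitions and 4 transversions", {
  expect_equal(classify_substitution("A", "G"), "transition")
  expect_equal(classify_substitution("A", "T"), "transversion")
  pairs <- combn(c("A", "C", "G", "T"), 2)
  cls <- classify_substitution(pairs[1, ], pairs[2, ])
  expect_equal(sum(cls == "transition"), 2L)
  expect_equal(sum(cls == "transversion"), 4L)
  expect_error(classify_substitution("A", "A"), "differ")
  expect_error(classify_substitution("A", "X"), "A,C,G,T")
})

test_that("strict calls are a subset of loose calls at default thresholds", {
  set.seed(101)
  for (i in 1:200) {
    calls <- call_snps(suppressWarnings(random_alignment()), "any")
    expect_true(all(!calls$passes_strict | calls$passes_loose))
  }
})

test_that("vectorised caller matches the brute-force column recount", {
  set.seed(202)
  for (i in 1:60) {
    aln <- suppressWarnings(random_alignment(min_len = 40, max_len = 50))
    got <- call_snps(aln, "any")
    want <- brute_force_snps(aln)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$column, want$column)
      expect_equal(got$position, want$position)
      expect_equal(got$major_allele, want$major)
      expect_equal(got$minor_allele, want$minor)
      expect_equal(got$coverage, want$coverage)
      expect_equal(got$passes_loose, unname(want$loose))
      expect_equal(got$passes_strict, unname(want$strict))
    }
  }
})

test_that("variant regions chain polymorphic columns by the gap rule", {
  # two polymorphic columns with 5 monomorphic between; haplotypes
  # A....C and G....T on 3 reads each -> one region spanning 7 columns
  h1 <- "AAAAAAC"; h2 <- "GAAAAAT"
  aln <- make_aln(strrep("A", 7), c(rep(h1, 3), rep(h2, 3)))
  reg <- detect_variant_regions(aln)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$start_column, 1L)
  expect_equal(reg$end_column, 7L)
  expect_equal(reg$length_bp, 7L)
  expect_equal(reg$n_variants, 2L)
  expect_equal(sort(unname(reg$support[[1]])), c(3L, 3L))

  # 12 monomorphic columns between two polymorphic ones: the chain
  # breaks (12 > 11) and single-column chains are not reported
  cons <- strrep("A", 14)
  h1 <- paste0("C", strrep("A", 12), "G")
  h2 <- paste0("T", strrep("A", 12), "T")
  aln <- make_aln(cons, c(rep(h1, 3), rep(h2, 3)))
  expect_equal(nrow(detect_variant_regions(aln)), 0L)

  # exactly 11 between: still one region
  cons <- strrep("A", 13)
  h1 <- paste0("C", strrep("A", 11), "G")
  h2 <- paste0("T", strrep("A", 11), "T")
  aln <- make_aln(cons, c(rep(h1, 3), rep(h2, 3)))
  expect_equal(nrow(detect_variant_regions(aln)), 1L)

  # monomorphic contig
  aln <- make_aln("ACGT", rep("ACGT", 5))
  expect_equal(nrow(detect_variant_regions(aln)), 0L)
})

test_that("variant support requires full-span reads and pads count as states", {
  # pad alleles form a state; a partial read cannot vote for a variant
  cons <- "ACGTACG"
  reads <- c(rep("ACGTACG", 2), rep("A-GTA-G", 2), "ACG")
  aln <- make_aln(cons, reads)
  reg <- detect_variant_regions(aln)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$n_variants, 2L)          # the short read is ignored
  expect_equal(sum(unlist(reg$support)), 4L)
})

test_that("snp_rate_summary uses contigs-with-SNPs as denominator", {
  cons <- strrep("A", 500)
  a1 <- make_aln(cons, c(rep(cons, 4), rep(paste0("C", strrep("A", 499)), 4)),
                 contig_id = "c1")
  a2 <- make_aln(cons, rep(cons, 6), contig_id = "c2")   # monomorphic
  calls <- call_snps(list(a1, a2), "any")
  s <- snp_rate_summary(list(a1, a2), calls, "strict")
  expect_equal(s$n_snps, 1L)
  expect_equal(s$n_contigs_with_snps, 1L)
  expect_equal(s$bp_in_contigs_with_snps, 500)
  expect_equal(s$snps_per_kb, 2)
  expect_equal(s$transversions + s$transitions, s$n_snps)

  empty <- snp_rate_summary(list(a2), call_snps(a2, "any"), "strict")
  expect_equal(empty$n_snps, 0L)
  expect_true(is.na(empty$snps_per_kb))
})

test_that("snp tables round-trip and VCF output is well formed", {
  aln <- make_aln("GATT", c(rep("GATT", 4), rep("GCTT", 3)),
                  contig_id = "ctg9")
  calls <- call_snps(aln, "any")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_snp_tsv(calls, f)
  tab <- utils::read.delim(f)
  expect_equal(tab$position0, calls$position - 1L)

  back <- read_snp_tsv(f)
  expect_equal(back$position, calls$position)
  expect_equal(back$coding_class, calls$coding_class)

  v <- withr::local_tempfile(fileext = ".vcf")
  write_snp_vcf(calls, aln, v)
  lines <- readLines(v)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, nrow(calls))
  fields <- strsplit(body[1], "\t")[[1]]
  expect_equal(fields[1], "ctg9")
  expect_equal(fields[2], "2")        # 1-based position
  expect_equal(fields[4], "A")        # consensus base as REF
  expect_equal(fields[5], "C")
  expect_match(fields[8], "DP=7;AC=4,3")
})
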