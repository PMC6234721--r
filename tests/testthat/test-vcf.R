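test_that("a single-sample VCF line becomes one normalized called record", {
  p <- write_vcf(vcf_line(100, "A", "C", qual = "50"))
  cs <- read_single_sample_vcf(p, "S1")
  expect_s3_class(cs, "sample_callset")
  r <- cs$records
  expect_equal(nrow(r), 1)
  expect_equal(r$pos, 100L)
  expect_equal(r$record_class, "substitution")
  expect_equal(r$qual, 50)
  expect_equal(r$genotype_status, "called")
  expect_equal(r$raw_line, vcf_line(100, "A", "C", qual = "50"))
})

test_that("input-contract violations raise errors naming the problem", {
  p <- write_vcf(vcf_line(100, "A", "A,T"))
  expect_error(read_single_sample_vcf(p, "S1"), "multi-allelic")
  p2 <- write_vcf(vcf_line(100, "A", "<DEL>"))
  expect_error(read_single_sample_vcf(p2, "S1"), "symbolic")
  p3 <- write_vcf(paste(vcf_line(100, "A", "C"), "0/1", sep = "\t"),
                  samples = c("S1", "S2"))
  expect_error(read_single_sample_vcf(p3, "S1"), "single sample")
  expect_error(read_single_sample_vcf(tempfile(), "S1"), "not found")
})

test_that("missing genotypes and padded records are handled on read", {
  p <- write_vcf(c(vcf_line(100, "GTCA", "ATCA"),
                   vcf_line(200, "AT", "A", gt = "./.", qual = ".")))
  cs <- read_single_sample_vcf(p, "S1")
  expect_equal(cs$records$ref[1], "G")   # trimmed to minimal representation
  expect_equal(cs$records$alt[1], "A")
  expect_equal(cs$records$pos[1], 100L)
  expect_equal(cs$records$genotype_status, c("called", "missing"))
  expect_true(is.na(cs$records$qual[2]))
})

test_that("multi-sample splitting includes records by carried ALT allele", {
  body <- c(paste(vcf_line(100, "A", "C"), "0/0", "./.", sep = "\t"),
            paste(vcf_line(300, "T", "TG"), "1/1", "0/1", sep = "\t"))
  p <- write_vcf(body, samples = c("S1", "S2", "S3"))
  css <- split_multi_sample(p)
  expect_named(css, c("S1", "S2", "S3"))
  expect_equal(css$S1$records$pos, c(100L, 300L))
  expect_equal(css$S2$records$pos, 300L)       # 0/0 at 100 is dropped
  expect_equal(css$S3$records$pos, c(100L, 300L))
  expect_equal(css$S3$records$genotype_status, c("missing", "called"))
  # split raw lines are the corresponding single-sample lines
  expect_equal(css$S2$records$raw_line, vcf_line(300, "T", "TG", gt = "1/1"))

  one <- write_vcf(vcf_line(100, "A", "C"))
  expect_equal(split_multi_sample(one)$S1$records,
               read_single_sample_vcf(one, "S1")$records)
})

test_that("splitting conserves records per the genotype-inclusion rule", {
  set.seed(5)
  gts <- c("0/0", "0/1", "1/1", "./.", "0|1")
  n_sites <- 40; samples <- paste0("S", 1:5)
  gt_mat <- matrix(sample(gts, n_sites * 5, replace = TRUE), nrow = n_sites)
  body <- vapply(seq_len(n_sites), function(i)
    paste(c("chr1", i * 10, ".", "A", "T", "50", "PASS", ".", "GT",
            gt_mat[i, ]), collapse = "\t"),
    character(1))
  p <- write_vcf(body, samples = samples)
  css <- split_multi_sample(p)
  for (j in seq_along(samples)) {
    carried <- grepl("1", gt_mat[, j])          # oracle: GT contains allele 1
    missing <- gt_mat[, j] == "./."
    expect_equal(sort(css[[j]]$records$pos[
      css[[j]]$records$genotype_status == "called"]),
      sort((seq_len(n_sites) * 10L)[carried]))
    expect_equal(sum(css[[j]]$records$genotype_status == "missing"),
                 sum(missing))
  }
})

test_that("parsed fixed fields agree with vcfR on a fixture", {
  body <- c(vcf_line(100, "A", "C", qual = "12.5"),
            vcf_line(250, "TAAG", "T", qual = "33"),
            vcf_line(900, "G", "GTT", qual = "."))
  p <- write_vcf(body)
  ours <- read_single_sample_vcf(p, "S1")$records
  v <- vcfR::read.vcfR(p, verbose = FALSE)
  expect_equal(ours$chrom, unname(v@fix[, "CHROM"]))
  # positions/alleles match after applying the same normalization to vcfR's
  norm <- t(mapply(function(pos, ref, alt)
    unlist(normalize_record("chr1", as.integer(pos), ref, alt)[c("pos", "ref", "alt")]),
    v@fix[, "POS"], v@fix[, "REF"], v@fix[, "ALT"]))
  expect_equal(ours$pos, as.integer(norm[, "pos"]))
  expect_equal(ours$ref, unname(norm[, "ref"]))
  expect_equal(ours$alt, unname(norm[, "alt"]))
  expect_equal(ours$qual, as.numeric(v@fix[, "QUAL"]))
})

test_that("gVCF flattening yields records plus merged coverage intervals", {
  body <- c("chr1\t1\t.\tA\t<NON_REF>\t.\t.\tEND=1000\tGT\t0/0",
            vcf_line(500, "AT", "A"),
            "chr1\t1001\t.\tA\t<NON_REF>\t.\t.\tEND=2000\tGT\t0/0")
  p <- write_vcf(body)
  cs <- flatten_gvcf(p, "S1")
  expect_true(cs$has_coverage)
  expect_equal(nrow(cs$records), 1)
  # adjacent blocks merge into one half-open interval
  expect_equal(cs$covered_intervals$start, 1L)
  expect_equal(cs$covered_intervals$end, 2001L)

  bad <- write_vcf("chr1\t1\t.\tA\t<NON_REF>\t.\t.\t.\tGT\t0/0")
  expect_error(flatten_gvcf(bad, "S1"), "without a valid END")

  # variant rows may carry the gVCF <NON_REF> alternative
  p2 <- write_vcf(c("chr1\t10\t.\tA\tC,<NON_REF>\t40\t.\t.\tGT\t0/1"))
  expect_equal(flatten_gvcf(p2, "S1")$records$alt, "C")
})

test_that("normalization reproduces worked examples and the trim oracle", {
  n <- normalize_record("chr1", 100, "GTCA", "ATCA")
  expect_equal(n[c("pos", "ref", "alt")], list(pos = 100L, ref = "G", alt = "A"))
  expect_equal(normalize_record("chr1", 5, "A", "C")$pos, 5L)
  n2 <- normalize_record("chr1", 200, "TGA", "TGC")
  expect_equal(n2[c("pos", "ref", "alt")],
               list(pos = 202L, ref = "A", alt = "C"))
  expect_error(normalize_record("chr1", 1, "AX", "A"), "alphabet")

  set.seed(7)
  for (k in 1:200) {
    pr <- random_allele_pair()
    got <- normalize_record("chr1", 500, pr[1], pr[2])
    expect_equal(got[c("pos", "ref", "alt")], oracle_trim(500L, pr[1], pr[2]))
    # idempotence
    again <- normalize_record("chr1", got$pos, got$ref, got$alt)
    expect_equal(again, got)
  }
})

test_that("left alignment shifts equivalent spellings to one representation", {
  #     123456789012
  ctx <- "AAGTGTGTGTCC"   # GT repeat: deleting any GT copy is the same event
  a <- normalize_record("chr1", 2, "AGT", "A", context = ctx)
  b <- normalize_record("chr1", 6, "TGT", "T", context = ctx)
  c_ <- normalize_record("chr1", 8, "TGT", "T", context = ctx)
  expect_equal(a, b)
  expect_equal(a, c_)
  expect_equal(a$pos, 2L)
  # substitutions are untouched by the context
  expect_equal(normalize_record("chr1", 5, "G", "C", context = ctx)$pos, 5L)
})

test_that("classification is definitional and padding-invariant", {
  expect_equal(classify_record("A", "G"), "substitution")
  expect_equal(classify_record("A", "AT"), "insertion")
  expect_equal(classify_record("ATT", "A"), "deletion")
  n <- normalize_record("chr1", 10, "ATGC", "AGT")
  expect_equal(classify_record(n$ref, n$alt), "complex")

  set.seed(8)
  for (k in 1:100) {
    pr <- random_allele_pair()
    n0 <- normalize_record("chr1", 50, pr[1], pr[2])
    b <- sample(c("A", "C", "G", "T"), 1)
    n1 <- normalize_record("chr1", 50, paste0(pr[1], b), paste0(pr[2], b))
    expect_equal(classify_record(n1$ref, n1$alt),
                 classify_record(n0$ref, n0$alt))
  }
})
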