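test_that("the indel window holds 200 positions centred with left bias", {
  expect_equal(indel_window(1000), c(900L, 1099L))
  expect_equal(indel_window(50), c(1L, 149L))
  w <- indel_window(1000)
  expect_true(1099 >= w[1] && 1099 <= w[2])
  expect_false(1100 <= w[2])
})

test_that("exact indel matching is representation-invariant", {
  site <- truth_row(1, 1000, "AT", "A", "deletion")
  expect_true(exact_indel_match(site, list(chrom = "chr1", pos = 1000,
                                           ref = "AT", alt = "A")))
  # same event spelled padded
  expect_true(exact_indel_match(site, list(chrom = "chr1", pos = 999,
                                           ref = "CAT", alt = "CA")))
  expect_false(exact_indel_match(site, list(chrom = "chr1", pos = 1000,
                                            ref = "ATT", alt = "A")))
})

test_that("a 24bp deletion split into 13+11bp counts 2 detections, no match", {
  del24 <- paste(sample(c("A", "C", "G", "T"), 24, replace = TRUE),
                 collapse = "")
  site <- truth_row(607, 10000, paste0("G", del24), "G", "deletion")
  halves <- perturb_representation(site, "split")
  expect_equal(nrow(halves), 2)
  lens <- nchar(halves$ref) - nchar(halves$alt)
  expect_equal(sort(lens), c(11, 13))
  for (k in 1:2)
    expect_false(exact_indel_match(site, as.list(halves[k, ])))
  p <- write_vcf(vapply(1:2, function(k)
    vcf_line(halves$pos[k], halves$ref[k], halves$alt[k]), character(1)))
  ev <- evaluate_site(as_truth_catalog(site)[1, ],
                      read_single_sample_vcf(p, "S1"))
  expect_equal(ev$status, "TP")
  expect_equal(ev$detection_count, 2L)
  expect_false(ev$represented_correctly)
})

test_that("substitution sites demand the exact allele at the exact position", {
  cat_ <- mixed_catalog()
  cs <- read_single_sample_vcf(write_vcf(vcf_line(1000, "A", "G")), "S1")
  ev <- evaluate_site(cat_[1, ], cs)
  expect_equal(ev$status, "TP")
  expect_true(ev$exact_match)

  wrong <- read_single_sample_vcf(write_vcf(vcf_line(1000, "A", "T")), "S1")
  ev2 <- evaluate_site(cat_[1, ], wrong)
  expect_equal(ev2$status, "FN")
  expect_equal(ev2$flag, "incorrect_call_present")
  expect_equal(ev2$detection_count, 0L)

  # any substitution at a negative substitution site's position is FP
  fp <- read_single_sample_vcf(write_vcf(vcf_line(5000, "C", "T")), "S1")
  expect_equal(evaluate_site(cat_[5, ], fp)$status, "FP")
  # a nearby substitution does not count
  near <- read_single_sample_vcf(write_vcf(vcf_line(5001, "C", "T")), "S1")
  expect_equal(evaluate_site(cat_[5, ], near)$status, "TN")
})

test_that("negative indel sites flag any in-window indel as a false call", {
  cat_ <- mixed_catalog()
  up40 <- read_single_sample_vcf(write_vcf(vcf_line(5960, "T", "TAG")), "S1")
  ev <- evaluate_site(cat_[6, ], up40)
  expect_equal(ev$status, "FP")
  expect_equal(ev$detection_count, 1L)
  # a substitution in the window is ignored for indel sites
  sub_in <- read_single_sample_vcf(write_vcf(vcf_line(6010, "A", "G")), "S1")
  expect_equal(evaluate_site(cat_[6, ], sub_in)$status, "TN")
})

test_that("positive indel sites separate detection from representation", {
  cat_ <- mixed_catalog()     # site 2: chr1:2000 ATT>A deletion
  body <- c(vcf_line(1950, "CAA", "C"), vcf_line(2010, "G", "GT"),
            vcf_line(2090, "TGC", "T"))
  cs <- read_single_sample_vcf(write_vcf(body), "S1")
  ev <- evaluate_site(cat_[2, ], cs)
  expect_equal(ev$status, "TP")
  expect_equal(ev$detection_count, 3L)
  expect_false(ev$represented_correctly)
  expect_false(ev$exact_match)

  exact <- read_single_sample_vcf(write_vcf(vcf_line(1999, "CATT", "CA")),
                                  "S1")
  ev2 <- evaluate_site(cat_[2, ], exact)
  expect_true(ev2$exact_match)
  expect_true(ev2$represented_correctly)
})

test_that("uncovered or missing loci are no-calls: FN positive, TN negative", {
  cat_ <- mixed_catalog()
  gp <- write_vcf("chr1\t1\t.\tA\t<NON_REF>\t.\t.\tEND=500\tGT\t0/0")
  gcs <- flatten_gvcf(gp, "S1")
  ev <- evaluate_site(cat_[1, ], gcs)     # positive site at 1000, uncovered
  expect_true(ev$no_call)
  expect_equal(ev$status, "FN")
  evn <- evaluate_site(cat_[6, ], gcs)    # negative site, uncovered
  expect_true(evn$no_call)
  expect_equal(evn$status, "TN")

  miss <- read_single_sample_vcf(
    write_vcf(vcf_line(1000, "A", "G", gt = "./.")), "S1")
  evm <- evaluate_site(cat_[1, ], miss)
  expect_true(evm$no_call)
  expect_equal(evm$flag, "no_call:missing_genotype")

  other <- read_single_sample_vcf(write_vcf(vcf_line(10, "A", "C")), "S2")
  expect_error(evaluate_site(cat_[1, ], other), "belongs to sample")
})

test_that("evaluate_all isolates missing callsets and orders by site_id", {
  gen <- generate_scenario(small_spec(21), tempfile("iso"))
  catalog <- load_truth(gen$truth_path)
  callsets <- load_callsets(read_sample_map(gen$sample_map_path))
  drop <- names(callsets)[2]
  callsets[drop] <- list(NULL)
  expect_warning(res <- evaluate_all(catalog, callsets), "no callset")
  expect_equal(res$site_id, sort(res$site_id))
  hit <- res$sample_id == drop
  expect_true(all(res$no_call[hit]))
  expect_true(all(res$flag[hit] == "no_call:callset_absent"))
  # other samples are unaffected: all-clean scenario stays clean
  expect_true(all(res$status[!hit & res$polarity == "positive"] == "TP"))
  expect_true(all(res$status[!hit & res$polarity == "negative"] == "TN"))
})

test_that("adding a record never lowers detection or demotes a TP", {
  set.seed(31)
  cat_ <- mixed_catalog()
  for (k in 1:25) {
    n_base <- sample(0:4, 1)
    mk_line <- function() {
      pos <- sample(900:6100, 1)
      if (runif(1) < 0.5) vcf_line(pos, "A", "G")
      else vcf_line(pos, paste0("A", paste(sample(c("A", "C", "G", "T"),
        sample(1:5, 1), replace = TRUE), collapse = "")), "A")
    }
    base_lines <- if (n_base) vapply(seq_len(n_base), function(i) mk_line(),
                                     character(1)) else character()
    extra <- mk_line()
    cs1 <- read_single_sample_vcf(write_vcf(c(base_lines)), "S1")
    cs2 <- read_single_sample_vcf(write_vcf(c(base_lines, extra)), "S1")
    for (i in seq_len(nrow(cat_))) {
      e1 <- evaluate_site(cat_[i, ], cs1)
      e2 <- evaluate_site(cat_[i, ], cs2)
      expect_gte(e2$detection_count, e1$detection_count)
      if (e1$status == "TP") expect_equal(e2$status, "TP")
    }
  }
})
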