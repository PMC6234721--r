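# Shared fixture builders and independent oracles.

vcf_header <- function(samples = "S1") {
  c("##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

write_vcf <- function(body, samples = "S1", path = tempfile(fileext = ".vcf")) {
  writeLines(c(vcf_header(samples), body), path)
  path
}

vcf_line <- function(pos, ref, alt, qual = "50", gt = "0/1", chrom = "chr1",
                     info = ".", filter = "PASS") {
  paste(chrom, pos, ".", ref, alt, qual, filter, info, "GT", gt, sep = "\t")
}

# One-row truth builders.
truth_row <- function(site_id, pos, ref, alt, class,
                      polarity = "positive", sample_id = "S1") {
  data.frame(site_id = site_id, sample_id = sample_id, chrom = "chr1",
             pos = pos, expected_ref = ref, expected_alt = alt,
             polarity = polarity, variant_class = class,
             transcript_id = "", stringsAsFactors = FALSE)
}

neg_row <- function(site_id, pos, class, sample_id = "S1") {
  truth_row(site_id, pos, "", "", class, polarity = "negative",
            sample_id = sample_id)
}

mixed_catalog <- function() {
  as_truth_catalog(rbind(
    truth_row(1, 1000, "A", "G", "substitution"),
    truth_row(2, 2000, "ATT", "A", "deletion"),
    truth_row(3, 3000, "A", "ACG", "insertion"),
    truth_row(4, 4000, "CAT", "GC", "complex"),
    neg_row(5, 5000, "substitution"),
    neg_row(6, 6000, "indel")))
}

# Independent minimal-representation oracle: enumerate every (prefix i,
# suffix j) trim that leaves >=1 base per allele, validate by direct
# substring comparison, and pick the maximal suffix then maximal prefix.
oracle_trim <- function(pos, ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  best <- NULL
  for (j in 0:(min(nr, na) - 1L)) {
    if (substr(ref, nr - j + 1L, nr) != substr(alt, na - j + 1L, na)) next
    for (i in 0:(min(nr, na) - 1L - j)) {
      if (substr(ref, 1L, i) != substr(alt, 1L, i)) next
      if (nr - i - j < 1L || na - i - j < 1L) next
      cand <- list(pos = pos + i, ref = substr(ref, i + 1L, nr - j),
                   alt = substr(alt, i + 1L, na - j), i = i, j = j)
      if (is.null(best) || cand$j > best$j ||
          (cand$j == best$j && cand$i > best$i)) best <- cand
    }
  }
  best[c("pos", "ref", "alt")]
}

random_allele_pair <- function() {
  repeat {
    ref <- paste(sample(c("A", "C", "G", "T"), sample(1:8, 1),
                        replace = TRUE), collapse = "")
    alt <- paste(sample(c("A", "C", "G", "T"), sample(1:8, 1),
                        replace = TRUE), collapse = "")
    if (ref != alt) return(c(ref, alt))
  }
}

# Brute-force windowed indel count: scan every record for every site.
brute_window_count <- function(site_pos, site_chrom, records) {
  n <- 0L
  for (k in seq_len(nrow(records))) {
    r <- records[k, ]
    if (r$genotype_status != "called") next
    if (!(r$record_class %in% c("insertion", "deletion", "complex"))) next
    if (r$chrom != site_chrom) next
    if (r$pos >= site_pos - 100L && r$pos <= site_pos + 99L) n <- n + 1L
  }
  n
}

# Expand printed TP/FN/TN/FP counts into a status table for compute_summary.
counts_to_results <- function(sub_counts, indel_counts) {
  expand <- function(cls, counts) {
    data.frame(variant_class = cls,
               status = rep(c("TP", "FN", "TN", "FP"), counts),
               stringsAsFactors = FALSE)
  }
  rbind(expand("substitution", sub_counts), expand("deletion", indel_counts))
}

small_spec <- function(seed, ...) {
  scenario_spec(n_samples = 4, n_substitution = 6, n_deletion = 5,
                n_insertion = 4, n_complex = 2, n_negative_substitution = 4,
                n_negative_indel = 6, seed = seed, ...)
}

evaluate_scenario <- function(gen, gvcf = FALSE) {
  catalog <- load_truth(gen$truth_path)
  callsets <- load_callsets(read_sample_map(gen$sample_map_path), gvcf = gvcf)
  evaluate_all(catalog, callsets)
}

expect_matches_ledger <- function(res, led) {
  led <- led[order(led$site_id), ]
  expect_equal(res$site_id, led$site_id)
  expect_equal(res$status, led$status)
  expect_equal(res$detection_count, led$detection_count)
  expect_equal(res$exact_match, led$exact_match)
  expect_equal(res$no_call, led$no_call)
  expect_equal(is.na(res$represented_correctly),
               is.na(led$represented_correctly))
  expect_true(all(res$represented_correctly == led$represented_correctly,
                  na.rm = TRUE))
}
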