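test_that("rate formatting rounds ties to even and guards inputs", {
  expect_equal(format_rate(404, 416), "404/416 (97%)")
  expect_equal(format_rate(0, 10), "0/10 (0%)")
  expect_equal(format_rate(20, 301), "20/301 (7%)")   # 6.64 rounds up
  expect_equal(format_rate(35, 41), "35/41 (85%)")    # 85.37 rounds down
  expect_equal(format_rate(7, 280), "7/280 (2%)")     # 2.5 ties to even
  expect_equal(format_rate(3, 200), "3/200 (2%)")     # 1.5 ties to even
  expect_equal(format_rate(0, 0), "NA")
  expect_error(format_rate(5, 4), "exceeds")
})

test_that("summary categories are consistent and sum to overall", {
  res <- counts_to_results(c(10, 2, 5, 1), c(20, 4, 9, 3))
  s <- compute_summary(res)
  expect_equal(s$category, c("overall", "substitutions", "indels"))
  for (col in c("TP", "FN", "TN", "FP"))
    expect_equal(s[[col]][1], s[[col]][2] + s[[col]][3])
  expect_equal(s$sensitivity[1], "30/36 (83%)")
  expect_equal(s$fdr[3], "3/23 (13%)")
  expect_equal(s$fdr[2], "1/11 (9%)")
})

test_that("group assignment intersects baselines and drops unclean sites", {
  gen <- generate_scenario(small_spec(41), tempfile("grp"))
  clean <- evaluate_scenario(gen)
  # all-clean baselines: every positive in A, every negative in B
  g1 <- assign_groups(list(clean, clean))
  expect_equal(g1$group_a, clean$site_id[clean$polarity == "positive"])
  expect_equal(g1$group_b, clean$site_id[clean$polarity == "negative"])
  # single-baseline assignment equals that baseline's own sets
  expect_equal(assign_groups(clean)$group_a, g1$group_a)

  # plant discordance: 2 positives missed, 1 negative called, 1 negative
  # no-call in a second baseline
  other <- clean
  pos_ids <- clean$site_id[clean$polarity == "positive"]
  neg_ids <- clean$site_id[clean$polarity == "negative"]
  flip <- c(pos_ids[1], pos_ids[5])
  other$status[other$site_id %in% flip] <- "FN"
  other$status[other$site_id == neg_ids[2]] <- "FP"
  other$detection_count[other$site_id == neg_ids[2]] <- 1L
  other$no_call[other$site_id == neg_ids[4]] <- TRUE
  g2 <- assign_groups(list(clean, other))
  expect_equal(g2$group_a, setdiff(pos_ids, flip))
  expect_equal(g2$group_b, setdiff(neg_ids, neg_ids[c(2, 4)]))

  bad <- other[-1, ]
  expect_error(assign_groups(list(clean, bad)), "different site_id")
})

test_that("benchmarking reports exactly the planted group failures", {
  gen <- generate_scenario(small_spec(42), tempfile("bm"))
  clean <- evaluate_scenario(gen)
  groups <- assign_groups(clean)
  bm0 <- benchmark_against_groups(clean, groups)
  expect_length(bm0$missed_group_a, 0)
  expect_length(bm0$violated_group_b, 0)

  run <- clean
  miss <- groups$group_a[c(2, 7)]
  run$status[run$site_id %in% miss] <- "FN"
  viol <- groups$group_b[3]
  run$status[run$site_id == viol] <- "FP"
  bm <- benchmark_against_groups(run, groups)
  expect_equal(bm$missed_group_a, miss)
  expect_equal(bm$violated_group_b, viol)
})

test_that("run comparison labels every change type and is anti-symmetric", {
  gen <- generate_scenario(small_spec(43), tempfile("cmp"))
  old <- evaluate_scenario(gen)
  expect_equal(nrow(compare_runs(old, old)), 0)
  expect_equal(attr(compare_runs(old, old), "n_unchanged"), nrow(old))

  new <- old
  pos_ids <- old$site_id[old$polarity == "positive"]
  neg_ids <- old$site_id[old$polarity == "negative"]
  ind_ids <- old$site_id[old$polarity == "positive" &
                         old$variant_class != "substitution"]
  new$status[new$site_id == pos_ids[1]] <- "FN"           # lost_detection
  new$status[new$site_id == neg_ids[1]] <- "FP"           # gained_false_call
  i2 <- which(new$site_id == ind_ids[2])                  # extra in-window call
  new$detection_count[i2] <- new$detection_count[i2] + 1L
  i3 <- which(new$site_id == ind_ids[3])                  # repr. regression
  new$represented_correctly[i3] <- FALSE
  cmp <- compare_runs(old, new)
  got <- split(cmp$site_id, cmp$change_type)
  expect_equal(got$lost_detection, pos_ids[1])
  expect_equal(got$gained_false_call, neg_ids[1])
  expect_equal(got$detection_count_change, ind_ids[2])
  expect_equal(got$representation_change, ind_ids[3])

  rev <- compare_runs(new, old)
  swap <- c(gained_detection = "lost_detection",
            lost_detection = "gained_detection",
            gained_false_call = "lost_false_call",
            lost_false_call = "gained_false_call",
            detection_count_change = "detection_count_change",
            representation_change = "representation_change")
  expect_equal(sort(paste(rev$site_id, unname(swap[rev$change_type]))),
               sort(paste(cmp$site_id, cmp$change_type)))
})

test_that("quality sweep recomputes statuses from records", {
  gen <- filter_demo_scenario(tempfile("sw"), seed = 9, n_samples = 4,
                              n_positive = 20, n_negative = 10, n_false = 3,
                              low_false_quals = c(9.3, 20.3))
  res <- evaluate_scenario(gen)
  sw <- sweep_quality_threshold(res, c(0, 30, 1000), "substitution")
  s0 <- sw[sw$threshold == 0 & sw$category == "substitutions", ]
  base <- compute_summary(res)
  expect_equal(s0$sensitivity, base$sensitivity[2])   # t=0 is unfiltered
  expect_equal(s0$specificity, base$specificity[2])
  shigh <- sw[sw$threshold == 1000 & sw$category == "substitutions", ]
  expect_equal(shigh$TP, 0)                           # everything filtered
  expect_equal(shigh$FP, 0)
  expect_equal(shigh$sensitivity, "0/20 (0%)")

  # monotone in t for the filtered class
  subs <- sw[sw$category == "substitutions", ]
  expect_true(all(diff(subs$FP) <= 0))
  expect_true(all(diff(subs$TP) <= 0))

  # a record without QUAL is warned about and treated as below threshold
  recs <- attr(res, "site_records")
  first <- names(recs)[vapply(recs, nrow, 1L) > 0][1]
  recs[[first]]$qual <- NA_real_
  attr(res, "site_records") <- recs
  expect_warning(sweep_quality_threshold(res, 0, "substitution"),
                 "lack a QUAL")
})

test_that("groups files round-trip", {
  g <- structure(list(group_a = c(1L, 3L, 9L), group_b = c(2L, 4L),
                      baseline_labels = "x"), class = "group_assignment")
  p <- tempfile(fileext = ".tsv")
  write_groups(g, p)
  g2 <- read_groups(p)
  expect_equal(g2$group_a, g$group_a)
  expect_equal(g2$group_b, g$group_b)
})
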