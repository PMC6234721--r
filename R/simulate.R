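#' @title Synthetic scenarios with a known planted-outcome ledger
#' @description Generates truth catalogs and per-sample VCF callsets whose
#'   error structure is fully known in advance: planted exact calls,
#'   missed variants, false calls at negative sites, misrepresented indels
#'   (padded, split or garbled spellings), clustered in-window calls,
#'   missing genotypes / coverage gaps, and planted quality scores.  The
#'   generator writes standard truth-TSV and VCF files plus a ledger
#'   giving the expected per-site verdict, so the whole evaluation
#'   pipeline can be exercised end-to-end and checked exactly.
#' @name synthetic_fixtures
NULL

#' Specify a synthetic benchmarking scenario
#'
#' The defaults mirror the validated study layout: 142 samples and 704
#' sites — 123 positive base substitutions, 293 positive indels
#' (allocated 203 deletions / 80 insertions / 10 complex), 41 negative
#' substitution sites and 247 negative indel sites — with no planted
#' errors.  Sites are placed more than 200 bp apart on one simulated
#' contig so detection windows never overlap and every planted outcome is
#' independent and exact.
#'
#' @param n_samples Number of samples; sites are assigned round-robin.
#' @param n_substitution,n_deletion,n_insertion,n_complex Positive site
#'   counts per class.
#' @param n_negative_substitution,n_negative_indel Negative site counts.
#' @param fn_rate Probability a positive site is missed entirely.
#' @param fp_rate_negative Probability a negative site receives a false call.
#' @param misrepresentation_rate Probability a detected variant is emitted
#'   in a wrong spelling (wrong ALT at substitution sites, which scores as
#'   a missed variant; split/garbled representation at indel sites).
#' @param missing_rate Probability a site is a no-call (missing genotype,
#'   or a coverage gap in gVCF mode).
#' @param cluster_probability Probability a planted indel call is
#'   accompanied by a second in-window indel call.
#' @param pad_probability Probability an exactly matching indel call is
#'   emitted padded (equivalent after normalization).
#' @param qual_true,qual_false Mean and sd of the QUAL scores of true and
#'   false calls.
#' @param seed Integer seed; all randomness flows from it.
#' @param gvcf Emit gVCF callsets (reference blocks with END; no-calls
#'   become coverage gaps instead of missing genotypes).
#' @return A validated \code{scenario_spec} list.
#' @export
scenario_spec <- function(n_samples = 142L,
                          n_substitution = 123L, n_deletion = 203L,
                          n_insertion = 80L, n_complex = 10L,
                          n_negative_substitution = 41L,
                          n_negative_indel = 247L,
                          fn_rate = 0, fp_rate_negative = 0,
                          misrepresentation_rate = 0, missing_rate = 0,
                          cluster_probability = 0, pad_probability = 0.3,
                          qual_true = c(mean = 50, sd = 10),
                          qual_false = c(mean = 15, sd = 5),
                          seed = 1L, gvcf = FALSE) {
  spec <- list(n_samples = as.integer(n_samples),
               n_substitution = as.integer(n_substitution),
               n_deletion = as.integer(n_deletion),
               n_insertion = as.integer(n_insertion),
               n_complex = as.integer(n_complex),
               n_negative_substitution = as.integer(n_negative_substitution),
               n_negative_indel = as.integer(n_negative_indel),
               fn_rate = fn_rate, fp_rate_negative = fp_rate_negative,
               misrepresentation_rate = misrepresentation_rate,
               missing_rate = missing_rate,
               cluster_probability = cluster_probability,
               pad_probability = pad_probability,
               qual_true = qual_true, qual_false = qual_false,
               seed = as.integer(seed), gvcf = isTRUE(gvcf))
  probs <- c(spec$fn_rate, spec$fp_rate_negative,
             spec$misrepresentation_rate, spec$missing_rate,
             spec$cluster_probability, spec$pad_probability)
  if (any(probs < 0 | probs > 1))
    stop("all rates must be probabilities in [0, 1]", call. = FALSE)
  counts <- unlist(spec[grep("^n_", names(spec))])
  if (any(counts < 0) || spec$n_samples < 1)
    stop("counts must be non-negative and n_samples >= 1", call. = FALSE)
  if (!all(c("mean", "sd") %in% names(spec$qual_true)) ||
      !all(c("mean", "sd") %in% names(spec$qual_false)))
    stop("qual distributions need named 'mean' and 'sd'", call. = FALSE)
  class(spec) <- "scenario_spec"
  spec
}

#' Read a scenario spec from a YAML config file
#'
#' Keys are the \code{\link{scenario_spec}} arguments; \code{qual_true} /
#' \code{qual_false} are maps with \code{mean} and \code{sd}.
#'
#' @param path Path to the YAML file.
#' @return A \code{scenario_spec}.
#' @export
read_scenario_spec <- function(path) {
  y <- yaml::read_yaml(path)
  for (q in c("qual_true", "qual_false"))
    if (!is.null(y[[q]])) y[[q]] <- unlist(y[[q]])
  do.call(scenario_spec, y)
}

.rand_base <- function(n = 1L) sample(c("A", "C", "G", "T"), n, replace = TRUE)
.other_base <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L)
.rand_seq <- function(n) paste(.rand_base(n), collapse = "")

#' Perturb the representation of a positive indel site
#'
#' Produces alternative spellings of a truth indel for representation
#' testing.  \code{pad} prepends (or, at position 1, appends) a shared
#' base, giving an equivalent record that still matches exactly after
#' normalization.  \code{split} breaks a deletion of D >= 2 bases into two
#' in-window deletions whose lengths sum to D (detected twice, never an
#' exact match).  \code{garble} alters the indel alleles in place
#' (detected once, misrepresented).
#'
#' @param site Positive indel-type truth site (one-row data frame or list).
#' @param mode One of \code{"pad"}, \code{"split"}, \code{"garble"}.
#' @return Data frame of raw call rows (\code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}).
#' @export
perturb_representation <- function(site, mode = c("pad", "split", "garble")) {
  mode <- match.arg(mode)
  if (is.data.frame(site)) site <- as.list(site)
  ref <- site$expected_ref; alt <- site$expected_alt; pos <- site$pos
  cls <- classify_record(ref, alt)
  if (cls == "substitution")
    stop("perturb_representation applies to indel-type sites", call. = FALSE)
  row <- function(p, r, a) data.frame(chrom = site$chrom, pos = p, ref = r,
                                      alt = a, stringsAsFactors = FALSE)
  if (mode == "pad") {
    # left-padding is only normalization-neutral when the alleles' last
    # bases differ (otherwise it unblocks suffix trimming and shifts the
    # minimal form); pad on the right in that case
    last_r <- substr(ref, nchar(ref), nchar(ref))
    last_a <- substr(alt, nchar(alt), nchar(alt))
    if (pos > 1L && last_r != last_a)
      return(row(pos - 1L, paste0("A", ref), paste0("A", alt)))
    return(row(pos, paste0(ref, "A"), paste0(alt, "A")))
  }
  if (mode == "split") {
    if (cls != "deletion")
      stop("split mode requires a deletion site", call. = FALSE)
    na <- nchar(alt); nr <- nchar(ref); D <- nr - na
    if (D < 2L)
      stop("split mode requires a deletion of >= 2 bases", call. = FALSE)
    d1 <- if (D == 2L) 1L else as.integer(ceiling((D + 1) / 2))
    rbind(row(pos, substr(ref, 1L, na + d1), alt),
          row(pos + na + d1 - 1L, substr(ref, na + d1, nr),
              substr(ref, na + d1, na + d1)))
  } else {  # garble
    if (cls == "insertion") {
      b <- if (substr(alt, nchar(alt), nchar(alt)) == "A") "C" else "A"
      row(pos, ref, paste0(alt, b))
    } else if (cls == "deletion") {
      b <- if (substr(alt, nchar(alt), nchar(alt)) == "A") "C" else "A"
      row(pos, paste0(ref, b), alt)
    } else {
      b <- if (substr(ref, nchar(ref), nchar(ref)) == "A") "C" else "A"
      row(pos, ref, paste0(alt, b))
    }
  }
}

# Build the truth-site table of a spec (deterministic given the RNG state).
.build_sites <- function(spec) {
  classes <- c(rep("substitution", spec$n_substitution),
               rep("deletion", spec$n_deletion),
               rep("insertion", spec$n_insertion),
               rep("complex", spec$n_complex),
               rep("neg_substitution", spec$n_negative_substitution),
               rep("neg_indel", spec$n_negative_indel))
  n <- length(classes)
  if (!n) stop("scenario has zero sites", call. = FALSE)
  samples <- sprintf("S%03d", ((seq_len(n) - 1L) %% spec$n_samples) + 1L)
  pos <- 1000L + (seq_len(n) - 1L) * 500L
  ref <- character(n); alt <- character(n)
  for (i in seq_len(n)) {
    cl <- classes[i]
    if (cl == "substitution") {
      ref[i] <- .rand_base(); alt[i] <- .other_base(ref[i])
    } else if (cl == "deletion") {
      ref[i] <- paste0(.rand_base(), .rand_seq(sample(1:20, 1L)))
      alt[i] <- substr(ref[i], 1L, 1L)
    } else if (cl == "insertion") {
      alt[i] <- paste0(.rand_base(), .rand_seq(sample(1:20, 1L)))
      ref[i] <- substr(alt[i], 1L, 1L)
    } else if (cl == "complex") {
      ref[i] <- .rand_seq(3L)
      alt[i] <- paste0(.other_base(substr(ref[i], 1L, 1L)),
                       .other_base(substr(ref[i], 3L, 3L)))
    }
  }
  polarity <- ifelse(startsWith(classes, "neg_"), "negative", "positive")
  vclass <- sub("^neg_", "", classes)
  data.frame(site_id = seq_len(n), sample_id = samples, chrom = "chr1",
             pos = pos, expected_ref = ref, expected_alt = alt,
             polarity = polarity, variant_class = vclass,
             transcript_id = "", stringsAsFactors = FALSE)
}

.draw_qual <- function(par) {
  round(max(0.1, stats::rnorm(1L, par[["mean"]], par[["sd"]])), 1L)
}

#' Generate a synthetic scenario on disk
#'
#' Writes a loadable truth catalog, one VCF (or gVCF) per sample, a
#' sample map, and the planted-outcome ledger recording the expected
#' verdict of every site (status, detection count, exact match,
#' representation accuracy, no-call, planted QUALs).  Running
#' \code{\link{evaluate_all}} on the generated files reproduces the
#' ledger row for row.  Identical spec and seed give byte-identical
#' output files.
#'
#' @param spec A \code{\link{scenario_spec}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with \code{truth_path}, \code{sample_map_path},
#'   \code{ledger_path}, \code{vcf_paths}, the \code{catalog} and the
#'   \code{ledger} data frame.
#' @export
generate_scenario <- function(spec, dir) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create ", dir, call. = FALSE)
  set.seed(spec$seed)
  sites <- .build_sites(spec)
  n <- nrow(sites)
  sample_ids <- sprintf("S%03d", seq_len(spec$n_samples))
  calls <- stats::setNames(
    rep(list(data.frame(pos = integer(), ref = character(),
                        alt = character(), qual = numeric(),
                        gt = character(), stringsAsFactors = FALSE)),
        spec$n_samples), sample_ids)
  uncovered <- stats::setNames(rep(list(integer()), spec$n_samples),
                               sample_ids)
  led <- data.frame(site_id = sites$site_id, sample_id = sites$sample_id,
                    polarity = sites$polarity,
                    variant_class = sites$variant_class,
                    status = NA_character_, detection_count = 0L,
                    exact_match = FALSE, represented_correctly = NA,
                    no_call = FALSE, quals = "", stringsAsFactors = FALSE)

  add_call <- function(s, pos, ref, alt, qual, gt = "0/1") {
    calls[[s]] <<- rbind(calls[[s]], data.frame(
      pos = as.integer(pos), ref = ref, alt = alt, qual = qual, gt = gt,
      stringsAsFactors = FALSE))
  }

  for (i in seq_len(n)) {
    s <- sites$sample_id[i]
    pos <- sites$pos[i]; ref <- sites$expected_ref[i]
    alt <- sites$expected_alt[i]
    positive <- sites$polarity[i] == "positive"
    is_sub <- sites$variant_class[i] == "substitution"
    quals <- numeric()

    if (stats::runif(1L) < spec$missing_rate) {
      led$no_call[i] <- TRUE
      led$status[i] <- if (positive) "FN" else "TN"
      if (positive) led$represented_correctly[i] <- FALSE
      if (spec$gvcf) {
        uncovered[[s]] <- c(uncovered[[s]], pos)
      } else {
        mr <- if (positive) c(ref, alt) else c("A", "T")
        add_call(s, pos, mr[1], mr[2], NA_real_, gt = "./.")
      }
    } else if (positive) {
      if (stats::runif(1L) < spec$fn_rate) {
        led$status[i] <- "FN"
        led$represented_correctly[i] <- FALSE
      } else if (is_sub) {
        if (stats::runif(1L) < spec$misrepresentation_rate) {
          q <- .draw_qual(spec$qual_true); quals <- q
          add_call(s, pos, ref, .other_base(c(ref, alt)), q)
          led$status[i] <- "FN"          # wrong ALT scores as a miss
          led$represented_correctly[i] <- FALSE
        } else {
          q <- .draw_qual(spec$qual_true); quals <- q
          add_call(s, pos, ref, alt, q)
          led$status[i] <- "TP"; led$detection_count[i] <- 1L
          led$exact_match[i] <- TRUE
          led$represented_correctly[i] <- TRUE
        }
      } else {
        site_row <- sites[i, , drop = FALSE]
        if (stats::runif(1L) < spec$misrepresentation_rate) {
          mode <- if (sites$variant_class[i] == "deletion" &&
                      nchar(ref) - nchar(alt) >= 2L) "split" else "garble"
          p <- perturb_representation(site_row, mode)
          for (k in seq_len(nrow(p))) {
            q <- .draw_qual(spec$qual_true); quals <- c(quals, q)
            add_call(s, p$pos[k], p$ref[k], p$alt[k], q)
          }
          led$status[i] <- "TP"
          led$detection_count[i] <- nrow(p)
          led$represented_correctly[i] <- FALSE
        } else {
          p <- if (stats::runif(1L) < spec$pad_probability)
            perturb_representation(site_row, "pad")
          else data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt,
                          stringsAsFactors = FALSE)
          q <- .draw_qual(spec$qual_true); quals <- q
          add_call(s, p$pos[1], p$ref[1], p$alt[1], q)
          led$status[i] <- "TP"; led$detection_count[i] <- 1L
          led$exact_match[i] <- TRUE
          led$represented_correctly[i] <- TRUE
        }
        if (led$detection_count[i] > 0L &&
            stats::runif(1L) < spec$cluster_probability) {
          b <- .rand_base()
          q <- .draw_qual(spec$qual_true); quals <- c(quals, q)
          add_call(s, pos + 37L, b, paste0(b, .rand_seq(2L)), q)
          led$detection_count[i] <- led$detection_count[i] + 1L
        }
      }
    } else {  # negative site, assessable
      if (stats::runif(1L) < spec$fp_rate_negative) {
        led$status[i] <- "FP"
        if (is_sub) {
          r <- .rand_base()
          q <- .draw_qual(spec$qual_false); quals <- q
          add_call(s, pos, r, .other_base(r), q)
          led$detection_count[i] <- 1L
        } else {
          off <- sample(-80:80, 1L)
          b <- .rand_base()
          q <- .draw_qual(spec$qual_false); quals <- q
          add_call(s, pos + off, paste0(b, .rand_seq(2L)), b, q)
          led$detection_count[i] <- 1L
          if (stats::runif(1L) < spec$cluster_probability) {
            b2 <- .rand_base()
            q2 <- .draw_qual(spec$qual_false); quals <- c(quals, q2)
            add_call(s, pos + 25L, b2, paste0(b2, .rand_seq(3L)), q2)
            led$detection_count[i] <- 2L
          }
        }
      } else {
        led$status[i] <- "TN"
      }
    }
    led$quals[i] <- paste(quals, collapse = ";")
  }

  catalog <- as_truth_catalog(sites, build_label = "synthetic",
                              normalize = FALSE)
  truth_path <- file.path(dir, "truth.tsv")
  write_truth(catalog, truth_path)
  contig_len <- max(sites$pos) + 300L
  vcf_paths <- stats::setNames(
    file.path(dir, paste0(sample_ids, if (spec$gvcf) ".g.vcf" else ".vcf")),
    sample_ids)
  for (s in sample_ids)
    .write_sample_vcf(vcf_paths[[s]], s, calls[[s]], spec$gvcf,
                      uncovered[[s]], contig_len)
  map_path <- file.path(dir, "sample_map.tsv")
  writeLines(c("sample_id\tvcf_path",
               paste(sample_ids, basename(vcf_paths), sep = "\t")),
             map_path)
  ledger_path <- file.path(dir, "ledger.tsv")
  utils::write.table(led, ledger_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(list(truth_path = truth_path, sample_map_path = map_path,
                 ledger_path = ledger_path, vcf_paths = vcf_paths,
                 catalog = catalog, ledger = led))
}

.write_sample_vcf <- function(path, sample_id, calls, gvcf, uncovered,
                              contig_len) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=chr1,length=%d>", contig_len),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample_id), collapse = "\t"))
  body <- character()
  if (nrow(calls)) {
    calls <- calls[order(calls$pos), , drop = FALSE]
    qual <- ifelse(is.na(calls$qual), ".", sprintf("%.1f", calls$qual))
    body <- paste("chr1", calls$pos, ".", calls$ref, calls$alt, qual,
                  "PASS", ".", "GT", calls$gt, sep = "\t")
  }
  if (gvcf) {
    # reference blocks: complement of the uncovered positions over the contig
    bounds <- sort(unique(uncovered))
    starts <- c(1L, bounds + 1L); ends <- c(bounds - 1L, contig_len)
    keep <- starts <= ends
    blocks <- paste("chr1", starts[keep], ".", "A", "<NON_REF>", ".", ".",
                    sprintf("END=%d", ends[keep]), "GT", "0/0", sep = "\t")
    body <- c(body, blocks)
    ord <- order(as.integer(vapply(strsplit(body, "\t", fixed = TRUE),
                                   `[`, "", 2L)))
    body <- body[ord]
  }
  writeLines(c(hdr, body), path)
}

#' @export
print.scenario_spec <- function(x, ...) {
  n <- x$n_substitution + x$n_deletion + x$n_insertion + x$n_complex +
    x$n_negative_substitution + x$n_negative_indel
  cat(sprintf("Scenario spec: %d sites over %d samples (seed %d%s)\n", n,
              x$n_samples, x$seed, if (x$gvcf) ", gVCF" else ""))
  cat(sprintf("  rates: fn %.3g, fp(neg) %.3g, misrep %.3g, missing %.3g, cluster %.3g\n",
              x$fn_rate, x$fp_rate_negative, x$misrepresentation_rate,
              x$missing_rate, x$cluster_probability))
  invisible(x)
}

#' Build the base-substitution filter-optimization scenario
#'
#' Constructs the worked example used to study QUAL filtering of base
#' substitution calls: every one of \code{n_positive} positive
#' substitution sites is detected exactly, with a single call carrying a
#' QUAL just below the candidate threshold (29.3) and all others a high
#' QUAL; \code{n_false} of the \code{n_negative} negative substitution
#' sites receive a false call, four of them with QUAL between 9.3 and
#' 20.3 and the rest high.  Sweeping a threshold of 30 over this scenario
#' excludes exactly one true call and four false calls.
#'
#' @param dir Output directory.
#' @param seed Integer seed driving positions, alleles and assignments.
#' @param n_samples,n_positive,n_negative,n_false Scenario dimensions.
#' @param low_true_qual QUAL of the single low-quality true call.
#' @param low_false_quals QUALs of the false calls failing the filter.
#' @param high_qual QUAL of every other call.
#' @return Invisibly, the same file-path/catalog/ledger list as
#'   \code{\link{generate_scenario}}.
#' @export
filter_demo_scenario <- function(dir, seed = 1L, n_samples = 10L,
                                 n_positive = 123L, n_negative = 41L,
                                 n_false = 6L, low_true_qual = 29.3,
                                 low_false_quals = c(9.3, 13.4, 16.8, 20.3),
                                 high_qual = 50) {
  stopifnot(n_false >= length(low_false_quals), n_negative >= n_false,
            n_positive >= 1L)
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create ", dir, call. = FALSE)
  set.seed(as.integer(seed))
  spec <- scenario_spec(n_samples = n_samples, n_substitution = n_positive,
                        n_deletion = 0L, n_insertion = 0L, n_complex = 0L,
                        n_negative_substitution = n_negative,
                        n_negative_indel = 0L, seed = as.integer(seed))
  sites <- .build_sites(spec)
  sample_ids <- sprintf("S%03d", seq_len(n_samples))
  calls <- stats::setNames(
    rep(list(data.frame(pos = integer(), ref = character(),
                        alt = character(), qual = numeric(),
                        gt = character(), stringsAsFactors = FALSE)),
        n_samples), sample_ids)
  pos_idx <- which(sites$polarity == "positive")
  neg_idx <- which(sites$polarity == "negative")
  low_site <- sample(pos_idx, 1L)
  fp_sites <- sample(neg_idx, n_false)
  fp_quals <- c(low_false_quals,
                rep(high_qual, n_false - length(low_false_quals)))
  led <- data.frame(site_id = sites$site_id, sample_id = sites$sample_id,
                    polarity = sites$polarity,
                    variant_class = sites$variant_class,
                    status = ifelse(sites$polarity == "positive", "TP", "TN"),
                    detection_count = ifelse(sites$polarity == "positive",
                                             1L, 0L),
                    exact_match = sites$polarity == "positive",
                    represented_correctly = ifelse(
                      sites$polarity == "positive", TRUE, NA),
                    no_call = FALSE, quals = "", stringsAsFactors = FALSE)
  for (i in pos_idx) {
    q <- if (i == low_site) low_true_qual else high_qual
    s <- sites$sample_id[i]
    calls[[s]] <- rbind(calls[[s]], data.frame(
      pos = sites$pos[i], ref = sites$expected_ref[i],
      alt = sites$expected_alt[i], qual = q, gt = "0/1",
      stringsAsFactors = FALSE))
    led$quals[i] <- format(q)
  }
  for (k in seq_along(fp_sites)) {
    i <- fp_sites[k]; s <- sites$sample_id[i]
    r <- .rand_base()
    calls[[s]] <- rbind(calls[[s]], data.frame(
      pos = sites$pos[i], ref = r, alt = .other_base(r),
      qual = fp_quals[k], gt = "0/1", stringsAsFactors = FALSE))
    led$status[i] <- "FP"; led$detection_count[i] <- 1L
    led$quals[i] <- format(fp_quals[k])
  }
  catalog <- as_truth_catalog(sites, build_label = "synthetic",
                              normalize = FALSE)
  truth_path <- file.path(dir, "truth.tsv")
  write_truth(catalog, truth_path)
  contig_len <- max(sites$pos) + 300L
  vcf_paths <- stats::setNames(
    file.path(dir, paste0(sample_ids, ".vcf")), sample_ids)
  for (s in sample_ids)
    .write_sample_vcf(vcf_paths[[s]], s, calls[[s]], FALSE, integer(),
                      contig_len)
  map_path <- file.path(dir, "sample_map.tsv")
  writeLines(c("sample_id\tvcf_path",
               paste(sample_ids, basename(vcf_paths), sep = "\t")),
             map_path)
  ledger_path <- file.path(dir, "ledger.tsv")
  utils::write.table(led, ledger_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(list(truth_path = truth_path, sample_map_path = map_path,
                 ledger_path = ledger_path, vcf_paths = vcf_paths,
                 catalog = catalog, ledger = led))
}
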