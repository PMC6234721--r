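#' @title Tabular outputs and the one-page report
#' @name reporting
NULL

.metric_labels <- c(sensitivity = "Sensitivity",
                    specificity = "Specificity",
                    fdr = "FalseDetectionRate")
.category_labels <- c(overall = "Overall",
                      substitutions = "BaseSubstitutions",
                      indels = "Indels")

.column_dictionary <- c(
  site_id = "Unique identifier of the truth site",
  sample_id = "Sample in which the site was validated",
  chrom = "Chromosome of the site",
  pos = "1-based position (minimal representation for positive sites)",
  expected_ref = "Validated reference allele (empty at negative sites)",
  expected_alt = "Validated alternate allele (empty at negative sites)",
  polarity = "positive (variant present) or negative (variant absent)",
  variant_class = "substitution/deletion/insertion/complex, or indel for negative sites",
  transcript_id = "Reference transcript used during validation (provenance only)",
  detection_count = "Indel calls in the 200bp window (0/1 at substitution sites)",
  exact_match = "A call reproduces the truth alleles exactly after normalization",
  represented_correctly = "Detected variant is accurately represented (NA at negative sites)",
  status = "Site verdict: TP/FN at positive sites, TN/FP at negative sites",
  no_call = "Locus had a missing genotype or no coverage assertion",
  flag = "Qualifier: incorrect_call_present, misrepresented or no_call reason",
  n_matched = "Number of exactly matching call records",
  n_false = "Number of false call records at this (negative) site",
  Metric = "Summary metric name",
  Category = "Overall, BaseSubstitutions or Indels",
  Numerator = "Count in the metric numerator",
  Denominator = "Count in the metric denominator",
  Rate = "Formatted rate: n/d (p%)",
  vcf_line = "Verbatim line of the input VCF for this call"
)

#' Write the result tables of a run
#'
#' Writes five tab-separated files to \code{outdir}:
#' \code{Summary.txt} (9 metric cells: sensitivity, specificity and FDR
#' for overall / base substitutions / indels), \code{FullResults.txt}
#' (one row per truth site with all truth and verdict fields),
#' \code{TruePositives.txt} and \code{FalsePositives.txt} (the verbatim
#' input-VCF lines of exactly matching calls at TP sites and of false
#' calls at FP sites, prefixed by sample and site), and
#' \code{ColumnHeaders.txt} describing every column.
#'
#' @param results Full-results table from \code{\link{evaluate_all}}.
#' @param summary Its \code{\link{compute_summary}} output (recomputed if
#'   omitted).
#' @param outdir Output directory (created if needed).
#' @return Named character vector of the file paths, invisibly.
#' @export
write_result_tables <- function(results, summary = NULL, outdir = ".") {
  if (is.null(summary)) summary <- compute_summary(results)
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", outdir, call. = FALSE)
  paths <- c(summary = file.path(outdir, "Summary.txt"),
             full = file.path(outdir, "FullResults.txt"),
             tp = file.path(outdir, "TruePositives.txt"),
             fp = file.path(outdir, "FalsePositives.txt"),
             columns = file.path(outdir, "ColumnHeaders.txt"))

  srows <- do.call(rbind, lapply(seq_len(nrow(summary)), function(i) {
    cat <- summary$category[i]
    data.frame(
      Metric = unname(.metric_labels),
      Category = unname(.category_labels[cat]),
      Numerator = c(summary$TP[i], summary$TN[i], summary$FP[i]),
      Denominator = c(summary$TP[i] + summary$FN[i],
                      summary$TN[i] + summary$FP[i],
                      summary$FP[i] + summary$TP[i]),
      Rate = c(summary$sensitivity[i], summary$specificity[i],
               summary$fdr[i]),
      stringsAsFactors = FALSE)
  }))
  utils::write.table(srows, paths["summary"], sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")

  utils::write.table(as.data.frame(results), paths["full"], sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")

  site_records <- attr(results, "site_records") %||% list()
  collect_lines <- function(role, statuses) {
    rows <- list()
    for (i in seq_len(nrow(results))) {
      if (!(results$status[i] %in% statuses)) next
      cand <- site_records[[as.character(results$site_id[i])]]
      if (is.null(cand) || !nrow(cand)) next
      cand <- cand[cand$role == role, , drop = FALSE]
      if (!nrow(cand)) next
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = results$sample_id[i], site_id = results$site_id[i],
        vcf_line = cand$raw_line, stringsAsFactors = FALSE)
    }
    if (length(rows)) do.call(rbind, rows)
    else data.frame(sample_id = character(), site_id = integer(),
                    vcf_line = character(), stringsAsFactors = FALSE)
  }
  utils::write.table(collect_lines("matched", "TP"), paths["tp"], sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.table(collect_lines("false", "FP"), paths["fp"], sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")

  dict <- data.frame(column = names(.column_dictionary),
                     description = unname(.column_dictionary),
                     stringsAsFactors = FALSE)
  utils::write.table(dict, paths["columns"], sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(paths)
}

#' Parse a Summary.txt file back into summary metrics
#'
#' Inverse of the Summary.txt writer: the returned object equals the
#' \code{\link{compute_summary}} output the file was written from.
#'
#' @param path Path to a Summary.txt file.
#' @return A \code{summary_metrics} data frame.
#' @export
parse_summary <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("Metric", "Category", "Numerator", "Denominator",
                  "Rate") %in% names(tab)))
  rows <- lapply(names(.category_labels), function(cat) {
    sub <- tab[tab$Category == .category_labels[cat], , drop = FALSE]
    get <- function(metric) sub[sub$Metric == .metric_labels[metric], ]
    sens <- get("sensitivity"); spec <- get("specificity"); fdr <- get("fdr")
    tp <- sens$Numerator; fn <- sens$Denominator - tp
    tn <- spec$Numerator; fp <- spec$Denominator - tn
    if (fdr$Numerator != fp || fdr$Denominator != fp + tp)
      stop("inconsistent Summary file: FDR row disagrees with counts",
           call. = FALSE)
    data.frame(category = cat, TP = tp, FN = fn, TN = tn, FP = fp,
               sensitivity = format_rate(tp, tp + fn),
               specificity = format_rate(tn, tn + fp),
               fdr = format_rate(fp, fp + tp), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("summary_metrics", "data.frame")
  out
}

.rate_line <- function(label, s, i)
  sprintf("- %s: sensitivity %s, specificity %s, false detection rate %s",
          label, s$sensitivity[i], s$specificity[i], s$fdr[i])

#' Render the one-page summary report
#'
#' Builds a Markdown report directly from the summary and full-results
#' tables (every number in the report is re-derivable from them): headline
#' rates overall and per class, the no-call sites at which missing data
#' prevented assessment, benchmarking against baseline Group A/B sets when
#' supplied, and a side-by-side rate table when baseline summaries are
#' supplied.  Output is deterministic for fixed inputs.
#'
#' @param summary A \code{summary_metrics}.
#' @param results The matching full-results table.
#' @param groups Optional \code{group_assignment}.
#' @param baseline_summaries Optional named list of \code{summary_metrics}
#'   of the baseline runs.
#' @return Character vector of Markdown lines, class \code{valbench_report}.
#' @export
render_report <- function(summary, results, groups = NULL,
                          baseline_summaries = NULL) {
  ln <- c("# Variant calling performance report", "",
          "## Headline metrics", "",
          .rate_line("Overall", summary, 1L),
          .rate_line("Base substitutions", summary, 2L),
          .rate_line("Indels", summary, 3L), "")
  nc <- results[results$no_call, , drop = FALSE]
  ln <- c(ln, "## Missing data", "")
  if (nrow(nc)) {
    ln <- c(ln, sprintf(paste("Missing data prevents assessment at %d",
                              "site(s): %s."), nrow(nc),
                        paste(sort(nc$site_id), collapse = ", ")))
  } else {
    ln <- c(ln, "All sites were assessable (no missing calls or coverage gaps).")
  }
  ln <- c(ln, "")
  if (!is.null(groups)) {
    bm <- benchmark_against_groups(results, groups)
    ln <- c(ln, "## Baseline benchmarking", "",
            sprintf("- Missed Group A variants: %d%s",
                    length(bm$missed_group_a),
                    if (length(bm$missed_group_a))
                      paste0(" (site_id ",
                             paste(bm$missed_group_a, collapse = ", "), ")")
                    else ""),
            sprintf("- Group B violations: %d%s",
                    length(bm$violated_group_b),
                    if (length(bm$violated_group_b))
                      paste0(" (site_id ",
                             paste(bm$violated_group_b, collapse = ", "), ")")
                    else ""), "")
  }
  if (!is.null(baseline_summaries)) {
    ln <- c(ln, "## Comparison with baseline pipelines", "",
            paste("| Pipeline | Sensitivity | Specificity |",
                  "False detection rate |"),
            "|---|---|---|---|",
            sprintf("| this run | %s | %s | %s |", summary$sensitivity[1],
                    summary$specificity[1], summary$fdr[1]))
    for (nm in names(baseline_summaries)) {
      b <- baseline_summaries[[nm]]
      ln <- c(ln, sprintf("| %s | %s | %s | %s |", nm, b$sensitivity[1],
                          b$specificity[1], b$fdr[1]))
    }
    ln <- c(ln, "")
  }
  structure(ln, class = "valbench_report")
}

#' @export
print.valbench_report <- function(x, ...) {
  cat(unclass(x), sep = "\n")
  invisible(x)
}

#' Read a FullResults.txt file back into a results table
#'
#' Restores the full-results table written by
#' \code{\link{write_result_tables}} for group assignment, benchmarking
#' and run comparison.  The per-site call records are not stored in the
#' file, so a quality sweep requires re-evaluating from the VCFs instead.
#'
#' @param path Path to a FullResults.txt file.
#' @return A \code{valbench_results} data frame (without site records).
#' @export
read_full_results <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           na.strings = "NA", quote = "")
  need <- c("site_id", "polarity", "variant_class", "status",
            "detection_count", "no_call")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("not a FullResults table; missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (ch in c("expected_ref", "expected_alt", "transcript_id", "flag"))
    if (ch %in% names(tab)) tab[[ch]][is.na(tab[[ch]])] <- ""
  class(tab) <- c("valbench_results", "data.frame")
  tab
}
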