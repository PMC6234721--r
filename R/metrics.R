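#' @title Summary metrics, baselines, regression comparison, filter sweeps
#' @name metrics_summary
NULL

.categories <- c("overall", "substitutions", "indels")

#' Format a count rate as "n/d (p%)"
#'
#' The percent is rounded to the nearest integer with ties to even (the
#' convention of base \code{round}, which reproduces the published
#' benchmark cells, e.g. 7/280 prints as 2\%).  A zero denominator yields
#' \code{"NA"}.
#'
#' @param numerator,denominator Non-negative counts, numerator <= denominator.
#' @return Character scalar.
#' @examples
#' format_rate(404, 416)  # "404/416 (97%)"
#' format_rate(20, 301)   # "20/301 (7%)"
#' @export
format_rate <- function(numerator, denominator) {
  stopifnot(length(numerator) == 1L, length(denominator) == 1L,
            numerator >= 0, denominator >= 0)
  if (numerator > denominator)
    stop("numerator exceeds denominator (", numerator, "/", denominator, ")",
         call. = FALSE)
  if (denominator == 0) return("NA")
  p <- round(100 * numerator / denominator)
  sprintf("%d/%d (%d%%)", numerator, denominator, p)
}

# Category membership of result rows: substitutions vs indel-type sites.
.category_rows <- function(results, category) {
  switch(category,
         overall = rep(TRUE, nrow(results)),
         substitutions = results$variant_class == "substitution",
         indels = results$variant_class != "substitution")
}

#' Summarize site evaluations into sensitivity, specificity and FDR
#'
#' Counts TP/FN/TN/FP per category (overall, base substitutions, indels)
#' from the site statuses and derives sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP) and false detection rate = FP/(FP+TP), each
#' formatted via \code{\link{format_rate}}.
#'
#' @param results Full-results table from \code{\link{evaluate_all}} (any
#'   data frame with \code{variant_class} and \code{status} columns works).
#' @return Data frame of class \code{summary_metrics} with one row per
#'   category and columns \code{TP}, \code{FN}, \code{TN}, \code{FP},
#'   \code{sensitivity}, \code{specificity}, \code{fdr}.
#' @export
compute_summary <- function(results) {
  stopifnot(all(c("variant_class", "status") %in% names(results)))
  rows <- lapply(.categories, function(cat) {
    r <- results[.category_rows(results, cat), , drop = FALSE]
    tp <- sum(r$status == "TP"); fn <- sum(r$status == "FN")
    tn <- sum(r$status == "TN"); fp <- sum(r$status == "FP")
    data.frame(category = cat, TP = tp, FN = fn, TN = tn, FP = fp,
               sensitivity = format_rate(tp, tp + fn),
               specificity = format_rate(tn, tn + fp),
               fdr = format_rate(fp, fp + tp),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("summary_metrics", "data.frame")
  out
}

#' @export
print.summary_metrics <- function(x, ...) {
  cat("Performance summary\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-14s sensitivity %-16s specificity %-16s FDR %s\n",
                x$category[i], x$sensitivity[i], x$specificity[i], x$fdr[i]))
  invisible(x)
}

#' Derive baseline Group A / Group B site sets
#'
#' Group A holds the positive sites detected (status TP) by every baseline
#' run; any adequate pipeline is expected to call all of them.  Group B
#' holds the negative sites that are clean in every baseline run — status
#' TN with detection count 0 and assessable (not a no-call) — where no
#' adequate pipeline should call a variant.  Sites discordant across
#' baselines, and no-call negatives, belong to neither group.
#'
#' @param baseline_results List of one or more full-results tables over
#'   the same catalog.
#' @param labels Optional baseline names.
#' @return A \code{group_assignment} list with \code{group_a},
#'   \code{group_b} (sorted site_id vectors) and \code{baseline_labels}.
#' @export
assign_groups <- function(baseline_results, labels = NULL) {
  if (inherits(baseline_results, "data.frame"))
    baseline_results <- list(baseline_results)
  stopifnot(length(baseline_results) >= 1L)
  ids <- sort(baseline_results[[1]]$site_id)
  for (b in baseline_results[-1])
    if (!identical(sort(b$site_id), ids))
      stop("baseline tables cover different site_id sets", call. = FALSE)
  ref <- baseline_results[[1]]
  positives <- ref$site_id[ref$polarity == "positive"]
  negatives <- ref$site_id[ref$polarity == "negative"]
  in_a <- rep(TRUE, length(positives)); in_b <- rep(TRUE, length(negatives))
  for (b in baseline_results) {
    b <- b[order(b$site_id), , drop = FALSE]
    st <- stats::setNames(b$status, b$site_id)
    dc <- stats::setNames(b$detection_count, b$site_id)
    nc <- stats::setNames(b$no_call, b$site_id)
    in_a <- in_a & st[as.character(positives)] == "TP"
    in_b <- in_b & st[as.character(negatives)] == "TN" &
      dc[as.character(negatives)] == 0 & !nc[as.character(negatives)]
  }
  structure(list(group_a = sort(positives[in_a]),
                 group_b = sort(negatives[in_b]),
                 baseline_labels = labels %||%
                   paste0("baseline_", seq_along(baseline_results))),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat(sprintf("Baseline groups from %d run(s): Group A %d sites, Group B %d sites\n",
              length(x$baseline_labels), length(x$group_a), length(x$group_b)))
  invisible(x)
}

#' Benchmark a run against baseline groups
#'
#' @param results Full-results table of the run under assessment.
#' @param groups A \code{group_assignment}.
#' @return List with \code{missed_group_a} (Group A sites the run did not
#'   call TP) and \code{violated_group_b} (Group B sites where the run
#'   made a false call).
#' @export
benchmark_against_groups <- function(results, groups) {
  stopifnot(inherits(groups, "group_assignment"))
  st <- stats::setNames(results$status, results$site_id)
  if (!all(as.character(groups$group_a) %in% names(st)) ||
      !all(as.character(groups$group_b) %in% names(st)))
    stop("results table does not cover all group sites", call. = FALSE)
  list(missed_group_a =
         groups$group_a[st[as.character(groups$group_a)] != "TP"],
       violated_group_b =
         groups$group_b[st[as.character(groups$group_b)] == "FP"])
}

#' Site-level regression comparison of two evaluation runs
#'
#' Classifies every site whose verdict changed between an old and a new
#' run: \code{gained_detection} (FN to TP), \code{lost_detection} (TP to
#' FN), \code{gained_false_call} (TN to FP), \code{lost_false_call} (FP to
#' TN), \code{detection_count_change} (same status, different in-window
#' count) and \code{representation_change} (same status, different
#' representation accuracy).  A site may carry several labels.
#'
#' @param results_old,results_new Full-results tables over the same catalog.
#' @return Data frame of class \code{run_comparison} with one row per
#'   (site, change type); the number of unchanged sites is stored in the
#'   \code{"n_unchanged"} attribute.
#' @export
compare_runs <- function(results_old, results_new) {
  if (!identical(sort(results_old$site_id), sort(results_new$site_id)))
    stop("runs cover different site_id sets", call. = FALSE)
  o <- results_old[order(results_old$site_id), , drop = FALSE]
  n <- results_new[order(results_new$site_id), , drop = FALSE]
  changes <- list()
  add <- function(i, type) {
    changes[[length(changes) + 1L]] <<- data.frame(
      site_id = o$site_id[i], change_type = type,
      old_status = o$status[i], new_status = n$status[i],
      old_detection = o$detection_count[i],
      new_detection = n$detection_count[i], stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(o))) {
    so <- o$status[i]; sn <- n$status[i]
    if (so == "FN" && sn == "TP") add(i, "gained_detection")
    if (so == "TP" && sn == "FN") add(i, "lost_detection")
    if (so == "TN" && sn == "FP") add(i, "gained_false_call")
    if (so == "FP" && sn == "TN") add(i, "lost_false_call")
    if (so == sn) {
      if (o$detection_count[i] != n$detection_count[i])
        add(i, "detection_count_change")
      ro <- o$represented_correctly[i]; rn <- n$represented_correctly[i]
      if (!is.na(ro) && !is.na(rn) && ro != rn)
        add(i, "representation_change")
    }
  }
  out <- if (length(changes)) do.call(rbind, changes)
         else data.frame(site_id = integer(), change_type = character(),
                         old_status = character(), new_status = character(),
                         old_detection = integer(), new_detection = integer(),
                         stringsAsFactors = FALSE)
  attr(out, "n_unchanged") <- nrow(o) - length(unique(out$site_id))
  class(out) <- c("run_comparison", "data.frame")
  out
}

#' @export
print.run_comparison <- function(x, ...) {
  cat("Run comparison:", length(unique(x$site_id)), "site(s) changed,",
      attr(x, "n_unchanged"), "unchanged\n")
  if (nrow(x)) print(table(x$change_type))
  invisible(x)
}

# Re-derive the no-call context of a result row (used by the sweep).
.ctx_from_row <- function(row) {
  list(missing_genotype = identical(row$flag, "no_call:missing_genotype"),
       uncovered = identical(row$flag, "no_call:uncovered"),
       absent = identical(row$flag, "no_call:callset_absent"))
}

#' Sweep a QUAL threshold and recompute the summary metrics
#'
#' For each threshold t the per-site verdicts are recomputed from the
#' stored per-site call records, counting only calls of the filtered
#' class with \code{QUAL >= t} (calls of the other class are unaffected).
#' Records without a QUAL value are treated as below every threshold and
#' flagged with a warning.  Because statuses are recomputed from records,
#' sites holding both high- and low-quality calls are handled correctly,
#' and false-positive counts are non-increasing in t.
#'
#' @param results Full-results table from \code{\link{evaluate_all}} (must
#'   carry the \code{"site_records"} attribute).
#' @param thresholds Numeric vector of QUAL thresholds.
#' @param variant_class_filter Which call class the threshold applies to:
#'   \code{"substitution"}, \code{"indel"} or \code{"both"}.
#' @return Data frame of class \code{quality_sweep}: one row per
#'   (threshold, category) with the recomputed counts and rates.
#' @export
sweep_quality_threshold <- function(results, thresholds,
                                    variant_class_filter = c("substitution",
                                                             "indel", "both")) {
  variant_class_filter <- match.arg(variant_class_filter)
  site_records <- attr(results, "site_records")
  if (is.null(site_records))
    stop("results must carry per-site records ",
         "(use the table returned by evaluate_all)", call. = FALSE)
  stopifnot(length(thresholds) >= 1L)
  scope <- switch(variant_class_filter,
                  substitution = "substitution",
                  indel = .indel_classes,
                  both = c("substitution", .indel_classes))
  if (any(vapply(site_records,
                 function(r) nrow(r) > 0 && anyNA(r$qual), logical(1))))
    warning("some calls lack a QUAL value; they are treated as below ",
            "every threshold", call. = FALSE)
  out <- list()
  for (t in thresholds) {
    res_t <- results
    for (i in seq_len(nrow(results))) {
      cand <- site_records[[as.character(results$site_id[i])]]
      if (nrow(cand)) {
        keep <- !(cand$record_class %in% scope) |
          (!is.na(cand$qual) & cand$qual >= t)
        cand <- cand[keep, , drop = FALSE]
      }
      site <- as.list(results[i, , drop = FALSE])
      v <- .site_verdict(site, cand, .ctx_from_row(site))
      res_t$status[i] <- v$status
      res_t$detection_count[i] <- v$detection_count
      res_t$exact_match[i] <- v$exact_match
      res_t$represented_correctly[i] <- v$represented_correctly
      res_t$no_call[i] <- v$no_call
    }
    s <- compute_summary(res_t)
    s$threshold <- t
    out[[length(out) + 1L]] <- s
  }
  out <- do.call(rbind, lapply(out, as.data.frame))
  out <- out[, c("threshold", setdiff(names(out), "threshold"))]
  rownames(out) <- NULL
  class(out) <- c("quality_sweep", "data.frame")
  out
}

#' @export
print.quality_sweep <- function(x, ...) {
  cat("QUAL threshold sweep (", length(unique(x$threshold)),
      " thresholds)\n", sep = "")
  print.data.frame(x)
  invisible(x)
}

#' Read / write a baseline groups file
#'
#' Tab-separated with header \code{site_id<TAB>group}, group A or B.
#'
#' @param path File path.
#' @return \code{read_groups}: a \code{group_assignment} (without baseline
#'   labels); \code{write_groups}: \code{path}, invisibly.
#' @export
read_groups <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("site_id", "group") %in% names(tab)))
  if (!all(tab$group %in% c("A", "B")))
    stop("group column must be 'A' or 'B'", call. = FALSE)
  structure(list(group_a = sort(tab$site_id[tab$group == "A"]),
                 group_b = sort(tab$site_id[tab$group == "B"]),
                 baseline_labels = character()),
            class = "group_assignment")
}

#' @rdname read_groups
#' @param groups A \code{group_assignment}.
#' @export
write_groups <- function(groups, path) {
  stopifnot(inherits(groups, "group_assignment"))
  tab <- data.frame(site_id = c(groups$group_a, groups$group_b),
                    group = c(rep("A", length(groups$group_a)),
                              rep("B", length(groups$group_b))),
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
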