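#' @title Site-level evaluation
#' @description Scores every truth site against its sample's callset.
#'   Base substitutions are matched at the exact position with exact
#'   alleles; indel-type sites count indel calls inside a 200 bp window
#'   centred on the site and additionally check whether any in-window call
#'   reproduces the truth alleles exactly after normalization (detection
#'   vs representation).  Missing genotypes and uncovered loci (gVCF) are
#'   reported as no-calls: false negative at positive sites, flagged true
#'   negative at negative sites.
#' @name site_evaluation
NULL

#' 200 bp detection window around an indel site
#'
#' The window holds exactly 200 positions, centred with a one-base left
#' bias (an even-width window cannot be perfectly centred):
#' \code{[pos - 100, pos + 99]}, clamped below at 1.
#'
#' @param pos 1-based site position.
#' @return Integer vector \code{c(start, end)}, inclusive.
#' @examples
#' indel_window(1000)  # 900 1099
#' indel_window(50)    # 1 149
#' @export
indel_window <- function(pos) {
  stopifnot(length(pos) == 1L, pos >= 1)
  c(max(1L, as.integer(pos) - 100L), as.integer(pos) + 99L)
}

#' Exact indel match between a truth site and a call record
#'
#' True iff the truth alleles and the call agree on (chrom, pos, ref, alt)
#' after both are reduced to minimal representation, so padded spellings
#' of the same event match while split or garbled representations do not.
#'
#' @param site A positive indel-type truth site (one-row data frame or
#'   list with \code{chrom}, \code{pos}, \code{expected_ref},
#'   \code{expected_alt}).
#' @param record A call record (list or one-row data frame with
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt}).
#' @return Logical scalar.
#' @export
exact_indel_match <- function(site, record) {
  s <- normalize_record(site$chrom, site$pos, site$expected_ref,
                        site$expected_alt)
  r <- normalize_record(record$chrom, record$pos, record$ref, record$alt)
  identical(s[c("chrom", "pos", "ref", "alt")],
            r[c("chrom", "pos", "ref", "alt")])
}

# Candidate records for a site: called records of the relevant class in
# the relevant scope (exact position for substitution-type sites, the
# 200bp window for indel-type sites).  Records are already normalized.
.site_candidates <- function(site, records) {
  if (!nrow(records)) return(records)
  called <- records[records$genotype_status == "called" &
                    records$chrom == site$chrom, , drop = FALSE]
  if (site$variant_class %in% c("substitution")) {
    called[called$record_class == "substitution" &
           called$pos == site$pos, , drop = FALSE]
  } else {
    w <- indel_window(site$pos)
    called[called$record_class %in% .indel_classes &
           called$pos >= w[1] & called$pos <= w[2], , drop = FALSE]
  }
}

# No-call context: does a missing-genotype record overlap the site
# position, and (gVCF) is the position uncovered?
.no_call_context <- function(site, callset) {
  if (is.null(callset))
    return(list(missing_genotype = FALSE, uncovered = TRUE, absent = TRUE))
  recs <- callset$records
  missing_overlap <- FALSE
  if (nrow(recs)) {
    m <- recs$genotype_status == "missing" & recs$chrom == site$chrom &
      recs$pos <= site$pos & (recs$pos + nchar(recs$ref) - 1L) >= site$pos
    missing_overlap <- any(m)
  }
  uncovered <- FALSE
  if (isTRUE(callset$has_coverage)) {
    iv <- callset$covered_intervals
    hit <- nrow(iv) && any(iv$chrom == site$chrom & iv$start <= site$pos &
                           site$pos < iv$end)
    uncovered <- !hit
  }
  list(missing_genotype = missing_overlap, uncovered = uncovered,
       absent = FALSE)
}

# Core verdict from a candidate table plus no-call context.  Shared by
# evaluate_site and the quality-threshold sweep (which re-runs it on
# qual-filtered candidates).
.site_verdict <- function(site, cand, ctx) {
  positive <- site$polarity == "positive"
  is_sub <- site$variant_class == "substitution"
  exact_rows <- logical(nrow(cand))
  if (positive && nrow(cand)) {
    exact_rows <- cand$pos == site$pos & cand$ref == site$expected_ref &
      cand$alt == site$expected_alt
  }
  flag <- ""
  if (is_sub) {
    if (positive) {
      exact <- any(exact_rows)
      detection <- as.integer(exact)
      status <- if (exact) "TP" else "FN"
      if (!exact && nrow(cand)) flag <- "incorrect_call_present"
      represented <- exact
    } else {
      detection <- as.integer(nrow(cand) > 0)
      status <- if (detection > 0) "FP" else "TN"
      exact <- FALSE
      represented <- NA
    }
  } else {
    detection <- nrow(cand)
    if (positive) {
      exact <- any(exact_rows)
      status <- if (detection > 0) "TP" else "FN"
      represented <- exact
      if (status == "TP" && !represented) flag <- "misrepresented"
    } else {
      exact <- FALSE
      status <- if (detection > 0) "FP" else "TN"
      represented <- NA
    }
  }
  no_call <- FALSE
  if (nrow(cand) == 0L &&
      (ctx$absent || ctx$missing_genotype || ctx$uncovered)) {
    no_call <- TRUE
    detection <- 0L
    exact <- FALSE
    if (positive) represented <- FALSE
    status <- if (positive) "FN" else "TN"
    flag <- if (ctx$absent) "no_call:callset_absent"
            else if (ctx$missing_genotype) "no_call:missing_genotype"
            else "no_call:uncovered"
  }
  matched <- cand[exact_rows, , drop = FALSE]
  false_r <- if (!positive && status == "FP") cand
             else cand[0, , drop = FALSE]
  list(detection_count = detection, exact_match = exact,
       represented_correctly = represented, status = status,
       no_call = no_call, flag = flag, candidates = cand,
       matched_records = matched, false_records = false_r)
}

#' Evaluate one truth site against its sample's callset
#'
#' @param site One-row \code{truth_catalog} subset (or a list with the
#'   truth-site fields).
#' @param callset The \code{sample_callset} of \code{site$sample_id}, or
#'   \code{NULL} for an absent callset (the site becomes a no-call).
#' @return A \code{site_evaluation} list: \code{site_id},
#'   \code{detection_count}, \code{exact_match},
#'   \code{represented_correctly} (NA at negative sites), \code{status}
#'   (TP/FN at positive sites, TN/FP at negative sites), \code{no_call},
#'   \code{flag}, and the \code{matched_records} / \code{false_records}
#'   tables.
#' @export
evaluate_site <- function(site, callset) {
  if (is.data.frame(site)) {
    stopifnot(nrow(site) == 1L)
    site <- as.list(site)
  }
  if (!is.null(callset)) {
    stopifnot(inherits(callset, "sample_callset"))
    if (!identical(callset$sample_id, site$sample_id))
      stop("callset belongs to sample '", callset$sample_id,
           "' but the site expects '", site$sample_id, "'", call. = FALSE)
  }
  cand <- if (is.null(callset)) .empty_records()
          else .site_candidates(site, callset$records)
  v <- .site_verdict(site, cand, .no_call_context(site, callset))
  structure(c(list(site_id = site$site_id), v), class = "site_evaluation")
}

#' @export
print.site_evaluation <- function(x, ...) {
  cat(sprintf("Site %s: %s (detected %d%s%s)\n", x$site_id, x$status,
              x$detection_count,
              if (isTRUE(x$exact_match)) ", exact match" else "",
              if (x$no_call) ", no call" else ""))
  invisible(x)
}

#' Evaluate every site of a truth catalog
#'
#' Produces the full-results table: one row per truth site (ordered by
#' \code{site_id}) joining the truth fields to the per-site verdict.  A
#' sample without a callset has all its sites reported as no-calls, with a
#' warning; other samples are unaffected.
#'
#' @param catalog A \code{truth_catalog}.
#' @param callsets Named list mapping \code{sample_id} to
#'   \code{sample_callset} (e.g. from \code{\link{load_callsets}} or
#'   \code{\link{split_multi_sample}}).
#' @return A data frame of class \code{valbench_results} with the truth
#'   columns plus \code{detection_count}, \code{exact_match},
#'   \code{represented_correctly}, \code{status}, \code{no_call},
#'   \code{flag}, \code{n_matched}, \code{n_false}.  Per-site candidate
#'   records (with quality scores) are retained in the
#'   \code{"site_records"} attribute for the quality sweep and the
#'   true/false-positive output files.
#' @export
evaluate_all <- function(catalog, callsets) {
  stopifnot(inherits(catalog, "truth_catalog"))
  absent <- setdiff(unique(catalog$sample_id),
                    names(callsets)[!vapply(callsets, is.null, logical(1))])
  if (length(absent))
    warning("no callset for sample(s) ", paste(absent, collapse = ", "),
            "; their sites are reported as no-calls", call. = FALSE)
  n <- nrow(catalog)
  cols <- list(detection_count = integer(n), exact_match = logical(n),
               represented_correctly = rep(NA, n), status = character(n),
               no_call = logical(n), flag = character(n),
               n_matched = integer(n), n_false = integer(n))
  site_records <- vector("list", n)
  for (i in seq_len(n)) {
    site <- as.list(catalog[i, , drop = FALSE])
    cs <- callsets[[site$sample_id]]
    cand <- if (is.null(cs)) .empty_records()
            else .site_candidates(site, cs$records)
    v <- .site_verdict(site, cand, .no_call_context(site, cs))
    cols$detection_count[i] <- v$detection_count
    cols$exact_match[i] <- v$exact_match
    cols$represented_correctly[i] <- v$represented_correctly
    cols$status[i] <- v$status
    cols$no_call[i] <- v$no_call
    cols$flag[i] <- v$flag
    cols$n_matched[i] <- nrow(v$matched_records)
    cols$n_false[i] <- nrow(v$false_records)
    cand$role <- rep("candidate", nrow(cand))
    if (nrow(v$matched_records))
      cand$role[rownames(cand) %in% rownames(v$matched_records)] <- "matched"
    if (nrow(v$false_records)) cand$role[] <- "false"
    site_records[[i]] <- cand
  }
  out <- cbind(as.data.frame(catalog), as.data.frame(cols,
                                                     stringsAsFactors = FALSE))
  rownames(out) <- NULL
  names(site_records) <- as.character(out$site_id)
  attr(out, "site_records") <- site_records
  attr(out, "build_label") <- attr(catalog, "build_label")
  class(out) <- c("valbench_results", "data.frame")
  out
}

#' @export
print.valbench_results <- function(x, ...) {
  cat("Site evaluation:", nrow(x), "sites\n")
  tab <- table(factor(x$status, levels = c("TP", "FN", "TN", "FP")))
  cat(sprintf("  TP %d  FN %d  TN %d  FP %d  (no-call %d)\n",
              tab["TP"], tab["FN"], tab["TN"], tab["FP"], sum(x$no_call)))
  invisible(x)
}
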