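#' @title Truth-site catalogs
#' @description Functions to load, validate, write and summarize the
#'   catalog of orthogonally validated truth sites: positive sites where a
#'   variant was confirmed present (with its expected alleles) and negative
#'   sites where a variant call was confirmed absent.
#' @name truth_catalog
NULL

.truth_columns <- c("site_id", "sample_id", "chrom", "pos",
                    "expected_ref", "expected_alt", "polarity",
                    "variant_class", "transcript_id")
.positive_classes <- c("substitution", "deletion", "insertion", "complex")
.negative_classes <- c("substitution", "indel")

#' Load a truth-site catalog
#'
#' Reads the tab-separated truth file (9 fixed columns, see Details),
#' validates it and returns a \code{truth_catalog} data frame.  Expected
#' alleles of positive sites are normalized to minimal representation on
#' load; a warning is emitted if the file's representation was not already
#' minimal.
#'
#' @details The schema is a UTF-8 tab-separated table with header
#'   \code{site_id, sample_id, chrom, pos, expected_ref, expected_alt,
#'   polarity, variant_class, transcript_id}.  Positive sites carry
#'   non-empty expected alleles and a class in \code{substitution},
#'   \code{deletion}, \code{insertion}, \code{complex}; negative sites
#'   carry empty alleles and a class in \code{substitution}, \code{indel}.
#'
#' @param path Path to the truth file.
#' @param build_label Optional reference-build tag stored on the catalog.
#' @return A data frame of class \code{truth_catalog}.
#' @export
load_truth <- function(path, build_label = "unspecified") {
  if (!file.exists(path)) stop("truth file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", quote = "",
                           na.strings = NULL, check.names = FALSE,
                           fileEncoding = "UTF-8")
  missing_cols <- setdiff(.truth_columns, names(tab))
  extra_cols <- setdiff(names(tab), .truth_columns)
  if (length(missing_cols))
    stop("truth file is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (length(extra_cols))
    stop("truth file has unexpected column(s): ",
         paste(extra_cols, collapse = ", "), call. = FALSE)
  tab <- tab[, .truth_columns]
  tab$site_id <- suppressWarnings(as.integer(tab$site_id))
  tab$pos <- suppressWarnings(as.integer(tab$pos))
  cat <- as_truth_catalog(tab, build_label = build_label, normalize = TRUE)
  cat
}

#' Construct and validate a truth catalog from a data frame
#'
#' @param df Data frame with the truth-catalog columns.
#' @param build_label Reference-build tag.
#' @param normalize Normalize positive expected alleles to minimal
#'   representation (warning when the input was not minimal).
#' @return A validated \code{truth_catalog}.
#' @export
as_truth_catalog <- function(df, build_label = "unspecified", normalize = TRUE) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  stopifnot(all(.truth_columns %in% names(df)))
  df <- df[, .truth_columns]
  rownames(df) <- NULL
  .validate_truth(df)
  pos_idx <- which(df$polarity == "positive")
  if (normalize && length(pos_idx)) {
    changed <- FALSE
    for (i in pos_idx) {
      n <- normalize_record(df$chrom[i], df$pos[i],
                            df$expected_ref[i], df$expected_alt[i])
      if (n$pos != df$pos[i] || n$ref != df$expected_ref[i] ||
          n$alt != df$expected_alt[i]) changed <- TRUE
      df$pos[i] <- n$pos
      df$expected_ref[i] <- n$ref
      df$expected_alt[i] <- n$alt
    }
    if (changed)
      warning("expected alleles were not in minimal representation; ",
              "normalized on load", call. = FALSE)
    # classes must match the (now minimal) alleles
    cls <- classify_record(df$expected_ref[pos_idx], df$expected_alt[pos_idx])
    bad <- df$variant_class[pos_idx] != cls
    if (any(bad))
      stop("variant_class inconsistent with expected alleles at site_id ",
           paste(df$site_id[pos_idx][bad], collapse = ", "),
           " (expected ", paste(cls[bad], collapse = ", "), ")",
           call. = FALSE)
  }
  df <- df[order(df$site_id), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "build_label") <- build_label
  class(df) <- c("truth_catalog", "data.frame")
  df
}

.validate_truth <- function(df) {
  if (anyNA(df$site_id) || any(df$site_id <= 0))
    stop("site_id must be a positive integer", call. = FALSE)
  dup <- unique(df$site_id[duplicated(df$site_id)])
  if (length(dup))
    stop("duplicate site_id: ", paste(dup, collapse = ", "), call. = FALSE)
  if (anyNA(df$pos) || any(df$pos < 1))
    stop("pos must be >= 1", call. = FALSE)
  if (any(!nzchar(df$chrom)))
    stop("chrom must be non-empty", call. = FALSE)
  if (any(!nzchar(df$sample_id)))
    stop("sample_id must be non-empty", call. = FALSE)
  if (!all(df$polarity %in% c("positive", "negative")))
    stop("polarity must be 'positive' or 'negative'", call. = FALSE)
  pos <- df$polarity == "positive"
  if (any(pos & (!nzchar(df$expected_ref) | !nzchar(df$expected_alt))))
    stop("positive sites must carry non-empty expected alleles (site_id ",
         paste(df$site_id[pos & (!nzchar(df$expected_ref) |
                                 !nzchar(df$expected_alt))], collapse = ", "),
         ")", call. = FALSE)
  if (any(pos & df$expected_ref == df$expected_alt))
    stop("expected_ref and expected_alt must differ at positive sites",
         call. = FALSE)
  if (any(!pos & (nzchar(df$expected_ref) | nzchar(df$expected_alt))))
    stop("negative sites must have empty expected alleles", call. = FALSE)
  if (!all(df$variant_class[pos] %in% .positive_classes))
    stop("positive variant_class must be one of ",
         paste(.positive_classes, collapse = ", "), call. = FALSE)
  if (!all(df$variant_class[!pos] %in% .negative_classes))
    stop("negative variant_class must be one of ",
         paste(.negative_classes, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Write a truth catalog back to its tab-separated form
#'
#' Inverse of \code{\link{load_truth}}: \code{load_truth(write_truth(x))}
#' reproduces \code{x} field by field.
#'
#' @param catalog A \code{truth_catalog}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_truth <- function(catalog, path) {
  stopifnot(inherits(catalog, "truth_catalog"))
  utils::write.table(as.data.frame(catalog), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Census of a truth catalog by site class
#'
#' Counts the four top-level site classes (positive substitutions, positive
#' indels, negative substitutions, negative indels), the positive-indel
#' sub-classes, and the grand total.  The four top-level counts always sum
#' to the catalog size.
#'
#' @param catalog A \code{truth_catalog}.
#' @return A list with components \code{positive_substitution},
#'   \code{positive_indel}, \code{negative_substitution},
#'   \code{negative_indel}, \code{deletion}, \code{insertion},
#'   \code{complex} and \code{total}.
#' @export
catalog_census <- function(catalog) {
  stopifnot(inherits(catalog, "truth_catalog"))
  pos <- catalog$polarity == "positive"
  cls <- catalog$variant_class
  out <- list(
    positive_substitution = sum(pos & cls == "substitution"),
    positive_indel        = sum(pos & cls %in% .indel_classes),
    negative_substitution = sum(!pos & cls == "substitution"),
    negative_indel        = sum(!pos & cls == "indel"),
    deletion              = sum(pos & cls == "deletion"),
    insertion             = sum(pos & cls == "insertion"),
    complex               = sum(pos & cls == "complex"),
    total                 = nrow(catalog)
  )
  stopifnot(out$positive_substitution + out$positive_indel +
            out$negative_substitution + out$negative_indel == out$total)
  out
}

#' @export
print.truth_catalog <- function(x, ...) {
  cen <- catalog_census(x)
  cat("Truth catalog:", cen$total, "sites",
      sprintf("(build: %s)\n", attr(x, "build_label") %||% "unspecified"))
  cat(sprintf("  positive substitutions: %d\n", cen$positive_substitution))
  cat(sprintf("  positive indels:        %d (del %d / ins %d / complex %d)\n",
              cen$positive_indel, cen$deletion, cen$insertion, cen$complex))
  cat(sprintf("  negative substitutions: %d\n", cen$negative_substitution))
  cat(sprintf("  negative indels:        %d\n", cen$negative_indel))
  cat(sprintf("  samples referenced:     %d\n", length(unique(x$sample_id))))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
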