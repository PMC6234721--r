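#' @title VCF ingest
#' @description Readers that turn VCF v4.x inputs (plain single-sample,
#'   multi-sample, gVCF) into normalized single-sample callsets satisfying
#'   the evaluation contract: exactly one ALT allele per record, minimal
#'   allele representation, missing genotypes tracked, and the verbatim
#'   source line preserved for the true/false-positive output files.
#' @name vcf_ingest
NULL

.empty_records <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), qual = numeric(), filter_field = character(),
             genotype_status = character(), record_class = character(),
             raw_line = character(), stringsAsFactors = FALSE)
}

.new_callset <- function(sample_id, records, covered = NULL,
                         has_coverage = FALSE, source_path = "") {
  if (nrow(records)) {
    ord <- order(records$chrom, records$pos)
    records <- records[ord, , drop = FALSE]
    rownames(records) <- NULL
  }
  structure(list(sample_id = sample_id, records = records,
                 covered_intervals = covered %||% data.frame(
                   chrom = character(), start = integer(), end = integer(),
                   stringsAsFactors = FALSE),
                 has_coverage = has_coverage, source_path = source_path),
            class = "sample_callset")
}

#' @export
print.sample_callset <- function(x, ...) {
  cat("Sample callset:", x$sample_id, "\n")
  cat(sprintf("  records: %d (%d with missing genotype)\n", nrow(x$records),
              sum(x$records$genotype_status == "missing")))
  if (x$has_coverage)
    cat(sprintf("  coverage intervals: %d\n", nrow(x$covered_intervals)))
  invisible(x)
}

# Split a VCF file into header, column names and data lines.
.read_vcf_lines <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !startsWith(lines[1], "##fileformat=VCF"))
    stop("not a VCF v4.x file (missing ##fileformat header): ", path,
         call. = FALSE)
  hdr_idx <- which(startsWith(lines, "#CHROM"))
  if (length(hdr_idx) != 1L)
    stop("malformed VCF: expected exactly one #CHROM header line in ", path,
         call. = FALSE)
  cols <- strsplit(sub("^#", "", lines[hdr_idx]), "\t", fixed = TRUE)[[1]]
  data <- lines[seq_along(lines) > hdr_idx]
  data <- data[nzchar(data)]
  list(columns = cols, data = data,
       samples = if (length(cols) > 9L) cols[10:length(cols)] else character())
}

.gt_of <- function(format, sample_field, line_no) {
  keys <- strsplit(format, ":", fixed = TRUE)[[1]]
  gi <- match("GT", keys)
  if (is.na(gi))
    stop("malformed genotype column (no GT key) at data line ", line_no,
         call. = FALSE)
  vals <- strsplit(sample_field, ":", fixed = TRUE)[[1]]
  if (gi > length(vals)) {
    # a bare "." sample field truncates trailing keys: treat as missing
    if (identical(sample_field, ".")) return(".")
    stop("malformed genotype column at data line ", line_no, call. = FALSE)
  }
  vals[gi]
}

.gt_is_missing <- function(gt) {
  alleles <- strsplit(gt, "[/|]")[[1]]
  all(alleles == ".")
}

.check_alt_contract <- function(alt, line_no) {
  if (grepl(",", alt, fixed = TRUE))
    stop("multi-allelic ALT '", alt, "' at data line ", line_no,
         ": each record must carry exactly one ALT call", call. = FALSE)
  if (grepl("[^ACGTNacgtn]", alt))
    stop("unsupported symbolic/breakend ALT '", alt, "' at data line ",
         line_no, call. = FALSE)
  invisible(TRUE)
}

# Build one normalized CallRecord row from parsed fields.
.make_record <- function(fields, genotype_status, raw_line, line_no) {
  chrom <- fields[1]
  pos <- suppressWarnings(as.integer(fields[2]))
  if (is.na(pos)) stop("bad POS at data line ", line_no, call. = FALSE)
  ref <- fields[4]; alt <- fields[5]
  .check_alt_contract(alt, line_no)
  qual <- if (fields[6] == ".") NA_real_ else suppressWarnings(as.numeric(fields[6]))
  if (!is.na(qual) && qual < 0)
    stop("negative QUAL at data line ", line_no, call. = FALSE)
  n <- normalize_record(chrom, pos, ref, alt)
  data.frame(chrom = n$chrom, pos = n$pos, ref = n$ref, alt = n$alt,
             qual = qual, filter_field = fields[7],
             genotype_status = genotype_status,
             record_class = classify_record(n$ref, n$alt),
             raw_line = raw_line, stringsAsFactors = FALSE)
}

#' Read a single-sample VCF file
#'
#' Each data line becomes one normalized call record.  The file must carry
#' at most one sample column; a record whose genotype is \code{./.} (or a
#' bare \code{.}) is kept with \code{genotype_status = "missing"} so that
#' downstream evaluation can report the site as a no-call.  Multi-allelic
#' ALT fields and symbolic/breakend alleles are contract violations and
#' raise errors naming the offending line.
#'
#' @param path Path to a VCF v4.x file with zero or one sample column.
#' @param sample_id Sample identifier to attach to the callset.
#' @return A \code{sample_callset}.
#' @export
read_single_sample_vcf <- function(path, sample_id) {
  v <- .read_vcf_lines(path)
  if (length(v$samples) > 1L)
    stop("VCF must represent a single sample; found ", length(v$samples),
         " sample columns (", paste(v$samples, collapse = ", "), ") in ",
         path, call. = FALSE)
  has_gt <- length(v$samples) == 1L
  recs <- vector("list", length(v$data))
  for (i in seq_along(v$data)) {
    f <- strsplit(v$data[i], "\t", fixed = TRUE)[[1]]
    status <- "called"
    if (has_gt) {
      gt <- .gt_of(f[9], f[10], i)
      if (.gt_is_missing(gt)) status <- "missing"
    }
    recs[[i]] <- .make_record(f, status, v$data[i], i)
  }
  records <- if (length(recs)) do.call(rbind, recs) else .empty_records()
  .new_callset(sample_id, records, source_path = path)
}

#' Split a multi-sample VCF into per-sample callsets
#'
#' A data line is included in a sample's callset iff that sample's genotype
#' carries at least one copy of the ALT allele (allele index 1; there is
#' exactly one ALT per record by contract).  A sample whose genotype is
#' missing at a line receives the record with
#' \code{genotype_status = "missing"}; homozygous-reference genotypes are
#' dropped.  The preserved raw line is rewritten as the corresponding
#' single-sample line (fixed columns + FORMAT + that sample's field).
#'
#' @param path Path to a multi-sample VCF v4.x file.
#' @return Named list of \code{sample_callset}, one per sample column.
#' @export
split_multi_sample <- function(path) {
  v <- .read_vcf_lines(path)
  if (!length(v$samples))
    stop("no sample columns in ", path, call. = FALSE)
  per_sample <- lapply(v$samples, function(s) list())
  names(per_sample) <- v$samples
  for (i in seq_along(v$data)) {
    f <- strsplit(v$data[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L + length(v$samples))
      stop("malformed data line ", i, ": expected ",
           9L + length(v$samples), " columns, found ", length(f),
           call. = FALSE)
    for (j in seq_along(v$samples)) {
      gt <- .gt_of(f[9], f[9 + j], i)
      raw <- paste(c(f[1:9], f[9 + j]), collapse = "\t")
      if (.gt_is_missing(gt)) {
        rec <- .make_record(f, "missing", raw, i)
      } else {
        alleles <- strsplit(gt, "[/|]")[[1]]
        if (!all(alleles %in% c("0", "1", ".")))
          stop("malformed genotype '", gt, "' at data line ", i, call. = FALSE)
        if (!any(alleles == "1")) next
        rec <- .make_record(f, "called", raw, i)
      }
      per_sample[[j]] <- c(per_sample[[j]], list(rec))
    }
  }
  out <- lapply(seq_along(v$samples), function(j) {
    records <- if (length(per_sample[[j]])) do.call(rbind, per_sample[[j]])
               else .empty_records()
    .new_callset(v$samples[j], records, source_path = path)
  })
  names(out) <- v$samples
  out
}

# Merge sorted (chrom,start,end) half-open intervals, fusing adjacency.
.merge_intervals <- function(iv) {
  if (!nrow(iv)) return(iv)
  iv <- iv[order(iv$chrom, iv$start), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    k <- nrow(out)
    if (iv$chrom[i] == out$chrom[k] && iv$start[i] <= out$end[k]) {
      out$end[k] <- max(out$end[k], iv$end[i])
    } else {
      out <- rbind(out, iv[i, , drop = FALSE])
    }
  }
  rownames(out) <- NULL
  out
}

#' Flatten a single-sample gVCF into a callset with coverage intervals
#'
#' Variant rows become normalized call records (a trailing
#' \code{<NON_REF>} alternative, inherent to gVCF, is stripped before the
#' single-ALT contract is applied).  Reference-block rows (\code{ALT} of
#' \code{.} or \code{<NON_REF>}) populate the covered intervals from their
#' \code{END} annotation; adjacent blocks are merged.  A locus under
#' neither a variant record nor a reference block is later reported as a
#' no-call by site evaluation.
#'
#' @param path Path to a single-sample gVCF.
#' @param sample_id Sample identifier.
#' @return A \code{sample_callset} with \code{has_coverage = TRUE}.
#' @export
flatten_gvcf <- function(path, sample_id) {
  v <- .read_vcf_lines(path)
  if (length(v$samples) > 1L)
    stop("gVCF must represent a single sample; found ",
         length(v$samples), " sample columns in ", path, call. = FALSE)
  has_gt <- length(v$samples) == 1L
  recs <- list(); ivs <- list()
  for (i in seq_along(v$data)) {
    f <- strsplit(v$data[i], "\t", fixed = TRUE)[[1]]
    alt <- f[5]
    if (alt %in% c(".", "<NON_REF>")) {
      m <- regmatches(f[8], regexpr("(?:^|;)END=([0-9]+)", f[8], perl = TRUE))
      if (!length(m))
        stop("reference block without a valid END at data line ", i,
             call. = FALSE)
      end <- as.integer(sub(".*END=", "", m))
      pos <- as.integer(f[2])
      if (is.na(end) || end < pos)
        stop("reference block without a valid END at data line ", i,
             call. = FALSE)
      ivs[[length(ivs) + 1L]] <- data.frame(
        chrom = f[1], start = pos, end = end + 1L, stringsAsFactors = FALSE)
      next
    }
    f[5] <- sub(",<NON_REF>$", "", alt)
    status <- "called"
    if (has_gt) {
      gt <- .gt_of(f[9], f[10], i)
      if (.gt_is_missing(gt)) status <- "missing"
    }
    rec <- .make_record(f, status, v$data[i], i)
    recs[[length(recs) + 1L]] <- rec
    # a variant record asserts coverage over its (raw) REF span
    ivs[[length(ivs) + 1L]] <- data.frame(
      chrom = f[1], start = as.integer(f[2]),
      end = as.integer(f[2]) + nchar(f[4]), stringsAsFactors = FALSE)
  }
  records <- if (length(recs)) do.call(rbind, recs) else .empty_records()
  covered <- if (length(ivs)) .merge_intervals(do.call(rbind, ivs))
             else data.frame(chrom = character(), start = integer(),
                             end = integer(), stringsAsFactors = FALSE)
  .new_callset(sample_id, records, covered = covered, has_coverage = TRUE,
               source_path = path)
}

#' Read a sample map (sample_id to VCF path)
#'
#' Two-column tab-separated table; a header row
#' \code{sample_id<TAB>vcf_path} is recognized and skipped.  Relative VCF
#' paths are resolved against the map file's directory.
#'
#' @param path Path to the sample-map file.
#' @return Data frame with columns \code{sample_id}, \code{vcf_path}.
#' @export
read_sample_map <- function(path) {
  if (!file.exists(path)) stop("sample map not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("sample map must have exactly two tab-separated columns",
         call. = FALSE)
  m <- do.call(rbind, parts)
  if (identical(unname(m[1, ]), c("sample_id", "vcf_path")))
    m <- m[-1, , drop = FALSE]
  vcf_path <- ifelse(grepl("^/", m[, 2]), m[, 2],
                     file.path(dirname(path), m[, 2]))
  data.frame(sample_id = m[, 1], vcf_path = vcf_path,
             stringsAsFactors = FALSE)
}

#' Load all callsets referenced by a sample map
#'
#' @param sample_map Data frame from \code{\link{read_sample_map}} (or of
#'   the same shape).
#' @param gvcf Read files as gVCF (\code{\link{flatten_gvcf}}) instead of
#'   plain single-sample VCF.
#' @return Named list of \code{sample_callset}; a sample whose file is
#'   absent maps to \code{NULL} with a warning (its sites become no-calls).
#' @export
load_callsets <- function(sample_map, gvcf = FALSE) {
  out <- vector("list", nrow(sample_map))
  names(out) <- sample_map$sample_id
  for (i in seq_len(nrow(sample_map))) {
    p <- sample_map$vcf_path[i]
    if (!file.exists(p)) {
      warning("VCF for sample ", sample_map$sample_id[i],
              " not found (", p, "); its sites will be no-calls",
              call. = FALSE)
      out[i] <- list(NULL)
      next
    }
    out[[i]] <- if (gvcf) flatten_gvcf(p, sample_map$sample_id[i])
                else read_single_sample_vcf(p, sample_map$sample_id[i])
  }
  out
}
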