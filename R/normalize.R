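#' Reduce an allele pair to its minimal representation
#'
#' Variant callers emit the same event in many equivalent spellings
#' (padded, partially trimmed, shifted).  Comparing calls to truth alleles
#' therefore requires both to be reduced to a canonical minimal form first:
#' the longest shared suffix is stripped, then the longest shared prefix
#' (advancing the position by the number of leading bases removed), always
#' keeping at least one base in each allele.  For example \code{GTCA/ATCA}
#' at position 100 trims to \code{G/A} at 100, and \code{TGA/TGC} at 200
#' trims to \code{A/C} at 202.
#'
#' When a reference context is supplied, length-changing variants are
#' additionally left-aligned: the event is shifted leftwards through
#' identical reference sequence to its leftmost equivalent position, then
#' re-anchored.  Without a context the trimmed position is kept; because
#' truth sites and calls are normalized identically, matching is
#' well defined either way.
#'
#' The operation is idempotent.
#'
#' @param chrom Chromosome name (carried through unchanged).
#' @param pos 1-based position of the first base of \code{ref}.
#' @param ref,alt Allele strings over \code{A,C,G,T,N}; must differ and be
#'   non-empty.
#' @param context Optional reference context for left alignment: a single
#'   string giving the sequence of \code{chrom} starting at base 1.
#' @return A list with elements \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt} holding the minimal representation.
#' @examples
#' normalize_record("chr1", 100, "GTCA", "ATCA")   # -> 100 G/A
#' normalize_record("chr1", 200, "TGA", "TGC")     # -> 202 A/C
#' normalize_record("chr1", 999, "CAT", "CA")      # -> 1000 AT/A
#' @export
normalize_record <- function(chrom, pos, ref, alt, context = NULL) {
  stopifnot(length(pos) == 1L, length(ref) == 1L, length(alt) == 1L)
  if (!nzchar(ref) || !nzchar(alt))
    stop("ref and alt must be non-empty", call. = FALSE)
  if (ref == alt)
    stop("ref and alt must differ", call. = FALSE)
  if (!grepl("^[ACGTN]+$", ref) || !grepl("^[ACGTN]+$", alt))
    stop("alleles must use the alphabet A,C,G,T,N (got ", ref, "/", alt, ")",
         call. = FALSE)
  out <- .trim_alleles(as.integer(pos), ref, alt)
  if (!is.null(context) && nchar(out$ref) != nchar(out$alt))
    out <- .left_align(out$pos, out$ref, out$alt, context)
  list(chrom = chrom, pos = out$pos, ref = out$ref, alt = out$alt)
}

# Suffix-then-prefix trimming, retaining >=1 base per allele.
.trim_alleles <- function(pos, ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  while (nr > 1L && na > 1L &&
         substr(ref, nr, nr) == substr(alt, na, na)) {
    nr <- nr - 1L; na <- na - 1L
  }
  ref <- substr(ref, 1L, nr); alt <- substr(alt, 1L, na)
  k <- 0L
  while (nr - k > 1L && na - k > 1L &&
         substr(ref, k + 1L, k + 1L) == substr(alt, k + 1L, k + 1L)) {
    k <- k + 1L
  }
  list(pos = pos + k, ref = substr(ref, k + 1L, nr), alt = substr(alt, k + 1L, na))
}

# Left-align a trimmed length-changing variant through identical reference
# context (vt-normalize style: shrink shared ends, extend left, re-anchor).
.left_align <- function(pos, ref, alt, context) {
  ctx_at <- function(p) substr(context, p, p)
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    if (nr > 0L && na > 0L && substr(ref, nr, nr) == substr(alt, na, na)) {
      ref <- substr(ref, 1L, nr - 1L)
      alt <- substr(alt, 1L, na - 1L)
    } else if (nr == 0L || na == 0L) {
      if (pos <= 1L || !nzchar(ctx_at(pos - 1L))) break
      b <- ctx_at(pos - 1L)
      ref <- paste0(b, ref); alt <- paste0(b, alt)
      pos <- pos - 1L
    } else break
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  if (!nzchar(ref) || !nzchar(alt)) {
    # context exhausted on the left edge: anchor on the right instead
    p_after <- pos + nchar(ref)
    b <- ctx_at(p_after)
    ref <- paste0(ref, b); alt <- paste0(alt, b)
  }
  list(pos = pos, ref = ref, alt = alt)
}

# Vectorized trim for internal use on record tables (no left alignment).
.trim_alleles_vec <- function(pos, ref, alt) {
  n <- length(pos)
  out_pos <- integer(n); out_ref <- character(n); out_alt <- character(n)
  for (i in seq_len(n)) {
    t <- .trim_alleles(as.integer(pos[i]), ref[i], alt[i])
    out_pos[i] <- t$pos; out_ref[i] <- t$ref; out_alt[i] <- t$alt
  }
  list(pos = out_pos, ref = out_ref, alt = out_alt)
}

#' Classify a minimally represented allele pair
#'
#' @param ref,alt Allele strings in minimal representation (see
#'   \code{\link{normalize_record}}); vectorized.
#' @return Character vector over \code{substitution}, \code{insertion}
#'   (ref is a proper prefix of alt), \code{deletion} (alt is a proper
#'   prefix of ref) or \code{complex}.
#' @examples
#' classify_record("A", "G")          # substitution
#' classify_record("A", "AT")         # insertion
#' classify_record(c("ATT", "AG"), c("A", "TC"))  # deletion, complex
#' @export
classify_record <- function(ref, alt) {
  stopifnot(length(ref) == length(alt))
  nr <- nchar(ref); na <- nchar(alt)
  cls <- rep("complex", length(ref))
  cls[nr == 1L & na == 1L] <- "substitution"
  cls[nr < na & substr(alt, 1L, nr) == ref] <- "insertion"
  cls[na < nr & substr(ref, 1L, na) == alt] <- "deletion"
  cls
}

# Indel-type record classes (everything length-changing or multi-base).
.indel_classes <- c("insertion", "deletion", "complex")
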