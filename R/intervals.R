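#' Genomic intervals
#'
#' All coordinates in this package are 1-based and inclusive on both ends, the
#' convention of array CNV callers and of the published candidate tables this
#' pipeline mirrors. Chromosome labels are carried without a "chr" prefix
#' ("8", "X"); readers strip the prefix on input.
#'
#' @param chrom chromosome label (character); "chr" prefixes are stripped.
#' @param start,end 1-based inclusive base positions, `end >= start >= 1`.
#' @return a tibble with columns `chrom`, `start`, `end` (one row per
#'   interval); vectorised over its arguments.
#' @examples
#' genomic_interval("chr8", 83573868, 83964230)
#' @export
genomic_interval <- function(chrom, start, end) {
  chrom <- normalize_chrom(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(is.na(chrom)) || any(is.na(start)) || any(is.na(end))) {
    stop("genomic_interval: missing chrom/start/end", call. = FALSE)
  }
  if (any(start < 1)) stop("genomic_interval: start must be >= 1", call. = FALSE)
  if (any(end < start)) stop("genomic_interval: end < start", call. = FALSE)
  tibble::tibble(chrom = chrom, start = start, end = end)
}

#' Strip "chr" prefixes from chromosome labels
#' @param x character vector of chromosome labels.
#' @return labels in un-prefixed form ("8", "X", "Y").
#' @export
normalize_chrom <- function(x) {
  sub("^chr", "", as.character(x), ignore.case = TRUE)
}

assert_valid_interval <- function(x, what = "interval") {
  if (!all(c("chrom", "start", "end") %in% names(x))) {
    stop(what, ": needs chrom/start/end columns", call. = FALSE)
  }
  if (nrow(x) > 0 && (any(x$end < x$start) || any(x$start < 1))) {
    stop(what, ": malformed interval (end < start or start < 1)", call. = FALSE)
  }
  invisible(x)
}

#' Shared bases between two intervals
#'
#' Number of bases shared by `a` and `b` under 1-based inclusive coordinates:
#' adjacent intervals (e.g. 1-10 and 11-20) share nothing, intervals meeting at
#' a single base (1-10 and 10-20) share one.
#'
#' @param a,b single-row interval tibbles (see [genomic_interval()]).
#' @return integer number of shared bases; 0 when on different chromosomes or
#'   disjoint. Symmetric in its arguments.
#' @export
overlap_bp <- function(a, b) {
  assert_valid_interval(a, "overlap_bp: a")
  assert_valid_interval(b, "overlap_bp: b")
  if (a$chrom != b$chrom) return(0L)
  as.integer(max(0, min(a$end, b$end) - max(a$start, b$start) + 1))
}

#' Fraction of a query interval covered by a feature set
#'
#' The fraction of the query's bases covered by the union of the features;
#' overlapping features are never double-counted. Only features on the query's
#' chromosome contribute. This is the quantity the candidate-selection rules
#' threshold ("< 35% overlap with" a reference polymorphism set).
#'
#' @param query single-row interval tibble.
#' @param features interval tibble (any number of rows, any chromosomes).
#' @return fraction in \[0, 1\].
#' @export
coverage_fraction <- function(query, features) {
  assert_valid_interval(query, "coverage_fraction: query")
  if (nrow(query) != 1) stop("coverage_fraction: query must be a single interval", call. = FALSE)
  if (is.null(features) || nrow(features) == 0) return(0)
  assert_valid_interval(features, "coverage_fraction: features")
  feats <- features[features$chrom == query$chrom, , drop = FALSE]
  if (nrow(feats) == 0) return(0)
  q <- IRanges::IRanges(start = query$start, end = query$end)
  f <- IRanges::reduce(IRanges::IRanges(start = feats$start, end = feats$end))
  covered <- sum(IRanges::width(IRanges::intersect(q, f)))
  covered / IRanges::width(q)
}

#' Reciprocal overlap of two intervals
#'
#' The smaller of the two coverage fractions: both intervals must cover at
#' least this fraction of each other. Used for caller-concordance labeling and
#' recurrence grouping.
#' @param a,b single-row interval tibbles.
#' @return fraction in \[0, 1\].
#' @export
reciprocal_overlap <- function(a, b) {
  ov <- overlap_bp(a, b)
  if (ov == 0) return(0)
  min(ov / (a$end - a$start + 1), ov / (b$end - b$start + 1))
}

#' Round half away from zero
#'
#' Deterministic commercial rounding (0.5 always rounds up in magnitude),
#' unlike base R's round-half-to-even. Matches every printed size and
#' percentage in the study's tables.
#' @param x numeric vector.
#' @param digits decimal places to keep.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Interval size in kilobases
#'
#' `(end - start + 1) / 1000`, rounded half away from zero to the nearest
#' integer Kb, the convention recovered from the study's candidate table.
#' @param i interval tibble (vectorised over rows).
#' @return integer Kb per row.
#' @export
size_kb <- function(i) {
  assert_valid_interval(i, "size_kb")
  as.integer(round_half_away((i$end - i$start + 1) / 1000))
}

#' Interval size in bases
#' @param i interval tibble.
#' @return numeric vector of sizes (end - start + 1).
#' @export
size_bp <- function(i) {
  assert_valid_interval(i, "size_bp")
  i$end - i$start + 1
}
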