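#' Apply per-caller confidence and probe-count thresholds
#'
#' Retains partitionstyle calls with confidence >= 35 (the caller's default
#' threshold), pennstyle calls with confidence >= 10, and in both cases only
#' calls supported by at least `min_probes` consecutive probes (three, the
#' calling floor used genome-wide). Idempotent.
#'
#' @param calls a calls tibble (see [read_cnv_calls()]).
#' @param penn_conf,partition_conf per-caller confidence floors.
#' @param min_probes minimum probe support.
#' @return the retained subset.
#' @export
apply_caller_thresholds <- function(calls, penn_conf = 10, partition_conf = 35,
                                    min_probes = 3) {
  floor_for <- ifelse(calls$caller == "pennstyle", penn_conf, partition_conf)
  keep <- !is.na(calls$confidence) & calls$confidence >= floor_for &
    calls$n_probes >= min_probes
  calls[keep, , drop = FALSE]
}

#' Merge adjacent same-state calls
#'
#' Mirrors the merge step applied to raw caller output: two calls from the
#' same sample, caller, chromosome and copy number are merged when the
#' inter-call gap is at most `gap_fraction` of the span of the merged call
#' (default 0.2, the documented default of the PennCNV clean_cnv utility).
#' Merging iterates to a fixed point; the merged call's probe count is the sum
#' and its confidence the minimum of its parts.
#'
#' @param calls calls tibble.
#' @param gap_fraction maximum gap as a fraction of the merged span.
#' @return merged calls tibble.
#' @export
merge_adjacent_calls <- function(calls, gap_fraction = 0.2) {
  if (gap_fraction < 0) stop("merge_adjacent_calls: negative gap_fraction", call. = FALSE)
  if (nrow(calls) < 2) return(calls)
  key <- paste(calls$sample, calls$caller, calls$chrom, calls$copy_number, sep = "\r")
  merged <- lapply(split(calls, key), merge_group, gap_fraction = gap_fraction)
  out <- dplyr::bind_rows(merged)
  out[order(out$sample, out$caller, chrom_rank(out$chrom), out$start), , drop = FALSE]
}

merge_group <- function(g, gap_fraction) {
  repeat {
    g <- g[order(g$start), , drop = FALSE]
    if (nrow(g) < 2) return(g)
    done <- TRUE
    i <- 1
    while (i < nrow(g)) {
      gap <- g$start[i + 1] - g$end[i] - 1
      span <- max(g$end[i], g$end[i + 1]) - g$start[i] + 1
      if (gap <= gap_fraction * span) {
        g$end[i] <- max(g$end[i], g$end[i + 1])
        g$n_probes[i] <- g$n_probes[i] + g$n_probes[i + 1]
        g$confidence[i] <- min(g$confidence[i], g$confidence[i + 1])
        g$end_marker[i] <- g$end_marker[i + 1]
        g <- g[-(i + 1), , drop = FALSE]
        done <- FALSE
      } else {
        i <- i + 1
      }
    }
    if (done) return(g)
  }
}

#' Label cross-caller concordance
#'
#' A call is labeled `"both"` when the other caller has a same-sample,
#' same-CNV-type call with at least `reciprocal` reciprocal overlap (default
#' 0.5, the field convention); otherwise `"penn_only"` / `"partition_only"`.
#' The union of calls is retained downstream regardless of label.
#'
#' @param penn,partition thresholded, merged calls tibbles from the two callers.
#' @param reciprocal reciprocal-overlap floor for a match.
#' @param sex optional named vector (sample -> "M"/"F") for typing
#'   sex-chromosome calls; autosomal typing needs none.
#' @return one tibble: the union of both inputs with a `concordance` column.
#' @export
label_concordance <- function(penn, partition, reciprocal = 0.5, sex = NULL) {
  penn$cnv_type <- cnv_type_of(penn, sex)
  partition$cnv_type <- cnv_type_of(partition, sex)
  match_one <- function(call, others) {
    if (nrow(others) == 0) return(FALSE)
    cand <- others[others$sample == call$sample &
                     others$chrom == call$chrom &
                     others$cnv_type == call$cnv_type, , drop = FALSE]
    if (nrow(cand) == 0) return(FALSE)
    any(vapply(seq_len(nrow(cand)), function(i) {
      reciprocal_overlap(call, cand[i, ]) >= reciprocal
    }, TRUE))
  }
  lab <- function(calls, others, only) {
    if (nrow(calls) == 0) return(character())
    vapply(seq_len(nrow(calls)), function(i) {
      if (match_one(calls[i, ], others)) "both" else only
    }, "")
  }
  penn$concordance <- lab(penn, partition, "penn_only")
  partition$concordance <- lab(partition, penn, "partition_only")
  dplyr::bind_rows(penn, partition)
}

#' CNV type (loss/gain) relative to expected ploidy
#'
#' Autosomes and pseudoautosomal/X-transposed regions are diploid in both
#' sexes; male X and Y outside those regions have expected ploidy 1.
#' @param calls calls tibble (uses `chrom`, `copy_number`, optional
#'   `region_class`).
#' @param sex named vector sample -> "M"/"F"; may be NULL for autosomes only.
#' @return character vector "loss"/"gain" (NA where copy number equals ploidy).
#' @export
cnv_type_of <- function(calls, sex = NULL) {
  if (nrow(calls) == 0) return(character())
  ploidy <- expected_ploidy(calls, sex)
  ifelse(calls$copy_number < ploidy, "loss",
         ifelse(calls$copy_number > ploidy, "gain", NA_character_))
}

expected_ploidy <- function(calls, sex = NULL) {
  ploidy <- rep(2, nrow(calls))
  sexchrom <- calls$chrom %in% c("X", "Y")
  if (!any(sexchrom)) return(ploidy)
  region <- if ("region_class" %in% names(calls)) calls$region_class else rep(NA, nrow(calls))
  diploid_region <- !is.na(region) & region %in% c("PAR", "XTR")
  if (is.null(sex)) {
    if (any(sexchrom & !diploid_region)) {
      stop("expected_ploidy: sex-chromosome calls need sample sex", call. = FALSE)
    }
    return(ploidy)
  }
  s <- unname(sex[calls$sample])
  if (any(sexchrom & is.na(s))) {
    stop("expected_ploidy: unknown sample sex for sex-chromosome call", call. = FALSE)
  }
  male <- !is.na(s) & s == "M"
  ploidy[calls$chrom == "X" & male & !diploid_region] <- 1
  ploidy[calls$chrom == "Y" & !diploid_region] <- 1
  # Y outside PAR does not exist in females; treat any female Y call as vs ploidy 0 -> gain
  ploidy[calls$chrom == "Y" & !male & !diploid_region] <- 0
  ploidy
}

#' Classify sex-chromosome regions
#'
#' Labels each call `autosome`, `PAR`, `XTR`, `X_nonPAR` or `Y_nonPAR` by
#' majority overlap with the supplied pseudoautosomal / X-transposed region
#' intervals.
#' @param calls calls tibble.
#' @param par_regions,xtr_regions interval tibbles (may be empty).
#' @return `calls` with a `region_class` column.
#' @export
assign_region_class <- function(calls, par_regions = NULL, xtr_regions = NULL) {
  cls <- rep("autosome", nrow(calls))
  cls[calls$chrom == "X"] <- "X_nonPAR"
  cls[calls$chrom == "Y"] <- "Y_nonPAR"
  frac_in <- function(i, regions) {
    if (is.null(regions) || nrow(regions) == 0) return(0)
    coverage_fraction(calls[i, c("chrom", "start", "end")], regions)
  }
  for (i in which(calls$chrom %in% c("X", "Y"))) {
    if (frac_in(i, par_regions) > 0.5) {
      cls[i] <- "PAR"
    } else if (frac_in(i, xtr_regions) > 0.5) {
      cls[i] <- "XTR"
    }
  }
  calls$region_class <- cls
  calls
}

#' Detect runs of copy-neutral homozygosity (ROH)
#'
#' Maximal runs of consecutive homozygous (AA/BB) probes, tolerating no-calls
#' (NC), terminated by any heterozygous (AB) probe. A run is reported when it
#' spans at least `min_mb` megabases (the study's 1 Mb rule) and contains at
#' least `min_probes` homozygous probes (a floor against spurious ROH in
#' sparse regions).
#'
#' @param probes probe tibble for one sample (columns `chrom`, `position`,
#'   `genotype`), position-sorted within chromosome.
#' @param sample sample id to report.
#' @param min_mb minimum segment span in Mb.
#' @param min_probes minimum homozygous probes in the run.
#' @return tibble of ROH segments: `sample`, `chrom`, `start`, `end`,
#'   `n_probes`.
#' @export
detect_roh <- function(probes, sample, min_mb = 1, min_probes = 50) {
  out <- list()
  for (chr in unique(probes$chrom)) {
    p <- probes[probes$chrom == chr, , drop = FALSE]
    if (is.unsorted(p$position)) {
      stop("detect_roh: probes not position-sorted on chromosome ", chr, call. = FALSE)
    }
    hom <- p$genotype %in% c("AA", "BB")
    nonhet <- p$genotype != "AB"
    runs <- rle(nonhet)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    for (k in which(runs$values & runs$lengths >= min_probes)) {
      idx <- seq(starts[k], ends[k])
      idx <- idx[hom[idx]]
      if (length(idx) < min_probes) next
      seg_start <- p$position[min(idx)]
      seg_end <- p$position[max(idx)]
      if ((seg_end - seg_start + 1) >= min_mb * 1e6) {
        out[[length(out) + 1]] <- tibble::tibble(
          sample = sample, chrom = chr, start = seg_start, end = seg_end,
          n_probes = length(idx)
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(sample = character(), chrom = character(),
                          start = numeric(), end = numeric(), n_probes = integer()))
  }
  dplyr::bind_rows(out)
}
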