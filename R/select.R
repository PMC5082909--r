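#' Candidate-selection configuration
#'
#' Bundles the thresholds of the rule-based CNV prioritization: probe and size
#' floors (10 probes / 25 Kb), the strict "< 35%" ceiling on overlap with each
#' reference polymorphism set, the DGV exclusion rule (at least 2 same-type
#' entries each covering at least 50% of the candidate), the reciprocal
#' overlap used to group recurrent candidates across cases, and the minimum
#' mean log-R-ratio shift used by the automated call review.
#'
#' @param min_probes minimum probe support for an autosomal candidate.
#' @param min_size_kb minimum size in Kb (applies to autosomal and
#'   sex-chromosome candidates).
#' @param max_ref_overlap strict upper bound on the fraction of a candidate
#'   covered by each reference set (same CNV type).
#' @param reference_sets named list of reference CNV tibbles (see
#'   [read_reference_cnv_set()]), e.g. `hapmap_cnp`, `chop_blocks`,
#'   `internal_controls`, `unrelated_case_db`.
#' @param dgv DGV-like reference tibble (entries kept individual, not unioned).
#' @param dgv_min_entries,dgv_min_fraction the "substantial overlap with
#'   multiple DGV entries" rule.
#' @param recurrence_reciprocal reciprocal-overlap floor for recurrence
#'   grouping.
#' @param lrr_min_shift minimum |mean LRR| across a candidate's probes, with
#'   sign matching the copy-number direction, for the review flag to pass.
#' @return a `filter_config` list.
#' @export
filter_config <- function(min_probes = 10, min_size_kb = 25,
                          max_ref_overlap = 0.35, reference_sets = list(),
                          dgv = NULL, dgv_min_entries = 2,
                          dgv_min_fraction = 0.5,
                          recurrence_reciprocal = 0.5, lrr_min_shift = 0.1) {
  stopifnot(min_probes > 0, min_size_kb > 0,
            max_ref_overlap > 0, max_ref_overlap <= 1,
            dgv_min_fraction > 0, dgv_min_fraction <= 1,
            recurrence_reciprocal > 0, recurrence_reciprocal <= 1)
  structure(list(
    min_probes = min_probes, min_size_kb = min_size_kb,
    max_ref_overlap = max_ref_overlap, reference_sets = reference_sets,
    dgv = dgv, dgv_min_entries = dgv_min_entries,
    dgv_min_fraction = dgv_min_fraction,
    recurrence_reciprocal = recurrence_reciprocal,
    lrr_min_shift = lrr_min_shift
  ), class = "filter_config")
}

#' Overlap profile of one call against the reference sets
#'
#' For each configured reference set, the fraction of the call covered by the
#' union of same-type features; features typed `"both"` contribute to either
#' CNV type.
#' @param call single-row calls tibble with a `cnv_type` column.
#' @param config a [filter_config()].
#' @return named numeric vector of coverage fractions (one per reference set).
#' @export
profile_overlaps <- function(call, config) {
  sets <- config$reference_sets
  if (length(sets) == 0) return(stats::setNames(numeric(), character()))
  if (is.null(names(sets)) || any(!nzchar(names(sets)))) {
    stop("profile_overlaps: reference sets must be named", call. = FALSE)
  }
  vapply(names(sets), function(nm) {
    set <- sets[[nm]]
    if (is.null(set)) stop("profile_overlaps: missing reference set: ", nm, call. = FALSE)
    feats <- set[set$type %in% c(call$cnv_type, "both"), , drop = FALSE]
    coverage_fraction(call[, c("chrom", "start", "end")], feats)
  }, 0)
}

# Classify calls against the probe/size/reference-overlap cascade.
# fate is the FIRST failing rule (probes, then size, then reference overlap),
# or "retained" when every rule passes.
classify_calls <- function(calls, config, apply_probe_floor = TRUE) {
  n <- nrow(calls)
  fate <- rep("retained", n)
  failed_set <- rep(NA_character_, n)
  kb <- if (n > 0) size_bp(calls) / 1000 else numeric()
  prof <- matrix(0, nrow = n, ncol = length(config$reference_sets),
                 dimnames = list(NULL, names(config$reference_sets)))
  for (i in seq_len(n)) {
    if (apply_probe_floor && calls$n_probes[i] < config$min_probes) {
      fate[i] <- "filtered_probes"
      next
    }
    if (kb[i] < config$min_size_kb) {
      fate[i] <- "filtered_size"
      next
    }
    p <- profile_overlaps(calls[i, ], config)
    if (length(p) > 0) prof[i, names(p)] <- p
    if (length(p) > 0 && any(p >= config$max_ref_overlap)) {
      fate[i] <- "filtered_common"
      failed_set[i] <- names(p)[which.max(p)]
    }
  }
  calls$size_kb <- as.integer(round_half_away(kb))
  calls$fate <- fate
  calls$failed_set <- failed_set
  for (nm in colnames(prof)) calls[[paste0("ov_", nm)]] <- prof[, nm]
  calls
}

#' Select autosomal candidate CNVs
#'
#' Applies the prioritization rules to harmonized autosomal calls: at least
#' `min_probes` probes, at least `min_size_kb` Kb, and strictly less than
#' `max_ref_overlap` of the call covered by each reference set of the same
#' CNV type. With `audit = TRUE` every input call is returned together with
#' its fate (`retained`, `filtered_probes`, `filtered_size`,
#' `filtered_common`), the first rule it failed.
#'
#' @param calls harmonized calls tibble with `cnv_type`.
#' @param config a [filter_config()].
#' @param audit return all calls with fates instead of the survivors only.
#' @return candidate tibble (survivors, with `size_kb` and `ov_*` overlap
#'   columns), or the full audited tibble when `audit = TRUE`.
#' @export
select_autosomal_candidates <- function(calls, config, audit = FALSE) {
  auto <- calls[!calls$chrom %in% c("X", "Y"), , drop = FALSE]
  out <- classify_calls(auto, config, apply_probe_floor = TRUE)
  if (audit) out else out[out$fate == "retained", , drop = FALSE]
}

#' Flag a candidate for exclusion on DGV evidence
#'
#' TRUE when at least `dgv_min_entries` same-type DGV entries EACH cover at
#' least `dgv_min_fraction` of the candidate. Entries are kept individual
#' (never unioned): one entry covering the whole candidate does not trigger
#' the rule, which requires "multiple" entries.
#'
#' @param candidate single-row candidate tibble with `cnv_type`.
#' @param dgv DGV-like reference tibble; defaults to `config$dgv`.
#' @param config a [filter_config()].
#' @return logical: exclude?
#' @export
flag_dgv_exclusion <- function(candidate, dgv = NULL, config = filter_config()) {
  if (is.null(dgv)) dgv <- config$dgv
  if (is.null(dgv) || nrow(dgv) == 0) return(FALSE)
  ent <- dgv[dgv$chrom == candidate$chrom &
               dgv$type %in% c(candidate$cnv_type, "both"), , drop = FALSE]
  if (nrow(ent) == 0) return(FALSE)
  csize <- candidate$end - candidate$start + 1
  cov <- pmax(0, pmin(candidate$end, ent$end) - pmax(candidate$start, ent$start) + 1) / csize
  sum(cov >= config$dgv_min_fraction) >= config$dgv_min_entries
}

#' Select sex-chromosome candidate CNVs
#'
#' Sex-chromosome calls of at least `min_size_kb` Kb are retained, except
#' calls at copy number 2 within pseudoautosomal (PAR) or X-transposed (XTR)
#' regions, which are normal diploid states there. Survivors then pass the
#' same reference-overlap exclusion as autosomes (a rule-based stand-in for
#' the study's manual review). Calls must carry `region_class` (see
#' [assign_region_class()]) and every sample must have a known sex.
#'
#' @param calls harmonized calls tibble restricted to or including X/Y calls.
#' @param config a [filter_config()].
#' @param sex named vector sample -> "M"/"F".
#' @param audit return all sex-chromosome calls with fates.
#' @return candidate tibble of surviving sex-chromosome calls.
#' @export
select_sex_chromosome_candidates <- function(calls, config, sex, audit = FALSE) {
  sexcalls <- calls[calls$chrom %in% c("X", "Y"), , drop = FALSE]
  if (nrow(sexcalls) == 0) {
    return(if (audit) sexcalls else sexcalls)
  }
  if (!"region_class" %in% names(sexcalls)) {
    stop("select_sex_chromosome_candidates: calls lack region_class", call. = FALSE)
  }
  if (any(is.na(sex[sexcalls$sample]))) {
    stop("select_sex_chromosome_candidates: unknown sample sex", call. = FALSE)
  }
  sexcalls$cnv_type <- cnv_type_of(sexcalls, sex)
  diploid_par <- sexcalls$copy_number == 2 &
    sexcalls$region_class %in% c("PAR", "XTR")
  out <- classify_calls(sexcalls, config, apply_probe_floor = FALSE)
  out$fate[diploid_par] <- "filtered_diploid_par"
  out$sex <- unname(sex[out$sample])
  if (audit) out else out[out$fate == "retained", , drop = FALSE]
}

#' Automated LRR plausibility review of a candidate
#'
#' A rule-based stand-in for manual LRR/BAF plot inspection: the mean log-R
#' ratio across the sample's probes inside the candidate must shift in the
#' direction of the called copy number by at least `lrr_min_shift`
#' (default 0.1). `"fail"` marks calls whose intensity data do not support
#' them.
#'
#' @param candidate single-row candidate tibble with `cnv_type`.
#' @param probes probe tibble (needs `sample`, `chrom`, `position`, `lrr`).
#' @param config a [filter_config()].
#' @return `"pass"` or `"fail"`.
#' @export
review_flag_lrr <- function(candidate, probes, config = filter_config()) {
  p <- probes[probes$sample == candidate$sample &
                probes$chrom == candidate$chrom &
                probes$position >= candidate$start &
                probes$position <= candidate$end, , drop = FALSE]
  if (nrow(p) == 0) return("fail")
  m <- mean(p$lrr, na.rm = TRUE)
  ok <- (candidate$cnv_type == "loss" && m <= -config$lrr_min_shift) ||
    (candidate$cnv_type == "gain" && m >= config$lrr_min_shift)
  if (isTRUE(ok)) "pass" else "fail"
}

#' Collapse duplicate candidate calls across callers
#'
#' The harmonized call set keeps one row per caller, so an event detected by
#' both callers survives selection twice. Same-sample, same-type calls with
#' at least `reciprocal` reciprocal overlap are collapsed to one candidate;
#' the representative keeps pennstyle coordinates on autosomes and
#' partitionstyle coordinates on sex chromosomes (the coordinate provenance
#' of the study's candidate table), and records which callers contributed.
#'
#' @param candidates candidate tibble (retained calls, possibly two callers).
#' @param reciprocal reciprocal-overlap floor for treating calls as one event.
#' @return deduplicated candidate tibble with a `callers` column
#'   (`both` / `pennstyle` / `partitionstyle`).
#' @export
dedupe_candidates <- function(candidates, reciprocal = 0.5) {
  n <- nrow(candidates)
  if (n == 0) {
    candidates$callers <- character()
    return(candidates)
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  edges <- c()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (candidates$sample[i] != candidates$sample[j]) next
      if (!identical(candidates$cnv_type[i], candidates$cnv_type[j])) next
      if (reciprocal_overlap(candidates[i, ], candidates[j, ]) >= reciprocal) {
        edges <- c(edges, i, j)
      }
    }
  }
  if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  rows <- vapply(split(seq_len(n), comp), function(idx) {
    grp <- candidates[idx, ]
    pref <- if (grp$chrom[1] %in% c("X", "Y")) "partitionstyle" else "pennstyle"
    pick <- idx[grp$caller == pref]
    if (length(pick) == 0) pick <- idx
    pick[order(candidates$start[pick])][1]
  }, 0L)
  out <- candidates[sort(unname(rows)), , drop = FALSE]
  callers <- vapply(split(candidates$caller, comp), function(cl) {
    if (length(unique(cl)) > 1) "both" else cl[1]
  }, "")
  out$callers <- unname(callers[order(unname(rows))])
  out
}

#' Group recurrent candidates across cases
#'
#' Two candidates in different samples are co-recurrent when they share CNV
#' type and reciprocally overlap by at least `recurrence_reciprocal`.
#' Connected groups (transitively) share one CNV identifier; identifiers are
#' numbered in (chrom, start) order of each group's leftmost member, so the
#' grouping partitions the candidates deterministically.
#'
#' @param candidates candidate tibble across all samples.
#' @param config a [filter_config()].
#' @return `candidates` with `cnv_id`, `recurrent`, `n_cases_sharing`.
#' @export
count_recurrence <- function(candidates, config = filter_config()) {
  n <- nrow(candidates)
  if (n == 0) {
    candidates$cnv_id <- integer()
    candidates$recurrent <- logical()
    candidates$n_cases_sharing <- integer()
    return(candidates)
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  edges <- c()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (candidates$sample[i] == candidates$sample[j]) next
      if (!identical(candidates$cnv_type[i], candidates$cnv_type[j])) next
      if (reciprocal_overlap(candidates[i, ], candidates[j, ]) >=
          config$recurrence_reciprocal) {
        edges <- c(edges, i, j)
      }
    }
  }
  if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  # renumber groups by genomic order of each group's leftmost member
  ord <- order(chrom_rank(candidates$chrom), candidates$start, candidates$sample)
  first_seen <- comp[ord][!duplicated(comp[ord])]
  renum <- stats::setNames(seq_along(first_seen), first_seen)
  candidates$cnv_id <- unname(renum[as.character(comp)])
  shared <- vapply(split(candidates$sample, candidates$cnv_id),
                   function(s) length(unique(s)), 0L)
  candidates$n_cases_sharing <- unname(shared[as.character(candidates$cnv_id)])
  candidates$recurrent <- candidates$n_cases_sharing > 1
  candidates
}

#' Export the call superset used for external phenotype ranking
#'
#' The permissive filter used to hand all plausibly real calls to an external
#' CNV ranking tool: pennstyle calls with at least 10 probes and 25 Kb;
#' partitionstyle autosomal calls of at least 25 Kb (no probe floor);
#' partitionstyle sex-chromosome calls of at least 25 Kb excluding copy-2
#' calls inside PAR/XTR.
#'
#' @param calls harmonized calls tibble (with `region_class` for X/Y calls).
#' @param min_probes,min_size_kb the pennstyle floors.
#' @return the retained subset.
#' @export
export_ranking_input <- function(calls, min_probes = 10, min_size_kb = 25) {
  kb <- size_bp(calls) / 1000
  region <- if ("region_class" %in% names(calls)) calls$region_class else rep("autosome", nrow(calls))
  is_sex <- calls$chrom %in% c("X", "Y")
  diploid_par <- is_sex & calls$copy_number == 2 & region %in% c("PAR", "XTR")
  keep_penn <- calls$caller == "pennstyle" & calls$n_probes >= min_probes & kb >= min_size_kb
  keep_part_auto <- calls$caller == "partitionstyle" & !is_sex & kb >= min_size_kb
  keep_part_sex <- calls$caller == "partitionstyle" & is_sex & kb >= min_size_kb & !diploid_par
  calls[keep_penn | keep_part_auto | keep_part_sex, , drop = FALSE]
}
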