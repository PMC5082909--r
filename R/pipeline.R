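#' Pipeline configuration
#'
#' Paths to every input of an end-to-end run plus the stage configurations.
#' All paths are checked at run start. A bundle written by
#' [generate_cohort()] satisfies the default layout via
#' [pipeline_config_from_bundle()].
#'
#' @param paths named list of input paths: `penn_calls` (character vector),
#'   `partition_calls` (character vector), `probes`, `samples`,
#'   `hapmap_cnp`, `chop_blocks`, `internal_controls`, `unrelated_case_db`,
#'   `dgv`, `transcriptome`, `candidate_genes`, `gene_sets`, `variants`,
#'   `demographics` (the last two optional).
#' @param filter a [filter_config()] (reference sets are loaded from `paths`
#'   and installed into it at run time).
#' @param out_dir output directory.
#' @param par_regions,xtr_regions PAR/XTR interval tibbles for
#'   sex-chromosome region classification.
#' @param max_af rarity ceiling for variant triage.
#' @param enrichment_alpha adjusted-p ceiling for enrichment filtering.
#' @param map_cutoff overlap-coefficient cutoff for the enrichment map.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(paths, out_dir, filter = filter_config(),
                            par_regions = NULL, xtr_regions = NULL,
                            max_af = 0.005, enrichment_alpha = 0.05,
                            map_cutoff = 0.5) {
  structure(list(paths = paths, out_dir = out_dir, filter = filter,
                 par_regions = par_regions, xtr_regions = xtr_regions,
                 max_af = max_af, enrichment_alpha = enrichment_alpha,
                 map_cutoff = map_cutoff),
            class = "pipeline_config")
}

#' Pipeline configuration for a synthetic-cohort bundle directory
#' @param bundle_dir directory written by [generate_cohort()].
#' @param out_dir output directory (default `<bundle_dir>/out`).
#' @param ... passed to [pipeline_config()].
#' @export
pipeline_config_from_bundle <- function(bundle_dir, out_dir = file.path(bundle_dir, "out"), ...) {
  p <- list(
    penn_calls = sort(list.files(file.path(bundle_dir, "calls"),
                                 pattern = "\\.penn\\.rawcnv$", full.names = TRUE)),
    partition_calls = sort(list.files(file.path(bundle_dir, "calls"),
                                      pattern = "\\.partition\\.tsv$", full.names = TRUE)),
    probes = file.path(bundle_dir, "probes.tsv"),
    samples = file.path(bundle_dir, "samples.tsv"),
    hapmap_cnp = file.path(bundle_dir, "hapmap_cnp.tsv"),
    chop_blocks = file.path(bundle_dir, "chop_blocks.tsv"),
    internal_controls = file.path(bundle_dir, "internal_controls.tsv"),
    unrelated_case_db = file.path(bundle_dir, "unrelated_case_db.tsv"),
    dgv = file.path(bundle_dir, "dgv.tsv"),
    transcriptome = file.path(bundle_dir, "transcriptome.bed"),
    candidate_genes = file.path(bundle_dir, "candidate_genes.txt"),
    gene_sets = file.path(bundle_dir, "gene_sets.gmt"),
    variants = file.path(bundle_dir, "variants.tsv"),
    demographics = file.path(bundle_dir, "demographics.tsv")
  )
  pipeline_config(p, out_dir, par_regions = tibble::tibble(
    chrom = c("X", "Y"), start = c(1, 1), end = c(1e6, 1e6)),
    xtr_regions = tibble::tibble(chrom = "X", start = 15e6, end = 15.5e6), ...)
}

#' Pipeline configuration from a YAML file
#'
#' The YAML mirrors [pipeline_config()]: a `paths` mapping, an `out_dir`, and
#' optional `filter` threshold overrides (any argument of
#' [filter_config()]).
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  fc <- do.call(filter_config, as.list(y$filter %||% list()))
  pipeline_config(paths = y$paths, out_dir = y$out_dir, filter = fc,
                  max_af = y$max_af %||% 0.005,
                  enrichment_alpha = y$enrichment_alpha %||% 0.05,
                  map_cutoff = y$map_cutoff %||% 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_fail <- function(stage, e) {
  stop("pipeline stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
}

#' Run the CNV discovery-and-prioritization pipeline end to end
#'
#' Stage order follows the study's workflow: caller harmonization
#' (thresholds, merging, concordance, ROH) -> candidate selection
#' (probe/size/reference-overlap rules, DGV exclusion, LRR review) ->
#' recurrence grouping -> transcript and candidate-gene annotation ->
#' sequencing-variant triage -> gene-set enrichment with enrichment-map
#' clustering. Every filter decision is retained in the audited call table;
#' summary counts are written to a machine-readable run summary.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with all stage outputs: `harmonized`, `audit`,
#'   `candidates`, `roh`, `triage`, `enrichment`, `map`, `demographics`,
#'   `summary`.
#' @export
run_pipeline <- function(config) {
  paths <- config$paths
  required <- c("penn_calls", "partition_calls", "samples", "hapmap_cnp",
                "chop_blocks", "internal_controls", "unrelated_case_db",
                "dgv", "transcriptome", "candidate_genes", "gene_sets")
  for (nm in required) {
    p <- paths[[nm]]
    if (is.null(p) || length(p) == 0 || !all(file.exists(p))) {
      stop("run_pipeline: missing input '", nm, "'", call. = FALSE)
    }
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  # ---- stage: read + harmonize calls ----
  harmonized <- tryCatch({
    penn <- dplyr::bind_rows(lapply(paths$penn_calls, read_cnv_calls, dialect = "pennstyle"))
    part <- dplyr::bind_rows(lapply(paths$partition_calls, read_cnv_calls, dialect = "partitionstyle"))
    sex_tbl <- utils::read.delim(paths$samples, stringsAsFactors = FALSE)
    sex <- stats::setNames(sex_tbl$sex, sex_tbl$sample)
    penn <- merge_adjacent_calls(apply_caller_thresholds(penn))
    part <- merge_adjacent_calls(apply_caller_thresholds(part))
    penn <- assign_region_class(penn, config$par_regions, config$xtr_regions)
    part <- assign_region_class(part, config$par_regions, config$xtr_regions)
    h <- label_concordance(penn, part, sex = sex)
    attr(h, "sex") <- sex
    h
  }, error = function(e) stage_fail("harmonize", e))
  sex <- attr(harmonized, "sex")

  # ---- stage: ROH ----
  roh <- tryCatch({
    if (!is.null(paths$probes) && file.exists(paths$probes)) {
      probes <- read_probe_table(paths$probes)
      segs <- lapply(unique(probes$sample), function(smp) {
        detect_roh(probes[probes$sample == smp, ], smp)
      })
      attr(probes, "loaded") <- TRUE
      roh <- dplyr::bind_rows(segs)
      attr(roh, "probes") <- probes
      roh
    } else {
      tibble::tibble(sample = character(), chrom = character(),
                     start = numeric(), end = numeric(), n_probes = integer())
    }
  }, error = function(e) stage_fail("roh", e))
  probes <- attr(roh, "probes")
  attr(roh, "probes") <- NULL

  # ---- stage: candidate selection with full audit ----
  audit <- tryCatch({
    fc <- config$filter
    fc$reference_sets <- list(
      hapmap_cnp = read_reference_cnv_set(paths$hapmap_cnp),
      chop_blocks = read_reference_cnv_set(paths$chop_blocks),
      internal_controls = read_reference_cnv_set(paths$internal_controls),
      unrelated_case_db = read_reference_cnv_set(paths$unrelated_case_db)
    )
    fc$dgv <- read_reference_cnv_set(paths$dgv)
    auto <- select_autosomal_candidates(harmonized, fc, audit = TRUE)
    sexc <- select_sex_chromosome_candidates(harmonized, fc, sex, audit = TRUE)
    aud <- dplyr::bind_rows(auto, sexc)
    retained <- aud$fate == "retained"
    for (i in which(retained)) {
      if (flag_dgv_exclusion(aud[i, ], fc$dgv, fc)) {
        aud$fate[i] <- "filtered_dgv"
      } else if (!is.null(probes)) {
        if (review_flag_lrr(aud[i, ], probes, fc) == "fail") {
          aud$fate[i] <- "artifact_flagged"
        }
      }
    }
    aud$review_flag <- ifelse(aud$fate == "artifact_flagged", "fail", "pass")
    attr(aud, "filter") <- fc
    aud
  }, error = function(e) stage_fail("select", e))
  fc <- attr(audit, "filter")

  # ---- stage: recurrence + annotation ----
  candidates <- tryCatch({
    cand <- audit[audit$fate == "retained", , drop = FALSE]
    cand <- dedupe_candidates(cand)
    cand <- count_recurrence(cand, fc)
    transcripts <- read_transcript_annotation(paths$transcriptome, "BED")
    cand_list <- toupper(readLines(paths$candidate_genes, warn = FALSE))
    cand <- annotate_candidates(cand, transcripts, cand_list, ea_known_genes())
    if (!"sex" %in% names(cand)) cand$sex <- NA_character_
    cand$sex[is.na(cand$sex)] <- unname(sex[cand$sample[is.na(cand$sex)]])
    cand$locus <- sprintf("%s:%d-%d", cand$chrom, as.integer(cand$start),
                          as.integer(cand$end))
    write_candidate_report(cand, file.path(config$out_dir, "candidates.tsv"))
    cand
  }, error = function(e) stage_fail("annotate", e))

  # ---- stage: variant triage ----
  triage <- tryCatch({
    if (!is.null(paths$variants) && file.exists(paths$variants)) {
      v <- read_variants(paths$variants, "TSV")
      tri <- triage_variants(v, max_af = config$max_af)
      write_variants(tri$known_tier, file.path(config$out_dir, "variants_known_tier.tsv"))
      write_variants(tri$candidate_tier, file.path(config$out_dir, "variants_candidate_tier.tsv"))
      tri
    } else NULL
  }, error = function(e) stage_fail("triage", e))

  # ---- stage: enrichment ----
  enrichment <- tryCatch({
    library_ <- read_gene_set_library(paths$gene_sets)
    queries <- build_query_lists(candidates)
    recs <- dplyr::bind_rows(
      fisher_enrichment(queries$all, library_, source = "all"),
      fisher_enrichment(queries$deletions, library_, source = "deletions"),
      fisher_enrichment(queries$duplications, library_, source = "duplications")
    )
    surviving <- apply_exclusion_rules(recs, alpha = config$enrichment_alpha)
    map <- build_enrichment_map(surviving, library_, cutoff = config$map_cutoff)
    flat <- surviving
    flat$overlap_genes <- vapply(flat$overlap_genes, paste, "", collapse = ";")
    flat$cnv_ids <- vapply(flat$cnv_ids, paste, "", collapse = ";")
    utils::write.table(as.data.frame(flat),
                       file.path(config$out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(map$edges),
                       file.path(config$out_dir, "enrichment_map_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(map$nodes),
                       file.path(config$out_dir, "enrichment_map_nodes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(records = recs, surviving = surviving, map = map)
  }, error = function(e) stage_fail("enrich", e))

  # ---- stage: cohort statistics ----
  demographics <- tryCatch({
    if (!is.null(paths$demographics) && file.exists(paths$demographics)) {
      d <- utils::read.delim(paths$demographics, stringsAsFactors = FALSE)
      rep_ <- demographics_report(tibble::as_tibble(d))
      utils::write.table(as.data.frame(rep_),
                         file.path(config$out_dir, "demographics_report.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      rep_
    } else NULL
  }, error = function(e) stage_fail("stats", e))

  # ---- run summary ----
  summary <- list(
    n_calls_penn = sum(harmonized$caller == "pennstyle"),
    n_calls_partition = sum(harmonized$caller == "partitionstyle"),
    n_concordant_both = sum(harmonized$concordance == "both"),
    n_audited = nrow(audit),
    fates = as.list(table(audit$fate)),
    n_candidates = nrow(candidates),
    n_distinct_cnv_ids = length(unique(candidates$cnv_id)),
    n_recurrent_groups = length(unique(candidates$cnv_id[candidates$recurrent])),
    n_cases_with_candidate = length(unique(candidates$sample)),
    n_roh_segments = nrow(roh),
    n_variants_reported = if (is.null(triage)) 0L else
      triage$summary$n_known_variants + triage$summary$n_candidate_variants,
    n_gene_sets_surviving = nrow(enrichment$surviving),
    n_map_components = nrow(enrichment$map$components)
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  aud_out <- audit
  utils::write.table(as.data.frame(aud_out[, c(
    "sample", "chrom", "start", "end", "copy_number", "cnv_type", "n_probes",
    "confidence", "caller", "concordance", "size_kb", "fate", "failed_set")]),
    file.path(config$out_dir, "audited_calls.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(roh) > 0) {
    utils::write.table(as.data.frame(roh), file.path(config$out_dir, "roh.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  invisible(list(harmonized = harmonized, audit = audit,
                 candidates = candidates, roh = roh, triage = triage,
                 enrichment = enrichment, demographics = demographics,
                 summary = summary))
}

#' Compare pipeline fates against a planted-truth table
#'
#' Matches each planted event (excluding `not_called` ones, which the
#' selection stage never saw) to the audited calls by sample, chromosome,
#' CNV type and reciprocal overlap of at least 0.5, and derives the
#' pipeline's fate for the event: retained if any matching call was
#' retained, otherwise the fate of the best-overlapping call.
#'
#' @param truth planted-event tibble (from [generate_cohort()]).
#' @param audit audited calls tibble (from [run_pipeline()]).
#' @param candidates retained-candidate tibble with recurrence columns.
#' @return truth with `pipeline_fate` and `fate_match` columns.
#' @export
evaluate_truth_recovery <- function(truth, audit, candidates = NULL) {
  fate_map <- c(retained = "retained_candidate",
                filtered_probes = "filtered_probes",
                filtered_size = "filtered_size",
                filtered_common = "filtered_common",
                filtered_dgv = "filtered_dgv",
                artifact_flagged = "artifact_flagged",
                filtered_diploid_par = "filtered_diploid_par")
  n <- nrow(truth)
  pf <- rep("not_found", n)
  for (i in seq_len(n)) {
    if (truth$expected_fate[i] == "not_called") {
      pf[i] <- NA_character_
      next
    }
    cand <- audit[audit$sample == truth$sample[i] &
                    audit$chrom == truth$chrom[i] &
                    !is.na(audit$cnv_type) &
                    audit$cnv_type == truth$cnv_type[i], , drop = FALSE]
    if (nrow(cand) == 0) next
    ro <- vapply(seq_len(nrow(cand)), function(j) {
      reciprocal_overlap(truth[i, c("chrom", "start", "end")],
                         cand[j, c("chrom", "start", "end")])
    }, 0)
    # prefer a >= 50% reciprocal match; for events smaller than the caller's
    # boundary jitter this can fail, so fall back to any overlap (planting
    # slots keep events far apart, so the fallback is unambiguous)
    floor_ro <- if (any(ro >= 0.5)) 0.5 else .Machine$double.eps
    cand <- cand[ro >= floor_ro, , drop = FALSE]
    if (nrow(cand) == 0) next
    ro <- ro[ro >= floor_ro]
    if (any(cand$fate == "retained")) {
      pf[i] <- "retained_candidate"
    } else {
      pf[i] <- unname(fate_map[cand$fate[which.max(ro)]])
    }
  }
  truth$pipeline_fate <- pf
  truth$fate_match <- !is.na(pf) & pf == truth$expected_fate
  truth
}
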