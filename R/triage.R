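#' Allelic balance of a called variant
#'
#' Alternate-read fraction `alt / (ref + alt)`. True heterozygotes are
#' expected near 0.5; systematically low balance marks likely capture or
#' alignment artifacts.
#' @param ref_reads,alt_reads non-negative read counts (vectorised).
#' @return fraction in \[0, 1\].
#' @export
allelic_balance <- function(ref_reads, alt_reads) {
  tot <- ref_reads + alt_reads
  if (any(tot < 1)) stop("allelic_balance: zero read depth", call. = FALSE)
  alt_reads / tot
}

#' Classify a variant by allelic balance
#'
#' Bands recovered from the study's validation outcome: balance below 0.25 is
#' a likely artifact (such calls consistently failed Sanger confirmation);
#' 0.40-0.85 is the expected heterozygous band; anything else needs review.
#' The three classes partition \[0, 1\].
#' @param ab allelic balance in \[0, 1\] (vectorised).
#' @return factor-like character: `likely_artifact`, `expected_het` or
#'   `review`.
#' @export
classify_allelic_balance <- function(ab) {
  if (any(ab < 0 | ab > 1)) stop("classify_allelic_balance: ab outside [0,1]", call. = FALSE)
  ifelse(ab < 0.25, "likely_artifact",
         ifelse(ab >= 0.40 & ab <= 0.85, "expected_het", "review"))
}

#' Population-frequency rarity filter
#'
#' Retains variants absent from the population reference database or with
#' allele frequency strictly below `max_af` (default 0.005; every variant the
#' study retained sits well under this).
#' @param population_af numeric vector; NA means absent from the database.
#' @param max_af rarity ceiling.
#' @return logical: retained?
#' @export
rare_frequency_filter <- function(population_af, max_af = 0.005) {
  is.na(population_af) | population_af < max_af
}

#' Default cardiomyopathy gene panel used in case-level summaries
#'
#' Genes associated with autosomal dominant cardiomyopathy that the cohort
#' summary counts carriers against.
#' @return character vector of gene symbols.
#' @export
cardiomyopathy_panel <- function() c("MYH7", "MYH6", "TTN", "TCAP", "JUP")

#' Triage targeted-sequencing variants into validated-candidate tiers
#'
#' Applies the allelic-balance classification and the rarity filter to every
#' variant. Variants in the candidate-gene tier must additionally carry a
#' predicted-impact annotation (loss of function, high impact, or predicted
#' pathogenic by multiple algorithms); known-disease-gene-tier variants do
#' not. Likely artifacts are excluded from the report; the expected-het and
#' review classes form the confirmation (Sanger) candidate list.
#'
#' @param variants variant tibble (see [read_variants()]).
#' @param max_af rarity ceiling for [rare_frequency_filter()].
#' @param panel gene panel for the case-level summary (default
#'   [cardiomyopathy_panel()]).
#' @return list with `variants` (all inputs with `ab`, `ab_class`, `rare`,
#'   `reported` columns), `known_tier` and `candidate_tier` reports,
#'   `sanger_list`, and `summary` (per-tier variant/case counts plus
#'   distinct-case count for the panel).
#' @export
triage_variants <- function(variants, max_af = 0.005, panel = cardiomyopathy_panel()) {
  v <- variants
  v$ab <- allelic_balance(v$ref_reads, v$alt_reads)
  v$ab_class <- classify_allelic_balance(v$ab)
  v$rare <- rare_frequency_filter(v$population_af, max_af)
  impact_ok <- ifelse(v$tier == "candidate_gene",
                      (v$lof %in% TRUE) | (v$pathogenic %in% TRUE),
                      TRUE)
  v$reported <- v$rare & impact_ok & v$ab_class != "likely_artifact"
  known <- v[v$reported & v$tier == "known_ea_gene", , drop = FALSE]
  cand <- v[v$reported & v$tier == "candidate_gene", , drop = FALSE]
  reported <- v[v$reported, , drop = FALSE]
  panel_cases <- unique(reported$sample[toupper(reported$gene) %in% toupper(panel)])
  list(
    variants = v,
    known_tier = known,
    candidate_tier = cand,
    sanger_list = reported[reported$ab_class %in% c("expected_het", "review"), , drop = FALSE],
    summary = tibble::tibble(
      n_known_variants = nrow(known),
      n_known_cases = length(unique(known$sample)),
      n_candidate_variants = nrow(cand),
      n_candidate_cases = length(unique(cand$sample)),
      n_panel_cases = length(panel_cases)
    )
  )
}
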