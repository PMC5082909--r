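# Synthetic cohort generator with planted truth.
#
# The generator emulates the study's input universe at desk scale: a small
# genome (two 30 Mb autosomes plus optional X/Y with PAR/XTR sub-regions), a
# dense SNP array (1000 probes/Mb, about the genome-wide density of the
# 2.5M-probe array used in the study), per-probe genotype/BAF/LRR with the
# study's reported LRR noise (sd 0.133), two pseudo-callers emitting the
# pennstyle and partitionstyle dialects with boundary jitter, occasional call
# splitting, misses, sub-threshold confidences and small false-positive
# calls, reference polymorphism sets carrying the planted common events, a
# tiled transcriptome, a gene-set library with one planted enriched set,
# sequencing variants with binomial read counts, and a demographics table.
# Every planted event carries an expected pipeline fate, jitter-invariant by
# construction (event size classes keep a clear margin around each filter
# threshold).

#' Synthetic cohort configuration
#'
#' Defaults are the package's study conditions; see the methods vignette for
#' the rationale behind each value.
#'
#' @param seed integer RNG seed; a fixed seed gives byte-identical bundles.
#' @param n_cases,n_controls cohort sizes.
#' @param chromosomes named vector of chromosome lengths in bp.
#' @param include_sex_chromosomes add X/Y (with PAR/XTR) to the genome.
#' @param probe_density probes per Mb.
#' @param n_events number of planted autosomal CNV events.
#' @param class_probs sampling weights over planted classes
#'   (`rare_candidate`, `common_cnp`, `dgv_like`, `artifact`).
#' @param rare_small_probes_frac,rare_small_size_frac fractions of
#'   rare_candidate events planted below the probe floor (3-5.5 Kb) or the
#'   size floor (15-22 Kb).
#' @param n_recurrent_pairs recurrent events planted in two cases each.
#' @param jitter_sd,jitter_max caller boundary jitter: Gaussian sd (bp),
#'   clamped at `jitter_max`.
#' @param split_prob probability a caller splits an event into two adjacent
#'   calls (gap 4\% of the span, re-mergeable by [merge_adjacent_calls()]).
#' @param miss_prob per-caller probability of missing an event entirely.
#' @param lowconf_frac fraction of emitted calls drawn below the caller's
#'   confidence threshold (exercises [apply_caller_thresholds()]).
#' @param fp_rate Poisson mean of small false-positive calls per sample per
#'   caller (3-15 Kb, always below the candidate size floor).
#' @param lrr_sd,lrr_loss_mean,lrr_gain_mean log-R-ratio noise sd and state
#'   means.
#' @param het_rate,nc_rate background heterozygosity and no-call rates.
#' @param n_roh planted runs of homozygosity (1.2-2.5 Mb) across the cohort.
#' @param n_true_het,n_artifact_variants,n_common_variants,n_noimpact_variants
#'   planted sequencing variants per class.
#' @param depth_mu,depth_size,depth_min sequencing depth distribution
#'   (negative binomial, truncated below).
#' @param n_gene_sets,gene_set_size_range gene-set library dimensions.
#' @return a `cohort_config` list.
#' @export
cohort_config <- function(seed = 1,
                          n_cases = 47, n_controls = 3,
                          chromosomes = c(`1` = 30e6, `2` = 30e6),
                          include_sex_chromosomes = TRUE,
                          probe_density = 1000,
                          n_events = 50,
                          class_probs = c(rare_candidate = 0.5, common_cnp = 0.2,
                                          dgv_like = 0.15, artifact = 0.15),
                          rare_small_probes_frac = 0.15,
                          rare_small_size_frac = 0.15,
                          n_recurrent_pairs = 2,
                          jitter_sd = 500, jitter_max = 1250,
                          split_prob = 0.05, miss_prob = 0.05,
                          lowconf_frac = 0.05, fp_rate = 3,
                          lrr_sd = 0.133, lrr_loss_mean = -0.45,
                          lrr_gain_mean = 0.3,
                          het_rate = 0.3, nc_rate = 0.005,
                          n_roh = 2,
                          n_true_het = 40, n_artifact_variants = 20,
                          n_common_variants = 10, n_noimpact_variants = 10,
                          depth_mu = 120, depth_size = 8, depth_min = 30,
                          n_gene_sets = 40, gene_set_size_range = c(10, 60)) {
  chroms <- chromosomes
  par_regions <- xtr_regions <- NULL
  if (include_sex_chromosomes) {
    chroms <- c(chroms, X = 20e6, Y = 10e6)
    par_regions <- tibble::tibble(chrom = c("X", "Y"), start = c(1, 1),
                                  end = c(1e6, 1e6))
    xtr_regions <- tibble::tibble(chrom = "X", start = 15e6, end = 15.5e6)
  }
  structure(list(
    seed = as.integer(seed), n_cases = n_cases, n_controls = n_controls,
    chromosomes = chroms, include_sex_chromosomes = include_sex_chromosomes,
    par_regions = par_regions, xtr_regions = xtr_regions,
    probe_density = probe_density, n_events = n_events,
    class_probs = class_probs,
    rare_small_probes_frac = rare_small_probes_frac,
    rare_small_size_frac = rare_small_size_frac,
    n_recurrent_pairs = n_recurrent_pairs,
    jitter_sd = jitter_sd, jitter_max = jitter_max,
    split_prob = split_prob, miss_prob = miss_prob,
    lowconf_frac = lowconf_frac, fp_rate = fp_rate,
    lrr_sd = lrr_sd, lrr_loss_mean = lrr_loss_mean,
    lrr_gain_mean = lrr_gain_mean,
    het_rate = het_rate, nc_rate = nc_rate, n_roh = n_roh,
    n_true_het = n_true_het, n_artifact_variants = n_artifact_variants,
    n_common_variants = n_common_variants,
    n_noimpact_variants = n_noimpact_variants,
    depth_mu = depth_mu, depth_size = depth_size, depth_min = depth_min,
    n_gene_sets = n_gene_sets, gene_set_size_range = gene_set_size_range
  ), class = "cohort_config")
}

SLOT_WIDTH <- 400e3     # non-overlapping planting slots
ROH_RESERVE <- 3e6      # tail of each autosome reserved for planted ROH

autosomes_of <- function(config) {
  names(config$chromosomes)[!names(config$chromosomes) %in% c("X", "Y")]
}

# Deterministic probe map: near-regular grid with small positional jitter.
make_probe_map <- function(config) {
  spacing <- 1e6 / config$probe_density
  maps <- lapply(names(config$chromosomes), function(chr) {
    L <- config$chromosomes[[chr]]
    pos <- seq(spacing / 2, L, by = spacing)
    pos <- round(pos + stats::rnorm(length(pos), 0, 0.2 * spacing))
    pos <- sort(unique(pmax(1, pmin(L, pos))))
    tibble::tibble(marker = sprintf("snp_%s_%06d", chr, seq_along(pos)),
                   chrom = chr, position = pos)
  })
  dplyr::bind_rows(maps)
}

count_probes_in <- function(probe_map, chrom, start, end) {
  sum(probe_map$chrom == chrom & probe_map$position >= start &
        probe_map$position <= end)
}

# Allocate disjoint planting slots and draw the planted event set.
plant_events <- function(config, probe_map, samples_cases, sex) {
  autos <- autosomes_of(config)
  slots <- dplyr::bind_rows(lapply(autos, function(chr) {
    L <- config$chromosomes[[chr]] - ROH_RESERVE
    n <- floor(L / SLOT_WIDTH)
    # every other slot only: guarantees >= one empty slot between any two
    # planted events, so same-sample events can never satisfy the merge rule
    tibble::tibble(chrom = chr,
                   slot_start = (seq(1, n, by = 2) - 1) * SLOT_WIDTH + 1)
  }))
  n_total <- config$n_events + config$n_recurrent_pairs
  if (n_total > nrow(slots)) stop("plant_events: more events than slots", call. = FALSE)
  picked <- slots[sample.int(nrow(slots), n_total), ]
  cls <- sample(names(config$class_probs), config$n_events, replace = TRUE,
                prob = config$class_probs)
  draw_size <- function(class) {
    if (class == "rare_candidate") {
      u <- stats::runif(1)
      if (u < config$rare_small_probes_frac) {
        stats::runif(1, 3e3, 5.5e3)         # below the 10-probe floor
      } else if (u < config$rare_small_probes_frac + config$rare_small_size_frac) {
        stats::runif(1, 15e3, 22e3)         # >=10 probes but below 25 Kb
      } else {
        stats::runif(1, 40e3, 300e3)
      }
    } else {
      stats::runif(1, 40e3, 300e3)
    }
  }
  ev <- list()
  for (i in seq_len(config$n_events)) {
    size <- round(draw_size(cls[i]))
    offset <- round(stats::runif(1, 10e3, SLOT_WIDTH - size - 10e3))
    start <- picked$slot_start[i] + offset
    cn <- sample(c(1L, 3L), 1)
    ev[[i]] <- tibble::tibble(
      event_id = sprintf("ev%03d", i), class = cls[i],
      sample = sample(samples_cases, 1),
      chrom = picked$chrom[i], start = start, end = start + size - 1,
      copy_number = cn, recurrent_group = NA_integer_
    )
  }
  # recurrent pairs: identical interval and type in two different cases
  for (k in seq_len(config$n_recurrent_pairs)) {
    i <- config$n_events + k
    size <- round(stats::runif(1, 60e3, 200e3))
    offset <- round(stats::runif(1, 10e3, SLOT_WIDTH - size - 10e3))
    start <- picked$slot_start[i] + offset
    cn <- sample(c(1L, 3L), 1)
    carriers <- sample(samples_cases, 2)
    for (j in 1:2) {
      ev[[length(ev) + 1]] <- tibble::tibble(
        event_id = sprintf("ev%03d_r%d", i, j), class = "rare_candidate",
        sample = carriers[j], chrom = picked$chrom[i],
        start = start, end = start + size - 1,
        copy_number = cn, recurrent_group = k
      )
    }
  }
  events <- dplyr::bind_rows(ev)
  if (nrow(events) == 0) {
    events <- tibble::tibble(
      event_id = character(), class = character(), sample = character(),
      chrom = character(), start = numeric(), end = numeric(),
      copy_number = integer(), recurrent_group = integer())
  }
  events$cnv_type <- as.character(ifelse(events$copy_number < 2, "loss", "gain"))
  events$n_probes_true <- mapply(function(c_, s_, e_) {
    count_probes_in(probe_map, c_, s_, e_)
  }, events$chrom, events$start, events$end)
  events$size_bp <- events$end - events$start + 1
  # class-determined fate (jitter-invariant by the size-class margins)
  events$expected_fate <- dplyr::case_when(
    events$class == "artifact" ~ "artifact_flagged",
    events$class == "common_cnp" ~ "filtered_common",
    events$class == "dgv_like" ~ "filtered_dgv",
    events$size_bp < 10e3 ~ "filtered_probes",
    events$size_bp < 25e3 ~ "filtered_size",
    TRUE ~ "retained_candidate"
  )
  events
}

clamp <- function(x, lo, hi) pmax(lo, pmin(hi, x))

# Emit one caller's calls for the planted events plus false positives.
emit_caller_calls <- function(config, events, probe_map, samples, caller) {
  conf_good <- function(n) {
    if (caller == "pennstyle") stats::runif(n, 15, 120) else stats::runif(n, 40, 250)
  }
  conf_low <- function(n) {
    if (caller == "pennstyle") stats::runif(n, 0, 9.9) else stats::runif(n, 0, 34.9)
  }
  calls <- list()
  emitted <- logical(nrow(events))
  for (i in seq_len(nrow(events))) {
    if (stats::runif(1) < config$miss_prob) next
    jit <- clamp(stats::rnorm(2, 0, config$jitter_sd),
                 -config$jitter_max, config$jitter_max)
    s <- max(1, round(events$start[i] + jit[1]))
    e <- min(config$chromosomes[[events$chrom[i]]], round(events$end[i] + jit[2]))
    if (e <= s) next
    low <- stats::runif(1) < config$lowconf_frac
    if (low) next_conf <- conf_low(1) else next_conf <- conf_good(1)
    if (stats::runif(1) < config$split_prob && (e - s) > 20e3) {
      gap <- round(0.04 * (e - s + 1))
      mid <- round((s + e) / 2)
      pieces <- list(c(s, mid - ceiling(gap / 2)), c(mid + floor(gap / 2), e))
    } else {
      pieces <- list(c(s, e))
    }
    for (p in pieces) {
      np <- count_probes_in(probe_map, events$chrom[i], p[1], p[2])
      if (np < 3) next   # both callers require >= 3 consecutive probes
      emitted[i] <- emitted[i] || !low
      calls[[length(calls) + 1]] <- tibble::tibble(
        sample = events$sample[i], chrom = events$chrom[i],
        start = p[1], end = p[2], copy_number = events$copy_number[i],
        n_probes = np, confidence = next_conf, caller = caller,
        event_id = events$event_id[i]
      )
    }
  }
  # small false-positive calls, always below the candidate size floor
  for (smp in samples) {
    nfp <- stats::rpois(1, config$fp_rate)
    for (k in seq_len(nfp)) {
      chr <- sample(autosomes_of(config), 1)
      size <- round(stats::runif(1, 3e3, 15e3))
      s <- round(stats::runif(1, 1, config$chromosomes[[chr]] - size))
      calls[[length(calls) + 1]] <- tibble::tibble(
        sample = smp, chrom = chr, start = s, end = s + size - 1,
        copy_number = sample(c(1L, 3L), 1),
        n_probes = count_probes_in(probe_map, chr, s, s + size - 1),
        confidence = conf_good(1), caller = caller, event_id = NA_character_
      )
    }
  }
  out <- dplyr::bind_rows(calls)
  if (nrow(out) > 0) {
    out <- out[out$n_probes >= 1, , drop = FALSE]
    out <- out[order(out$sample, chrom_rank(out$chrom), out$start), ]
  }
  list(calls = out, emitted = emitted)
}

# Reference sets: planted common events plus random background entries in
# otherwise unused genomic space (the far tail of each autosome's slot range).
make_reference_sets <- function(config, events) {
  common <- events[events$class == "common_cnp", , drop = FALSE]
  base <- tibble::tibble(chrom = common$chrom, start = common$start,
                         end = common$end, type = common$cnv_type)
  background <- function(n) {
    chr <- sample(autosomes_of(config), n, replace = TRUE)
    # background entries live in the ROH reserve tail, away from all slots
    s <- vapply(chr, function(c_) {
      L <- config$chromosomes[[c_]]
      round(stats::runif(1, L - ROH_RESERVE + 1, L - 600e3))
    }, 0)
    tibble::tibble(chrom = chr, start = s,
                   end = s + round(stats::runif(n, 50e3, 400e3)),
                   type = sample(c("loss", "gain", "both"), n, replace = TRUE))
  }
  dgv_ev <- events[events$class == "dgv_like", , drop = FALSE]
  dgv <- dplyr::bind_rows(
    # two same-type entries each fully covering the event
    tibble::tibble(chrom = dgv_ev$chrom,
                   start = pmax(1, dgv_ev$start - round(0.2 * dgv_ev$size_bp)),
                   end = dgv_ev$end + round(0.1 * dgv_ev$size_bp),
                   type = dgv_ev$cnv_type),
    tibble::tibble(chrom = dgv_ev$chrom,
                   start = pmax(1, dgv_ev$start - round(0.1 * dgv_ev$size_bp)),
                   end = dgv_ev$end + round(0.2 * dgv_ev$size_bp),
                   type = dgv_ev$cnv_type),
    background(15)
  )
  list(
    hapmap_cnp = dplyr::bind_rows(base, background(20)),
    chop_blocks = dplyr::bind_rows(base, background(20)),
    internal_controls = background(10),
    unrelated_case_db = background(10),
    dgv = dgv
  )
}

# Tiled transcriptome over the synthetic genome.
make_transcriptome <- function(config) {
  rows <- lapply(names(config$chromosomes), function(chr) {
    L <- config$chromosomes[[chr]]
    starts <- seq(20e3, L - 60e3, by = 150e3)
    widths <- round(stats::runif(length(starts), 5e3, 40e3))
    tibble::tibble(
      gene = sprintf("G%s_%04d", chr, seq_along(starts)),
      chrom = chr, start = starts, end = starts + widths,
      biotype = "protein_coding"
    )
  })
  dplyr::bind_rows(rows)
}

make_gene_sets <- function(config, transcriptome, events) {
  universe <- c(transcriptome$gene, "MYH7", "GATA4", "NKX2-5")
  universe <- unique(toupper(universe))
  retained <- events[events$expected_fate == "retained_candidate", , drop = FALSE]
  hit_genes <- character()
  for (i in seq_len(nrow(retained))) {
    t <- transcriptome[transcriptome$chrom == retained$chrom[i] &
                         transcriptome$start <= retained$end[i] &
                         transcriptome$end >= retained$start[i], ]
    hit_genes <- c(hit_genes, t$gene)
  }
  hit_genes <- unique(toupper(hit_genes))
  planted <- unique(c(hit_genes,
                      sample(setdiff(universe, hit_genes),
                             max(0, 10 - length(hit_genes)))))
  sets <- list(planted_enriched = planted)
  for (k in seq_len(config$n_gene_sets - 1)) {
    sz <- sample(seq(config$gene_set_size_range[1], config$gene_set_size_range[2]), 1)
    sets[[sprintf("random_set_%03d", k)]] <- sample(universe, sz)
  }
  sets
}

#' Generate planted sequencing variants
#'
#' True heterozygotes draw `alt_reads ~ Binomial(depth, 0.5)`, planted
#' artifacts `~ Binomial(depth, 0.1)`; depth is negative-binomial
#' (`mu = depth_mu`, `size = depth_size`) truncated at `depth_min`.
#' Common variants carry a population frequency above the rarity ceiling, and
#' no-impact variants lack the predicted-impact annotation that the
#' candidate-gene tier requires.
#'
#' @param config a [cohort_config()].
#' @param samples sample ids to draw carriers from (defaults to the config's
#'   case samples).
#' @return list with `variants` (a tibble [read_variants()]-compatible) and
#'   `truth` (adds `class` and `expected_reported`).
#' @export
generate_variants <- function(config, samples = NULL) {
  if (is.null(samples)) samples <- sprintf("case%02d", seq_len(config$n_cases))
  known_genes <- c("MYH7", "GATA4", "NKX2-5")
  panel <- cardiomyopathy_panel()
  other_genes <- c("TBX5", "SMARCA4", "CORIN", "ZNF534", "BMPR2")
  draw_depth <- function(n) {
    pmax(stats::rnbinom(n, mu = config$depth_mu, size = config$depth_size),
         config$depth_min)
  }
  bases <- c("A", "C", "G", "T")
  mk <- function(n, class) {
    if (n == 0) return(NULL)
    depth <- draw_depth(n)
    p_alt <- if (class == "artifact") 0.1 else 0.5
    n_alt <- stats::rbinom(n, depth, p_alt)
    gene <- sample(c(known_genes, panel, other_genes), n, replace = TRUE)
    af <- if (class == "common") {
      stats::runif(n, 0.02, 0.2)
    } else {
      ifelse(stats::runif(n) < 0.7, NA_real_, stats::runif(n, 0, 0.003))
    }
    tier <- ifelse(gene %in% known_genes, "known_ea_gene", "candidate_gene")
    impact <- class != "noimpact"
    ref <- sample(bases, n, replace = TRUE)
    tibble::tibble(
      sample = sample(samples, n, replace = TRUE),
      chrom = sample(autosomes_of(config), n, replace = TRUE),
      pos = round(stats::runif(n, 1e4, 1e6)),
      ref = ref,
      alt = vapply(ref, function(b) sample(setdiff(bases, b), 1), ""),
      gene = gene,
      ref_reads = depth - n_alt, alt_reads = n_alt,
      population_af = af, tier = tier,
      lof = impact & stats::runif(n) < 0.5,
      pathogenic = impact,
      zygosity_call = "het",
      class = class
    )
  }
  v <- dplyr::bind_rows(
    mk(config$n_true_het, "true_het"),
    mk(config$n_artifact_variants, "artifact"),
    mk(config$n_common_variants, "common"),
    mk(config$n_noimpact_variants, "noimpact")
  )
  if (nrow(v) == 0) {
    v <- tibble::tibble(
      sample = character(), chrom = character(), pos = numeric(),
      ref = character(), alt = character(), gene = character(),
      ref_reads = integer(), alt_reads = integer(),
      population_af = numeric(), tier = character(), lof = logical(),
      pathogenic = logical(), zygosity_call = character(), class = character())
  }
  v <- v[v$ref_reads + v$alt_reads >= 1, , drop = FALSE]
  v <- v[order(v$sample, chrom_rank(v$chrom), v$pos), ]
  # expected report status by construction: rare, non-artifact balance, and
  # (for the candidate tier) a predicted-impact annotation
  ab <- v$alt_reads / (v$ref_reads + v$alt_reads)
  rare <- is.na(v$population_af) | v$population_af < 0.005
  impact_ok <- v$tier == "known_ea_gene" | v$lof | v$pathogenic
  v$expected_reported <- rare & impact_ok & ab >= 0.25
  truth <- v
  variants <- v[, setdiff(names(v), c("class", "expected_reported"))]
  list(variants = variants, truth = truth)
}

# Per-probe genotype/BAF/LRR for every sample (long format).
make_probe_data <- function(config, probe_map, samples, events, roh) {
  n <- nrow(probe_map)
  out <- vector("list", length(samples))
  for (si in seq_along(samples)) {
    smp <- samples[si]
    lrr <- stats::rnorm(n, 0, config$lrr_sd)
    u <- stats::runif(n)
    geno <- ifelse(u < config$nc_rate, "NC",
                   ifelse(u < config$nc_rate + config$het_rate, "AB",
                          ifelse(stats::runif(n) < 0.5, "AA", "BB")))
    mine <- events[events$sample == smp, , drop = FALSE]
    for (i in seq_len(nrow(mine))) {
      idx <- probe_map$chrom == mine$chrom[i] &
        probe_map$position >= mine$start[i] & probe_map$position <= mine$end[i]
      if (mine$class[i] != "artifact") {
        shift <- if (mine$copy_number[i] < 2) config$lrr_loss_mean else config$lrr_gain_mean
        lrr[idx] <- lrr[idx] + shift
        if (mine$copy_number[i] < 2) {
          geno[idx & geno == "AB"] <- ifelse(
            stats::runif(sum(idx & geno == "AB")) < 0.5, "AA", "BB")
        }
      }
    }
    myroh <- roh[roh$sample == smp, , drop = FALSE]
    for (i in seq_len(nrow(myroh))) {
      idx <- probe_map$chrom == myroh$chrom[i] &
        probe_map$position >= myroh$start[i] & probe_map$position <= myroh$end[i] &
        geno == "AB"
      geno[idx] <- ifelse(stats::runif(sum(idx)) < 0.5, "AA", "BB")
    }
    baf <- numeric(n)
    baf[geno == "AA"] <- clamp(stats::rnorm(sum(geno == "AA"), 0.01, 0.01), 0, 1)
    baf[geno == "BB"] <- clamp(stats::rnorm(sum(geno == "BB"), 0.99, 0.01), 0, 1)
    baf[geno == "AB"] <- clamp(stats::rnorm(sum(geno == "AB"), 0.5, 0.03), 0, 1)
    baf[geno == "NC"] <- stats::runif(sum(geno == "NC"))
    out[[si]] <- tibble::tibble(
      sample = smp, marker = probe_map$marker, chrom = probe_map$chrom,
      position = probe_map$position, genotype = geno,
      baf = round(baf, 4), lrr = round(lrr, 4)
    )
  }
  dplyr::bind_rows(out)
}

plant_roh <- function(config, samples_cases) {
  if (config$n_roh == 0) {
    return(tibble::tibble(sample = character(), chrom = character(),
                          start = numeric(), end = numeric()))
  }
  autos <- autosomes_of(config)
  rows <- lapply(seq_len(config$n_roh), function(i) {
    chr <- sample(autos, 1)
    L <- config$chromosomes[[chr]]
    size <- round(stats::runif(1, 1.2e6, 2.5e6))
    s <- round(stats::runif(1, L - ROH_RESERVE + 1, L - size))
    tibble::tibble(sample = sample(samples_cases, 1), chrom = chr,
                   start = s, end = s + size - 1)
  })
  dplyr::bind_rows(rows)
}

simple_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
  sprintf("%010d", h)
}

#' Generate a complete synthetic cohort bundle
#'
#' Writes, under `dir`, everything the pipeline reads: a probe map, per-probe
#' genotype/BAF/LRR tables, one pennstyle and one partitionstyle call file
#' per sample, the five reference CNV sets, a transcriptome (BED4), a
#' candidate-gene list, a gene-set library (GMT), a sequencing-variant table,
#' a demographics table, the planted-truth table and a manifest. Identical
#' seeds give byte-identical bundles.
#'
#' Each planted event's `expected_fate` records what the selection cascade
#' should do with it: `retained_candidate`, `filtered_probes`,
#' `filtered_size`, `filtered_common`, `filtered_dgv` or `artifact_flagged`.
#' Events whose every emitted call fell below a caller confidence threshold
#' (or was missed by both callers) are marked `not_called`: the selection
#' stage never sees them.
#'
#' @param config a [cohort_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the in-memory pieces: `probe_map`,
#'   `probes`, `calls` (both callers, with event ids), `events` (truth),
#'   `reference_sets`, `transcriptome`, `candidate_genes`, `gene_sets`,
#'   `variants`, `variant_truth`, `roh`, `sex`, `demographics`, `paths`.
#' @export
generate_cohort <- function(config, dir) {
  set.seed(config$seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  samples_cases <- sprintf("case%02d", seq_len(config$n_cases))
  samples_controls <- sprintf("ctrl%02d", seq_len(config$n_controls))
  samples <- c(samples_cases, samples_controls)
  sex <- stats::setNames(rep(c("M", "F"), length.out = length(samples)), samples)

  probe_map <- make_probe_map(config)
  events <- plant_events(config, probe_map, samples_cases, sex)
  bad <- events$end > config$chromosomes[events$chrom]
  if (any(bad)) stop("generate_cohort: planted event outside chromosome", call. = FALSE)

  penn <- emit_caller_calls(config, events, probe_map, samples, "pennstyle")
  part <- emit_caller_calls(config, events, probe_map, samples, "partitionstyle")
  events$expected_fate[!(penn$emitted | part$emitted)] <- "not_called"

  refs <- make_reference_sets(config, events)
  transcriptome <- make_transcriptome(config)
  candidate_genes <- sort(sample(transcriptome$gene,
                                 round(0.1 * nrow(transcriptome))))
  gene_sets <- make_gene_sets(config, transcriptome, events)
  vg <- generate_variants(config, samples_cases)
  roh <- plant_roh(config, samples_cases)
  probes <- make_probe_data(config, probe_map, samples, events, roh)

  demographics <- tibble::tibble(
    characteristic = rep(c("case_sex", "maternal_age"), c(2, 3)),
    category = c("Male", "Female", "<20", "20-34", ">=35"),
    population_count = c(512000, 488000, 78000, 740000, 182000),
    case_count = c(sum(sex[samples_cases] == "M"), sum(sex[samples_cases] == "F"),
                   round(config$n_cases * 0.1), round(config$n_cases * 0.7),
                   config$n_cases - round(config$n_cases * 0.1) -
                     round(config$n_cases * 0.7))
  )

  # ---- write bundle (deterministic order everywhere) ----
  paths <- list()
  wt <- function(x, name) {
    p <- file.path(dir, name)
    utils::write.table(as.data.frame(x), p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p
  }
  paths$probe_map <- wt(probe_map, "probe_map.tsv")
  paths$probes <- file.path(dir, "probes.tsv")
  readr::write_tsv(probes, paths$probes)   # large table; fast writer
  dir.create(file.path(dir, "calls"), showWarnings = FALSE)
  call_cols <- c("sample", "chrom", "start", "end", "copy_number", "n_probes",
                 "confidence", "caller")
  paths$penn_calls <- paths$partition_calls <- character()
  for (smp in samples) {
    pc <- penn$calls[penn$calls$sample == smp, , drop = FALSE]
    pc$start_marker <- sprintf("snp_s%06d", seq_len(nrow(pc)))
    pc$end_marker <- sprintf("snp_e%06d", seq_len(nrow(pc)))
    f <- file.path(dir, "calls", paste0(smp, ".penn.rawcnv"))
    write_cnv_calls(pc, f, "pennstyle")
    paths$penn_calls <- c(paths$penn_calls, f)
    qc <- part$calls[part$calls$sample == smp, , drop = FALSE]
    f2 <- file.path(dir, "calls", paste0(smp, ".partition.tsv"))
    write_cnv_calls(qc, f2, "partitionstyle")
    paths$partition_calls <- c(paths$partition_calls, f2)
  }
  for (nm in names(refs)) paths[[nm]] <- wt(refs[[nm]], paste0(nm, ".tsv"))
  paths$transcriptome <- write_transcript_bed(transcriptome,
                                              file.path(dir, "transcriptome.bed"))
  paths$candidate_genes <- file.path(dir, "candidate_genes.txt")
  writeLines(candidate_genes, paths$candidate_genes)
  paths$gene_sets <- write_gene_set_library(gene_sets, file.path(dir, "gene_sets.gmt"))
  paths$variants <- wt(vg$variants, "variants.tsv")
  paths$variant_truth <- wt(vg$truth, "variant_truth.tsv")
  paths$demographics <- wt(demographics, "demographics.tsv")
  truth <- events[, c("event_id", "class", "sample", "chrom", "start", "end",
                      "copy_number", "cnv_type", "n_probes_true", "size_bp",
                      "recurrent_group", "expected_fate")]
  paths$truth <- wt(truth, "truth.tsv")
  sex_tbl <- tibble::tibble(sample = samples, sex = unname(sex))
  paths$sex <- wt(sex_tbl, "samples.tsv")
  manifest <- list(seed = config$seed, config_hash = simple_hash(unclass(config)),
                   n_cases = config$n_cases, n_controls = config$n_controls,
                   files = sort(basename(unlist(paths))))
  paths$manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(
    probe_map = probe_map, probes = probes,
    calls = dplyr::bind_rows(penn$calls, part$calls),
    events = events, reference_sets = refs, transcriptome = transcriptome,
    candidate_genes = candidate_genes, gene_sets = gene_sets,
    variants = vg$variants, variant_truth = vg$truth, roh = roh,
    sex = sex, demographics = demographics, paths = paths, config = config
  ))
}
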