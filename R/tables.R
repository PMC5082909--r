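# Published study tables, transcribed as in-code fixtures. These are inputs
# to the pipeline's arithmetic (sizes, percentages, prevalences, case-level
# summaries), used by the analysis scripts and by the verification tests.

#' Cohort accounting constants of the study
#'
#' Live births, total ascertained cases, the exclusion cascade, and the number
#' of cases genotyped.
#' @return named list.
#' @export
ea_cohort_numbers <- function() {
  list(
    births = 2023083L,
    total_cases = 117L,
    exclusions = c(syndromes_chromosomal = 14L, other_chd = 37L,
                   other_major_defects = 14L, plural_births = 1L),
    eligible_cases = 51L,
    genotyped_cases = 47L
  )
}

#' Demographic comparison table (cases vs all state live births)
#'
#' Long-format counts with the printed percentages and p-values retained for
#' verification.
#' @return tibble with `characteristic`, `category`, `population_count`,
#'   `case_count`, `printed_population_pct`, `printed_case_pct`, `printed_p`.
#' @export
ea_table1 <- function() {
  tribble_ <- tibble::tribble
  tribble_(
    ~characteristic, ~category, ~population_count, ~case_count, ~printed_population_pct, ~printed_case_pct, ~printed_p,
    "maternal_age", "<20", 157085, 3, 7.8, 5.9, 0.88,
    "maternal_age", "20-34", 1480911, 38, 73.2, 74.5, 0.88,
    "maternal_age", ">=35", 384744, 10, 19.0, 19.6, 0.88,
    "race_ethnicity", "Non-Hispanic White", 1051561, 29, 52.1, 56.9, 0.85,
    "race_ethnicity", "Black", 361836, 8, 17.9, 15.7, 0.85,
    "race_ethnicity", "Hispanic", 437846, 10, 21.7, 19.6, 0.85,
    "race_ethnicity", "Asian", 135374, 4, 6.7, 7.8, 0.85,
    "race_ethnicity", "Other", 31220, 0, 1.6, 0.0, 0.85,
    "maternal_education", "<12", 384781, 11, 19.3, 21.6, 0.91,
    "maternal_education", "12", 594659, 15, 29.8, 29.4, 0.91,
    "maternal_education", ">12", 1017827, 25, 51.0, 49.0, 0.91,
    "parity", "Nulliparous", 846801, 18, 41.9, 35.3, 0.34,
    "parity", "Multiparous", 1176248, 33, 58.1, 64.7, 0.34,
    "maternal_smoking", "No", 1842757, 46, 91.1, 90.2, 0.82,
    "maternal_smoking", "Yes", 180292, 5, 8.9, 9.8, 0.82,
    "bmi", "<18.5", 40332, 0, 4.1, 0.0, 0.66,
    "bmi", "18.5-24.9", 523438, 14, 53.5, 56.0, 0.66,
    "bmi", "25-29.9", 182264, 6, 18.6, 24.0, 0.66,
    "bmi", ">=30", 233251, 5, 23.8, 20.0, 0.66,
    "case_sex", "Male", 1036825, 30, 51.3, 58.8, 0.28,
    "case_sex", "Female", 986210, 21, 48.8, 41.2, 0.28
  )
}

#' Candidate CNV table of the study
#'
#' One row per (CNV, carrying case): identifier, study id, CNV type, locus,
#' printed coordinates (from the pennstyle caller for autosomes, the
#' partitionstyle caller for sex chromosomes), printed size in Kb, the
#' printed transcript list, and which of those transcripts the study's
#' model-organism candidate-gene list flagged.
#' @return candidate tibble.
#' @export
ea_table2 <- function() {
  t <- tibble::tribble(
    ~cnv_id, ~sample, ~type, ~chrom, ~locus, ~start, ~end, ~printed_kb, ~transcripts_str, ~flagged_str,
    2L, "C12", "Dupl", "8", "8q21.13", 83573868, 83964230, 390L, "CTD-2272D18.1;RP11-653B10.1;RP11-731N10.1", "",
    2L, "C47", "Dupl", "8", "8q21.13", 83848688, 83981829, 133L, "CTD-2272D18.1;RP11-731N10.1", "",
    4L, "C43", "Dupl", "1", "1p36.12", 21002613, 21037639, 35L, "KIF17", "",
    5L, "C4", "Dupl", "1", "1p34.1", 44195344, 44428902, 234L, "ARTN;IPO13;RP11-7O11.3;ST3GAL3", "ARTN",
    6L, "C34", "Dupl", "1", "1p34.1", 46058525, 46101490, 43L, "CCDC17;GPBP1L1;NASP", "NASP",
    7L, "C43", "Dupl", "2", "2p23.1", 30656586, 30735763, 79L, "LCLAT1", "LCLAT1",
    8L, "C22", "Het Del", "2", "2q23.1-24.1", 149164048, 156511426, 7347L,
    "ARL5A;ARL6IP6;CACNB4;EPC2;FMNL2;GALNT13;KCNJ3;KIF5C;LYPD6;LYPD6B;MBD5;MIR4773-1;MMADHC;NEB;NMI;PRPF40A;RBM43;RIF1;RN7SL124P;RNA5SP107;RND3;RPRM;SNORD56;STAM2;TNFAIP6",
    "CACNB4;EPC2;KCNJ3;KIF5C;MBD5;NEB;RIF1;RND3;TNFAIP6",
    9L, "C20", "Dupl", "2", "2q33.1-33.2", 203134839, 203796988, 662L,
    "BMPR2;CARF;FAM117B;ICA1L;NOP58;RN7SL40P;RN7SL753P;RP11-686O6.1;RP11-686O6.2;WDR12", "BMPR2;FAM117B",
    10L, "C14", "Het Del", "3", "3p26.2", 3804555, 3830671, 26L, "SUMF1", "SUMF1",
    11L, "C2", "Het Del", "3", "3p21.1", 53406740, 53491422, 85L, "SNORA26", "",
    12L, "C23", "Het Del", "4", "4q13.1", 60249365, 60294193, 45L, "", "",
    13L, "C47", "Dupl", "4", "4q26", 120028773, 120162705, 134L, "MYOZ2;RP11-455G16.1;USP53", "MYOZ2",
    14L, "C10", "Dupl", "4", "4q35.1-35.2", 187078181, 187190810, 113L, "CYP4V2;F11;FAM149A;KLKB1", "F11;KLKB1",
    15L, "C34", "Dupl", "5", "5q22.1", 110417428, 110444810, 27L, "CTC-551A13.2;WDR36", "WDR36",
    17L, "C13", "Het Del", "6", "6p25.3", 1831050, 2175663, 345L, "GMDS", "GMDS",
    18L, "C20", "Dupl", "6", "6q22.1", 118039508, 118237605, 198L, "SLC35F1", "",
    19L, "C6", "Dupl", "6", "6q24.3", 148005232, 148138720, 133L, "RP11-307P5.1;RP11-307P5.2", "",
    20L, "C43", "Het Del", "6", "6q25.1", 151427385, 151655101, 228L,
    "AKAP12;RN7SKP268;RNU6-1247P;RNU6-300P;RNY4P20;RP1-292B18.4;RP1-297M16.2", "AKAP12",
    21L, "C26", "Het Del", "8", "8p23.1", 9258509, 9298347, 40L, "RP11-115J16.2", "",
    22L, "C38", "Dupl", "8", "8q11.21", 48170319, 48204412, 34L, "SPIDR", "",
    23L, "C3", "Het Del", "8", "8q21.12", 79775378, 80038602, 263L, "AC009941.1", "",
    24L, "C42", "Het Del", "9", "9p24.1", 7658764, 7889991, 231L, "RP11-77E14.2;TMEM261", "",
    25L, "C34", "Dupl", "10", "10q24.33", 105157553, 105215741, 58L, "CALHM1;CALHM2;PDCD11;RP11-225H22.4;RP11-225H22.7", "",
    26L, "C46", "Dupl", "10", "10q25.1", 108765792, 108793878, 28L, "SORCS1", "",
    27L, "C34", "Het Del", "11", "11p13", 35538329, 35611601, 73L, "PAMR1;RP5-945I17.2", "",
    28L, "C15", "Dupl", "11", "11q13.3", 69239611, 69434379, 195L, "AP000439.1;AP000439.2;AP000439.3;AP000439.5", "",
    29L, "C30", "Dupl", "12", "12p12.1", 22608226, 22649460, 41L, "C2CD5;RP11-359J14.2", "",
    30L, "C35", "Dupl", "12", "12q13.12", 50893815, 50995674, 102L, "DIP2B", "DIP2B",
    31L, "C4", "Dupl", "13", "13q21.32", 67843475, 67900578, 57L, "", "",
    32L, "C4", "Dupl", "13", "13q22.2", 76247612, 76281850, 34L, "LMO7;RP11-29G8.3", "LMO7",
    33L, "C9", "Dupl", "16", "16p13.2", 9041214, 9295696, 254L,
    "C16orf72;RP11-473I1.10;RP11-473I1.5;RP11-473I1.6;RP11-473I1.9;RP11-77H9.8;USP7", "USP7",
    34L, "C36", "Het Del", "16", "16q23.2", 80245950, 80316836, 71L, "RP11-525K10.3", "",
    35L, "C3", "Het Del", "19", "19q13.41", 52932290, 52984708, 52L, "ZNF534;ZNF578", "",
    36L, "C14", "Dupl (3,F)", "X", "Xp22.33", 902677, 1262175, 359L, "RP11-309M23.1", "",
    37L, "C25", "Dupl (3,F)", "X", "Xp11.3", 44381642, 44872791, 491L, "DUSP21;FUNDC1;KDM6A;RN7SL291P;RNU6-523P", "KDM6A",
    38L, "C42", "Del (0,M)", "Y", "Xq11.1", 61726006, 62027422, 301L, "", ""
  )
  split_field <- function(x) {
    lapply(x, function(v) if (v == "") character() else strsplit(v, ";", fixed = TRUE)[[1]])
  }
  t$transcripts <- split_field(t$transcripts_str)
  t$flagged_candidate_genes <- split_field(t$flagged_str)
  t$cnv_type <- ifelse(grepl("Del", t$type), "loss", "gain")
  t$copy_number <- ifelse(grepl("\\(0", t$type), 0L,
                          ifelse(t$cnv_type == "loss", 1L, 3L))
  t$transcripts_str <- NULL
  t$flagged_str <- NULL
  t
}

#' Validated rare sequence variants in the known disease genes
#' @return variant tibble (tier `known_ea_gene`).
#' @export
ea_table3 <- function() {
  tibble::tribble(
    ~chrom, ~pos, ~gene, ~transcript, ~cdna, ~aa, ~rsid, ~population_af, ~sample,
    "5", 172661963, "NKX2-5", "ENST00000329198", "c.124G>C", "p.Ala42Pro", "rs113818864", 1.58e-4, "C46",
    "14", 23886518, "MYH7", "ENST00000355349", "c.4363G>A", "p.Glu1455Lys", NA, NA, "C37",
    "14", 23888685, "MYH7", "ENST00000355349", "c.3853+7C>T", NA, "rs45467397", 2.29e-3, "C26",
    "14", 23900793, "MYH7", "ENST00000355349", "c.732+1G>A", NA, "rs730880850", NA, "C30",
    "14", 23900798, "MYH7", "ENST00000355349", "c.728G>A", "p.Arg243His", "rs267606910", 8.24e-6, "C19",
    "14", 23901862, "MYH7", "ENST00000355349", "c.488A>C", "p.Gln163Pro", NA, NA, "C41"
  ) |> dplyr::mutate(tier = "known_ea_gene")
}

#' Validated rare sequence variants in candidate disease genes
#' @return variant tibble (tier `candidate_gene`).
#' @export
ea_table4 <- function() {
  tibble::tribble(
    ~chrom, ~pos, ~gene, ~transcript, ~cdna, ~aa, ~rsid, ~population_af, ~sample,
    "2", 179446303, "TTN", "ENST00000589042", "c.66692G>A", "p.Arg22231His", "rs200971254", 3.76e-4, "C7",
    "2", 179575832, "TTN", "ENST00000589042", "c.28131C>A", "p.Asn9377Lys", "rs72648997", 4.23e-5, "C4",
    "2", 179664626, "TTN", "ENST00000589042", "c.593_595delAAG", "p.Glu198del", "rs771898264", 1.49e-4, "C4",
    "2", 203420616, "BMPR2", "ENST00000374580", "c.2228A>G", "p.Tyr743Cys", "rs148257675", 3.30e-5, "C18",
    "4", 47647166, "CORIN", "ENST00000273857", "c.1889G>A", "p.Cys630Tyr", "rs373155410", 8.25e-6, "C47",
    "12", 114793401, "TBX5", "ENST00000310346", "c.1493C>A", "p.Ser498Tyr", NA, NA, "C45",
    "14", 23856987, "MYH6", "ENST00000356287", "c.4505G>A", "p.Arg1502Gln", "rs199936506", 1.81e-4, "C14",
    "14", 23862177, "MYH6", "ENST00000356287", "c.3195G>C", "p.Gln1065His", "rs267606904", 2.31e-4, "C31",
    "17", 37821649, "TCAP", "ENST00000309889", "c.37_39delGAG", "p.Glu13del", "rs397516862", NA, "C2",
    "17", 39921023, "JUP", "ENST00000310706", "c.1100G>T", "p.Arg367Leu", NA, NA, "C36",
    "19", 11152089, "SMARCA4", "ENST00000358026", "c.4373C>T", "p.Thr1458Ile", NA, NA, "C1",
    "19", 52941827, "ZNF534", "ENST00000332323", "c.1153C>G", "p.His385Asp", "rs201395526", 5.48e-4, "C11"
  ) |> dplyr::mutate(tier = "candidate_gene")
}

#' Published variant tables as triage-ready input
#'
#' Binds the two validated-variant tables into a [triage_variants()]-ready
#' tibble. The tables print no read counts (all variants validated as
#' heterozygous), so balanced counts at depth 40 are filled in; every
#' candidate-tier row carries the predicted-impact annotation the study
#' required of them.
#' @return variant tibble.
#' @export
ea_tables34_variants <- function() {
  v <- dplyr::bind_rows(ea_table3(), ea_table4())
  tibble::tibble(
    sample = v$sample, chrom = v$chrom, pos = v$pos, ref = "N", alt = "N",
    gene = v$gene, ref_reads = 20L, alt_reads = 20L,
    population_af = v$population_af, tier = v$tier,
    lof = v$tier == "candidate_gene", pathogenic = v$tier == "candidate_gene",
    zygosity_call = "het"
  )
}

#' hg19 intervals of the known Ebstein anomaly genes
#' @return tibble with `gene`, `chrom`, `start`, `end`.
#' @export
ea_known_genes <- function() {
  tibble::tribble(
    ~gene, ~chrom, ~start, ~end,
    "NKX2-5", "5", 172659112, 172662360,
    "GATA4", "8", 11534468, 11617511,
    "MYH7", "14", 23881947, 23904870
  )
}

#' Synthetic transcriptome reproducing the candidate table's transcript lists
#'
#' One transcript record per printed transcript symbol, placed inside its
#' CNV's printed span, so that [intersect_transcripts()] on the printed
#' coordinates reproduces each row's transcript list exactly. Coordinates of
#' the transcripts themselves are synthetic (the table prints only the CNV
#' spans).
#' @return transcript tibble.
#' @export
ea_table2_transcriptome <- function() {
  t2 <- ea_table2()
  all_syms <- unique(unlist(t2$transcripts))
  rows <- list()
  for (g in all_syms) {
    listed <- vapply(t2$transcripts, function(s) g %in% s, TRUE)
    chrom <- unique(t2$chrom[listed])
    # a transcript must lie inside every span that lists it and outside every
    # same-chromosome span that does not
    must <- IRanges::IRanges(start = t2$start[listed], end = t2$end[listed])
    region <- IRanges::IRanges(max(IRanges::start(must)), min(IRanges::end(must)))
    other <- t2[!listed & t2$chrom == chrom, , drop = FALSE]
    if (nrow(other) > 0) {
      region <- IRanges::setdiff(
        region, IRanges::IRanges(start = other$start, end = other$end))
    }
    if (length(region) == 0) {
      stop("ea_table2_transcriptome: no feasible placement for ", g, call. = FALSE)
    }
    s <- IRanges::start(region)[1]
    e <- min(IRanges::end(region)[1], s + 999)
    rows[[g]] <- tibble::tibble(gene = g, chrom = chrom, start = s, end = e,
                                biotype = "synthetic")
  }
  out <- dplyr::bind_rows(rows)
  out[order(chrom_rank(out$chrom), out$start, out$gene), ]
}
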