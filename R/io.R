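#' Read per-sample CNV caller output
#'
#' Two caller dialects are supported:
#' \describe{
#'   \item{`pennstyle`}{the PennCNV rawcnv text layout: whitespace-delimited
#'     records `chrN:start-end numsnp=K length=L stateS,cn=C sample
#'     startsnp=.. endsnp=.. conf=F`.}
#'   \item{`partitionstyle`}{a GenomeStudio/cnvPartition-style tab-delimited
#'     table with header columns Sample ID, Chr, Start, End, Value (copy
#'     number), Confidence and #SNPs.}
#' }
#' Chromosome labels are normalized (no "chr" prefix) and copy numbers are
#' integers. Lines that cannot be parsed raise an error naming the line.
#'
#' @param path file to read.
#' @param dialect `"pennstyle"` or `"partitionstyle"`.
#' @return a tibble of CNV calls: `sample`, `chrom`, `start`, `end`,
#'   `copy_number`, `n_probes`, `confidence`, `caller`, plus opaque
#'   `start_marker`/`end_marker` annotations for the pennstyle dialect.
#' @export
read_cnv_calls <- function(path, dialect = c("pennstyle", "partitionstyle")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("read_cnv_calls: no such file: ", path, call. = FALSE)
  if (dialect == "pennstyle") read_penn_rawcnv(path) else read_partition_table(path)
}

read_penn_rawcnv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_calls())
  rx <- paste0(
    "^(\\S+):([0-9,]+)-([0-9,]+)\\s+numsnp=([0-9,]+)\\s+length=([0-9,]+)\\s+",
    "state[0-9]+,cn=([0-9]+)\\s+(\\S+)\\s+startsnp=(\\S+)\\s+endsnp=(\\S+)",
    "(?:\\s+conf=([0-9.eE+-]+))?\\s*$"
  )
  m <- regmatches(lines, regexec(rx, lines))
  bad <- which(vapply(m, length, 0L) == 0)
  if (length(bad) > 0) {
    stop("read_cnv_calls: unparseable pennstyle record at line ", bad[1],
         ": ", lines[bad[1]], call. = FALSE)
  }
  f <- function(i) vapply(m, `[[`, "", i + 1L)
  denum <- function(x) as.numeric(gsub(",", "", x))
  tibble::tibble(
    sample = f(7),
    chrom = normalize_chrom(f(1)),
    start = denum(f(2)),
    end = denum(f(3)),
    copy_number = as.integer(f(6)),
    n_probes = as.integer(denum(f(4))),
    confidence = ifelse(nzchar(f(10)), as.numeric(f(10)), NA_real_),
    caller = "pennstyle",
    start_marker = f(8),
    end_marker = f(9)
  )
}

read_partition_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) return(empty_calls())
  pick <- function(aliases) {
    hit <- which(tolower(names(df)) %in% tolower(aliases))
    if (length(hit) == 0) {
      stop("read_cnv_calls: partitionstyle table lacks column ",
           aliases[1], call. = FALSE)
    }
    df[[hit[1]]]
  }
  tibble::tibble(
    sample = as.character(pick(c("Sample ID", "SampleID", "sample"))),
    chrom = normalize_chrom(pick(c("Chr", "Chromosome", "chrom"))),
    start = as.numeric(pick(c("Start", "start"))),
    end = as.numeric(pick(c("End", "end"))),
    copy_number = as.integer(pick(c("Value", "Copy Number", "CN", "copy_number"))),
    n_probes = as.integer(pick(c("#SNPs", "Num SNPs", "n_probes"))),
    confidence = as.numeric(pick(c("Confidence", "confidence"))),
    caller = "partitionstyle",
    start_marker = NA_character_,
    end_marker = NA_character_
  )
}

empty_calls <- function() {
  tibble::tibble(
    sample = character(), chrom = character(), start = numeric(),
    end = numeric(), copy_number = integer(), n_probes = integer(),
    confidence = numeric(), caller = character(),
    start_marker = character(), end_marker = character()
  )
}

#' Write caller output files for a set of calls
#'
#' Emits byte-valid files in the dialect named by each call's `caller` column;
#' the synthetic-cohort generator uses this to produce inputs that
#' [read_cnv_calls()] parses back exactly.
#' @param calls a calls tibble (see [read_cnv_calls()]).
#' @param path output file.
#' @param dialect which dialect to write.
#' @return `path`, invisibly.
#' @export
write_cnv_calls <- function(calls, path, dialect = c("pennstyle", "partitionstyle")) {
  dialect <- match.arg(dialect)
  if (dialect == "pennstyle") {
    lines <- sprintf(
      "chr%s:%d-%d\tnumsnp=%d\tlength=%s\tstate%d,cn=%d\t%s\tstartsnp=%s\tendsnp=%s\tconf=%.3f",
      calls$chrom, as.integer(calls$start), as.integer(calls$end),
      calls$n_probes, format(as.integer(calls$end - calls$start + 1), big.mark = ",", trim = TRUE),
      penn_state_code(calls$copy_number), calls$copy_number, calls$sample,
      ifelse(is.na(calls$start_marker), "-", calls$start_marker),
      ifelse(is.na(calls$end_marker), "-", calls$end_marker),
      calls$confidence
    )
    writeLines(lines, path)
  } else {
    if (nrow(calls) == 0) {
      writeLines(paste(c("Sample ID", "Chr", "Start", "End", "Value",
                         "Confidence", "#SNPs"), collapse = "\t"), path)
      return(invisible(path))
    }
    df <- data.frame(
      `Sample ID` = calls$sample, Chr = paste0("chr", calls$chrom),
      Start = as.integer(calls$start), End = as.integer(calls$end),
      Value = calls$copy_number, Confidence = calls$confidence,
      `#SNPs` = calls$n_probes, check.names = FALSE
    )
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

# PennCNV HMM state codes: state1=cn0, state2=cn1, state3/4=cn2, state5=cn3, state6=cn4
penn_state_code <- function(cn) {
  c(`0` = 1L, `1` = 2L, `2` = 3L, `3` = 5L, `4` = 6L)[as.character(cn)]
}

#' Read transcript annotation (BED4 or GTF)
#'
#' BED input uses 0-based half-open starts and is converted to the package's
#' 1-based inclusive convention on read; GTF is 1-based inclusive already.
#' Overlapping transcripts of one gene are preserved as separate records.
#'
#' @param path annotation file.
#' @param format `"BED"` or `"GTF"`.
#' @return a tibble of transcript records: `gene`, `chrom`, `start`, `end`,
#'   `biotype`.
#' @export
read_transcript_annotation <- function(path, format = c("BED", "GTF")) {
  format <- match.arg(format)
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("read_transcript_annotation requires rtracklayer", call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = tolower(format))
  if (format == "GTF") {
    md <- S4Vectors::mcols(gr)
    if ("type" %in% names(md)) gr <- gr[as.character(md$type) == "transcript"]
    md <- S4Vectors::mcols(gr)
    gene <- if ("gene_name" %in% names(md)) as.character(md$gene_name) else as.character(md$gene_id)
    biotype <- if ("transcript_biotype" %in% names(md)) {
      as.character(md$transcript_biotype)
    } else if ("gene_biotype" %in% names(md)) {
      as.character(md$gene_biotype)
    } else NA_character_
  } else {
    gene <- as.character(S4Vectors::mcols(gr)$name)
    biotype <- NA_character_
  }
  out <- tibble::tibble(
    gene = gene,
    chrom = normalize_chrom(as.character(GenomicRanges::seqnames(gr))),
    start = as.numeric(GenomicRanges::start(gr)),
    end = as.numeric(GenomicRanges::end(gr)),
    biotype = biotype
  )
  if (nrow(out) > 0 && any(out$end < out$start)) {
    stop("read_transcript_annotation: coordinate conversion produced end < start",
         call. = FALSE)
  }
  out
}

#' Write a BED4 transcript annotation (1-based inclusive -> 0-based half-open)
#' @param transcripts tibble with `gene`, `chrom`, `start`, `end`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_transcript_bed <- function(transcripts, path) {
  lines <- sprintf("chr%s\t%d\t%d\t%s",
                   transcripts$chrom, as.integer(transcripts$start) - 1L,
                   as.integer(transcripts$end), transcripts$gene)
  writeLines(lines, path)
  invisible(path)
}

#' Read a reference CNV set (common polymorphisms, control CNVs, DGV-like)
#'
#' Tab-delimited with header columns `chrom`, `start`, `end`, `type`; `type`
#' is one of `loss`, `gain`, `both` ("both" matches either CNV type during
#' overlap profiling).
#' @param path file to read.
#' @return a tibble with normalized chromosomes and a `type` column.
#' @export
read_reference_cnv_set <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), type = character()))
  }
  bad <- setdiff(unique(df$type), c("loss", "gain", "both"))
  if (length(bad) > 0) {
    stop("read_reference_cnv_set: unknown CNV type label(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(chrom = normalize_chrom(df$chrom), start = as.numeric(df$start),
                 end = as.numeric(df$end), type = df$type)
}

#' Write a reference CNV set
#' @param set tibble with `chrom`, `start`, `end`, `type`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_reference_cnv_set <- function(set, path) {
  utils::write.table(as.data.frame(set), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene-set library in GMT format
#'
#' One set per line: name, description, then member symbols, tab-delimited.
#' Members are uppercased and deduplicated; empty member lists are retained as
#' empty sets; duplicate set names are an error.
#' @param path GMT file.
#' @return named list of character vectors (set name -> member symbols).
#' @export
read_gene_set_library <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(stats::setNames(list(), character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  names_ <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(names_)) {
    stop("read_gene_set_library: duplicate set name(s): ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "), call. = FALSE)
  }
  members <- lapply(parts, function(p) {
    m <- if (length(p) >= 3) p[-(1:2)] else character()
    unique(toupper(m[nzchar(m)]))
  })
  stats::setNames(members, names_)
}

#' Write a gene-set library in GMT format
#' @param library named list of member symbol vectors.
#' @param path output file.
#' @param descriptions optional character vector of set descriptions.
#' @return `path`, invisibly.
#' @export
write_gene_set_library <- function(library, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(library))
  lines <- mapply(function(nm, desc, members) {
    paste(c(nm, desc, members), collapse = "\t")
  }, names(library), descriptions, library)
  writeLines(unname(lines), path)
  invisible(path)
}

#' Write the candidate-CNV report
#'
#' Tab-delimited table mirroring the study's candidate table: CNV identifier,
#' study ID, CNV type and copy number, sex (sex-chromosome calls only), locus
#' label, coordinates, size in Kb, semicolon-joined transcripts ("-" when the
#' candidate lies in a gene desert), candidate-gene hits, recurrence flags and
#' the LRR review flag. Row order is deterministic (chrom, start, sample).
#' Recurrent CNVs shared by several cases appear as one row per case sharing
#' one CNV identifier. `read_candidate_report()` round-trips the file.
#'
#' @param candidates annotated candidate tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_candidate_report <- function(candidates, path) {
  cols <- c("cnv_id", "sample", "cnv_type", "copy_number", "sex", "locus",
            "chrom", "start", "end", "size_kb", "transcripts",
            "candidate_genes", "recurrent", "n_cases_sharing", "review_flag")
  out <- candidates
  for (col in cols) if (!col %in% names(out)) out[[col]] <- NA
  joinsym <- function(x) {
    vapply(x, function(v) {
      if (is.null(v) || length(v) == 0 || all(is.na(v))) "-" else paste(sort(v), collapse = ";")
    }, "")
  }
  if (is.list(out$transcripts)) out$transcripts <- joinsym(out$transcripts)
  if (is.list(out$candidate_genes)) out$candidate_genes <- joinsym(out$candidate_genes)
  out$transcripts[is.na(out$transcripts) | out$transcripts == ""] <- "-"
  out$candidate_genes[is.na(out$candidate_genes) | out$candidate_genes == ""] <- "-"
  out <- out[order(chrom_rank(out$chrom), out$start, out$sample), cols]
  utils::write.table(as.data.frame(out), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a candidate-CNV report back
#' @param path report written by [write_candidate_report()].
#' @return candidate tibble with `transcripts`/`candidate_genes` as
#'   list-columns ("-" maps back to empty).
#' @export
read_candidate_report <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character", sample = "character"))
  out <- tibble::as_tibble(df)
  splitsym <- function(x) {
    lapply(x, function(v) if (is.na(v) || v == "-") character() else strsplit(v, ";", fixed = TRUE)[[1]])
  }
  out$transcripts <- splitsym(as.character(out$transcripts))
  out$candidate_genes <- splitsym(as.character(out$candidate_genes))
  out
}

# Sort key putting autosomes numerically before X then Y.
chrom_rank <- function(chrom) {
  n <- suppressWarnings(as.numeric(chrom))
  n[chrom %in% "X"] <- 100
  n[chrom %in% "Y"] <- 101
  n[is.na(n)] <- 200
  n
}

#' Read a probe table (marker map with genotype/BAF/LRR per sample)
#'
#' Tab-delimited with columns `marker`, `chrom`, `position`, `sample`,
#' `genotype` (AA/AB/BB/NC), `baf`, `lrr` (long format, one row per probe per
#' sample).
#' @param path file to read.
#' @return probe tibble sorted by sample, chrom, position.
#' @export
read_probe_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(chrom = readr::col_character()))
  out$chrom <- normalize_chrom(out$chrom)
  dplyr::arrange(out, .data$sample, chrom_rank(.data$chrom), .data$position)
}

#' Read a sequence-variant table
#'
#' Accepts either a flat tab-delimited table with explicit `ref_reads` /
#' `alt_reads` columns, or a VCF with per-allele depths in the `AD` FORMAT
#' field (requires the VariantAnnotation package). Both normalize to one
#' variant row per sample: `sample`, `chrom`, `pos`, `ref`, `alt`, `gene`,
#' `ref_reads`, `alt_reads`, `population_af` (NA when absent from the
#' reference database), `tier` (`known_ea_gene` / `candidate_gene`),
#' `lof`, `pathogenic`, `zygosity_call`.
#' @param path file to read.
#' @param format `"TSV"` or `"VCF"`.
#' @return variant tibble.
#' @export
read_variants <- function(path, format = c("TSV", "VCF")) {
  format <- match.arg(format)
  if (format == "TSV") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = c(chrom = "character"))
    out <- tibble::as_tibble(df)
    out$chrom <- normalize_chrom(out$chrom)
    out$population_af <- suppressWarnings(as.numeric(out$population_af))
    return(out)
  }
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("read_variants(format = 'VCF') requires VariantAnnotation", call. = FALSE)
  }
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ad <- VariantAnnotation::geno(vcf)$AD
  info <- VariantAnnotation::info(vcf)
  samples <- colnames(vcf)
  rows <- list()
  for (s in samples) {
    depths <- ad[, s]
    keep <- vapply(depths, function(d) length(d) == 2 && sum(d, na.rm = TRUE) > 0, TRUE)
    if (!any(keep)) next
    d <- depths[keep]
    rows[[s]] <- tibble::tibble(
      sample = s,
      chrom = normalize_chrom(as.character(GenomicRanges::seqnames(rr)))[keep],
      pos = as.numeric(GenomicRanges::start(rr))[keep],
      ref = as.character(SummarizedExperiment::rowRanges(vcf)$REF)[keep],
      alt = vapply(as.list(rr$ALT), function(a) as.character(a)[1], "")[keep],
      gene = as.character(info$GENE)[keep],
      ref_reads = vapply(d, `[[`, 0L, 1L),
      alt_reads = vapply(d, `[[`, 0L, 2L),
      population_af = suppressWarnings(as.numeric(info$PAF))[keep],
      tier = as.character(info$TIER)[keep],
      lof = as.logical(info$LOF)[keep],
      pathogenic = as.logical(info$PATH)[keep],
      zygosity_call = "het"
    )
  }
  dplyr::bind_rows(rows)
}

#' Write a sequence-variant table (TSV)
#' @param variants variant tibble (see [read_variants()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path) {
  utils::write.table(as.data.frame(variants), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
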