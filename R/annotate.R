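#' Transcripts intersecting a candidate CNV
#'
#' Any overlap of at least one base counts; the result is the alphabetically
#' sorted, deduplicated list of overlapping transcript symbols (rendered "-"
#' in reports when empty, i.e. a gene-desert candidate).
#'
#' @param candidate single-row candidate tibble.
#' @param transcripts transcript tibble (see [read_transcript_annotation()]).
#' @return character vector of symbols.
#' @export
intersect_transcripts <- function(candidate, transcripts) {
  t <- transcripts[transcripts$chrom == candidate$chrom &
                     transcripts$start <= candidate$end &
                     transcripts$end >= candidate$start, , drop = FALSE]
  sort(unique(t$gene))
}

#' Flag symbols present in a candidate-gene list
#'
#' Case-insensitive intersection with a disease candidate-gene list (e.g. a
#' model-organism phenotype-support list), preserving the input order.
#' @param symbols character vector of gene symbols.
#' @param candidate_list character vector (uppercase) of candidate genes.
#' @return the subset of `symbols` on the list.
#' @export
flag_candidate_genes <- function(symbols, candidate_list) {
  symbols[toupper(symbols) %in% toupper(candidate_list)]
}

#' Overlap with known disease genes, with distances
#'
#' Checks a candidate against known disease-gene intervals (for Ebstein
#' anomaly: NKX2-5, GATA4, MYH7). For each gene, reports whether the
#' candidate overlaps it and, when it does not but lies on the same
#' chromosome, the gap distance in Mb (one decimal).
#'
#' @param candidate single-row candidate tibble.
#' @param known_genes tibble with `gene`, `chrom`, `start`, `end`.
#' @return tibble with `gene`, `overlaps` (logical) and `distance_mb`
#'   (NA when overlapping or on a different chromosome).
#' @export
flag_known_ea_genes <- function(candidate, known_genes) {
  res <- lapply(seq_len(nrow(known_genes)), function(i) {
    g <- known_genes[i, ]
    same_chrom <- g$chrom == candidate$chrom
    ov <- same_chrom && g$start <= candidate$end && g$end >= candidate$start
    dist <- NA_real_
    if (same_chrom && !ov) {
      gap <- max(g$start - candidate$end, candidate$start - g$end) - 1
      dist <- round_half_away(gap / 1e6, 1)
    }
    tibble::tibble(gene = g$gene, overlaps = ov, distance_mb = dist)
  })
  dplyr::bind_rows(res)
}

#' Annotate a candidate table
#'
#' Adds per-candidate transcript lists, candidate-gene hits and known-gene
#' overlap flags; never alters coordinates.
#' @param candidates candidate tibble.
#' @param transcripts transcript tibble.
#' @param candidate_list character vector of candidate-gene symbols.
#' @param known_genes known disease-gene tibble (may be NULL).
#' @return `candidates` with list-columns `transcripts`, `candidate_genes`
#'   and a `known_gene_overlap` list-column.
#' @export
annotate_candidates <- function(candidates, transcripts,
                                candidate_list = character(),
                                known_genes = NULL) {
  n <- nrow(candidates)
  tx <- vector("list", n)
  cg <- vector("list", n)
  kg <- vector("list", n)
  for (i in seq_len(n)) {
    tx[[i]] <- intersect_transcripts(candidates[i, ], transcripts)
    cg[[i]] <- flag_candidate_genes(tx[[i]], candidate_list)
    kg[[i]] <- if (is.null(known_genes)) {
      tibble::tibble(gene = character(), overlaps = logical(), distance_mb = numeric())
    } else {
      flag_known_ea_genes(candidates[i, ], known_genes)
    }
  }
  candidates$transcripts <- tx
  candidates$candidate_genes <- cg
  candidates$known_gene_overlap <- kg
  candidates
}
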