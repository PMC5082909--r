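#' Build the three enrichment query lists
#'
#' From annotated candidates, three gene lists are formed: (1) genes from all
#' candidate CNVs, (2) genes from deletions only, (3) genes from duplications
#' only. The known disease genes are appended to each list (carrying a
#' sentinel CNV id of 0), and each gene retains the ids of the CNVs
#' contributing it.
#'
#' @param candidates annotated candidate tibble (needs `cnv_id`, `cnv_type`,
#'   list-column `transcripts`).
#' @param known character vector of known disease genes (default MYH7, GATA4,
#'   NKX2-5).
#' @return named list of three tibbles (`all`, `deletions`, `duplications`),
#'   each with `gene` and list-column `cnv_ids`.
#' @export
build_query_lists <- function(candidates,
                              known = c("MYH7", "GATA4", "NKX2-5")) {
  gene_table <- function(rows) {
    genes <- list()
    for (i in rows) {
      for (g in toupper(candidates$transcripts[[i]])) {
        genes[[g]] <- unique(c(genes[[g]], candidates$cnv_id[i]))
      }
    }
    for (g in toupper(known)) genes[[g]] <- unique(c(genes[[g]], 0L))
    tibble::tibble(gene = names(genes), cnv_ids = unname(genes))
  }
  idx <- seq_len(nrow(candidates))
  list(
    all = gene_table(idx),
    deletions = gene_table(idx[candidates$cnv_type == "loss"]),
    duplications = gene_table(idx[candidates$cnv_type == "gain"])
  )
}

#' Hypergeometric over-representation test across a gene-set library
#'
#' For each set, the one-sided p-value that the query contains at least the
#' observed number of set members, under hypergeometric sampling from the
#' background universe (Fisher's exact test on the implied 2x2 table). Query
#' symbols outside the background are dropped with a warning. Benjamini-
#' Hochberg adjusted p-values are added per library.
#'
#' @param query tibble with `gene` and list-column `cnv_ids` (see
#'   [build_query_lists()]), or a plain character vector.
#' @param library named list of member-symbol vectors.
#' @param background symbol universe; defaults to the union of all library
#'   members.
#' @param source label recorded on each record (`all` / `deletions` /
#'   `duplications`).
#' @return tibble of enrichment records: `set`, `n_set`, `n_query`,
#'   `n_overlap`, `overlap_genes` (list), `cnv_ids` (list), `p_value`,
#'   `adjusted_p`, `source`.
#' @export
fisher_enrichment <- function(query, library, background = NULL, source = "all") {
  if (is.character(query)) {
    query <- tibble::tibble(gene = toupper(query),
                            cnv_ids = replicate(length(query), integer(), simplify = FALSE))
  }
  if (is.null(background)) background <- unique(toupper(unlist(library)))
  if (length(background) == 0) stop("fisher_enrichment: empty background", call. = FALSE)
  background <- unique(toupper(background))
  outside <- setdiff(query$gene, background)
  if (length(outside) > 0) {
    warning("fisher_enrichment: dropping ", length(outside),
            " query gene(s) outside the background universe")
    query <- query[query$gene %in% background, , drop = FALSE]
  }
  N <- length(background)
  n_query <- nrow(query)
  recs <- lapply(names(library), function(nm) {
    members <- intersect(unique(toupper(library[[nm]])), background)
    hit <- query$gene %in% members
    k <- sum(hit)
    p <- stats::phyper(k - 1, length(members), N - length(members), n_query,
                       lower.tail = FALSE)
    tibble::tibble(
      set = nm, n_set = length(members), n_query = n_query, n_overlap = k,
      overlap_genes = list(sort(query$gene[hit])),
      cnv_ids = list(sort(unique(unlist(query$cnv_ids[hit])))),
      p_value = min(p, 1), source = source
    )
  })
  out <- dplyr::bind_rows(recs)
  out$adjusted_p <- bh_adjust(out$p_value)
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard FDR step-up adjusted p-values (monotone in rank, capped at 1).
#' @param pvalues numeric vector in \[0, 1\].
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  stats::p.adjust(pvalues, method = "BH")
}

#' Apply the study's enrichment exclusion rules
#'
#' Drops records that: (1) have adjusted p at or above `alpha`; (2) overlap
#' only the known disease genes; (3) draw all their overlap genes from a
#' single CNV (known-gene sentinels count as one extra pseudo-source when a
#' known gene is in the overlap, configurable); and (4) come from the
#' deletion- or duplication-only lists when the same set survives in the
#' all-CNVs list (redundancy rule). The result is always a subset of the
#' input and independent of rule order.
#'
#' @param records enrichment tibble (possibly several sources bound together).
#' @param known character vector of known disease genes.
#' @param alpha adjusted-p ceiling (default 0.05).
#' @param sentinel_counts whether a known gene in the overlap contributes a
#'   pseudo-CNV to the single-CNV rule.
#' @return the surviving records.
#' @export
apply_exclusion_rules <- function(records, known = c("MYH7", "GATA4", "NKX2-5"),
                                  alpha = 0.05, sentinel_counts = TRUE) {
  if (nrow(records) == 0) return(records)
  known <- toupper(known)
  keep_core <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    if (r$adjusted_p >= alpha) return(FALSE)
    genes <- r$overlap_genes[[1]]
    if (length(genes) == 0) return(FALSE)
    if (all(genes %in% known)) return(FALSE)
    real_ids <- setdiff(r$cnv_ids[[1]], 0L)
    n_sources <- length(unique(real_ids)) +
      (sentinel_counts && any(genes %in% known))
    if (n_sources <= 1) return(FALSE)
    TRUE
  }, TRUE)
  surv <- records[keep_core, , drop = FALSE]
  in_all <- surv$set[surv$source == "all"]
  drop_redundant <- surv$source %in% c("deletions", "duplications") &
    surv$set %in% in_all
  surv[!drop_redundant, , drop = FALSE]
}

#' Overlap coefficient between two gene sets
#'
#' `|A intersect B| / min(|A|, |B|)`, the similarity used for enrichment-map
#' edges.
#' @param a,b non-empty character vectors.
#' @return fraction in \[0, 1\].
#' @export
overlap_coefficient <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    stop("overlap_coefficient: empty set", call. = FALSE)
  }
  a <- unique(toupper(a))
  b <- unique(toupper(b))
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Build the enrichment map
#'
#' Nodes are the surviving gene sets; an edge joins two sets whose member
#' lists have overlap coefficient at or above `cutoff` (inclusive, default
#' 0.5), weighted by the coefficient. Connected components are labeled by
#' their alphabetically smallest member set, so the clustering is independent
#' of record order.
#'
#' @param records filtered enrichment tibble.
#' @param library the gene-set library (for member lists).
#' @param cutoff overlap-coefficient edge threshold.
#' @return list with `nodes` (set, source, adjusted_p, component, label),
#'   `edges` (from, to, weight) and `components` (label, size).
#' @export
build_enrichment_map <- function(records, library, cutoff = 0.5) {
  sets <- sort(unique(records$set))
  nodes <- records[!duplicated(records$set), , drop = FALSE]
  nodes <- nodes[order(nodes$set), c("set", "source", "adjusted_p")]
  n <- length(sets)
  edges <- tibble::tibble(from = character(), to = character(), weight = numeric())
  if (n >= 2) {
    pairs <- utils::combn(sets, 2)
    w <- apply(pairs, 2, function(p) {
      overlap_coefficient(library[[p[1]]], library[[p[2]]])
    })
    keep <- w >= cutoff
    edges <- tibble::tibble(from = pairs[1, keep], to = pairs[2, keep],
                            weight = w[keep])
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = sets)
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, rbind(match(edges$from, sets), match(edges$to, sets)))
  }
  comp <- igraph::components(g)$membership
  label_of <- vapply(split(sets, comp), min, "")
  nodes$component <- unname(comp[match(nodes$set, sets)])
  nodes$label <- unname(label_of[as.character(nodes$component)])
  comps <- tibble::tibble(
    label = unname(label_of),
    size = as.integer(table(comp)[names(label_of)])
  )
  comps <- comps[order(-comps$size, comps$label), ]
  list(nodes = nodes, edges = edges, components = comps)
}
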