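mk_candidates <- function() {
  t <- tibble::tibble(
    cnv_id = c(1L, 2L, 3L),
    cnv_type = c("loss", "gain", "loss"),
    transcripts = list(c("A1", "A2"), c("B1"), c("A2", "C1")))
  t
}

test_that("query lists split by CNV type and always carry the known genes", {
  empty <- tibble::tibble(cnv_id = integer(), cnv_type = character(),
                          transcripts = list())
  q0 <- build_query_lists(empty)
  expect_setequal(q0$all$gene, c("MYH7", "GATA4", "NKX2-5"))
  expect_setequal(q0$deletions$gene, c("MYH7", "GATA4", "NKX2-5"))

  q <- build_query_lists(mk_candidates())
  # deletion-only gene in lists 1 and 2 only
  expect_true("A1" %in% q$all$gene)
  expect_true("A1" %in% q$deletions$gene)
  expect_false("A1" %in% q$duplications$gene)
  # gene hit by CNVs 1 and 3 carries both ids in the all list
  expect_setequal(q$all$cnv_ids[q$all$gene == "A2"][[1]], c(1L, 3L))
  # known genes carry the sentinel id
  expect_equal(q$all$cnv_ids[q$all$gene == "MYH7"][[1]], 0L)
})

test_that("hypergeometric enrichment matches trivial and derived cases", {
  lib <- list(s = paste0("g", 1:5))
  bg <- paste0("g", 1:20)
  # disjoint query
  r <- fisher_enrichment(paste0("g", 6:10), lib, background = bg)
  expect_equal(r$p_value, 1.0)
  # query = set = background
  r2 <- fisher_enrichment(paste0("g", 1:3), list(s = paste0("g", 1:3)),
                          background = paste0("g", 1:3))
  expect_equal(r2$p_value, 1.0)
  # background 20, set 5, query 5, overlap 4: exhaustive tail = 76/15504
  r3 <- fisher_enrichment(c(paste0("g", 1:4), "g10"), lib, background = bg)
  expect_equal(r3$n_overlap, 4L)
  expect_equal(r3$p_value, enum_hyper_tail(20, 5, 5, 4))
  expect_equal(r3$p_value, 76 / 15504)
  expect_error(fisher_enrichment("g1", lib, background = character()), "empty background")
  expect_warning(fisher_enrichment(c("g1", "zzz"), lib, background = bg),
                 "outside the background")
})

test_that("enrichment p-values match exhaustive enumeration on small universes", {
  set.seed(23)
  for (rep in 1:100) {
    N <- sample(5:25, 1)
    bg <- paste0("g", seq_len(N))
    K <- sample.int(N, 1)
    n <- sample.int(N, 1)
    lib <- list(s = sample(bg, K))
    query <- sample(bg, n)
    r <- fisher_enrichment(query, lib, background = bg)
    k <- length(intersect(query, lib$s))
    expect_equal(r$p_value, enum_hyper_tail(N, K, n, k), tolerance = 1e-12)
  }
})

test_that("BH adjustment matches the step-up reference and is monotone", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.2, 0.2, 0.2)), c(0.2, 0.2, 0.2))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.9)), c(0.03, 0.03, 0.9))
  set.seed(77)
  for (rep in 1:50) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, manual_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-12))
    # same rejection set as the raw step-up procedure at alpha = 0.05
    m <- length(p); o <- order(p)
    kmax <- suppressWarnings(max(which(p[o] <= 0.05 * seq_len(m) / m)))
    stepup_reject <- if (is.finite(kmax)) o[seq_len(kmax)] else integer()
    expect_setequal(which(adj <= 0.05), stepup_reject)
  }
})

mk_records <- function() {
  tibble::tibble(
    set = c("sig_multi", "sig_knownonly", "sig_onecnv", "nonsig", "sig_multi"),
    n_set = 5L, n_query = 5L, n_overlap = 2L,
    overlap_genes = list(c("A1", "B1"), c("MYH7", "GATA4"), c("A1", "A2"),
                         c("A1", "B1"), c("A1", "B1")),
    cnv_ids = list(c(1L, 2L), 0L, 1L, c(1L, 2L), c(1L, 2L)),
    p_value = c(0.001, 0.001, 0.001, 0.5, 0.001),
    adjusted_p = c(0.01, 0.01, 0.01, 0.6, 0.01),
    source = c("all", "all", "all", "all", "deletions"))
}

test_that("exclusion rules drop each published category and commute", {
  recs <- mk_records()
  out <- apply_exclusion_rules(recs)
  expect_equal(out$set[out$source == "all"], "sig_multi")
  # adjusted p >= 0.05 dropped
  expect_false("nonsig" %in% out$set)
  # known-genes-only overlap dropped
  expect_false("sig_knownonly" %in% out$set)
  # single-CNV overlap dropped
  expect_false("sig_onecnv" %in% out$set)
  # deletion-list record dropped because the set survives in the all list
  expect_false(any(out$source == "deletions"))
  # output is a subset of the input and permutation-invariant
  expect_true(all(out$set %in% recs$set))
  perm <- apply_exclusion_rules(recs[c(5, 3, 1, 4, 2), ])
  expect_setequal(paste(perm$set, perm$source), paste(out$set, out$source))
  # a known gene in the overlap counts as a pseudo-source by default
  mixed <- recs[3, ]
  mixed$overlap_genes <- list(c("MYH7", "A1"))
  mixed$cnv_ids <- list(c(0L, 1L))
  expect_equal(nrow(apply_exclusion_rules(mixed)), 1L)
  expect_equal(nrow(apply_exclusion_rules(mixed, sentinel_counts = FALSE)), 0L)
})

test_that("overlap coefficient uses the smaller set as denominator", {
  expect_equal(overlap_coefficient(c("a", "b"), c("a", "b")), 1.0)
  expect_equal(overlap_coefficient(c("a", "b"), c("c", "d")), 0.0)
  expect_equal(overlap_coefficient(c("a", "b", "c", "d"),
                                   c(letters[1:2], paste0("z", 1:8))), 0.5)
  expect_error(overlap_coefficient(character(), "a"), "empty set")
})

test_that("the enrichment map clusters sets at the inclusive 0.5 cutoff", {
  lib <- list(
    a = paste0("g", 1:4), b = paste0("g", 3:6), c = paste0("g", 5:8),
    d = paste0("x", 1:4),
    e = c("g1", "g2", "y1", "y2"))   # coefficient with a exactly 0.5
  recs <- tibble::tibble(
    set = c("a", "b", "c", "d", "e"), n_set = 4L, n_query = 4L, n_overlap = 2L,
    overlap_genes = list("g1", "g3", "g5", "x1", "y1"),
    cnv_ids = list(c(1L, 2L), c(1L, 2L), c(1L, 2L), c(1L, 2L), c(1L, 2L)),
    p_value = 0.001, adjusted_p = 0.01, source = "all")
  map <- build_enrichment_map(recs, lib)
  # a-b and b-c edges connect transitively; e attaches to a at exactly 0.5
  comp_of <- function(s) map$nodes$component[map$nodes$set == s]
  expect_equal(comp_of("a"), comp_of("b"))
  expect_equal(comp_of("b"), comp_of("c"))
  expect_equal(comp_of("a"), comp_of("e"))
  expect_false(comp_of("d") == comp_of("a"))
  expect_true(any((map$edges$from == "a" & map$edges$to == "e") |
                    (map$edges$from == "e" & map$edges$to == "a")))
  # component labels use the smallest member name
  expect_equal(map$nodes$label[map$nodes$set == "c"], "a")
  # order invariance of component count and edges
  map2 <- build_enrichment_map(recs[c(4, 2, 5, 1, 3), ], lib)
  expect_equal(nrow(map2$components), nrow(map$components))
  expect_equal(nrow(map2$edges), nrow(map$edges))
  # no edges: all singletons
  map3 <- build_enrichment_map(recs[c(1, 4), ], lib)
  expect_equal(nrow(map3$edges), 0L)
  expect_equal(nrow(map3$components), 2L)
})
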