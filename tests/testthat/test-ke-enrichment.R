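test_that("a clique KE on a sparse background is enriched with ratio < 1", {
  # KE genes form a 5-clique; the rest of the graph is a long path, so the
  # network-wide average pairwise distance exceeds 1.
  clique <- igraph::make_full_graph(5)
  path <- igraph::make_ring(15, circular = FALSE)
  g <- igraph::disjoint_union(clique, path)
  g <- igraph::add_edges(g, c(5, 6))  # connect so paths exist across
  igraph::V(g)$name <- sprintf("g%02d", 1:20)
  net <- as_coexnet(g)
  aop <- tiny_aop(annotation = list(KE1 = sprintf("g%02d", 1:5)))
  enr <- topological_enrichment(net, aop, n_draws = 200, seed = 5)
  expect_equal(enr$event_id, "KE1")
  expect_equal(enr$mean_sp_ke, 1)            # clique: all pairwise distances 1
  expect_lt(enr$ratio, 1)
  expect_true(enr$enriched_raw)
  expect_true(enr$enriched)
})

test_that("enrichment is a function of the gene set only and deterministic under seed", {
  withr::with_seed(21, {
    g <- igraph::sample_gnp(40, 0.12)
    igraph::V(g)$name <- sprintf("g%02d", 1:40)
  })
  net <- as_coexnet(g)
  gs <- sprintf("g%02d", c(3, 7, 11, 19, 23))
  aop <- tiny_aop(annotation = list(KE1 = gs),
                  extra_events = data.frame(event_id = "KE2", event_type = "KE"))
  aop$annotation$KE2 <- gs  # identical gene set under a different id
  e1 <- topological_enrichment(net, aop, n_draws = 50, seed = 9)
  expect_equal(e1$ratio[1], e1$ratio[2])
  expect_equal(e1$p_avg[1], e1$p_avg[2])

  e2 <- topological_enrichment(net, aop, n_draws = 50, seed = 9)
  e1$genes <- e2$genes <- NULL
  attr(e1, "skipped") <- attr(e2, "skipped") <- NULL
  expect_identical(e1, e2)

  # n_draws = 2 twice with the same seed: still identical (seed contract)
  e3 <- topological_enrichment(net, aop, n_draws = 2, seed = 4)
  e4 <- topological_enrichment(net, aop, n_draws = 2, seed = 4)
  expect_equal(e3$p_avg, e4$p_avg)
})

test_that("KEs with too few connected genes are skipped with reasons", {
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(c("a", "b", "c")) + igraph::edges(c("a", "b"))  # c isolated
  net <- as_coexnet(g)
  aop <- tiny_aop(annotation = list(KE1 = c("a", "c")),
                  extra_events = data.frame(event_id = "KE2", event_type = "KE"))
  aop$annotation$KE2 <- c("a", "zzz")  # only one gene in the network
  enr <- topological_enrichment(net, aop, n_draws = 5, seed = 1)
  skipped <- attr(enr, "skipped")
  expect_setequal(skipped$event_id, c("KE1", "KE2"))
  expect_match(skipped$reason[skipped$event_id == "KE1"], "connected")
  expect_match(skipped$reason[skipped$event_id == "KE2"], "<2 annotated")
})

test_that("fisher_enrichment equals the hypergeometric enumeration oracle", {
  bg <- sprintf("b%03d", 1:100)
  ke_genes <- bg[1:5]
  aop <- tiny_aop(annotation = list(KE1 = ke_genes))

  # DEG set equal to the KE set: p = 1/choose(100, 5), the minimum attainable
  res <- fisher_enrichment(ke_genes, aop, bg, event_types = "KE")
  expect_equal(res$p, 1 / choose(100, 5), tolerance = 1e-12)
  expect_equal(res$overlap, 5)

  # zero overlap with |DEG| = 5: depletion side, p >= 0.5
  res0 <- fisher_enrichment(bg[6:10], aop, bg, event_types = "KE")
  expect_equal(res0$overlap, 0)
  expect_gte(res0$p, 0.5)

  # DEG = background: saturated margin, p = 1
  res1 <- fisher_enrichment(bg, aop, bg, event_types = "KE")
  expect_equal(res1$p, 1)

  # brute-force enumeration oracle over random configurations
  withr::with_seed(22, {
    for (i in 1:10) {
      nb <- sample(20:60, 1)
      bgi <- sprintf("x%03d", seq_len(nb))
      ke <- sample(bgi, sample(3:8, 1))
      deg <- sample(bgi, sample(3:10, 1))
      aopi <- tiny_aop(annotation = list(KE1 = ke))
      got <- fisher_enrichment(deg, aopi, bgi, event_types = "KE")$p
      ov <- length(intersect(deg, ke))
      # enumerate P(X >= ov) for X ~ Hypergeom(|KE|, nb - |KE|, |DEG|)
      want <- sum(dhyper(ov:min(length(ke), length(deg)), length(ke),
                         nb - length(ke), length(deg)))
      expect_equal(got, want, tolerance = 1e-10)
    }
  })

  expect_error(fisher_enrichment(ke_genes, aop, character(0)), "nonempty")
  expect_error(fisher_enrichment("not_in_bg", aop, bg), "subset")
})

test_that("filter_enriched applies the three stages in order", {
  mk_records <- function(n, p_avg, n_ann = 50, ratio = 0.8, p_adj = NULL) {
    out <- data.frame(event_id = sprintf("KE%02d", seq_len(n)),
                      n_genes_annotated = n_ann, ratio = ratio,
                      p_avg = p_avg,
                      p_adj = p_adj %||% p.adjust(p_avg, "BH"),
                      stringsAsFactors = FALSE)
    out$genes <- replicate(n, c("g1", "g2"), simplify = FALSE)
    out
  }
  contrast <- data.frame(gene = c("g1", "g2"), logFC = c(1.2, 0.1),
                         p = c(0.001, 0.5))

  # stage 1: the 1000-gene cap drops regardless of p
  rec <- mk_records(2, c(1e-6, 1e-6))
  rec$n_genes_annotated[1] <- 1001
  out <- filter_enriched(rec, contrast)
  expect_equal(out$event_id, "KE02")

  # stage 2 percentile: 40 survivors with distinct p_avg -> 2 survive
  rec40 <- mk_records(40, seq(1e-6, 1e-3, length.out = 40), p_adj = 1e-4)
  out40 <- filter_enriched(rec40, contrast)
  expect_equal(nrow(out40), 2)
  expect_equal(out40$event_id, c("KE01", "KE02"))

  # a singleton survivor passes its own percentile (inclusive cut)
  out1 <- filter_enriched(mk_records(1, 1e-4, p_adj = 1e-4), contrast)
  expect_equal(nrow(out1), 1)

  # stage 3: all annotated genes below the fold-change bar -> dropped
  rec3 <- mk_records(1, 1e-4, p_adj = 1e-4)
  rec3$genes <- list(c("g2"))
  out3 <- filter_enriched(rec3, contrast)
  expect_equal(nrow(out3), 0)
  expect_equal(unname(attr(out3, "stages")["logfc"]), 0)

  # ratio >= 1 never survives stage 1
  rec4 <- mk_records(1, 1e-4, ratio = 1.2, p_adj = 1e-4)
  expect_equal(nrow(filter_enriched(rec4, contrast)), 0)
})
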