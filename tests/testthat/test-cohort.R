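test_that("edge_distance_matrix matches per-measure brute force on hand-built networks", {
  n1 <- net_from_keys(c("a|b", "b|c", "c|d"), "n1")
  n2 <- net_from_keys(c("a|b", "b|c", "d|e"), "n2")
  n3 <- net_from_keys(c("x|y", "y|z"), "n3")
  dm <- edge_distance_matrix(list(n1, n2, n3))

  # brute-force oracle on the raw (pre-normalization) component values
  keys <- list(c("a|b", "b|c", "c|d"), c("a|b", "b|c", "d|e"), c("x|y", "y|z"))
  universe <- unique(unlist(keys))
  jac <- function(x, y) length(intersect(x, y)) / length(union(x, y))
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(dm$raw_components$jaccard_sim[i, j], 1 - jac(keys[[i]], keys[[j]]))
    iv <- universe %in% keys[[i]]; jv <- universe %in% keys[[j]]
    expect_equal(dm$raw_components$hamming[i, j], mean(iv != jv))
    expect_equal(dm$raw_components$smc[i, j], 1 - mean(iv == jv))
  }
  # edge-disjoint pair: jaccard distance exactly 1
  expect_equal(dm$raw_components$jaccard_dist[1, 3], 1)
  # kendall needs >= 3 common edges; here at most 2 -> component missing
  expect_true(all(is.na(dm$raw_components$kendall[upper.tri(diag(3))])))

  # premetric structure: symmetric, zero diagonal, nonnegative
  expect_equal(dm$matrix, t(dm$matrix))
  expect_equal(unname(diag(dm$matrix)), rep(0, 3))
  expect_true(all(dm$matrix >= 0))

  # identical networks sit at consensus distance 0
  dm2 <- edge_distance_matrix(list(n1, net_from_keys(c("a|b", "b|c", "c|d"), "n1b"), n3))
  expect_equal(dm2$matrix["n1", "n1b"], 0)

  expect_error(edge_distance_matrix(list(n1)), ">= 2 networks")
})

test_that("kendall component uses betweenness ranks of common edges", {
  # two identical 5-node paths: tau = 1 -> kendall distance 0
  p1 <- net_from_keys(c("a|b", "b|c", "c|d", "d|e"), "p1")
  p2 <- net_from_keys(c("a|b", "b|c", "c|d", "d|e"), "p2")
  st <- net_from_keys(c("a|b", "a|c", "a|d", "a|e"), "star")
  dm <- edge_distance_matrix(list(p1, p2, st))
  expect_equal(dm$raw_components$kendall["p1", "p2"], 0)
})

test_that("consensus_cluster recovers separated blobs and is deterministic", {
  n <- 8
  ids <- sprintf("s%d", 1:n)
  m <- matrix(0.9, n, n, dimnames = list(ids, ids))
  m[1:4, 1:4] <- 0.05
  m[5:8, 5:8] <- 0.05
  diag(m) <- 0
  dm <- structure(list(ids = ids, matrix = m, components = list()),
                  class = "network_distance_matrix")
  cl <- consensus_cluster(dm, k = 2)
  expect_equal(length(unique(cl$labels[1:4])), 1)
  expect_equal(length(unique(cl$labels[5:8])), 1)
  expect_false(cl$labels[1] == cl$labels[5])

  cl2 <- consensus_cluster(dm, k = 2)
  expect_identical(cl$labels, cl2$labels)

  # k = n gives singletons; k > n errors
  expect_equal(length(unique(consensus_cluster(dm, k = n)$labels)), n)
  expect_error(consensus_cluster(dm, k = n + 1), "exceeds")
})

test_that("cluster_moa_networks separates families and handles duplicates", {
  ids <- sprintf("K%d", 1:10)
  ev <- data.frame(event_id = ids, event_type = "KE")
  li <- data.frame(upstream_event_id = ids[-10], downstream_event_id = ids[-1])
  aop <- aop_network(ev, li, list(K1 = "g"))
  fam_a <- lapply(1:3, function(i)
    moa_from_ids(aop, c("K1", "K2", "K3", ids[6 + i]), exposure_id = paste0("a", i)))
  fam_b <- lapply(1:3, function(i)
    moa_from_ids(aop, c("K4", "K5", "K6", ids[6 + i]), exposure_id = paste0("b", i)))
  res <- cluster_moa_networks(c(fam_a, fam_b), k = 2)
  lab <- res$labels
  expect_equal(length(unique(lab[1:3])), 1)
  expect_equal(length(unique(lab[4:6])), 1)
  expect_false(lab[1] == lab[4])
  expect_match(res$newick, "^\\(")

  # duplicated MOA: distance 0, merged first (height 0)
  dup <- cluster_moa_networks(list(fam_a[[1]], fam_a[[1]], fam_b[[1]]))
  expect_equal(min(dup$hclust$height), 0)
  expect_equal(dup$distance[1, 2], 0)

  # all identical -> every merge at height 0
  same <- cluster_moa_networks(list(fam_a[[1]], fam_a[[1]], fam_a[[1]]))
  expect_true(all(same$hclust$height == 0))

  expect_error(cluster_moa_networks(fam_a[1]), ">= 2 MOA networks")
})

test_that("overrepresented_edges equals the hypergeometric pmf enumeration", {
  # spec example: edge in 3/3 cluster nets, 3/10 total, cluster_size 4
  nets <- c(lapply(1:3, function(i) net_from_keys(c("a|b", "x|y"), paste0("c", i))),
            lapply(1:6, function(i) net_from_keys("x|y", paste0("o", i))),
            list(net_from_keys(c("x|y", "q|r"), "o7")))
  cl <- c("c1", "c2", "c3", "o1")
  res <- overrepresented_edges(nets, cl, keep_all = TRUE)
  p_ab <- res$p[res$edge == "a|b"]
  expect_equal(p_ab, choose(3, 3) * choose(7, 1) / choose(10, 4),
               tolerance = 1e-12)  # = 1/30
  # edge present in every network: saturated margin, p = 1
  expect_equal(res$p[res$edge == "x|y"], 1)
  # edge absent from the cluster is not tested
  expect_false("q|r" %in% res$edge)

  expect_error(overrepresented_edges(nets, vapply(nets, function(n) n$exposure_id, "")),
               "full collection")
  expect_error(overrepresented_edges(nets, "nope"), "subset")
})

test_that("overrepresentation matches exhaustive enumeration for <= 12 networks", {
  # all (total, cluster_size, in_total, in_cluster) configurations realizable
  # with <= 12 networks, checked against the summed hypergeometric pmf
  for (total in c(4, 8, 12)) {
    for (csize in c(2, total %/% 2)) {
      for (in_total in 1:total) {
        for (in_cl in seq_len(min(csize, in_total))) {
          if (in_total - in_cl > total - csize) next
          ids <- sprintf("n%02d", seq_len(total))
          cl_ids <- ids[seq_len(csize)]
          with_edge <- c(cl_ids[seq_len(in_cl)],
                         setdiff(ids, cl_ids)[seq_len(in_total - in_cl)])
          nets <- lapply(ids, function(i)
            net_from_keys(if (i %in% with_edge) c("a|b", "z|w") else "z|w", i))
          got <- overrepresented_edges(nets, cl_ids, keep_all = TRUE)
          p_got <- got$p[got$edge == "a|b"]
          kmax <- min(csize, in_total)
          p_want <- sum(dhyper(in_cl:kmax, in_total, total - in_total, csize))
          expect_equal(p_got, p_want, tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("edge_set_enrichment scores and permutation p behave as specified", {
  # every ranked edge a hit -> es = 1 (and the permutation null is then
  # degenerate: every shuffle reproduces the all-hit pattern, so p = 1)
  edges <- data.frame(gene_a = c("a", "b", "c"), gene_b = c("b", "c", "a"),
                      p = c(1e-5, 1e-4, 1e-3))
  res <- edge_set_enrichment(edges, list(P = c("a", "b", "c")), n_perm = 50,
                             seed = 1)
  expect_equal(res$es, 1)
  expect_equal(res$p_perm, 1)

  # permutation p hits its 1/(n_perm + 1) floor when the observed score
  # beats every shuffle: strongly weighted hits packed at the top of a
  # long ranked list
  top <- data.frame(gene_a = c(rep("h", 3), sprintf("m%02d", 1:40)),
                    gene_b = c(paste0("k", 1:3), sprintf("n%02d", 1:40)),
                    p = c(rep(1e-12, 3), seq(0.5, 0.99, length.out = 40)))
  res_top <- edge_set_enrichment(top, list(P = c("h", paste0("k", 1:3))),
                                 n_perm = 50, seed = 2)
  expect_equal(res_top$p_perm, 1 / 51)

  # pathway with < 2 genes is skipped; no hits -> p 1
  res2 <- edge_set_enrichment(edges, list(tiny = "a", off = c("q", "r")),
                              n_perm = 30, seed = 1)
  expect_setequal(res2$set_name, "off")
  expect_equal(res2$p_perm, 1)
  expect_warning(edge_set_enrichment(edges, list(P = c("a", "b")), n_perm = 5,
                                     seed = 1), "coarse")
})

test_that("combine_edge_pvalues implements Fisher's sumlog method", {
  expect_equal(combine_edge_pvalues(c(1, 1)), 1)
  # chi-square tail oracle: X = -4 log 0.5 = 2.7726, df 4
  expect_equal(combine_edge_pvalues(c(0.5, 0.5)), 0.5966, tolerance = 1e-4)
  expect_equal(combine_edge_pvalues(c(0.5, 0.5)),
               pchisq(-2 * sum(log(c(0.5, 0.5))), 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(combine_edge_pvalues(0.1234), 0.1234, tolerance = 1e-12)
  expect_warning(p0 <- combine_edge_pvalues(c(0, 0.5)), "clamped")
  expect_gt(p0, 0)
  expect_error(combine_edge_pvalues(numeric(0)), "nonempty")
})

test_that("GMT round-trip preserves gene sets", {
  dir <- withr::local_tempdir()
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g9", "g2"))
  write_gmt(sets, file.path(dir, "s.gmt"))
  back <- read_gmt(file.path(dir, "s.gmt"))
  expect_equal(back, sets)
})
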