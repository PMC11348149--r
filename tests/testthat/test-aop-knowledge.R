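test_that("aop_network construction validates and queries as specified", {
  net <- tiny_aop(annotation = list(KE1 = c("g1", "g2")))
  expect_equal(nrow(net$events), 3)
  expect_equal(igraph::ecount(net$graph), 2)
  expect_setequal(net$annotation$KE1, c("g1", "g2"))
  expect_equal(net$annotation$MIE1, character(0))

  # link endpoints must exist / be typed
  expect_error(
    aop_network(data.frame(event_id = "KE1", event_type = "KE"),
                data.frame(upstream_event_id = "KE1",
                           downstream_event_id = "AO9")),
    "AO9")
  expect_error(
    aop_network(data.frame(event_id = c("a", "b"),
                           event_type = c("KE", "banana")),
                data.frame(upstream_event_id = "a",
                           downstream_event_id = "b")),
    "invalid event_type")
})

test_that("load_aop_network round-trips files, dedups links, keeps isolated events", {
  dir <- withr::local_tempdir()
  edge <- data.frame(upstream_event_id = c("MIE1", "KE1", "KE1"),
                     downstream_event_id = c("KE1", "AO1", "AO1"),
                     upstream_type = c("MIE", "KE", "KE"),
                     downstream_type = c("KE", "AO", "AO"))
  ann <- data.frame(event_id = c("KE1", "KE1", "KE9"),
                    gene = c("g1", "g2", "g7"))
  write_tsv_prov(edge, file.path(dir, "e.tsv"))
  write_tsv_prov(ann, file.path(dir, "a.tsv"))
  net <- load_aop_network(file.path(dir, "e.tsv"), file.path(dir, "a.tsv"))
  expect_equal(igraph::ecount(net$graph), 2)  # duplicated KE1->AO1 collapsed
  expect_equal(nrow(net$events), 4)           # KE9 retained as isolated node
  expect_equal(net$events$event_type[net$events$event_id == "KE9"], "KE")
  expect_setequal(net$annotation$KE1, c("g1", "g2"))

  # determinism: loading twice gives identical networks
  net2 <- load_aop_network(file.path(dir, "e.tsv"), file.path(dir, "a.tsv"))
  expect_identical(net$events, net2$events)
  expect_identical(net$annotation, net2$annotation)
  expect_identical(igraph::as_data_frame(net$graph, "edges"),
                   igraph::as_data_frame(net2$graph, "edges"))

  # missing required columns is a format error
  write_tsv_prov(edge[, 1:2], file.path(dir, "bad.tsv"))
  expect_error(load_aop_network(file.path(dir, "bad.tsv")), "missing required")
})

test_that("merge_redundant_kes follows single-linkage over the Jaccard threshold graph", {
  mk <- function(ann) {
    ev <- data.frame(event_id = names(ann),
                     event_type = rep("KE", length(ann)))
    aop_network(ev, data.frame(upstream_event_id = character(0),
                               downstream_event_id = character(0)), ann)
  }
  # identical sets at threshold 1 merge
  res <- merge_redundant_kes(mk(list(KEa = c("g1", "g2"), KEb = c("g1", "g2"))), 1.0)
  expect_equal(nrow(res$clusters), 1)
  expect_equal(res$clusters$n_genes, 2)
  expect_equal(unname(res$mapping["KEa"]), unname(res$mapping["KEb"]))

  # Jaccard 2/4 = 0.5 below threshold 0.6: no merge
  res <- merge_redundant_kes(mk(list(KEa = c("g1", "g2", "g3"),
                                     KEb = c("g2", "g3", "g4"))), 0.6)
  expect_equal(nrow(res$clusters), 0)

  # chain a~b, b~c above 0.8, a~c below: single linkage merges all three.
  # Oracle: brute-force connected components of the 3-node threshold graph.
  sets <- list(KEa = paste0("g", 1:10),
               KEb = paste0("g", 2:10),          # J(a,b) = 9/10
               KEc = paste0("g", 3:11))          # J(b,c) = 8/10, J(a,c) = 8/12
  jac <- function(x, y) length(intersect(x, y)) / length(union(x, y))
  adj <- outer(seq_along(sets), seq_along(sets),
               Vectorize(function(i, j) i != j && jac(sets[[i]], sets[[j]]) >= 0.8))
  comp_oracle <- igraph::components(
    igraph::graph_from_adjacency_matrix(adj, mode = "undirected"))$no
  expect_equal(comp_oracle, 1)  # forced arithmetic: one component
  res <- merge_redundant_kes(mk(sets), 0.8)
  expect_equal(nrow(res$clusters), 1)
  expect_equal(res$clusters$n_members, 3)
  expect_setequal(strsplit(res$clusters$member_event_ids, ",")[[1]],
                  c("KEa", "KEb", "KEc"))
  expect_equal(res$clusters$n_genes, length(Reduce(union, sets)))

  # invalid threshold
  expect_error(merge_redundant_kes(mk(sets), 1.5), "jaccard_threshold")
})

test_that("merged events inherit incident links and merging is idempotent", {
  ev <- data.frame(event_id = c("MIE1", "KEa", "KEb", "AO1"),
                   event_type = c("MIE", "KE", "KE", "AO"))
  links <- data.frame(upstream_event_id = c("MIE1", "KEb"),
                      downstream_event_id = c("KEa", "AO1"))
  net <- aop_network(ev, links, list(KEa = c("g1", "g2"), KEb = c("g1", "g2")))
  res <- merge_redundant_kes(net, 0.9)
  merged <- res$clusters$merged_event_id
  el <- igraph::as_data_frame(res$network$graph, "edges")
  expect_setequal(paste(el$from, el$to),
                  c(paste("MIE1", merged), paste(merged, "AO1")))

  res2 <- merge_redundant_kes(res$network, 0.9)
  expect_equal(nrow(res2$clusters), 0)
  expect_identical(res2$network$events, res$network$events)

  # threshold above the maximum observed Jaccard leaves the network unchanged
  res3 <- merge_redundant_kes(net, 1.0)  # sets identical here, J = 1, so use >1-J case below
  expect_equal(nrow(res3$clusters), 1)
  net2 <- aop_network(ev, links, list(KEa = c("g1", "g2"), KEb = c("g2", "g3")))
  res4 <- merge_redundant_kes(net2, 0.9)  # max J = 1/3
  expect_equal(nrow(res4$clusters), 0)
  expect_identical(res4$network$events, net2$events)
})

test_that("merge is idempotent on random annotations (property)", {
  withr::with_seed(42, {
    for (rep in 1:5) {
      n_ev <- 8
      ann <- lapply(seq_len(n_ev), function(i)
        sample(paste0("g", 1:15), sample(3:8, 1)))
      names(ann) <- paste0("KE", seq_len(n_ev))
      ev <- data.frame(event_id = names(ann), event_type = "KE")
      net <- aop_network(ev, data.frame(upstream_event_id = character(0),
                                        downstream_event_id = character(0)), ann)
      r1 <- merge_redundant_kes(net, 0.5)
      r2 <- merge_redundant_kes(r1$network, 0.5)
      expect_equal(nrow(r2$clusters), 0)
    }
  })
})

test_that("event_distance is the undirected min distance with Inf when unreachable", {
  net <- tiny_aop(extra_events = data.frame(event_id = "KE9", event_type = "KE"))
  expect_equal(event_distance(net, "MIE1", "AO1"), 2)
  expect_equal(event_distance(net, "KE1", "KE1"), 0)
  expect_equal(event_distance(net, "AO1", "MIE1"), 2)  # against link direction
  expect_equal(event_distance(net, "KE9", c("MIE1", "AO1")), Inf)
  expect_equal(event_distance(net, "MIE1", c("KE1", "AO1")), 1)
  expect_error(event_distance(net, "nope", "AO1"), "unknown event")

  # symmetry + triangle inequality on the connected triple
  ids <- c("MIE1", "KE1", "AO1")
  d <- outer(ids, ids, Vectorize(function(a, b) event_distance(net, a, b)))
  expect_equal(d, t(d))
  for (i in 1:3) for (j in 1:3) for (k in 1:3)
    expect_lte(d[i, j], d[i, k] + d[k, j])
})
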