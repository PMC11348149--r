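net_edge_keys <- function(net) {
  ed <- if (inherits(net, "coexpression_network"))
    net$edges[, c("gene_a", "gene_b")]
  else igraph::as_data_frame(moa_graph(net), what = "edges")[, 1:2]
  unique(edge_key(ed[[1]], ed[[2]]))
}

net_id <- function(net, fallback) {
  (if (inherits(net, "coexpression_network")) net$exposure_id
   else if (inherits(net, "moa_network")) net$exposure_id else NULL) %||% fallback
}

# Edge betweenness keyed by canonical edge key.
edge_betweenness_by_key <- function(net) {
  g <- if (inherits(net, "coexpression_network")) net$graph else moa_graph(net)
  if (igraph::ecount(g) == 0) return(stats::setNames(numeric(0), character(0)))
  eb <- igraph::edge_betweenness(g, directed = FALSE)
  el <- igraph::as_data_frame(g, what = "edges")
  stats::setNames(eb, edge_key(el$from, el$to))
}

#' Edge-based distance matrix for a collection of co-expression networks
#'
#' Five edge-similarity measures are computed per network pair and
#' combined: Jaccard similarity and Jaccard distance of the edge sets,
#' Hamming distance and simple-matching-coefficient similarity over the
#' indicator vectors on the union edge universe of all networks, and the
#' Kendall rank correlation of the common edges ranked by within-network
#' edge betweenness. Similarities are oriented as distances (`1 - x`;
#' Kendall via `(1 - tau)/2`), each component is min-max normalized over
#' the off-diagonal entries, and the consensus is the mean of the
#' components available for a pair (the Kendall component is dropped for
#' pairs with fewer than 3 common edges). Note the union-universe SMC and
#' normalized Hamming are complementary by construction; both are kept to
#' mirror the five published measures.
#'
#' @param nets list of >= 2 `coexpression_network` objects (unique
#'   exposure ids).
#' @return list of class `network_distance_matrix` with `ids`, `matrix`
#'   (consensus distance) and `components` (named list of per-measure
#'   distance matrices, `NA` where undefined).
#' @export
edge_distance_matrix <- function(nets) {
  if (length(nets) < 2) stopf("need >= 2 networks")
  ids <- vapply(seq_along(nets), function(i) net_id(nets[[i]], paste0("net", i)), "")
  if (anyDuplicated(ids)) stopf("duplicate network ids: %s",
                                paste(ids[duplicated(ids)], collapse = ", "))
  n <- length(nets)
  keys <- lapply(nets, net_edge_keys)
  universe <- unique(unlist(keys))
  U <- length(universe)
  ind <- matrix(FALSE, nrow = U, ncol = n)
  for (i in seq_len(n)) ind[, i] <- universe %in% keys[[i]]
  eb <- lapply(nets, edge_betweenness_by_key)
  comp_names <- c("jaccard_sim", "jaccard_dist", "hamming", "smc", "kendall")
  comps <- lapply(comp_names, function(x) {
    m <- matrix(0, n, n, dimnames = list(ids, ids)); m
  })
  names(comps) <- comp_names
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      jac <- jaccard_sets(keys[[i]], keys[[j]])
      comps$jaccard_sim[i, j] <- comps$jaccard_sim[j, i] <- 1 - jac
      comps$jaccard_dist[i, j] <- comps$jaccard_dist[j, i] <- 1 - jac
      if (U > 0) {
        ham <- sum(ind[, i] != ind[, j]) / U
      } else ham <- 0
      comps$hamming[i, j] <- comps$hamming[j, i] <- ham
      comps$smc[i, j] <- comps$smc[j, i] <- 1 - (1 - ham)  # 1 - SMC similarity
      common <- intersect(names(eb[[i]]), names(eb[[j]]))
      if (length(common) >= 3) {
        tau <- suppressWarnings(
          stats::cor(eb[[i]][common], eb[[j]][common], method = "kendall"))
        kd <- if (is.na(tau)) NA_real_ else (1 - tau) / 2
      } else kd <- NA_real_
      comps$kendall[i, j] <- comps$kendall[j, i] <- kd
    }
  }
  norm_comps <- lapply(comps, function(m) {
    off <- m[upper.tri(m)]
    rng <- range(off, na.rm = !all(is.na(off)))
    if (!all(is.finite(rng)) || diff(rng) == 0) {
      m[] <- ifelse(is.na(m), NA, 0); diag(m) <- 0; return(m)
    }
    out <- (m - rng[1]) / diff(rng)
    diag(out) <- 0
    out
  })
  consensus <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      vals <- vapply(norm_comps, function(m) m[i, j], numeric(1))
      consensus[i, j] <- consensus[j, i] <- mean(vals, na.rm = TRUE)
    }
  }
  structure(list(ids = ids, matrix = consensus, components = norm_comps,
                 raw_components = comps),
            class = "network_distance_matrix")
}

#' @export
print.network_distance_matrix <- function(x, ...) {
  cat(sprintf("network_distance_matrix: %d networks, %d components\n",
              length(x$ids), length(x$components)))
  invisible(x)
}

# ---- clustering -------------------------------------------------------------

# Affinity propagation on a similarity matrix (Frey & Dueck message
# passing). Deterministic: no noise injection; damping 0.9.
affinity_propagation <- function(S, preference = stats::median(S[upper.tri(S)]),
                                 damping = 0.9, maxit = 500, convits = 50) {
  n <- nrow(S)
  diag(S) <- preference
  R <- matrix(0, n, n); A <- matrix(0, n, n)
  last <- rep(-1L, n); stable <- 0L
  for (it in seq_len(maxit)) {
    AS <- A + S
    max1 <- apply(AS, 1, max)
    which1 <- max.col(AS, ties.method = "first")
    AS2 <- AS
    AS2[cbind(seq_len(n), which1)] <- -Inf
    max2 <- apply(AS2, 1, max)
    Rnew <- S - max1
    Rnew[cbind(seq_len(n), which1)] <- S[cbind(seq_len(n), which1)] - max2
    R <- damping * R + (1 - damping) * Rnew
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    cs <- colSums(Rp)
    Anew <- matrix(rep(cs, each = n), n, n) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew
    ex <- which(diag(A) + diag(R) > 0)
    if (length(ex)) {
      lab <- ex[max.col(S[, ex, drop = FALSE], ties.method = "first")]
      lab[ex] <- ex
    } else lab <- seq_len(n)
    if (identical(lab, last)) stable <- stable + 1L else stable <- 0L
    last <- lab
    if (stable >= convits) break
  }
  match(last, unique(last))
}

#' Consensus clustering of a network distance matrix
#'
#' Runs three base clusterings on the consensus distance, hierarchical
#' (average linkage, cut at `k`), k-medoids (PAM) and affinity propagation
#' (which self-selects its cluster count; `k` is ignored there, preference
#' set to the median similarity), then builds a co-association matrix (the
#' fraction of methods placing each pair together) and cuts a hierarchical
#' tree of `1 - co-association` into `k` clusters. All steps are
#' deterministic.
#'
#' @param dist a `network_distance_matrix` (or plain symmetric matrix).
#' @param k number of final clusters (2 <= k <= n).
#' @return list with `labels` (named integer vector), `base_labels`
#'   (matrix of the three base labelings) and `coassociation`.
#' @export
consensus_cluster <- function(dist, k) {
  m <- if (inherits(dist, "network_distance_matrix")) dist$matrix else dist
  n <- nrow(m)
  if (k > n) stopf("k (%d) exceeds the number of networks (%d)", k, n)
  if (k < 1) stopf("k must be >= 1")
  if (k == n) {
    labels <- stats::setNames(seq_len(n), rownames(m))
    return(list(labels = labels,
                base_labels = cbind(hierarchical = labels, pam = labels,
                                    affinity = labels),
                coassociation = diag(n)))
  }
  d <- stats::as.dist(m)
  lab_h <- stats::cutree(stats::hclust(d, method = "average"), k = k)
  lab_p <- cluster::pam(d, k = k, cluster.only = TRUE)
  lab_a <- affinity_propagation(-m)
  base <- cbind(hierarchical = lab_h, pam = lab_p, affinity = lab_a)
  co <- matrix(0, n, n, dimnames = dimnames(m))
  for (c in seq_len(ncol(base))) {
    same <- outer(base[, c], base[, c], "==")
    co <- co + same
  }
  co <- co / ncol(base)
  final <- stats::cutree(stats::hclust(stats::as.dist(1 - co),
                                       method = "average"), k = k)
  names(final) <- rownames(m)
  list(labels = final, base_labels = base, coassociation = co)
}

#' Cluster MOA networks by shared events and links
#'
#' Pairwise similarity is the mean of the node and edge Jaccard indices;
#' clustering is agglomerative with Ward-squared (`ward.D2`) linkage on
#' `1 - similarity`.
#'
#' @param moas list of >= 2 `moa_network` objects.
#' @param k optional number of flat clusters to cut.
#' @return list with `hclust`, `distance` (matrix), `labels` (when `k`
#'   given) and `newick` (dendrogram as a Newick string).
#' @export
cluster_moa_networks <- function(moas, k = NULL) {
  if (length(moas) < 2) stopf("need >= 2 MOA networks")
  ids <- vapply(seq_along(moas), function(i) net_id(moas[[i]], paste0("moa", i)), "")
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  n <- length(moas)
  nodes <- lapply(moas, function(m) igraph::V(moa_graph(m))$name)
  edges <- lapply(moas, net_edge_keys)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      sim <- mean(c(jaccard_or_1(nodes[[i]], nodes[[j]]),
                    jaccard_or_1(edges[[i]], edges[[j]])))
      d[i, j] <- d[j, i] <- 1 - sim
    }
  }
  hc <- stats::hclust(stats::as.dist(d), method = "ward.D2")
  labels <- if (!is.null(k)) stats::cutree(hc, k = k) else NULL
  newick <- tryCatch(ape::write.tree(ape::as.phylo(hc)),
                     error = function(e) NA_character_)
  list(hclust = hc, distance = d, labels = labels, newick = newick)
}

# ---- overrepresented edges --------------------------------------------------

#' Edges overrepresented in a cluster of networks
#'
#' For every edge present in at least one cluster network, the
#' hypergeometric upper-tail probability of observing at least the
#' cluster's occurrence count when `cluster_size` networks are drawn from
#' the full collection, with BH correction across tested edges.
#'
#' @param nets list of `coexpression_network` objects.
#' @param cluster_ids exposure ids forming the cluster (nonempty proper
#'   subset of the collection).
#' @param alpha BH-adjusted significance cutoff (default 0.05).
#' @param keep_all return all tested edges instead of only significant
#'   ones.
#' @return data.frame with `edge`, `gene_a`, `gene_b`, `in_cluster`,
#'   `cluster_size`, `in_total`, `total`, `p`, `p_adj`.
#' @export
overrepresented_edges <- function(nets, cluster_ids, alpha = 0.05,
                                  keep_all = FALSE) {
  ids <- vapply(seq_along(nets), function(i) net_id(nets[[i]], paste0("net", i)), "")
  if (!length(cluster_ids) || !all(cluster_ids %in% ids))
    stopf("cluster_ids must be a nonempty subset of the network ids")
  if (setequal(cluster_ids, ids))
    stopf("cluster equals the full collection; overrepresentation is undefined")
  keys <- lapply(nets, net_edge_keys)
  names(keys) <- ids
  in_cluster_nets <- keys[cluster_ids]
  cl_edges <- unique(unlist(in_cluster_nets))
  if (!length(cl_edges))
    return(data.frame(edge = character(0), gene_a = character(0),
                      gene_b = character(0), in_cluster = integer(0),
                      cluster_size = integer(0), in_total = integer(0),
                      total = integer(0), p = numeric(0), p_adj = numeric(0)))
  total <- length(ids)
  csize <- length(cluster_ids)
  in_cl <- vapply(cl_edges, function(e)
    sum(vapply(in_cluster_nets, function(k) e %in% k, logical(1))), integer(1))
  in_tot <- vapply(cl_edges, function(e)
    sum(vapply(keys, function(k) e %in% k, logical(1))), integer(1))
  p <- stats::phyper(in_cl - 1, in_tot, total - in_tot, csize,
                     lower.tail = FALSE)
  parts <- strsplit(cl_edges, "|", fixed = TRUE)
  out <- data.frame(edge = cl_edges,
                    gene_a = vapply(parts, `[`, "", 1),
                    gene_b = vapply(parts, `[`, "", 2),
                    in_cluster = in_cl, cluster_size = csize,
                    in_total = in_tot, total = total, p = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$edge), , drop = FALSE]
  rownames(out) <- NULL
  if (keep_all) out else out[out$p_adj <= alpha, , drop = FALSE]
}

# ---- edge-set enrichment ----------------------------------------------------

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then gene ids, tab-separated.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1)
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

# Weighted Kolmogorov-Smirnov running-sum score on a ranked 0/1 hit vector
# with per-position weights (used for hits only).
weighted_ks_es <- function(hits, weights) {
  n <- length(hits)
  nh <- sum(hits)
  if (nh == 0 || n == 0) return(0)
  w <- abs(weights)
  wh <- sum(w[hits])
  inc_hit <- if (wh > 0) (w * hits) / wh else hits / nh
  inc_miss <- if (n > nh) (1 - hits) / (n - nh) else rep(0, n)
  rs <- cumsum(inc_hit - inc_miss)
  rs[which.max(abs(rs))]
}

#' Edge-set enrichment of a ranked edge list against pathway gene sets
#'
#' The background edge set of a pathway is every unordered gene pair
#' co-annotated to it. Input edges, ranked from most to least
#' co-deregulated (ascending p), are scored with a weighted
#' Kolmogorov-Smirnov running sum; hit weights are proportional to
#' `-log10(p)`, so an enrichment score of 1 means every ranked edge is a
#' pathway edge concentrated at the top. Significance comes from `n_perm`
#' seeded random reassignments of the edge-set membership (set sizes
#' preserved, ranking fixed); the permutation p-value has resolution
#' `1/(n_perm + 1)`. BH correction across pathways.
#'
#' @param edges data.frame with `gene_a`, `gene_b`, `p` (combined across
#'   exposures upstream if needed, see [combine_edge_pvalues()]).
#' @param pathway_sets named list of pathway gene sets (e.g. from
#'   [read_gmt()]); pathways with < 2 annotated genes are skipped.
#' @param n_perm number of permutations (default 100; < 20 warns).
#' @param seed integer seed.
#' @param alpha BH significance threshold recorded in the `significant`
#'   column (default 0.05).
#' @return data.frame with `set_name`, `n_set_genes`, `n_hits`, `es`,
#'   `p_perm`, `p_adj`, `significant`.
#' @export
edge_set_enrichment <- function(edges, pathway_sets, n_perm = 100, seed = 1,
                                alpha = 0.05) {
  if (!all(c("gene_a", "gene_b", "p") %in% names(edges)))
    stopf("edges must have columns gene_a, gene_b, p")
  if (!length(pathway_sets)) stopf("pathway_sets must be nonempty")
  if (n_perm < 20) warnf("n_perm < 20 gives a very coarse permutation p-value")
  edges <- edges[order(edges$p, edge_key(edges$gene_a, edges$gene_b)), ,
                 drop = FALSE]
  ekeys <- edge_key(edges$gene_a, edges$gene_b)
  w <- -log10(pmax(edges$p, 1e-300))
  n <- length(ekeys)
  rows <- list()
  withr::with_seed(seed, {
    for (nm in names(pathway_sets)) {
      gs <- unique(pathway_sets[[nm]])
      if (length(gs) < 2) next
      hits <- edges$gene_a %in% gs & edges$gene_b %in% gs
      nh <- sum(hits)
      es <- weighted_ks_es(hits, w)
      if (nh == 0) {
        p_perm <- 1
      } else {
        perm_es <- vapply(seq_len(n_perm), function(b) {
          ph <- logical(n)
          ph[sample.int(n, nh)] <- TRUE
          weighted_ks_es(ph, w)
        }, numeric(1))
        p_perm <- (1 + sum(abs(perm_es) >= abs(es))) / (n_perm + 1)
      }
      rows[[nm]] <- data.frame(set_name = nm, n_set_genes = length(gs),
                               n_hits = nh, es = es, p_perm = p_perm,
                               stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(set_name = character(0), n_set_genes = integer(0),
                      n_hits = integer(0), es = numeric(0),
                      p_perm = numeric(0), p_adj = numeric(0),
                      significant = logical(0)))
  out$p_adj <- stats::p.adjust(out$p_perm, method = "BH")
  out$significant <- out$p_adj <= alpha
  rownames(out) <- NULL
  out
}

#' Combine p-values with Fisher's (sumlog) method
#'
#' `X = -2 * sum(log(p))` referred to a chi-square distribution with
#' `2 * length(p_list)` degrees of freedom. Zeros are clamped to the
#' smallest representable positive value with a warning.
#'
#' @param p_list numeric vector of p-values in `(0, 1]`.
#' @return the combined p-value.
#' @export
combine_edge_pvalues <- function(p_list) {
  if (!length(p_list)) stopf("p_list must be nonempty")
  if (any(p_list < 0 | p_list > 1)) stopf("p-values must lie in [0, 1]")
  if (any(p_list == 0)) {
    warnf("zero p-value(s) clamped to the smallest representable positive value")
    p_list[p_list == 0] <- .Machine$double.xmin
  }
  x <- -2 * sum(log(p_list))
  stats::pchisq(x, df = 2 * length(p_list), lower.tail = FALSE)
}
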