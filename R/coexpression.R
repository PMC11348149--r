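#' Two-sample Hotelling T-squared test for a gene pair
#'
#' Tests whether the bivariate mean of a gene pair differs between control
#' and exposed replicates. With group sizes `n1`, `n2` and dimension 2,
#' `T2 = (n1*n2/(n1+n2)) * d' S^-1 d` where `d` is the difference of the
#' bivariate means and `S` the pooled covariance;
#' `F = ((n1+n2-3)/(2*(n1+n2-2))) * T2` follows an F(2, n1+n2-3)
#' distribution under the null. Designed for the 3-vs-3 replicate layouts
#' typical of exposure transcriptomics.
#'
#' @param x_ctrl,y_ctrl control replicate values of gene x and gene y
#'   (same length, paired by sample).
#' @param x_exp,y_exp exposed replicate values.
#' @return list of class `hotelling_result` with `t2`, `f_stat`, `df1`,
#'   `df2`, `p`.
#' @export
hotelling_pair_test <- function(x_ctrl, y_ctrl, x_exp, y_exp) {
  n1 <- length(x_ctrl); n2 <- length(x_exp)
  if (length(y_ctrl) != n1 || length(y_exp) != n2)
    stopf("replicate vectors of a group must have equal length")
  if (n1 < 3 || n2 < 3)
    stopf("need >= 3 replicates per group for a 2-dimensional test")
  g1 <- cbind(x_ctrl, y_ctrl)
  g2 <- cbind(x_exp, y_exp)
  d <- colMeans(g2) - colMeans(g1)
  S <- ((n1 - 1) * stats::cov(g1) + (n2 - 1) * stats::cov(g2)) / (n1 + n2 - 2)
  det_s <- S[1, 1] * S[2, 2] - S[1, 2]^2
  if (!is.finite(det_s) || det_s <= .Machine$double.eps^0.9 * max(S[1, 1] * S[2, 2], 1e-300))
    stopf("singular pooled covariance (degenerate pair)")
  quad <- (d[1]^2 * S[2, 2] - 2 * d[1] * d[2] * S[1, 2] + d[2]^2 * S[1, 1]) / det_s
  t2 <- (n1 * n2 / (n1 + n2)) * quad
  f <- (n1 + n2 - 3) / (2 * (n1 + n2 - 2)) * t2
  structure(list(t2 = unname(t2), f_stat = unname(f), df1 = 2L,
                 df2 = n1 + n2 - 3L,
                 p = unname(stats::pf(f, 2, n1 + n2 - 3, lower.tail = FALSE))),
            class = "hotelling_result")
}

# Vectorized Hotelling p-values for all unordered pairs of rows of the two
# matrices (genes x replicates). Returns a data.frame of tested pairs and a
# character vector of degenerate pairs that were skipped.
hotelling_all_pairs <- function(x0, x1) {
  n1 <- ncol(x0); n2 <- ncol(x1)
  m <- nrow(x0)
  c0 <- x0 - rowMeans(x0)
  c1 <- x1 - rowMeans(x1)
  # pooled cross-product matrices: S[i,j] = pooled covariance of genes i, j
  S <- (tcrossprod(c0) + tcrossprod(c1)) / (n1 + n2 - 2)
  d <- rowMeans(x1) - rowMeans(x0)
  idx <- which(upper.tri(S), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  a <- diag(S)[i]; cc <- diag(S)[j]; b <- S[idx]
  det_s <- a * cc - b^2
  di <- d[i]; dj <- d[j]
  degen <- !is.finite(det_s) |
    det_s <= .Machine$double.eps^0.9 * pmax(a * cc, 1e-300)
  quad <- (di^2 * cc - 2 * di * dj * b + dj^2 * a) / det_s
  t2 <- (n1 * n2 / (n1 + n2)) * quad
  f <- (n1 + n2 - 3) / (2 * (n1 + n2 - 2)) * t2
  p <- stats::pf(f, 2, n1 + n2 - 3, lower.tail = FALSE)
  genes <- rownames(x0)
  pairs <- data.frame(gene_a = genes[i], gene_b = genes[j],
                      t2 = t2, f_stat = f, p = p, stringsAsFactors = FALSE)
  list(pairs = pairs[!degen, , drop = FALSE],
       degenerate = paste(genes[i[degen]], genes[j[degen]], sep = "|"))
}

#' Infer a binary co-expression network for one exposure
#'
#' Every unordered pair of seed genes is tested with
#' [hotelling_pair_test()]; Benjamini-Hochberg adjusted p-values are stored
#' alongside the raw ones, and the network keeps the pairs whose raw
#' p-value falls strictly below the `edge_percentile`-th percentile of the
#' tested-pair p distribution (the percentile cut on ranked p-values is the
#' operative edge selection; the FDR column preserves auditability). Node
#' attribute `logfc` comes from the study contrast; edge attribute
#' `neglog_p` is `-log10(p)`. Degenerate pairs (singular pooled covariance)
#' are excluded from both testing and the percentile distribution. The
#' procedure involves no randomness.
#'
#' @param study an [expression_study()].
#' @param seed_genes a `deg_selection` or character vector of gene ids
#'   (must be present in the study; >= 2).
#' @param edge_percentile percentile of the p distribution below which
#'   edges are retained (default 5).
#' @param contrast optional precomputed [differential_expression()] table;
#'   computed from the study when `NULL`.
#' @return object of class `coexpression_network`: list with `graph`
#'   (undirected [igraph::igraph]), `edges` (retained edges with `p`,
#'   `p_adj`, `neglog_p`), `tested_pairs` (all tested pairs),
#'   `degenerate_pairs`, `exposure_id`.
#' @export
infer_network <- function(study, seed_genes, edge_percentile = 5,
                          contrast = NULL) {
  stopifnot(inherits(study, "expression_study"))
  genes <- if (inherits(seed_genes, "deg_selection")) seed_genes$genes
           else as.character(seed_genes)
  missing_g <- setdiff(genes, rownames(study$matrix))
  if (length(missing_g))
    stopf("seed genes absent from study: %s",
          paste(utils::head(missing_g, 5), collapse = ", "))
  if (length(genes) < 2) stopf("need >= 2 seed genes")
  cond <- study$sample_meta$condition
  x0 <- study$matrix[genes, cond == "control", drop = FALSE]
  x1 <- study$matrix[genes, cond == "exposed", drop = FALSE]
  if (ncol(x0) < 3 || ncol(x1) < 3)
    stopf("need >= 3 replicates per condition for the pairwise Hotelling test")
  ht <- hotelling_all_pairs(x0, x1)
  tested <- ht$pairs
  if (nrow(tested) == 0) {
    warnf("all gene pairs degenerate; returning an empty network")
    keep <- tested
  } else {
    tested$p_adj <- stats::p.adjust(tested$p, method = "BH")
    tested <- tested[order(tested$p, tested$gene_a, tested$gene_b), , drop = FALSE]
    keep <- tested[strict_percentile_cut(tested$p, edge_percentile), , drop = FALSE]
  }
  contrast <- contrast %||% differential_expression(study)
  lfc <- contrast$logFC[match(genes, contrast$gene)]
  keep$neglog_p <- -log10(keep$p)
  g <- igraph::graph_from_data_frame(
    keep[, c("gene_a", "gene_b", "p", "p_adj", "neglog_p")],
    directed = FALSE,
    vertices = data.frame(name = genes, logfc = lfc, stringsAsFactors = FALSE))
  structure(list(graph = g, edges = keep, tested_pairs = tested,
                 degenerate_pairs = ht$degenerate,
                 exposure_id = study$study_id),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat(sprintf("coexpression_network '%s': %d nodes, %d edges (%d pairs tested, %d degenerate)\n",
              x$exposure_id, igraph::vcount(x$graph), igraph::ecount(x$graph),
              nrow(x$tested_pairs), length(x$degenerate_pairs)))
  invisible(x)
}

#' Export a co-expression network
#'
#' @param net a `coexpression_network`.
#' @param edgelist_path optional path for the flat tab-separated edge list
#'   (`gene_a`, `gene_b`, `p`, `p_adj`, `neglog_p`).
#' @param graphml_path optional path for GraphML output (node attribute
#'   `logfc`, edge attribute `neglog_p`).
#' @param config,seed provenance header fields for the edge list.
#' @return invisibly, `net`.
#' @export
write_coexpression_network <- function(net, edgelist_path = NULL,
                                       graphml_path = NULL,
                                       config = list(), seed = NULL) {
  stopifnot(inherits(net, "coexpression_network"))
  if (!is.null(edgelist_path))
    write_tsv_prov(net$edges[, c("gene_a", "gene_b", "p", "p_adj", "neglog_p")],
                   edgelist_path, config, seed)
  if (!is.null(graphml_path))
    igraph::write_graph(net$graph, graphml_path, format = "graphml")
  invisible(net)
}

#' Read a co-expression network from a flat edge list
#'
#' @param edgelist_path tab-separated file with columns `gene_a`, `gene_b`,
#'   `p` and optionally `p_adj`, `neglog_p`.
#' @param nodes optional character vector of node ids (to keep isolated
#'   nodes); defaults to the edge endpoints.
#' @param logfc optional named numeric vector of node log fold changes.
#' @param exposure_id identifier (defaults to the file name).
#' @return a `coexpression_network` (with `tested_pairs` equal to the
#'   stored edges; the full tested distribution is not serialized).
#' @export
read_coexpression_network <- function(edgelist_path, nodes = NULL,
                                      logfc = NULL,
                                      exposure_id = basename(edgelist_path)) {
  ed <- read_tsv_prov(edgelist_path)
  if (!all(c("gene_a", "gene_b", "p") %in% names(ed)))
    stopf("edge list must have columns gene_a, gene_b, p")
  if (!"p_adj" %in% names(ed)) ed$p_adj <- stats::p.adjust(ed$p, "BH")
  if (!"neglog_p" %in% names(ed)) ed$neglog_p <- -log10(ed$p)
  nodes <- nodes %||% unique(c(ed$gene_a, ed$gene_b))
  lfc <- if (is.null(logfc)) rep(NA_real_, length(nodes)) else unname(logfc[nodes])
  g <- igraph::graph_from_data_frame(
    ed[, c("gene_a", "gene_b", "p", "p_adj", "neglog_p")], directed = FALSE,
    vertices = data.frame(name = nodes, logfc = lfc, stringsAsFactors = FALSE))
  structure(list(graph = g, edges = ed, tested_pairs = ed,
                 degenerate_pairs = character(0), exposure_id = exposure_id),
            class = "coexpression_network")
}
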