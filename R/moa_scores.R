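moa_graph <- function(x) {
  if (inherits(x, "moa_network")) x$graph
  else if (inherits(x, "igraph")) x
  else stopf("expected a moa_network or igraph object")
}

#' Completeness metrics of a MOA network
#'
#' Four undirected connectedness measures quantifying the ability to
#' observe a complete chain of events from initiating events to outcomes:
#' global transitivity, mean vertex betweenness, mean shortest-path length
#' over connected node pairs, and diameter (longest shortest path within
#' components). Larger values indicate a longer reconstructable mechanism.
#' Empty or edgeless graphs return all zeros by convention so every
#' comparison is total.
#'
#' @param moa a `moa_network` (or bare igraph).
#' @return list of class `completeness_metrics` with `transitivity`,
#'   `mean_betweenness`, `mean_shortest_path`, `diameter`.
#' @export
completeness_metrics <- function(moa) {
  g <- igraph::as_undirected(moa_graph(moa), mode = "collapse")
  zero <- structure(list(transitivity = 0, mean_betweenness = 0,
                         mean_shortest_path = 0, diameter = 0),
                    class = "completeness_metrics")
  if (igraph::vcount(g) == 0 || igraph::ecount(g) == 0) return(zero)
  tr <- igraph::transitivity(g, type = "global")
  if (is.nan(tr)) tr <- 0
  btw <- mean(igraph::betweenness(g, directed = FALSE))
  D <- igraph::distances(g)
  sp <- D[upper.tri(D)]
  sp <- sp[is.finite(sp)]
  msp <- if (length(sp)) mean(sp) else 0
  dia <- igraph::diameter(g, directed = FALSE, unconnected = TRUE)
  structure(list(transitivity = tr, mean_betweenness = btw,
                 mean_shortest_path = msp, diameter = dia),
            class = "completeness_metrics")
}

#' @export
print.completeness_metrics <- function(x, ...) {
  cat(sprintf(paste0("completeness: transitivity=%.3f mean_betweenness=%.3f ",
                     "mean_shortest_path=%.3f diameter=%g\n"),
              x$transitivity, x$mean_betweenness, x$mean_shortest_path,
              x$diameter))
  invisible(x)
}

#' Compare two completeness metric sets
#'
#' The more informative network is the one strictly higher on at least
#' three of the four connectedness measures.
#'
#' @param a,b `completeness_metrics` objects.
#' @return `"A"`, `"B"` or `"tie"`.
#' @export
compare_completeness <- function(a, b) {
  keys <- c("transitivity", "mean_betweenness", "mean_shortest_path", "diameter")
  va <- unlist(a[keys]); vb <- unlist(b[keys])
  if (sum(va > vb) >= 3) "A" else if (sum(vb > va) >= 3) "B" else "tie"
}

#' Key-event connectivity score
#'
#' Ratio of connected events (degree >= 1 within the MOA) to isolated
#' ones, the denominator floored at 1 so the score stays finite when
#' nothing is isolated. Higher values indicate a more homogeneous,
#' less uncertain mechanism. An empty MOA scores 0.
#'
#' @param moa a `moa_network` (or bare igraph).
#' @return nonnegative number.
#' @export
connectivity_score <- function(moa) {
  g <- moa_graph(moa)
  if (igraph::vcount(g) == 0) return(0)
  deg <- igraph::degree(g, mode = "all")
  sum(deg >= 1) / max(sum(deg == 0), 1)
}

largest_component_diameter <- function(g) {
  g <- igraph::as_undirected(g, mode = "collapse")
  if (igraph::vcount(g) == 0 || igraph::ecount(g) == 0) return(0)
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(g, which(comp$membership == big))
  igraph::diameter(sub, directed = FALSE)
}

jaccard_or_1 <- function(a, b) {
  if (!length(a) && !length(b)) return(1)
  jaccard_sets(a, b)
}

#' Biological-system similarity of two response mechanisms
#'
#' Compares two MOA networks built against the same AOP network as the
#' mean of four scores in `[0, 1]`: similarity of AOP coverage
#' (`1 - |nA/N - nB/N|` where `n` counts enriched key events and `N` the
#' key events in the full AOP network), Jaccard of the event sets, Jaccard
#' of the link sets, and the min/max ratio of the largest-component
#' diameters (1 when both are 0). Empty-vs-empty set overlaps count as 1
#' (identical graphs must score 1).
#'
#' @param moa_a,moa_b `moa_network` objects from the same AOP network.
#' @param aop the shared [aop_network()].
#' @return list of class `similarity_breakdown` with `coverage_sim`,
#'   `node_jaccard`, `edge_jaccard`, `diameter_ratio`, `score`.
#' @export
biosystem_similarity <- function(moa_a, moa_b, aop) {
  stopifnot(inherits(moa_a, "moa_network"), inherits(moa_b, "moa_network"),
            inherits(aop, "aop_network"))
  sig <- aop_signature(aop)
  if (!identical(moa_a$aop_signature, sig) || !identical(moa_b$aop_signature, sig))
    stopf("MOA networks were not built against the supplied AOP network")
  n_total <- sum(aop$events$event_type == "KE")
  if (n_total == 0) stopf("AOP network contains no key events")
  na <- sum(moa_a$table$role == "enriched_ke")
  nb <- sum(moa_b$table$role == "enriched_ke")
  coverage_sim <- 1 - abs(na - nb) / n_total
  ea <- igraph::as_data_frame(moa_a$graph, what = "edges")
  eb <- igraph::as_data_frame(moa_b$graph, what = "edges")
  node_j <- jaccard_or_1(igraph::V(moa_a$graph)$name, igraph::V(moa_b$graph)$name)
  edge_j <- jaccard_or_1(paste(ea$from, ea$to), paste(eb$from, eb$to))
  da <- largest_component_diameter(moa_a$graph)
  db <- largest_component_diameter(moa_b$graph)
  dr <- if (max(da, db) == 0) 1 else min(da, db) / max(da, db)
  comp <- c(coverage_sim = coverage_sim, node_jaccard = node_j,
            edge_jaccard = edge_j, diameter_ratio = dr)
  structure(c(as.list(comp), list(score = mean(comp))),
            class = "similarity_breakdown")
}

#' @export
print.similarity_breakdown <- function(x, ...) {
  cat(sprintf(paste0("biosystem similarity: %.3f (coverage=%.3f nodes=%.3f ",
                     "edges=%.3f diameter=%.3f)\n"),
              x$score, x$coverage_sim, x$node_jaccard, x$edge_jaccard,
              x$diameter_ratio))
  invisible(x)
}
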