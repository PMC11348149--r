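# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# Minimal chain AOP: MIE1 -> KE1 -> AO1 (+ optional extra events).
tiny_aop <- function(annotation = list(KE1 = c("g1", "g2")),
                     extra_events = NULL, extra_links = NULL) {
  events <- data.frame(event_id = c("MIE1", "KE1", "AO1"),
                       event_type = c("MIE", "KE", "AO"),
                       stringsAsFactors = FALSE)
  links <- data.frame(upstream_event_id = c("MIE1", "KE1"),
                      downstream_event_id = c("KE1", "AO1"),
                      stringsAsFactors = FALSE)
  if (!is.null(extra_events)) events <- rbind(events, extra_events)
  if (!is.null(extra_links)) links <- rbind(links, extra_links)
  aop_network(events, links, annotation)
}

# Expression study with explicit per-gene control/exposed replicate rows.
study_from_rows <- function(ctrl, expo, study_id = "test") {
  stopifnot(nrow(ctrl) == nrow(expo))
  m <- cbind(ctrl, expo)
  colnames(m) <- c(paste0("c", seq_len(ncol(ctrl))),
                   paste0("e", seq_len(ncol(expo))))
  meta <- data.frame(sample_id = colnames(m),
                     condition = rep(c("control", "exposed"),
                                     c(ncol(ctrl), ncol(expo))),
                     stringsAsFactors = FALSE)
  expression_study(m, meta, study_id)
}

# Wrap a bare igraph (character vertex names) as a coexpression_network so
# graph-level operations can be tested on hand-built topologies.
as_coexnet <- function(g, exposure_id = "net", p_edges = NULL) {
  el <- igraph::as_data_frame(g, what = "edges")
  ne <- nrow(el)
  p <- p_edges %||% rep(0.01, ne)
  edges <- data.frame(gene_a = el$from %||% character(0),
                      gene_b = el$to %||% character(0),
                      p = p, p_adj = p, neglog_p = -log10(p),
                      stringsAsFactors = FALSE)
  if (is.null(igraph::vertex_attr(g, "logfc")))
    g <- igraph::set_vertex_attr(g, "logfc", value = 0)
  structure(list(graph = g, edges = edges, tested_pairs = edges,
                 degenerate_pairs = character(0), exposure_id = exposure_id),
            class = "coexpression_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Simple edge-set network for cohort tests: vector of "a|b" keys.
net_from_keys <- function(keys, id) {
  parts <- strsplit(keys, "|", fixed = TRUE)
  el <- data.frame(from = vapply(parts, `[`, "", 1),
                   to = vapply(parts, `[`, "", 2), stringsAsFactors = FALSE)
  as_coexnet(igraph::graph_from_data_frame(el, directed = FALSE), id)
}

# Deterministic MOA from explicit event sets on a given AOP.
moa_from_ids <- function(aop, enriched_ids, terminal_ids = character(0),
                         exposure_id = "moa") {
  enr <- data.frame(event_id = enriched_ids, stringsAsFactors = FALSE)
  terms <- if (length(terminal_ids)) {
    data.frame(event_id = terminal_ids,
               event_type = aop$events$event_type[
                 match(terminal_ids, aop$events$event_id)],
               rank = seq_along(terminal_ids), stringsAsFactors = FALSE)
  } else NULL
  assemble_moa(enr, terms, aop, exposure_id = exposure_id)
}
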