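#' Prioritize plausible MIEs and AOs around enriched key events
#'
#' Candidate molecular initiating events and adverse outcomes are all AOP
#' events of those types with at least one annotated gene passing the DEG
#' filter (`p < p_thresh`, `|logFC| > lfc_thresh`) in the contrast.
#' Plausibility combines molecular evidence and topology: each candidate is
#' scored by the mean of two within-type ranks, rank of `best_gene_p` (the
#' minimum contrast p over annotated DEGs, ascending) and rank of
#' `dist_to_enriched` (minimum undirected AOP distance to any enriched key
#' event, ascending). Unreachable candidates are discarded; ties break
#' toward smaller annotated gene sets (more specific events), then
#' lexicographic event id. At most `max_events` per type are kept.
#'
#' @param enriched table from [topological_enrichment()] (typically after
#'   [filter_enriched()]); only its `event_id` column is used.
#' @param aop an [aop_network()].
#' @param contrast table from [differential_expression()].
#' @param max_events cap per event type (default 20).
#' @param p_thresh,lfc_thresh DEG thresholds defining "differentially
#'   expressed annotated gene" (defaults 0.05, 0.58).
#' @return data.frame with `event_id`, `event_type`, `best_gene_p`,
#'   `dist_to_enriched`, `gene_set_size`, `rank` (unique within type).
#' @export
prioritize_terminals <- function(enriched, aop, contrast, max_events = 20,
                                 p_thresh = 0.05, lfc_thresh = 0.58) {
  stopifnot(inherits(aop, "aop_network"))
  empty <- data.frame(event_id = character(0), event_type = character(0),
                      best_gene_p = numeric(0), dist_to_enriched = numeric(0),
                      gene_set_size = integer(0), rank = integer(0))
  if (nrow(enriched) == 0) {
    warnf("no enriched key events; nothing to prioritize")
    return(empty)
  }
  enriched_ids <- enriched$event_id
  deg <- contrast[contrast$p < p_thresh & abs(contrast$logFC) > lfc_thresh, ,
                  drop = FALSE]
  cand <- aop$events[aop$events$event_type %in% c("MIE", "AO") &
                       lengths(aop$annotation[aop$events$event_id]) > 0, ,
                     drop = FALSE]
  gu <- igraph::as_undirected(aop$graph, mode = "collapse")
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    ev <- cand$event_id[i]
    gs <- aop$annotation[[ev]]
    hit_p <- deg$p[deg$gene %in% gs]
    if (!length(hit_p)) return(NULL)
    d <- min(igraph::distances(gu, v = ev, to = enriched_ids))
    if (!is.finite(d)) return(NULL)
    data.frame(event_id = ev, event_type = cand$event_type[i],
               best_gene_p = min(hit_p), dist_to_enriched = d,
               gene_set_size = length(gs), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  res <- lapply(split(out, out$event_type), function(tab) {
    r_p <- rank(tab$best_gene_p, ties.method = "average")
    r_d <- rank(tab$dist_to_enriched, ties.method = "average")
    comp <- (r_p + r_d) / 2
    tab <- tab[order(comp, tab$gene_set_size, tab$event_id), , drop = FALSE]
    tab$rank <- seq_len(nrow(tab))
    utils::head(tab, max_events)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Assemble the AOP-based mechanism-of-action network
#'
#' The induced subgraph of the AOP network on the enriched key events plus
#' the prioritized terminal events, preserving link direction. Included
#' events that end up isolated are retained; they feed the key-event
#' connectivity score.
#'
#' @param enriched table of enriched key events (needs `event_id`; `ratio`,
#'   `p_adj` carried into the tabular output when present).
#' @param terminals table from [prioritize_terminals()] (may have 0 rows).
#' @param aop an [aop_network()].
#' @param exposure_id identifier stored on the result.
#' @return object of class `moa_network`: list with `graph` (directed
#'   induced subgraph, vertex attributes `event_type` and `role`), `table`
#'   (tabular view: `event_id`, `event_type`, `role`, `ratio`, `p_adj`,
#'   `rank`), `exposure_id`, `aop_signature` and `provenance`.
#' @export
assemble_moa <- function(enriched, terminals, aop, exposure_id = "exposure") {
  stopifnot(inherits(aop, "aop_network"))
  if (is.null(terminals) || nrow(terminals) == 0)
    terminals <- data.frame(event_id = character(0), event_type = character(0),
                            rank = integer(0))
  ids <- unique(c(enriched$event_id, terminals$event_id))
  unknown <- setdiff(ids, aop$events$event_id)
  if (length(unknown))
    stopf("events not in the AOP network: %s", paste(unknown, collapse = ", "))
  g <- igraph::induced_subgraph(aop$graph, ids)
  role <- ifelse(igraph::V(g)$name %in% enriched$event_id, "enriched_ke",
                 "prioritized_terminal")
  g <- igraph::set_vertex_attr(g, "role", value = role)
  tab <- data.frame(
    event_id = igraph::V(g)$name,
    event_type = igraph::V(g)$event_type,
    role = role, stringsAsFactors = FALSE)
  tab$ratio <- enriched$ratio[match(tab$event_id, enriched$event_id)] %||% NA_real_
  tab$p_adj <- enriched$p_adj[match(tab$event_id, enriched$event_id)] %||% NA_real_
  tab$rank <- terminals$rank[match(tab$event_id, terminals$event_id)]
  tab <- tab[order(tab$role, tab$event_id), , drop = FALSE]
  rownames(tab) <- NULL
  # every included link must exist in the source network, by construction;
  # assert it anyway so corruption cannot propagate silently
  el <- igraph::as_data_frame(g, what = "edges")
  src <- igraph::as_data_frame(aop$graph, what = "edges")
  if (nrow(el) && !all(paste(el$from, el$to) %in% paste(src$from, src$to)))
    stopf("internal error: MOA link absent from the AOP network")
  structure(list(graph = g, table = tab, exposure_id = exposure_id,
                 aop_signature = aop_signature(aop),
                 provenance = list(n_enriched = nrow(enriched),
                                   n_terminals = nrow(terminals))),
            class = "moa_network")
}

aop_signature <- function(aop) {
  sprintf("%s|%d events|%d links", aop$annotation_source,
          nrow(aop$events), igraph::ecount(aop$graph))
}

#' @export
print.moa_network <- function(x, ...) {
  cat(sprintf("moa_network '%s': %d events (%d enriched KE, %d terminals), %d links\n",
              x$exposure_id, igraph::vcount(x$graph),
              sum(x$table$role == "enriched_ke"),
              sum(x$table$role == "prioritized_terminal"),
              igraph::ecount(x$graph)))
  invisible(x)
}

#' Write a MOA network (GraphML and/or tabular form)
#'
#' @param moa a `moa_network`.
#' @param graphml_path,table_path optional output paths.
#' @param config,seed provenance fields for the tabular output.
#' @return invisibly, `moa`.
#' @export
write_moa <- function(moa, graphml_path = NULL, table_path = NULL,
                      config = list(), seed = NULL) {
  stopifnot(inherits(moa, "moa_network"))
  if (!is.null(graphml_path))
    igraph::write_graph(moa$graph, graphml_path, format = "graphml")
  if (!is.null(table_path))
    write_tsv_prov(moa$table, table_path, config, seed)
  invisible(moa)
}
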