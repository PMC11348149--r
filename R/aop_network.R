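#' AOP event networks
#'
#' An `aop_network` is the knowledge layer of the framework: a directed graph
#' of typed events (molecular initiating events, key events, adverse
#' outcomes) as curated in AOP knowledge bases, together with a gene
#' annotation mapping events to sets of gene identifiers. All enrichment and
#' prioritization steps map exposure data onto this object.
#'
#' @param events data.frame with columns `event_id`, `event_type` (one of
#'   `"MIE"`, `"KE"`, `"AO"`) and optionally `label`.
#' @param links data.frame with columns `upstream_event_id`,
#'   `downstream_event_id`; duplicated links are removed.
#' @param annotation named list mapping event ids to character vectors of
#'   gene identifiers (one namespace throughout; empty sets allowed).
#' @param annotation_source free-text provenance string.
#' @return an object of class `aop_network` with elements `graph` (a directed
#'   [igraph::igraph] whose vertices carry `event_type`), `events`,
#'   `annotation` and `annotation_source`.
#' @export
aop_network <- function(events, links, annotation = list(),
                        annotation_source = "unspecified") {
  stopifnot(is.data.frame(events), is.data.frame(links))
  need <- c("event_id", "event_type")
  if (!all(need %in% names(events)))
    stopf("events table must have columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(events$event_id))
    stopf("duplicate event ids: %s",
          paste(unique(events$event_id[duplicated(events$event_id)]), collapse = ", "))
  bad_type <- !events$event_type %in% c("MIE", "KE", "AO")
  if (any(bad_type))
    stopf("invalid event_type for: %s",
          paste(events$event_id[bad_type], collapse = ", "))
  if (!all(c("upstream_event_id", "downstream_event_id") %in% names(links)))
    stopf("links table must have columns upstream_event_id, downstream_event_id")
  links <- unique(links[, c("upstream_event_id", "downstream_event_id")])
  self <- links$upstream_event_id == links$downstream_event_id
  if (any(self)) {
    warnf("dropping %d self-link(s)", sum(self))
    links <- links[!self, , drop = FALSE]
  }
  missing_ep <- setdiff(unlist(links[, 1:2], use.names = FALSE), events$event_id)
  if (length(missing_ep))
    stopf("links reference untyped/unknown events: %s",
          paste(missing_ep, collapse = ", "))
  unknown_ann <- setdiff(names(annotation), events$event_id)
  if (length(unknown_ann))
    stopf("annotation references unknown events: %s",
          paste(unknown_ann, collapse = ", "))
  if (!"label" %in% names(events)) events$label <- events$event_id
  ann <- lapply(events$event_id, function(e)
    unique(as.character(annotation[[e]] %||% character(0))))
  names(ann) <- events$event_id
  g <- igraph::graph_from_data_frame(
    links, directed = TRUE,
    vertices = events[, c("event_id", "event_type", "label")])
  structure(list(graph = g,
                 events = events[, c("event_id", "event_type", "label")],
                 annotation = ann,
                 annotation_source = annotation_source),
            class = "aop_network")
}

#' @export
print.aop_network <- function(x, ...) {
  tab <- table(factor(x$events$event_type, levels = c("MIE", "KE", "AO")))
  cat(sprintf("aop_network: %d events (%d MIE, %d KE, %d AO), %d links\n",
              nrow(x$events), tab[["MIE"]], tab[["KE"]], tab[["AO"]],
              igraph::ecount(x$graph)))
  n_ann <- sum(lengths(x$annotation) > 0)
  cat(sprintf("  %d events carry gene annotation (source: %s)\n",
              n_ann, x$annotation_source))
  invisible(x)
}

#' Load an AOP network from delimited text files
#'
#' The edge table is tab-separated with columns `upstream_event_id`,
#' `downstream_event_id`, `upstream_type`, `downstream_type`; the annotation
#' table has columns `event_id`, `gene` (long format, one gene per row).
#' Annotated events absent from the edge table are retained as isolated
#' nodes (defaulting to type `"KE"`); duplicated links are deduplicated.
#'
#' @param edge_table path to the edge table.
#' @param annotation_table path to the annotation table, or `NULL`.
#' @param annotation_source provenance string stored on the result.
#' @return an [aop_network()].
#' @export
load_aop_network <- function(edge_table, annotation_table = NULL,
                             annotation_source = NULL) {
  ed <- read_tsv_prov(edge_table)
  need <- c("upstream_event_id", "downstream_event_id",
            "upstream_type", "downstream_type")
  if (!all(need %in% names(ed)))
    stopf("edge table missing required column(s): %s",
          paste(setdiff(need, names(ed)), collapse = ", "))
  ev <- unique(rbind(
    data.frame(event_id = ed$upstream_event_id, event_type = ed$upstream_type,
               stringsAsFactors = FALSE),
    data.frame(event_id = ed$downstream_event_id, event_type = ed$downstream_type,
               stringsAsFactors = FALSE)))
  conf <- ev$event_id[duplicated(ev$event_id)]
  if (length(conf))
    stopf("conflicting event types for: %s", paste(unique(conf), collapse = ", "))
  untyped <- ev$event_id[is.na(ev$event_type) | ev$event_type == ""]
  if (length(untyped))
    stopf("links reference untyped events: %s", paste(untyped, collapse = ", "))
  annotation <- list()
  if (!is.null(annotation_table)) {
    an <- read_tsv_prov(annotation_table)
    if (!all(c("event_id", "gene") %in% names(an)))
      stopf("annotation table must have columns event_id, gene")
    annotation <- split(as.character(an$gene), an$event_id)
    extra <- setdiff(names(annotation), ev$event_id)
    if (length(extra))
      ev <- rbind(ev, data.frame(event_id = extra, event_type = "KE",
                                 stringsAsFactors = FALSE))
  }
  aop_network(ev,
              ed[, c("upstream_event_id", "downstream_event_id")],
              annotation,
              annotation_source = annotation_source %||% edge_table)
}

#' Write an AOP network to GraphML
#'
#' Event type is carried as a vertex attribute; the gene annotation is not
#' serialized (it lives in the long-format annotation table).
#'
#' @param net an [aop_network()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_aop_graphml <- function(net, path) {
  stopifnot(inherits(net, "aop_network"))
  igraph::write_graph(net$graph, path, format = "graphml")
  invisible(path)
}

gene_sets_of <- function(net, ids = NULL) {
  ids <- ids %||% net$events$event_id
  net$annotation[ids]
}

jaccard_sets <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Merge redundant key events by gene-set similarity
#'
#' Events whose annotated gene sets are near-identical (Jaccard index at or
#' above `jaccard_threshold`) are merged transitively (single linkage over
#' the threshold graph) into clustered events that inherit the union of the
#' member gene sets and of all incident links. Merging is iterated to a fixed
#' point so the operation is idempotent. Events with empty gene sets never
#' merge.
#'
#' @param net an [aop_network()].
#' @param jaccard_threshold similarity threshold in `[0, 1]` (default 0.8).
#' @return a list with `network` (the merged [aop_network()]), `clusters`
#'   (data.frame of merged events: `merged_event_id`, `member_event_ids`
#'   comma-joined, `n_members`, `n_genes`) and `mapping` (named character
#'   vector, original id -> id in the merged network).
#' @export
merge_redundant_kes <- function(net, jaccard_threshold = 0.8) {
  stopifnot(inherits(net, "aop_network"))
  if (!is.numeric(jaccard_threshold) || length(jaccard_threshold) != 1 ||
      jaccard_threshold < 0 || jaccard_threshold > 1)
    stopf("jaccard_threshold must be a single value in [0, 1]")

  cur <- net
  mapping <- stats::setNames(net$events$event_id, net$events$event_id)
  clusters <- list()
  repeat {
    res <- merge_once(cur, jaccard_threshold)
    if (is.null(res)) break
    cur <- res$network
    mapping <- stats::setNames(res$mapping[mapping], names(mapping))
    clusters <- c(clusters, res$clusters)
  }
  cl_df <- if (length(clusters)) {
    do.call(rbind, lapply(clusters, function(cl) data.frame(
      merged_event_id = cl$merged_event_id,
      member_event_ids = paste(sort(cl$member_event_ids), collapse = ","),
      n_members = length(cl$member_event_ids),
      n_genes = length(cl$gene_set),
      stringsAsFactors = FALSE)))
  } else {
    data.frame(merged_event_id = character(0), member_event_ids = character(0),
               n_members = integer(0), n_genes = integer(0))
  }
  list(network = cur, clusters = cl_df, mapping = mapping)
}

# One single-linkage merge pass; NULL when nothing is above threshold.
merge_once <- function(net, thr) {
  ids <- net$events$event_id[lengths(net$annotation[net$events$event_id]) > 0]
  if (length(ids) < 2) return(NULL)
  sets <- net$annotation[ids]
  m <- length(ids)
  adj <- matrix(FALSE, m, m)
  for (i in seq_len(m - 1)) {
    for (j in seq(i + 1, m)) {
      if (jaccard_sets(sets[[i]], sets[[j]]) >= thr) adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  if (!any(adj)) return(NULL)
  gthr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(gthr)$membership
  mapping <- stats::setNames(net$events$event_id, net$events$event_id)
  clusters <- list()
  drop_ids <- character(0)
  new_events <- net$events
  ann <- net$annotation
  links <- igraph::as_data_frame(net$graph, what = "edges")
  names(links) <- c("upstream_event_id", "downstream_event_id")
  for (k in unique(comp)) {
    members <- ids[comp == k]
    if (length(members) < 2) next
    merged_id <- paste0("CKE[", paste(sort(members), collapse = "+"), "]")
    gene_union <- sort(unique(unlist(sets[members], use.names = FALSE)))
    types <- unique(net$events$event_type[net$events$event_id %in% members])
    mtype <- if (length(types) == 1) types else "KE"
    clusters[[length(clusters) + 1L]] <-
      list(merged_event_id = merged_id, member_event_ids = members,
           gene_set = gene_union)
    mapping[members] <- merged_id
    drop_ids <- c(drop_ids, members)
    new_events <- rbind(new_events, data.frame(
      event_id = merged_id, event_type = mtype,
      label = paste(net$events$label[match(sort(members), net$events$event_id)],
                    collapse = " / "),
      stringsAsFactors = FALSE))
    ann[[merged_id]] <- gene_union
  }
  new_events <- new_events[!new_events$event_id %in% drop_ids, , drop = FALSE]
  ann <- ann[setdiff(names(ann), drop_ids)]
  links$upstream_event_id <- unname(mapping[links$upstream_event_id])
  links$downstream_event_id <- unname(mapping[links$downstream_event_id])
  links <- unique(links[links$upstream_event_id != links$downstream_event_id, ,
                        drop = FALSE])
  list(network = aop_network(new_events, links, ann, net$annotation_source),
       clusters = clusters, mapping = mapping)
}

#' Undirected distance from an event to the nearest of a set of events
#'
#' Shortest-path length in links on the undirected view of the AOP graph
#' (prioritization walks both with and against the causal direction).
#'
#' @param net an [aop_network()].
#' @param from_id a single event id.
#' @param to_ids character vector of target event ids.
#' @return the minimum path length (0 if `from_id` is in `to_ids`), or `Inf`
#'   if no target is reachable.
#' @export
event_distance <- function(net, from_id, to_ids) {
  stopifnot(inherits(net, "aop_network"))
  all_ids <- net$events$event_id
  unknown <- setdiff(c(from_id, to_ids), all_ids)
  if (length(unknown))
    stopf("unknown event id(s): %s", paste(unknown, collapse = ", "))
  g <- igraph::as_undirected(net$graph, mode = "collapse")
  d <- igraph::distances(g, v = from_id, to = to_ids)
  min(d)
}
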