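#' Topological enrichment of AOP key events in a co-expression network
#'
#' For every key event with at least two annotated genes present in the
#' input network, the multiset of finite pairwise shortest-path lengths
#' among those genes is compared against `n_draws` random node sets of the
#' same size drawn from the network's node universe. Each draw contributes
#' one Welch t-test between the two path-length multisets; `p_avg` is the
#' mean of the draw p-values and `ratio` is the key event's mean path
#' length over the mean of the random-set means. A ratio below 1 means the
#' event's genes sit closer together than chance. `p_adj` is
#' Benjamini-Hochberg across scored events; the pipeline's `enriched` call
#' requires both `ratio < 1` and `p_adj <= alpha` (the bare ratio rule is
#' reported as `enriched_raw`).
#'
#' Unreachable gene pairs are excluded from the path multisets; an event
#' (or a draw) with fewer than two reachable pairs is skipped, with the
#' reason recorded in the `skipped` attribute.
#'
#' @param net a `coexpression_network` (or any igraph wrapped the same way).
#' @param aop an [aop_network()].
#' @param n_draws number of random gene sets per event (default 1000).
#' @param seed integer seed governing the random draws.
#' @param alpha FDR level entering the `enriched` call (default 0.05).
#' @param event_types which event types to score (default `"KE"`).
#' @return data.frame with columns `event_id`, `event_type`,
#'   `n_genes_annotated`, `n_genes_in_network`, `n_pairs_used`,
#'   `mean_sp_ke`, `mean_sp_rand`, `ratio`, `p_avg`, `p_adj`,
#'   `enriched_raw`, `enriched`, plus a list column `genes` of the genes
#'   present in the network; attribute `skipped` is a data.frame of skipped
#'   events with reasons.
#' @export
topological_enrichment <- function(net, aop, n_draws = 1000, seed = 1,
                                   alpha = 0.05, event_types = "KE") {
  stopifnot(inherits(net, "coexpression_network"), inherits(aop, "aop_network"))
  if (n_draws < 2) stopf("n_draws must be >= 2")
  g <- net$graph
  nodes <- igraph::V(g)$name
  if (length(nodes) < 3) stopf("input network too small to score")
  D <- igraph::distances(g)
  cand <- aop$events$event_id[aop$events$event_type %in% event_types &
                                lengths(aop$annotation[aop$events$event_id]) > 0]
  skipped <- list()
  rows <- list()
  for (ev in cand) {
      genes_all <- aop$annotation[[ev]]
      genes <- intersect(genes_all, nodes)
      if (length(genes) < 2) {
        skipped[[ev]] <- "<2 annotated genes in network"
        next
      }
      # per-event RNG stream derived from the gene set, so the record is a
      # pure function of (network, gene set, seed): identical sets give
      # identical records regardless of event id or iteration order
      ev_seed <- (as.integer(seed) +
                    sum(vapply(sort(genes), function(g)
                      sum(utf8ToInt(g)), numeric(1)))) %% .Machine$integer.max
      sub <- D[genes, genes]
      ke_paths <- sub[upper.tri(sub)]
      ke_paths <- ke_paths[is.finite(ke_paths)]
      if (length(ke_paths) < 2) {
        skipped[[ev]] <- "<2 connected gene pairs in network"
        next
      }
      m_ke <- mean(ke_paths); v_ke <- stats::var(ke_paths)
      sz <- length(genes)
      draw_means <- rep(NA_real_, n_draws)
      draw_p <- rep(NA_real_, n_draws)
      withr::with_seed(ev_seed, {
        for (b in seq_len(n_draws)) {
          s <- sample(nodes, sz)
          ds <- D[s, s]
          vals <- ds[upper.tri(ds)]
          vals <- vals[is.finite(vals)]
          if (length(vals) < 2) next
          draw_means[b] <- mean(vals)
          draw_p[b] <- welch_p(m_ke, v_ke, length(ke_paths),
                               mean(vals), stats::var(vals), length(vals))
        }
      })
      ok <- !is.na(draw_p)
      if (!any(ok)) {
        skipped[[ev]] <- "no usable random draws"
        next
      }
      mean_rand <- mean(draw_means[ok])
      rows[[ev]] <- data.frame(
        event_id = ev,
        event_type = aop$events$event_type[aop$events$event_id == ev],
        n_genes_annotated = length(genes_all),
        n_genes_in_network = sz,
        n_pairs_used = length(ke_paths),
        n_draws_used = sum(ok),
        mean_sp_ke = m_ke,
        mean_sp_rand = mean_rand,
        ratio = m_ke / mean_rand,
        p_avg = mean(draw_p[ok]),
        stringsAsFactors = FALSE)
      rows[[ev]]$genes <- list(genes)
  }
  skipped_df <- if (length(skipped)) {
    data.frame(event_id = names(skipped), reason = unlist(skipped),
               stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(event_id = character(0), reason = character(0))
  }
  if (!length(rows)) {
    out <- data.frame(event_id = character(0), event_type = character(0),
                      n_genes_annotated = integer(0),
                      n_genes_in_network = integer(0),
                      n_pairs_used = integer(0), n_draws_used = integer(0),
                      mean_sp_ke = numeric(0), mean_sp_rand = numeric(0),
                      ratio = numeric(0), p_avg = numeric(0),
                      p_adj = numeric(0), enriched_raw = logical(0),
                      enriched = logical(0))
    out$genes <- list()
    attr(out, "skipped") <- skipped_df
    return(out)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj <- stats::p.adjust(out$p_avg, method = "BH")
  out$enriched_raw <- out$ratio < 1
  out$enriched <- out$enriched_raw & out$p_adj <= alpha
  out <- out[, c("event_id", "event_type", "n_genes_annotated",
                 "n_genes_in_network", "n_pairs_used", "n_draws_used",
                 "mean_sp_ke", "mean_sp_rand", "ratio", "p_avg", "p_adj",
                 "enriched_raw", "enriched", "genes")]
  attr(out, "skipped") <- skipped_df
  out
}

#' Fisher gene-set enrichment of key events
#'
#' Classical one-sided (overrepresentation) Fisher exact test of a DEG list
#' against each annotated event's gene set, on a caller-supplied background
#' (typically the union of the test system's genes and all clustered key
#' event genes). BH adjustment across events.
#'
#' @param degs a `deg_selection` or character vector of genes (subset of
#'   `background`).
#' @param aop an [aop_network()].
#' @param background character vector of background gene ids.
#' @param event_types event types to test (default all three).
#' @return data.frame with `event_id`, `event_type`, `n_genes_annotated`,
#'   `overlap`, `p`, `p_adj`.
#' @export
fisher_enrichment <- function(degs, aop, background,
                              event_types = c("MIE", "KE", "AO")) {
  stopifnot(inherits(aop, "aop_network"))
  genes <- if (inherits(degs, "deg_selection")) degs$genes else as.character(degs)
  background <- unique(as.character(background))
  if (!length(background)) stopf("background must be nonempty")
  if (!all(genes %in% background))
    stopf("DEG list must be a subset of the background")
  n_bg <- length(background)
  n_deg <- length(genes)
  cand <- aop$events$event_id[aop$events$event_type %in% event_types &
                                lengths(aop$annotation[aop$events$event_id]) > 0]
  rows <- lapply(cand, function(ev) {
    ke <- intersect(aop$annotation[[ev]], background)
    if (!length(ke)) return(NULL)
    ov <- length(intersect(genes, ke))
    p <- stats::phyper(ov - 1, length(ke), n_bg - length(ke), n_deg,
                       lower.tail = FALSE)
    data.frame(event_id = ev,
               event_type = aop$events$event_type[aop$events$event_id == ev],
               n_genes_annotated = length(ke), overlap = ov, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(event_id = character(0), event_type = character(0),
                      n_genes_annotated = integer(0), overlap = integer(0),
                      p = numeric(0), p_adj = numeric(0)))
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Filter topologically enriched key events
#'
#' Three sequential filters mirror the reconstruction procedure:
#' (1) discard events with more than `max_genes` annotated genes or
#' adjusted p-value above `alpha`; (2) among survivors keep events whose
#' `p_avg` does not exceed the `percentile`-th percentile of the survivors'
#' `p_avg` distribution (inclusive, so a lone survivor passes its own
#' percentile); (3) discard events none of whose annotated in-network genes
#' reaches `|logFC| >= lfc` in the contrast (aggregation: maximum |logFC|
#' by default, mean via `aggregate = "mean"`).
#'
#' @param records table from [topological_enrichment()].
#' @param contrast table from [differential_expression()].
#' @param max_genes annotation-size cap (default 1000).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param percentile percentile cut on `p_avg` among stage-1 survivors
#'   (default 5).
#' @param lfc absolute log2 fold-change the best annotated gene must reach
#'   (default 0.58).
#' @param aggregate `"max"` (default) or `"mean"` |logFC| over annotated
#'   in-network genes.
#' @return the surviving rows, with attribute `stages` recording survivor
#'   counts after each stage.
#' @export
filter_enriched <- function(records, contrast, max_genes = 1000, alpha = 0.05,
                            percentile = 5, lfc = 0.58, aggregate = "max") {
  stages <- c(input = nrow(records))
  s1 <- records[records$n_genes_annotated <= max_genes &
                  records$p_adj <= alpha & records$ratio < 1, , drop = FALSE]
  stages <- c(stages, size_fdr = nrow(s1))
  if (nrow(s1) == 0) {
    attr(s1, "stages") <- stages
    return(s1)
  }
  s2 <- s1[percentile_keep(s1$p_avg, percentile), , drop = FALSE]
  stages <- c(stages, percentile = nrow(s2))
  if (nrow(s2) == 0) {
    attr(s2, "stages") <- stages
    return(s2)
  }
  agg_fun <- switch(aggregate, max = max, mean = mean,
                    stopf("aggregate must be 'max' or 'mean'"))
  best <- vapply(s2$genes, function(gs) {
    v <- abs(contrast$logFC[match(gs, contrast$gene)])
    v <- v[!is.na(v)]
    if (!length(v)) 0 else agg_fun(v)
  }, numeric(1))
  s3 <- s2[best >= lfc, , drop = FALSE]
  stages <- c(stages, logfc = nrow(s3))
  attr(s3, "stages") <- stages
  s3
}

#' Write an enrichment table (list column flattened)
#'
#' @param records enrichment table.
#' @param path output path.
#' @param config,seed provenance fields.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(records, path, config = list(), seed = NULL) {
  flat <- records
  flat$genes <- vapply(records$genes, paste, "", collapse = ",")
  write_tsv_prov(flat, path, config, seed)
}
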