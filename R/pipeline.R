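#' Run the full MOA reconstruction pipeline for one exposure
#'
#' Chains the framework stages: exposed-vs-control contrast, top/bottom
#' seed-gene selection, pairwise Hotelling co-expression network,
#' topological key-event enrichment, the three-stage enrichment filter,
#' MIE/AO prioritization and MOA assembly.
#'
#' @param study an [expression_study()].
#' @param aop an [aop_network()].
#' @param k seed genes per fold-change side (default 100).
#' @param edge_percentile percentile cut for edge retention (default 5).
#' @param n_draws random sets per key event in the enrichment (default
#'   1000).
#' @param seed integer seed (random draws only; all other stages are
#'   deterministic).
#' @param alpha,percentile,lfc,max_genes enrichment-filter parameters (see
#'   [filter_enriched()]).
#' @param max_events terminal cap per type (see [prioritize_terminals()]).
#' @return list with `contrast`, `seeds`, `network`, `enrichment`,
#'   `enriched` (filtered), `terminals`, `moa`.
#' @export
run_moa_pipeline <- function(study, aop, k = 100, edge_percentile = 5,
                             n_draws = 1000, seed = 1, alpha = 0.05,
                             percentile = 5, lfc = 0.58, max_genes = 1000,
                             max_events = 20) {
  contrast <- differential_expression(study)
  seeds <- select_top_bottom(contrast, k = k)
  net <- infer_network(study, seeds, edge_percentile = edge_percentile,
                       contrast = contrast)
  enr <- topological_enrichment(net, aop, n_draws = n_draws, seed = seed,
                                alpha = alpha)
  kept <- filter_enriched(enr, contrast, max_genes = max_genes, alpha = alpha,
                          percentile = percentile, lfc = lfc)
  terms <- if (nrow(kept)) {
    prioritize_terminals(kept, aop, contrast, max_events = max_events)
  } else {
    data.frame(event_id = character(0), event_type = character(0),
               best_gene_p = numeric(0), dist_to_enriched = numeric(0),
               gene_set_size = integer(0), rank = integer(0))
  }
  moa <- assemble_moa(kept, terms, aop, exposure_id = study$study_id)
  list(contrast = contrast, seeds = seeds, network = net, enrichment = enr,
       enriched = kept, terminals = terms, moa = moa)
}
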