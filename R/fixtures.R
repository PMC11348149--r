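#' Specification of a synthetic toxicogenomics world
#'
#' Describes a seeded toy world: a gene universe, planted
#' MIE -> KE -> AO chains whose key-event gene modules are co-deregulated
#' in the exposed group, decoy events with random annotations, and a
#' 3-replicate control/exposed expression design. Defaults mirror a
#' desk-scale version of typical exposure transcriptomics: 3 replicates
#' per condition, a module shift of 2 on the log2 scale against a
#' replicate noise SD of 0.3 (a clearly responsive module over technical
#' noise), and a shared latent factor inducing within-module
#' co-deregulation.
#'
#' @param n_genes size of the gene universe (default 500).
#' @param n_chains number of planted MIE -> KE -> AO chains (default 1).
#' @param module_size genes per planted key-event module (default 20).
#' @param terminal_genes genes annotated to each planted MIE and AO, drawn
#'   from its chain's module (default 6).
#' @param n_decoy_chains decoy MIE -> KE -> AO chains annotated with
#'   unshifted genes (default 6).
#' @param decoy_genes genes annotated per decoy event (default 10).
#' @param effect_size mean log2 shift of planted module genes (default 2).
#' @param noise_sd replicate noise SD (default 0.3).
#' @param latent_sd SD of the shared module factor (default 0.1; kept
#'   below the replicate noise because the Hotelling statistic discounts
#'   mean shifts lying along directions of high pooled covariance, so a
#'   strong shared factor would mask the very signal it is meant to
#'   create).
#' @param n_replicates replicates per condition (default 3; >= 2).
#' @param baseline_mean,baseline_sd per-gene baseline log2 expression
#'   distribution (defaults 7 and 0.5).
#' @param seed integer seed; all randomness derives from it.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_genes = 500, n_chains = 1, module_size = 20,
                         terminal_genes = 6, n_decoy_chains = 6,
                         decoy_genes = 10, effect_size = 2, noise_sd = 0.3,
                         latent_sd = 0.1, n_replicates = 3,
                         baseline_mean = 7, baseline_sd = 0.5, seed = 1) {
  if (n_replicates < 2) stopf("n_replicates must be >= 2")
  if (effect_size < 0) stopf("effect_size must be >= 0")
  need <- n_chains * module_size + n_decoy_chains * decoy_genes
  if (need > n_genes)
    stopf("gene universe too small: need %d, have %d", need, n_genes)
  structure(list(n_genes = n_genes, n_chains = n_chains,
                 module_size = module_size, terminal_genes = terminal_genes,
                 n_decoy_chains = n_decoy_chains, decoy_genes = decoy_genes,
                 effect_size = effect_size, noise_sd = noise_sd,
                 latent_sd = latent_sd, n_replicates = n_replicates,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 seed = seed),
            class = "fixture_spec")
}

fixture_genes <- function(spec) {
  sprintf("g%04d", seq_len(spec$n_genes))
}

# Gene indices of planted module i (blocks at the start of the universe,
# decoy annotations drawn from the remainder).
planted_module_idx <- function(spec, chain) {
  (chain - 1) * spec$module_size + seq_len(spec$module_size)
}

#' Build a toy AOP network with planted chains and decoys
#'
#' Planted chains are paths `MIEi -> KEi -> AOi`; each KE is annotated
#' with its module genes and the MIE/AO with disjoint subsets of that
#' module (so terminal events carry responsive genes without being
#' near-duplicates of the KE). Decoy chains have the same shape but are
#' annotated with genes that never receive an exposure shift.
#' Deterministic under the spec seed.
#'
#' @param spec a [fixture_spec()].
#' @return an [aop_network()].
#' @export
make_toy_aop <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  genes <- fixture_genes(spec)
  withr::with_seed(spec$seed + 1L, {
    events <- list(); links <- list(); ann <- list()
    for (i in seq_len(spec$n_chains)) {
      mie <- sprintf("MIE%02d", i); ke <- sprintf("KE%02d", i)
      ao <- sprintf("AO%02d", i)
      events[[length(events) + 1L]] <- data.frame(
        event_id = c(mie, ke, ao), event_type = c("MIE", "KE", "AO"),
        stringsAsFactors = FALSE)
      links[[length(links) + 1L]] <- data.frame(
        upstream_event_id = c(mie, ke), downstream_event_id = c(ke, ao),
        stringsAsFactors = FALSE)
      mod <- genes[planted_module_idx(spec, i)]
      tg <- min(spec$terminal_genes, floor(length(mod) / 2))
      ann[[ke]] <- mod
      ann[[mie]] <- utils::head(mod, tg)
      ann[[ao]] <- utils::tail(mod, tg)
    }
    decoy_pool <- genes[-(seq_len(spec$n_chains * spec$module_size))]
    for (j in seq_len(spec$n_decoy_chains)) {
      mie <- sprintf("dMIE%02d", j); ke <- sprintf("dKE%02d", j)
      ao <- sprintf("dAO%02d", j)
      events[[length(events) + 1L]] <- data.frame(
        event_id = c(mie, ke, ao), event_type = c("MIE", "KE", "AO"),
        stringsAsFactors = FALSE)
      links[[length(links) + 1L]] <- data.frame(
        upstream_event_id = c(mie, ke), downstream_event_id = c(ke, ao),
        stringsAsFactors = FALSE)
      ann[[ke]] <- sample(decoy_pool, spec$decoy_genes)
      ann[[mie]] <- sample(decoy_pool, max(2, floor(spec$decoy_genes / 2)))
      ann[[ao]] <- sample(decoy_pool, max(2, floor(spec$decoy_genes / 2)))
    }
    aop_network(do.call(rbind, events), do.call(rbind, links), ann,
                annotation_source = sprintf("synthetic fixture seed=%d", spec$seed))
  })
}

#' Simulate a control/exposed expression study with planted modules
#'
#' Control replicates are per-gene baselines plus Gaussian replicate
#' noise. Exposed replicates add, for every planted key-event module, a
#' mean shift of `effect_size` plus a shared latent factor per replicate
#' (loading 1 on module genes), which induces both differential
#' expression and within-module co-deregulation, the bivariate mean shifts
#' the pairwise Hotelling test detects. All other genes are i.i.d. noise.
#' Deterministic under the spec seed.
#'
#' @param spec a [fixture_spec()].
#' @param aop optional toy AOP from [make_toy_aop()] (only used for the
#'   study id provenance; the planted modules are defined by the spec).
#' @return an [expression_study()].
#' @export
simulate_study <- function(spec, aop = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  genes <- fixture_genes(spec)
  nr <- spec$n_replicates
  withr::with_seed(spec$seed + 2L, {
    baseline <- stats::rnorm(spec$n_genes, spec$baseline_mean, spec$baseline_sd)
    ctrl <- baseline + matrix(stats::rnorm(spec$n_genes * nr, 0, spec$noise_sd),
                              spec$n_genes, nr)
    expo <- baseline + matrix(stats::rnorm(spec$n_genes * nr, 0, spec$noise_sd),
                              spec$n_genes, nr)
    for (i in seq_len(spec$n_chains)) {
      idx <- planted_module_idx(spec, i)
      z <- stats::rnorm(nr, 0, spec$latent_sd)
      expo[idx, ] <- expo[idx, ] + spec$effect_size +
        matrix(z, length(idx), nr, byrow = TRUE)
    }
    m <- cbind(ctrl, expo)
    rownames(m) <- genes
    colnames(m) <- c(paste0("ctrl_", seq_len(nr)), paste0("exp_", seq_len(nr)))
    meta <- data.frame(
      sample_id = colnames(m),
      condition = rep(c("control", "exposed"), each = nr),
      exposure = sprintf("synthetic_seed%d", spec$seed),
      dose = rep(c(0, 1), each = nr), time = 24,
      stringsAsFactors = FALSE)
    expression_study(m, meta, study_id = sprintf("synthetic_seed%d", spec$seed))
  })
}

#' Write a complete fixture directory
#'
#' Materializes every standard framework input for a spec: expression
#' matrix, sample metadata, AOP edge table, KE gene annotation and a small
#' GMT of pathway sets (the planted modules plus random decoy sets).
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly; files `matrix.tsv`, `metadata.tsv`,
#'   `aop_edges.tsv`, `aop_annotation.tsv`, `pathways.gmt`.
#' @export
write_fixture_dir <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  aop <- make_toy_aop(spec)
  study <- simulate_study(spec, aop)
  cfg <- unclass(spec)
  write_expression_study(study, file.path(dir, "matrix.tsv"),
                         file.path(dir, "metadata.tsv"), cfg, spec$seed)
  el <- igraph::as_data_frame(aop$graph, what = "edges")
  ev <- aop$events
  edge_tab <- data.frame(
    upstream_event_id = el$from, downstream_event_id = el$to,
    upstream_type = ev$event_type[match(el$from, ev$event_id)],
    downstream_type = ev$event_type[match(el$to, ev$event_id)],
    stringsAsFactors = FALSE)
  write_tsv_prov(edge_tab, file.path(dir, "aop_edges.tsv"), cfg, spec$seed)
  ann_tab <- do.call(rbind, lapply(names(aop$annotation), function(e) {
    gs <- aop$annotation[[e]]
    if (!length(gs)) return(NULL)
    data.frame(event_id = e, gene = gs, stringsAsFactors = FALSE)
  }))
  write_tsv_prov(ann_tab, file.path(dir, "aop_annotation.tsv"), cfg, spec$seed)
  sets <- withr::with_seed(spec$seed + 3L, {
    genes <- fixture_genes(spec)
    s <- lapply(seq_len(spec$n_chains), function(i)
      genes[planted_module_idx(spec, i)])
    names(s) <- sprintf("planted_module_%02d", seq_len(spec$n_chains))
    decoys <- lapply(1:4, function(j) sample(genes, 15))
    names(decoys) <- sprintf("decoy_pathway_%02d", 1:4)
    c(s, decoys)
  })
  write_gmt(sets, file.path(dir, "pathways.gmt"))
  invisible(dir)
}
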