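#' Expression studies
#'
#' An `expression_study` is the unit of one exposure: a genes x samples
#' matrix of log2 expression values plus per-sample metadata with a
#' `condition` column (`"control"` / `"exposed"`), an exposure label and
#' numeric dose and time. Three replicates per condition is the design the
#' framework targets, but any >= 2 per condition is accepted for contrasts.
#'
#' @param matrix numeric matrix, rows = genes (unique rownames), columns =
#'   samples.
#' @param sample_meta data.frame with columns `sample_id`, `condition` and
#'   optionally `exposure`, `dose`, `time`. `sample_id` must match the
#'   matrix column names (order taken from the metadata and never silently
#'   changed).
#' @param study_id identifier string.
#' @return object of class `expression_study`.
#' @export
expression_study <- function(matrix, sample_meta, study_id = "study") {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  if (is.null(rownames(matrix)) || anyDuplicated(rownames(matrix)))
    stopf("matrix must have unique gene rownames")
  if (!all(c("sample_id", "condition") %in% names(sample_meta)))
    stopf("sample_meta must have columns sample_id, condition")
  if (!setequal(sample_meta$sample_id, colnames(matrix)))
    stopf("sample_meta sample_id must match matrix column names")
  if (!all(sample_meta$condition %in% c("control", "exposed")))
    stopf("condition must be 'control' or 'exposed'")
  matrix <- matrix[, sample_meta$sample_id, drop = FALSE]
  if (!"exposure" %in% names(sample_meta)) sample_meta$exposure <- study_id
  if (!"dose" %in% names(sample_meta)) sample_meta$dose <- NA_real_
  if (!"time" %in% names(sample_meta)) sample_meta$time <- NA_real_
  structure(list(matrix = matrix, sample_meta = sample_meta,
                 study_id = study_id),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("expression_study '%s': %d genes x %d samples (%d control, %d exposed)\n",
              x$study_id, nrow(x$matrix), ncol(x$matrix),
              sum(x$sample_meta$condition == "control"),
              sum(x$sample_meta$condition == "exposed")))
  invisible(x)
}

#' Read an expression study from delimited text
#'
#' The matrix file is tab-separated with the gene id in the first column and
#' one column per sample; the metadata file has columns `sample_id`,
#' `condition`, and optionally `exposure`, `dose`, `time`.
#'
#' @param matrix_path path to the expression matrix.
#' @param meta_path path to the sample metadata.
#' @param study_id study identifier (defaults to the matrix file name).
#' @return an [expression_study()].
#' @export
read_expression_study <- function(matrix_path, meta_path,
                                  study_id = basename(matrix_path)) {
  tab <- read_tsv_prov(matrix_path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  meta <- read_tsv_prov(meta_path)
  expression_study(m, meta, study_id)
}

#' Write an expression study to delimited text
#'
#' @param study an [expression_study()].
#' @param matrix_path,meta_path output paths.
#' @param config,seed provenance header fields (see [write_tsv_prov()]).
#' @return invisibly, the matrix path.
#' @export
write_expression_study <- function(study, matrix_path, meta_path,
                                   config = list(), seed = NULL) {
  df <- data.frame(gene = rownames(study$matrix), study$matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_prov(df, matrix_path, config, seed)
  write_tsv_prov(study$sample_meta, meta_path, config, seed)
  invisible(matrix_path)
}

#' Exposed-vs-control contrast per gene
#'
#' Ordinary per-gene linear-model contrast: `logFC` is the difference of
#' condition means on the log2 scale and the two-sided p-value comes from
#' the pooled-variance t statistic with `n - 2` degrees of freedom;
#' `p_adj` is Benjamini-Hochberg across all genes. This deliberately avoids
#' any empirical-Bayes variance moderation: downstream steps consume only
#' ranks and thresholds, and a plain contrast keeps the statistic free of
#' hidden hyper-parameters. Genes with zero residual variance and a nonzero
#' mean difference get the smallest positive p and are flagged in the
#' `degenerate` column.
#'
#' @param study an [expression_study()] with >= 2 replicates per condition.
#' @return data.frame with columns `gene`, `logFC`, `t`, `p`, `p_adj`,
#'   `degenerate`, one row per gene.
#' @export
differential_expression <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  cond <- study$sample_meta$condition
  n0 <- sum(cond == "control"); n1 <- sum(cond == "exposed")
  if (n0 < 2 || n1 < 2)
    stopf("need >= 2 replicates per condition (control: %d, exposed: %d)", n0, n1)
  x0 <- study$matrix[, cond == "control", drop = FALSE]
  x1 <- study$matrix[, cond == "exposed", drop = FALSE]
  m0 <- rowMeans(x0); m1 <- rowMeans(x1)
  v0 <- apply(x0, 1, stats::var); v1 <- apply(x1, 1, stats::var)
  sp2 <- ((n0 - 1) * v0 + (n1 - 1) * v1) / (n0 + n1 - 2)
  d <- m1 - m0
  se <- sqrt(sp2 * (1 / n0 + 1 / n1))
  tt <- ifelse(se > 0, d / se, ifelse(abs(d) < .Machine$double.eps, 0, Inf))
  p <- 2 * stats::pt(-abs(tt), df = n0 + n1 - 2)
  degen <- se == 0 & abs(d) >= .Machine$double.eps
  p[degen] <- .Machine$double.xmin
  if (any(degen))
    warnf("%d gene(s) with zero residual variance flagged as degenerate", sum(degen))
  data.frame(gene = rownames(study$matrix), logFC = d, t = tt, p = p,
             p_adj = stats::p.adjust(p, method = "BH"),
             degenerate = degen, row.names = NULL, stringsAsFactors = FALSE)
}

deg_selection <- function(genes, direction, criterion) {
  structure(list(genes = genes, direction = direction, criterion = criterion),
            class = "deg_selection")
}

#' @export
print.deg_selection <- function(x, ...) {
  cat(sprintf("deg_selection: %d genes (direction: %s)\n",
              length(x$genes), x$direction))
  invisible(x)
}

#' Threshold filter for differentially expressed genes
#'
#' Keeps genes with `p < p_thresh` and `|logFC| > lfc_thresh` (both strict).
#' The raw p-value is used by default; set `use_adjusted = TRUE` to filter
#' on `p_adj` instead.
#'
#' @param rows contrast table from [differential_expression()].
#' @param p_thresh p-value cutoff (default 0.05).
#' @param lfc_thresh absolute log2 fold-change cutoff (default 0.58).
#' @param use_adjusted filter on BH-adjusted p-values instead of raw.
#' @param direction `"both"` (default), `"up"` or `"down"`.
#' @return a `deg_selection` (ordered by increasing p).
#' @export
filter_degs <- function(rows, p_thresh = 0.05, lfc_thresh = 0.58,
                        use_adjusted = FALSE, direction = "both") {
  stopifnot(p_thresh > 0, lfc_thresh > 0)
  pv <- if (use_adjusted) rows$p_adj else rows$p
  keep <- pv < p_thresh & abs(rows$logFC) > lfc_thresh
  keep <- keep & switch(direction,
    both = TRUE, up = rows$logFC > 0, down = rows$logFC < 0,
    stopf("direction must be 'both', 'up' or 'down'"))
  sel <- rows[keep, , drop = FALSE]
  sel <- sel[order(pv[keep], sel$gene), , drop = FALSE]
  deg_selection(sel$gene, direction,
                list(method = "threshold", p_thresh = p_thresh,
                     lfc_thresh = lfc_thresh,
                     p_used = if (use_adjusted) "adjusted" else "raw"))
}

# Composite rank (mean of |logFC|-descending and p-ascending ranks) within
# one sign; deterministic order: rank, then gene id.
rank_side <- function(rows) {
  r_fc <- rank(-abs(rows$logFC), ties.method = "average")
  r_p <- rank(rows$p, ties.method = "average")
  comp <- (r_fc + r_p) / 2
  rows$composite_rank <- comp
  rows[order(comp, rows$gene), , drop = FALSE]
}

#' Select the top and bottom deregulated genes
#'
#' Genes are ranked within each fold-change sign by the mean of two ranks:
#' |logFC| descending and p ascending. The `k` best up-regulated and `k`
#' best down-regulated genes seed the co-expression network (default
#' k = 100 per side). Genes with `logFC` exactly 0 belong to neither side.
#' Ties are broken lexicographically on gene id for reproducibility.
#'
#' @param rows contrast table from [differential_expression()].
#' @param k genes per side (default 100); truncated with a warning when a
#'   side has fewer candidates.
#' @return a `deg_selection` (up-regulated genes first, each side in rank
#'   order).
#' @export
select_top_bottom <- function(rows, k = 100) {
  if (!is.numeric(k) || length(k) != 1 || k <= 0 || k != round(k))
    stopf("k must be a positive integer")
  up <- rank_side(rows[rows$logFC > 0, , drop = FALSE])
  dn <- rank_side(rows[rows$logFC < 0, , drop = FALSE])
  if (nrow(up) < k || nrow(dn) < k)
    warnf("fewer than k=%d genes on a side (up: %d, down: %d); truncating",
          k, nrow(up), nrow(dn))
  genes <- unique(c(utils::head(up$gene, k), utils::head(dn$gene, k)))
  deg_selection(genes, "both",
                list(method = "top_bottom", k = k,
                     n_up = min(k, nrow(up)), n_down = min(k, nrow(dn))))
}
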