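# Internal helpers shared across modules.

# Welch two-sample p-value from summary statistics. Degenerate case (both
# variances zero) collapses to an equality test; p is kept in (0, 1].
welch_p <- function(m1, v1, n1, m2, v2, n2) {
  if (n1 < 2L || n2 < 2L) return(NA_real_)
  se2 <- v1 / n1 + v2 / n2
  if (se2 <= 0) {
    return(if (isTRUE(all.equal(m1, m2))) 1 else 1e-300)
  }
  tt <- (m1 - m2) / sqrt(se2)
  a <- v1 / n1
  b <- v2 / n2
  df <- se2^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tt), df = df)
  max(p, 1e-300)
}

# Count of values strictly below the type-7 q-th percentile of x.
strict_percentile_cut <- function(x, percentile) {
  thr <- stats::quantile(x, percentile / 100, type = 7, names = FALSE)
  x < thr
}

# Inclusive variant used where a singleton survivor must be able to pass.
percentile_keep <- function(x, percentile) {
  thr <- stats::quantile(x, percentile / 100, type = 7, names = FALSE)
  x <= thr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical unordered edge key "a|b" with a < b lexicographically.
edge_key <- function(a, b) {
  ifelse(a < b, paste(a, b, sep = "|"), paste(b, a, sep = "|"))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# ---- tabular IO with provenance headers ------------------------------------

moanet_version <- function() {
  as.character(utils::packageVersion("moanet"))
}

# Hash of the effective configuration: canonical "key=value" lines, md5.
# Input/output locations are excluded so equivalent runs in different
# directories stay byte-identical.
config_path_keys <- c("matrix", "metadata", "aop_edges", "aop_annotation",
                      "network", "networks", "contrast", "enrichment",
                      "moa_table", "moa_table_b", "pathways", "out_dir")

config_hash <- function(config) {
  config <- config[!names(config) %in% config_path_keys]
  if (length(config) == 0) return("empty")
  keys <- sort(names(config))
  canon <- paste(keys, vapply(config[keys], function(v)
    paste(format(v, digits = 15), collapse = ","), ""), sep = "=")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(canon, tf)
  unname(tools::md5sum(tf))
}

provenance_header <- function(config = list(), seed = NULL) {
  c(sprintf("# moanet %s", moanet_version()),
    sprintf("# config_hash=%s", config_hash(config)),
    sprintf("# seed=%s", if (is.null(seed)) "none" else format(seed)))
}

#' Write a table with a provenance header
#'
#' Tab-separated output preceded by `#`-prefixed comment lines recording the
#' package version, a hash of the effective configuration and the seed, so
#' that identically configured runs are byte-identical.
#'
#' @param df data.frame to write.
#' @param path output file path.
#' @param config named list of effective parameters (hashed into the header).
#' @param seed integer seed used for the run, or `NULL`.
#' @return `path`, invisibly.
#' @export
write_tsv_prov <- function(df, path, config = list(), seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(config, seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table, skipping provenance comments
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv_prov <- function(path) {
  if (!file.exists(path)) stopf("input file not found: %s", path)
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    quote = "")
}
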