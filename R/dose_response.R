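#' Dose series for one gene
#'
#' @param gene gene identifier.
#' @param doses numeric vector of distinct dose levels (>= 3, including 0).
#' @param responses numeric matrix of replicate log-expression values, one
#'   row per dose level.
#' @return object of class `dose_series` with flat `dose` / `response`
#'   observation vectors.
#' @export
dose_series <- function(gene, doses, responses) {
  responses <- as.matrix(responses)
  if (length(doses) != nrow(responses))
    stopf("responses must have one row per dose level")
  if (length(unique(doses)) < 3) stopf("need >= 3 distinct dose levels")
  if (!any(doses == 0)) stopf("dose 0 (control) must be present")
  structure(list(gene = gene, doses = doses, responses = responses,
                 dose = rep(doses, ncol(responses)),
                 response = as.vector(responses)),
            class = "dose_series")
}

# Model family: least-squares fits under constant variance. Each entry
# fits and returns a list(fit, predict(d), n_par) or NULL on failure.
bmd_models <- function() {
  list(
    linear = function(d, y) {
      fit <- stats::lm(y ~ d)
      co <- stats::coef(fit)
      list(fit = fit, f = function(x) co[1] + co[2] * x, n_par = 2L)
    },
    power = function(d, y) {
      lin <- stats::coef(stats::lm(y ~ d))
      fit <- stats::nls(y ~ a + b * d^c,
                        start = list(a = lin[1], b = lin[2], c = 1),
                        lower = c(-Inf, -Inf, 0.1), upper = c(Inf, Inf, 4),
                        algorithm = "port",
                        control = stats::nls.control(warnOnly = TRUE))
      co <- stats::coef(fit)
      list(fit = fit, f = function(x) co["a"] + co["b"] * x^co["c"], n_par = 3L)
    },
    exponential = function(d, y) {
      a0 <- mean(y[d == 0])
      fit <- stats::nls(y ~ a * exp(b * d),
                        start = list(a = a0, b = 0.01),
                        control = stats::nls.control(warnOnly = TRUE))
      co <- stats::coef(fit)
      list(fit = fit, f = function(x) co["a"] * exp(co["b"] * x), n_par = 2L)
    },
    hill = function(d, y) {
      a0 <- mean(y[d == 0])
      bmax <- mean(y[d == max(d)]) - a0
      if (abs(bmax) < 1e-8) bmax <- sign(bmax + 1e-12) * 1e-3
      k0 <- stats::median(d[d > 0])
      fit <- stats::nls(y ~ a + b * d^c / (k^c + d^c),
                        start = list(a = a0, b = bmax, c = 1, k = k0),
                        lower = c(-Inf, -Inf, 0.5, min(d[d > 0]) / 10),
                        upper = c(Inf, Inf, 8, max(d) * 10),
                        algorithm = "port",
                        control = stats::nls.control(warnOnly = TRUE))
      co <- stats::coef(fit)
      list(fit = fit,
           f = function(x) co["a"] + co["b"] * x^co["c"] / (co["k"]^co["c"] + x^co["c"]),
           n_par = 4L)
    })
}

fit_one_model <- function(name, d, y) {
  tryCatch({
    # port-algorithm convergence chatter is expected for flat genes
    m <- suppressWarnings(bmd_models()[[name]](d, y))
    m$aic <- stats::AIC(m$fit)
    m$sigma <- sqrt(sum(stats::resid(m$fit)^2) / (length(y) - m$n_par))
    m$sse <- sum(stats::resid(m$fit)^2)
    m$name <- name
    m
  }, error = function(e) NULL)
}

# First dose in (0, max_dose] where |f(d) - f(0)| reaches bmr; NA when the
# deviation never reaches bmr on the range.
solve_bmd <- function(f, bmr, max_dose) {
  g <- function(d) abs(f(d) - f(0)) - bmr
  grid <- seq(0, max_dose, length.out = 256)
  vals <- vapply(grid, g, numeric(1))
  hit <- which(vals >= 0)[1]
  if (is.na(hit) || hit == 1) return(NA_real_)
  stats::uniroot(g, lower = grid[hit - 1], upper = grid[hit])$root
}

pure_error_lof <- function(d, y, sse, n_par) {
  levels_ <- split(y, d)
  sspe <- sum(vapply(levels_, function(v) sum((v - mean(v))^2), numeric(1)))
  dfpe <- length(y) - length(levels_)
  dflof <- length(levels_) - n_par
  if (dfpe <= 0 || dflof <= 0) return(1)
  sslof <- max(sse - sspe, 0)
  if (sspe == 0) return(if (sslof == 0) 1 else .Machine$double.xmin)
  fstat <- (sslof / dflof) / (sspe / dfpe)
  stats::pf(fstat, dflof, dfpe, lower.tail = FALSE)
}

#' Fit a benchmark-dose model to one gene's dose series
#'
#' Fits linear, power, exponential and Hill models by least squares under
#' constant variance, keeps the minimum-AIC fit, and inverts it at the
#' benchmark response `BMR = bmrf * sigma` (residual SD; `bmrf = 1.349`
#' corresponds to a minimum 10% deviation from control under normality).
#' The benchmark dose solves `|f(bmd) - f(0)| = BMR` (two-sided, absolute
#' deviation). Lower/upper bounds `bmdl`/`bmdu` are the 2.5/97.5
#' percentiles of a seeded nonparametric bootstrap (replicates resampled
#' within dose levels, the selected model refit). The lack-of-fit p-value
#' is the standard pure-error F test.
#'
#' @param series a [dose_series()].
#' @param max_dose highest dose considered (default: max of the series).
#' @param bmrf benchmark response factor (default 1.349).
#' @param n_boot bootstrap resamples for the confidence bounds (default
#'   250; 0 skips the bounds).
#' @param seed integer seed for the bootstrap.
#' @return one-row data.frame: `gene`, `model`, `aic`, `lof_p`, `bmd`,
#'   `bmdl`, `bmdu`, `passed` (`TRUE` when a benchmark dose was found on
#'   the dose range).
#' @export
fit_bmd <- function(series, max_dose = max(series$doses), bmrf = 1.349,
                    n_boot = 250, seed = 1) {
  stopifnot(inherits(series, "dose_series"))
  if (bmrf <= 0) stopf("bmrf must be positive")
  d <- series$dose; y <- series$response
  fits <- Filter(Negate(is.null),
                 lapply(names(bmd_models()), fit_one_model, d = d, y = y))
  if (!length(fits)) stopf("all model fits failed for gene %s", series$gene)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "aic"))]]
  bmr <- bmrf * best$sigma
  bmd <- if (bmr > 0) solve_bmd(best$f, bmr, max_dose) else NA_real_
  lof <- pure_error_lof(d, y, best$sse, best$n_par)
  bmdl <- bmdu <- NA_real_
  if (!is.na(bmd) && n_boot > 0) {
    resp <- series$responses
    boot_bmds <- withr::with_seed(seed, vapply(seq_len(n_boot), function(b) {
      rs <- t(apply(resp, 1, function(v) v[sample.int(length(v), replace = TRUE)]))
      yb <- as.vector(rs)
      m <- fit_one_model(best$name, d, yb)
      if (is.null(m)) return(NA_real_)
      bmr_b <- bmrf * m$sigma
      if (bmr_b <= 0) return(NA_real_)
      solve_bmd(m$f, bmr_b, max_dose)
    }, numeric(1)))
    ok <- boot_bmds[is.finite(boot_bmds)]
    if (length(ok) >= 10) {
      q <- stats::quantile(ok, c(0.025, 0.975), names = FALSE)
      bmdl <- q[1]; bmdu <- q[2]
    }
  }
  data.frame(gene = series$gene, model = best$name, aic = best$aic,
             lof_p = lof, bmd = bmd, bmdl = bmdl, bmdu = bmdu,
             passed = !is.na(bmd), stringsAsFactors = FALSE)
}

#' Filter benchmark-dose records with the standard quality rules
#'
#' Keeps genes with lack-of-fit p above 0.01; defined BMD, BMDL and BMDU;
#' BMD and BMDU within the tested dose range; and precision ratios
#' `bmd/bmdl <= 20`, `bmdu/bmd <= 20`, `bmdu/bmdl <= 40`.
#'
#' @param records data.frame of rows from [fit_bmd()].
#' @param max_dose highest exposure dose.
#' @param lof_thresh lack-of-fit cutoff (default 0.01).
#' @return a `deg_selection` of the passing genes (order-independent:
#'   sorted by gene id).
#' @export
filter_bmd_genes <- function(records, max_dose, lof_thresh = 0.01) {
  keep <- records$passed &
    !is.na(records$bmd) & !is.na(records$bmdl) & !is.na(records$bmdu) &
    records$lof_p > lof_thresh &
    records$bmd <= max_dose & records$bmdu <= max_dose &
    records$bmd / records$bmdl <= 20 &
    records$bmdu / records$bmd <= 20 &
    records$bmdu / records$bmdl <= 40
  keep[is.na(keep)] <- FALSE
  deg_selection(sort(records$gene[keep]), "both",
                list(method = "bmd", max_dose = max_dose,
                     lof_thresh = lof_thresh))
}

#' Benchmark-dose screen over an expression matrix
#'
#' Convenience wrapper running [fit_bmd()] on every gene of a dose-series
#' study (metadata `dose` column defines the design).
#'
#' @param study an [expression_study()]-like object whose `sample_meta`
#'   has a numeric `dose` column (condition labels are ignored here).
#' @param bmrf,n_boot,seed passed to [fit_bmd()].
#' @return data.frame of one [fit_bmd()] row per gene.
#' @export
bmd_screen <- function(study, bmrf = 1.349, n_boot = 250, seed = 1) {
  doses <- study$sample_meta$dose
  if (any(is.na(doses))) stopf("all samples need a numeric dose")
  lv <- sort(unique(doses))
  out <- lapply(rownames(study$matrix), function(g) {
    resp <- t(vapply(lv, function(dd) study$matrix[g, doses == dd],
                     numeric(sum(doses == lv[1]))))
    fit_bmd(dose_series(g, lv, resp), max_dose = max(lv), bmrf = bmrf,
            n_boot = n_boot, seed = seed)
  })
  do.call(rbind, out)
}
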