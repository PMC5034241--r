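#' Read a cohort summary table
#'
#' Expects a TSV with header columns `pdb_id`, `g_prime`, `g_mean`,
#' `n_residues`, `human` (logical or 0/1), one row per dimer.
#'
#' @param path TSV file path.
#' @param provenance label recorded on the returned table.
#' @return A `cohort_table` (a data.frame with a `provenance` attribute).
#' @export
read_cohort_table <- function(path, provenance = "user") {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("pdb_id", "g_prime", "g_mean", "n_residues", "human")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("cohort table lacks column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(tab$pdb_id))
    stop("duplicated pdb_id in cohort table")
  if (any(tab$n_residues <= 0)) stop("n_residues must be positive")
  tab$human <- as.logical(tab$human)
  if (anyNA(tab$human) || anyNA(tab$g_prime) || anyNA(tab$g_mean))
    stop("cohort table contains missing values")
  attr(tab, "provenance") <- provenance
  class(tab) <- c("cohort_table", "data.frame")
  tab
}

#' The packaged domain-swapped dimer cohort
#'
#' The published reference cohort of 110 non-redundant domain-swapped dimers
#' with, per dimer, the open-chain Gaussian entanglement G', the
#' closure-averaged linking number G, the chain length N and a human-protein
#' flag. Ships with the package so cohort statistics run with no downloads.
#'
#' @return A `cohort_table` with 110 rows, provenance `"reference_cohort"`.
#' @export
swapped_dimer_cohort <- function() {
  path <- system.file("extdata", "table1_gauss_entanglement.tsv",
                      package = "dimerlink", mustWork = TRUE)
  read_cohort_table(path, provenance = "reference_cohort")
}

#' Entanglement threshold counts over a cohort
#'
#' Counts dimers beyond the |G'| = 1 entanglement thresholds and the
#' negative-G' fractions, overall and split by the human flag. Inequalities
#' are strict, so a dimer sitting exactly on a threshold is not counted as
#' extreme. Percentages are rounded to the nearest integer.
#'
#' @param table a `cohort_table`.
#' @return An object of class `threshold_counts`.
#' @export
threshold_counts <- function(table) {
  stopifnot(inherits(table, "cohort_table"), nrow(table) > 0)
  g <- table$g_prime
  h <- table$human
  one_group <- function(idx) {
    gg <- g[idx]
    list(n = length(gg),
         n_below_minus1 = sum(gg < -1),
         n_above_plus1 = sum(gg > 1),
         n_negative = sum(gg < 0),
         pct_negative = round(100 * sum(gg < 0) / length(gg)),
         pct_extreme = round(100 * sum(abs(gg) > 1) / length(gg)))
  }
  structure(list(total = one_group(rep(TRUE, length(g))),
                 human = one_group(h),
                 non_human = one_group(!h),
                 n_human = sum(h)),
            class = "threshold_counts")
}

#' @export
print.threshold_counts <- function(x, ...) {
  t <- x$total
  cat(sprintf("<threshold_counts> %d dimers (%d human)\n", t$n, x$n_human))
  cat(sprintf("  G' < -1: %d   G' > 1: %d   |G'| > 1: %d%%\n",
              t$n_below_minus1, t$n_above_plus1, t$pct_extreme))
  cat(sprintf("  G' < 0: %d%% overall, %d%% human, %d%% non-human\n",
              t$pct_negative, x$human$pct_negative,
              x$non_human$pct_negative))
  invisible(x)
}

#' Fit a location/scale model to the G' distribution
#'
#' Two fits are offered. `erf_cdf` (the bin-free default) least-squares fits
#' the normal CDF \eqn{F(x) = \frac12[1 + \mathrm{erf}((x-m)/\Delta)]} to the
#' empirical cumulative distribution function evaluated at the sorted sample
#' points (ECDF convention: fraction of values at most x). Both width scales
#' are reported: `sd` is the Gaussian standard deviation and `erf_width` the
#' error-function width \eqn{\Delta = \sqrt{2}\,\sigma} appearing directly in
#' the erf argument — published erf-fit widths for this cohort are on the
#' latter scale. `gaussian_histogram` fits a normal density to a density
#' histogram with bins of width `bin_width` centred on zero; its estimates
#' depend on the binning and are best treated as descriptive.
#'
#' @param values numeric vector (at least 10 values, not all equal).
#' @param fit_kind `"erf_cdf"` or `"gaussian_histogram"`.
#' @param bin_width histogram bin width (ignored for `erf_cdf`).
#' @return An object of class `distribution_fit`: `mean`, `sd`, `erf_width`,
#'   `fit_kind`, `bin_width`, `residual` (residual sum of squares).
#' @export
fit_gprime_distribution <- function(values,
                                    fit_kind = c("erf_cdf",
                                                 "gaussian_histogram"),
                                    bin_width = 0.25) {
  fit_kind <- match.arg(fit_kind)
  values <- as.numeric(values)
  if (length(values) < 10) stop("need at least 10 values")
  if (sd(values) == 0) stop("degenerate input: all values equal")
  if (fit_kind == "erf_cdf") {
    x <- sort(values)
    f_emp <- seq_along(x) / length(x)
    obj <- function(p) sum((f_emp - pnorm(x, p[1], exp(p[2])))^2)
    fit <- optim(c(mean(values), log(sd(values))), obj,
                 method = "Nelder-Mead",
                 control = list(reltol = 1e-12, maxit = 2000))
    m <- fit$par[1]
    s <- exp(fit$par[2])
    rss <- fit$value
    bw <- NA_real_
  } else {
    half <- bin_width / 2
    lo <- floor((min(values) + half) / bin_width) * bin_width - half
    hi <- ceiling((max(values) - half) / bin_width) * bin_width + half
    breaks <- seq(lo, hi, by = bin_width)
    h <- graphics::hist(values, breaks = breaks, plot = FALSE)
    obj <- function(p) sum((h$density - dnorm(h$mids, p[1], exp(p[2])))^2)
    fit <- optim(c(mean(values), log(sd(values))), obj,
                 method = "Nelder-Mead",
                 control = list(reltol = 1e-12, maxit = 2000))
    m <- fit$par[1]
    s <- exp(fit$par[2])
    rss <- fit$value
    bw <- bin_width
  }
  structure(list(mean = m, sd = s, erf_width = sqrt(2) * s,
                 fit_kind = fit_kind, bin_width = bw, residual = rss),
            class = "distribution_fit")
}

#' @export
print.distribution_fit <- function(x, ...) {
  cat(sprintf(
    "<distribution_fit> %s: mean = %.3f, sd = %.3f, erf width = %.3f (RSS %.2e)\n",
    x$fit_kind, x$mean, x$sd, x$erf_width, x$residual))
  invisible(x)
}

#' Running average of |G'| against chain length
#'
#' Orders the cohort by chain length (ties broken by pdb id) and computes a
#' centred moving average of |G'| with the given odd window; near the edges
#' the window is truncated to the available records. Used to check whether
#' the typical entanglement drifts with protein size.
#'
#' @param table a `cohort_table`.
#' @param window odd positive window size (default 21). A window not smaller
#'   than the table collapses to the single global mean.
#' @return A data.frame with `pdb_id`, `n_residues`, `gprime_abs` and
#'   `running_mean`.
#' @export
length_trend <- function(table, window = 21) {
  stopifnot(inherits(table, "cohort_table"), nrow(table) > 0)
  window <- as.integer(window)
  if (window < 1 || window %% 2L == 0L)
    stop("window must be a positive odd integer")
  ord <- order(table$n_residues, table$pdb_id)
  tab <- table[ord, , drop = FALSE]
  v <- abs(tab$g_prime)
  n <- length(v)
  half <- window %/% 2L
  rm <- if (window >= n) {
    rep(mean(v), n)
  } else {
    vapply(seq_len(n), function(i) {
      mean(v[max(1L, i - half):min(n, i + half)])
    }, numeric(1))
  }
  data.frame(pdb_id = tab$pdb_id, n_residues = tab$n_residues,
             gprime_abs = v, running_mean = rm,
             stringsAsFactors = FALSE, row.names = NULL)
}
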