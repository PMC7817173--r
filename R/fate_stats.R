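## Division-type scoring and renewal-rate estimation.
##
## An epidermal progenitor division leaves two daughters, each of which
## either stays in the basal (progenitor) layer or moves suprabasally and
## differentiates.  The three division types are
##   SR (symmetric renewal)          basal / basal
##   AD (asymmetric division)        basal / suprabasal
##   SD (symmetric differentiation)  suprabasal / suprabasal
## The renewal rate r = f_SR + f_AD/2 is the proportion of daughter cells
## that remain progenitors: r = 0.5 is homeostasis, r > 0.5 net growth.

.division_levels <- c("SR", "AD", "SD")
.layer_levels <- c("basal", "suprabasal")
.context_levels <- c("single_cell", "clone_edge", "clone_inner",
                     "wt_adjacent", "wt_distant", "field")

.norm_layer <- function(layer, what = "layer") {
  out <- tolower(trimws(as.character(layer)))
  bad <- is.na(out) | !(out %in% .layer_levels)
  if (any(bad)) {
    stop("invalid ", what, " value(s): ",
         paste(unique(layer[bad]), collapse = ", "),
         " (expected basal/suprabasal)", call. = FALSE)
  }
  out
}

#' Classify a progenitor division from its two daughter-cell layers
#'
#' A division with two basal daughters is symmetric renewal (`"SR"`), one
#' basal and one suprabasal daughter is an asymmetric division (`"AD"`),
#' and two suprabasal daughters is symmetric differentiation (`"SD"`).
#' The classification is symmetric in the order of the daughters.
#'
#' @param layer1,layer2 Character vectors of daughter-cell layers,
#'   `"basal"` or `"suprabasal"` (case-insensitive). Recycled to a common
#'   length.
#' @return A factor with levels `SR`, `AD`, `SD`.
#' @examples
#' classify_division("basal", "basal")
#' classify_division(c("basal", "suprabasal"), c("suprabasal", "suprabasal"))
#' @export
classify_division <- function(layer1, layer2) {
  l1 <- .norm_layer(layer1, "daughter 1 layer")
  l2 <- .norm_layer(layer2, "daughter 2 layer")
  n_basal <- (l1 == "basal") + (l2 == "basal")
  factor(c("SD", "AD", "SR")[n_basal + 1L], levels = .division_levels)
}

#' Construct a set of division-type fractions
#'
#' @param f_SR,f_AD,f_SD Fractions of symmetric-renewal, asymmetric and
#'   symmetric-differentiation divisions; must be in \[0, 1\] and sum to 1.
#' @param n_events Number of scored divisions the fractions are based on.
#' @param counts Optional integer vector of raw counts (SR, AD, SD).
#' @return An object of class `fate_fractions`.
#' @examples
#' fate_fractions(0.48, 0.42, 0.10, n_events = 100)
#' @export
fate_fractions <- function(f_SR, f_AD, f_SD, n_events, counts = NULL) {
  f <- c(f_SR, f_AD, f_SD)
  if (length(f) != 3L || anyNA(f) || any(f < -1e-12) || any(f > 1 + 1e-12))
    stop("fractions must be three numbers in [0, 1]", call. = FALSE)
  if (abs(sum(f) - 1) > 1e-8)
    stop("fractions must sum to 1 (got ", format(sum(f)), ")", call. = FALSE)
  if (length(n_events) != 1L || is.na(n_events) || n_events < 1)
    stop("n_events must be a positive integer", call. = FALSE)
  structure(
    list(f_SR = f_SR, f_AD = f_AD, f_SD = f_SD,
         n_events = as.integer(n_events), counts = counts),
    class = "fate_fractions")
}

#' @export
print.fate_fractions <- function(x, ...) {
  cat(sprintf(
    "Division-type fractions (n = %d events)\n  SR %.3f  AD %.3f  SD %.3f\n",
    x$n_events, x$f_SR, x$f_AD, x$f_SD))
  invisible(x)
}

#' Estimate division-type fractions from a division-event table
#'
#' Tallies symmetric renewal, asymmetric and symmetric differentiation
#' among the events that pass the requested filters and returns the three
#' fractions together with the number of contributing events.
#'
#' @param events Data frame with at least the columns `daughter1_layer` and
#'   `daughter2_layer`; the standard table also carries `animal_id`,
#'   `clone_id`, `context` and `week` (see [read_division_table()]).
#' @param context Optional character vector; keep only events whose
#'   `context` is among these values.
#' @param weeks Optional numeric vector; keep only events whose `week`
#'   falls in `range(weeks)` (inclusive).
#' @param predicate Optional function taking the events data frame and
#'   returning a logical row mask, applied after the other filters.
#' @return A [fate_fractions()] object.
#' @examples
#' ev <- sample_cfi_dataset(c(0.29, 0.44, 0.27), n_divisions = 200, seed = 1)
#' estimate_fate_fractions(ev)
#' @export
estimate_fate_fractions <- function(events, context = NULL, weeks = NULL,
                                    predicate = NULL) {
  stopifnot(is.data.frame(events))
  need <- c("daughter1_layer", "daughter2_layer")
  miss <- setdiff(need, names(events))
  if (length(miss))
    stop("events table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  keep <- rep(TRUE, nrow(events))
  if (!is.null(context)) keep <- keep & events$context %in% context
  if (!is.null(weeks)) {
    rng <- range(weeks)
    keep <- keep & events$week >= rng[1] & events$week <= rng[2]
  }
  if (!is.null(predicate)) keep <- keep & predicate(events)
  events <- events[keep, , drop = FALSE]
  if (nrow(events) == 0L)
    stop("no division events left after filtering", call. = FALSE)
  type <- classify_division(events$daughter1_layer, events$daughter2_layer)
  counts <- as.integer(table(type))
  n <- nrow(events)
  fate_fractions(counts[1] / n, counts[2] / n, counts[3] / n,
                 n_events = n, counts = stats::setNames(counts, .division_levels))
}

#' Division-based renewal rate from fate fractions
#'
#' Computes the proportion of daughter cells that remain basal
#' progenitors, `r = f_SR + f_AD / 2` (equivalently
#' `(2 n_SR + n_AD) / (2 n)`).  A rate of 0.5 maintains the progenitor
#' pool; above 0.5 the population expands.
#'
#' @param f A [fate_fractions()] object.
#' @param conf If non-`NULL`, a confidence level (e.g. 0.95); a percentile
#'   bootstrap interval over resampled divisions is attached (requires
#'   `seed`).
#' @param n_boot,seed Bootstrap resample count and seed, used only when
#'   `conf` is given.
#' @return An object of class `renewal_estimate` with elements `rate`,
#'   `method = "division_based"`, `ci_low`, `ci_high` and `n`.
#' @examples
#' renewal_rate_from_fractions(fate_fractions(0.48, 0.42, 0.10, 100))
#' @export
renewal_rate_from_fractions <- function(f, conf = NULL, n_boot = 2000,
                                        seed = NULL) {
  stopifnot(inherits(f, "fate_fractions"))
  rate <- f$f_SR + f$f_AD / 2
  ci <- c(NA_real_, NA_real_)
  if (!is.null(conf)) {
    if (is.null(seed)) stop("a seed is required for the bootstrap interval",
                            call. = FALSE)
    ## resample per-division daughter-renewal contributions (1, 1/2, 0)
    contrib <- rep(c(1, 0.5, 0),
                   times = round(c(f$f_SR, f$f_AD, f$f_SD) * f$n_events))
    ci <- bootstrap_ci(contrib, mean, n_boot = n_boot, seed = seed,
                       conf = conf)
  }
  structure(list(rate = rate, method = "division_based",
                 ci_low = ci[1], ci_high = ci[2], n = f$n_events),
            class = "renewal_estimate")
}

#' @export
print.renewal_estimate <- function(x, ...) {
  cat(sprintf("Renewal rate %.3f (%s, n = %d)", x$rate, x$method, x$n))
  if (!is.na(x$ci_low))
    cat(sprintf("  CI [%.3f, %.3f]", x$ci_low, x$ci_high))
  cat("\n")
  invisible(x)
}

#' Population-based renewal rate from a pulse-chase cell table
#'
#' The EdU/BrdU pulse-chase estimator: among all EdU-labelled cells, the
#' fraction that are K10-negative (undifferentiated) estimates the
#' population renewal rate.
#'
#' @param cells Data frame with logical/0-1 columns `edu` and `k10`
#'   (see [read_cell_table()]).
#' @return A `renewal_estimate` with `method = "population_based"`.
#' @export
renewal_rate_population <- function(cells) {
  stopifnot(is.data.frame(cells))
  miss <- setdiff(c("edu", "k10"), names(cells))
  if (length(miss))
    stop("cell table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  edu <- as.logical(cells$edu)
  k10 <- as.logical(cells$k10)
  n_edu <- sum(edu)
  if (n_edu == 0L) stop("no EdU+ cells in the table", call. = FALSE)
  structure(list(rate = sum(edu & !k10) / n_edu, method = "population_based",
                 ci_low = NA_real_, ci_high = NA_real_, n = n_edu),
            class = "renewal_estimate")
}

#' Proliferation rate of a clone's basal compartment
#'
#' Proportion of EdU-incorporating progenitor (basal) cells among all
#' basal cells of a clone over the labelling window.
#'
#' @param cells Cell table (see [read_cell_table()]).
#' @param clone Optional clone identifier; restrict to that clone.
#' @return Proportion in \[0, 1\].
#' @export
proliferation_rate <- function(cells, clone = NULL) {
  stopifnot(is.data.frame(cells))
  if (!is.null(clone)) cells <- cells[!is.na(cells$clone_id) &
                                        cells$clone_id == clone, , drop = FALSE]
  basal <- cells[tolower(cells$layer) == "basal", , drop = FALSE]
  if (nrow(basal) == 0L)
    stop("no basal cells in the selected clone", call. = FALSE)
  sum(as.logical(basal$edu)) / nrow(basal)
}

#' Two-tailed two-sample comparison of per-animal values
#'
#' Classical (equal-variance) Student's t-test on animal-level summary
#' values, the unit of replication in clonal lineage-tracing experiments.
#' Groups in which both samples have zero variance are handled explicitly:
#' equal means give t = 0, p = 1; unequal zero-variance means are an
#' error rather than a NaN.
#'
#' @param a,b Numeric vectors of per-animal values; each needs at least
#'   two animals.
#' @param var_equal Use the pooled-variance Student test (default) or the
#'   Welch test.
#' @return A list of class `group_comparison` with `t`, `df`, `p_value`,
#'   `mean_a`, `mean_b` and the significance `band`.
#' @examples
#' compare_groups(c(0.51, 0.49, 0.53), c(0.68, 0.71, 0.66))
#' @export
compare_groups <- function(a, b, var_equal = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least two animal-level values", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("NA values in group data", call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      res <- list(t = 0, df = length(a) + length(b) - 2L, p_value = 1)
    } else {
      stop("zero variance in both groups with unequal means: ",
           "t statistic undefined", call. = FALSE)
    }
  } else {
    ht <- stats::t.test(a, b, var.equal = var_equal)
    res <- list(t = unname(ht$statistic), df = unname(ht$parameter),
                p_value = ht$p.value)
  }
  structure(c(res, list(mean_a = mean(a), mean_b = mean(b),
                        band = significance_band(res$p_value))),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("t = %.3f, df = %.1f, p = %.4g (%s); means %.3f vs %.3f\n",
              x$t, x$df, x$p_value, x$band, x$mean_a, x$mean_b))
  invisible(x)
}

#' Map a p-value to its figure-legend significance band
#'
#' @param p Numeric vector of p-values.
#' @return Character vector: `"n.s."` (p > 0.05), `"*"` (p < 0.05),
#'   `"**"` (p < 0.01), `"***"` (p < 0.001), `"****"` (p < 0.0001).
#' @export
significance_band <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p must be in [0, 1]", call. = FALSE)
  out <- ifelse(p < 1e-4, "****",
         ifelse(p < 1e-3, "***",
         ifelse(p < 1e-2, "**",
         ifelse(p < 0.05, "*", "n.s."))))
  out
}

#' Percentile bootstrap confidence interval
#'
#' Resamples observations (vector elements, or data-frame rows) with
#' replacement and returns the percentile interval of the statistic.
#'
#' @param x Numeric vector or data frame of observations.
#' @param statistic Function mapping a resample of `x` to a scalar.
#' @param n_boot Number of bootstrap resamples; values below 100 trigger a
#'   warning.
#' @param seed Mandatory RNG seed for reproducibility.
#' @param conf Confidence level (default 0.95).
#' @return Named numeric vector `c(ci_low, ci_high)`.
#' @examples
#' bootstrap_ci(rbinom(50, 1, 0.5), mean, n_boot = 500, seed = 7)
#' @export
bootstrap_ci <- function(x, statistic, n_boot = 2000, seed, conf = 0.95) {
  if (missing(seed)) stop("bootstrap_ci requires an explicit seed",
                          call. = FALSE)
  n <- if (is.data.frame(x)) nrow(x) else length(x)
  if (n < 2L) stop("need at least two observations to bootstrap",
                   call. = FALSE)
  if (n_boot < 100) warning("n_boot < 100: interval will be unstable")
  set.seed(seed)
  take <- if (is.data.frame(x)) {
    function(idx) x[idx, , drop = FALSE]
  } else {
    function(idx) x[idx]
  }
  stat <- vapply(seq_len(n_boot), function(i) {
    statistic(take(sample.int(n, n, replace = TRUE)))
  }, numeric(1))
  alpha <- (1 - conf) / 2
  q <- stats::quantile(stat, c(alpha, 1 - alpha), names = FALSE)
  c(ci_low = q[1], ci_high = q[2])
}

#' Bin weeks post-induction to the 2-week collection grid
#'
#' Tissues are collected at 2-week intervals; arbitrary week values are
#' assigned to the nearest bin, with exact ties rounded down.
#'
#' @param week Non-negative numeric vector of weeks.
#' @return Numeric vector of bin centers (0, 2, 4, ...).
#' @examples
#' bin_week(c(0, 1, 3, 3.2, 9))
#' @export
bin_week <- function(week) {
  if (any(week < 0, na.rm = TRUE)) stop("weeks must be non-negative",
                                        call. = FALSE)
  2 * floor(week / 2 + 0.5 - 1e-9)
}
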