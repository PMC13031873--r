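# Last downward crossing of `threshold` after the trace maximum, with linear
# interpolation between samples; NA when the trace never exceeds threshold.
#' @noRd
downward_crossing <- function(time, od, threshold, which = c("last", "first")) {
  which <- match.arg(which)
  if (max(od) <= threshold) return(NA_real_)
  i0 <- which.max(od)
  idx <- seq(i0, length(od) - 1L)
  if (!length(idx)) return(NA_real_)
  cross <- idx[od[idx] >= threshold & od[idx + 1L] < threshold]
  if (!length(cross)) return(NA_real_)
  i <- if (which == "last") max(cross) else min(cross)
  t0 <- time[i]; t1 <- time[i + 1L]
  y0 <- od[i]; y1 <- od[i + 1L]
  t0 + (y0 - threshold) / (y0 - y1) * (t1 - t0)
}

#' Droplet lifetime and longevity from a turbidity trace
#'
#' The lifetime is the time at which OD600 falls below 0.12 after the trace
#' maximum; the longevity uses the higher threshold 0.2. Because traces are
#' noisy near thresholds, the crossing is the *last* downward crossing after
#' the global maximum (configurable to the first), linearly interpolated
#' between the 30-s samples. A trace that never exceeds the threshold
#' returns `NA`.
#'
#' @param trace a `turbidity_trace` (from [simulate_turbidity()] or
#'   [read_trace_tsv()]).
#' @param threshold OD600 threshold (0.12 for lifetime).
#' @param crossing `"last"` (default) or `"first"` downward crossing.
#' @return crossing time in minutes, or `NA` if never turbid.
#' @export
lifetime <- function(trace, threshold = 0.12, crossing = "last") {
  if (!inherits(trace, "turbidity_trace")) stopf("`trace` must be a turbidity_trace")
  if (threshold <= 0) stopf("`threshold` must be positive")
  downward_crossing(trace$time_min, trace$od600, threshold, crossing)
}

#' @rdname lifetime
#' @export
longevity <- function(trace, crossing = "last") {
  lifetime(trace, threshold = 0.2, crossing = crossing)
}

#' Critical salt concentration from dissolution titrations
#'
#' Per replicate, an ordinary least-squares line is fitted to
#' (concentration, OD600) over the points with OD600 > 0.12, and the
#' critical concentration is where the extrapolated fit crosses 0.1
#' downward. The result is the mean and standard deviation over replicates.
#' When dissolution is not linear the linear fit is not meaningful — a
#' non-negative fitted slope, fewer than two points above 0.12, or a
#' measured OD600 already below 0.1 at a concentration smaller than the
#' extrapolated crossing (the signature of hard-to-dissolve aggregates
#' dropping abruptly). Such replicates fall back to the first tabulated
#' concentration with measured OD600 < 0.1, with a warning.
#'
#' @param series a `titration_series` or list of replicate series
#'   (mode `"salt"`).
#' @param fit_threshold include points with OD600 above this in the fit
#'   (default 0.12).
#' @param cross_threshold the crossing level (default 0.1).
#' @return list with `critical_mM` (mean), `sd_mM`, and `per_replicate`.
#' @export
critical_salt <- function(series, fit_threshold = 0.12, cross_threshold = 0.1) {
  if (inherits(series, "titration_series")) series <- list(series)
  if (!length(series)) stopf("need at least one replicate series")
  per <- vapply(series, function(s) {
    if (!inherits(s, "titration_series")) stopf("replicates must be titration_series")
    sel <- s$od600 > fit_threshold
    fallback <- function() {
      i <- match(TRUE, s$od600 < cross_threshold)
      if (is.na(i)) NA_real_ else s$conc_mM[i]
    }
    if (sum(sel) < 2L) {
      warning("fewer than 2 points above the fit threshold; using first-crossing fallback",
              call. = FALSE)
      return(fallback())
    }
    fit <- stats::lm(od ~ conc, data = data.frame(conc = s$conc_mM[sel],
                                                  od = s$od600[sel]))
    b <- stats::coef(fit)
    if (b[2] >= 0) {
      warning("non-negative dissolution slope; using first-crossing fallback",
              call. = FALSE)
      return(fallback())
    }
    crossing <- unname((cross_threshold - b[1]) / b[2])
    measured <- fallback()
    tol <- 1e-6 * max(1, abs(crossing))
    if (!is.na(measured) && measured < crossing - tol) {
      warning("dissolution not linear (measured crossing precedes the fit); using first-crossing fallback",
              call. = FALSE)
      return(measured)
    }
    crossing
  }, numeric(1))
  list(critical_mM = mean(per),
       sd_mM = if (length(per) > 1L) stats::sd(per) else 0,
       per_replicate = per)
}

#' Critical fuel concentration from a formation titration
#'
#' The smallest tabulated concentration at which turbidity crosses above
#' 0.1; `NA` when it never does.
#'
#' @param series a `titration_series` with mode `"fuel"`.
#' @param threshold the onset threshold (default 0.1).
#' @return concentration in mM, or `NA`.
#' @export
critical_fuel <- function(series, threshold = 0.1) {
  if (!inherits(series, "titration_series")) stopf("`series` must be a titration_series")
  if (series$mode != "fuel") stopf("`series` must have mode 'fuel'")
  i <- match(TRUE, series$od600 > threshold)
  if (is.na(i)) NA_real_ else series$conc_mM[i]
}

#' Two-sided Welch's t-test for independent samples
#'
#' Unequal-variance t-test with Welch-Satterthwaite degrees of freedom, as
#' used for every significance call on lifetimes, critical concentrations
#' and diffusion coefficients. Wraps `stats::t.test(var.equal = FALSE)`.
#' When both samples are constant: equal means give `t = 0, p = 1`;
#' unequal means give a degenerate flag (`NA` statistics).
#'
#' @param sample_a,sample_b numeric vectors, each of length >= 2.
#' @return list with `t_statistic`, `df`, `p_two_sided`, `mean_a`, `mean_b`,
#'   `status` (`"ok"` or `"degenerate"`).
#' @export
welch_test <- function(sample_a, sample_b) {
  if (length(sample_a) < 2L || length(sample_b) < 2L) {
    stopf("each sample needs at least 2 observations")
  }
  va <- stats::var(sample_a); vb <- stats::var(sample_b)
  if (va == 0 && vb == 0) {
    if (mean(sample_a) == mean(sample_b)) {
      return(list(t_statistic = 0, df = NA_real_, p_two_sided = 1,
                  mean_a = mean(sample_a), mean_b = mean(sample_b),
                  status = "ok"))
    }
    return(list(t_statistic = NA_real_, df = NA_real_, p_two_sided = NA_real_,
                mean_a = mean(sample_a), mean_b = mean(sample_b),
                status = "degenerate"))
  }
  tt <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  list(t_statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_two_sided = tt$p.value, mean_a = mean(sample_a),
       mean_b = mean(sample_b), status = "ok")
}

#' Read a trace or titration TSV
#'
#' Reads the delimited formats written by [write_trace_tsv()]:
#' `time_min, od600` for turbidity traces and `conc_mM, od600` for
#' titrations.
#'
#' @param path TSV path.
#' @param mode for titrations, `"salt"` or `"fuel"`; `NULL` autodetects a
#'   turbidity trace by its `time_min` column.
#' @return a `turbidity_trace` or `titration_series`.
#' @export
read_trace_tsv <- function(path, mode = NULL) {
  df <- utils::read.delim(path)
  if ("time_min" %in% names(df)) {
    return(structure(list(time_min = df$time_min, od600 = df$od600,
                          replicate = 1L, truth = NULL),
                     class = "turbidity_trace"))
  }
  if (!"conc_mM" %in% names(df)) stopf("unrecognized trace table: %s", path)
  if (is.null(mode)) stopf("`mode` is required for titration tables")
  structure(list(conc_mM = df$conc_mM, od600 = df$od600,
                 mode = match.arg(mode, c("salt", "fuel")), truth = NULL),
            class = "titration_series")
}
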