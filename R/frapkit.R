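#' Raw FRAP ROI trace
#'
#' Container for fluorescence-recovery raw data: frame times, mean
#' intensities of the bleached ROI (`I`), an unbleached reference ROI in a
#' neighboring droplet (`N`) and a background ROI without droplets (`B`),
#' the number of pre-bleach frames, and the bleach-spot radius (already
#' corrected from the post-bleach frame).
#'
#' @param t frame times, seconds.
#' @param I,N,B intensity series, same length as `t`.
#' @param n_prebleach number of pre-bleach frames (>= 1).
#' @param radius bleach radius, micrometers (> 0).
#' @return a `frap_trace` object.
#' @export
frap_trace <- function(t, I, N, B, n_prebleach, radius) {
  n_prebleach <- check_count(n_prebleach, "n_prebleach")
  if (radius <= 0) stopf("`radius` must be positive")
  len <- length(t)
  if (length(I) != len || length(N) != len || length(B) != len) {
    stopf("t, I, N, B must have equal length")
  }
  if (n_prebleach >= len) stopf("need at least one post-bleach frame")
  structure(list(t = t, I = I, N = N, B = B, n_prebleach = n_prebleach,
                 radius = radius),
            class = "frap_trace")
}

#' Double normalization of a FRAP trace
#'
#' `F(t) = ((I_t - B_t) / (N_t - B_t)) * ((N0 - B0) / (I0 - B0))`, where
#' `I0`, `N0`, `B0` are the averages over all pre-bleach frames. The first
#' factor corrects each frame for background and acquisition bleaching; the
#' second scales the pre-bleach level to 1. A frame with `N_t <= B_t` is a
#' hard failure naming the frame.
#'
#' @param trace a [frap_trace()].
#' @return numeric vector `F(t)`, same length as `trace$t`.
#' @export
frap_normalize <- function(trace) {
  if (!inherits(trace, "frap_trace")) stopf("`trace` must be a frap_trace")
  bad <- which(trace$N <= trace$B)
  if (length(bad)) {
    stopf("reference ROI not above background at frame %d", bad[1])
  }
  pre <- seq_len(trace$n_prebleach)
  I0 <- mean(trace$I[pre]); N0 <- mean(trace$N[pre]); B0 <- mean(trace$B[pre])
  if (I0 <= B0) stopf("pre-bleach bleached-ROI mean not above background")
  (trace$I - trace$B) / (trace$N - trace$B) * (N0 - B0) / (I0 - B0)
}

#' Fit the exponential FRAP recovery
#'
#' Nonlinear least squares of `F(t) = a * (1 - exp(-b t)) + c` over the
#' post-bleach frames, with time re-zeroed at the first post-bleach frame.
#' `a` is the mobile amplitude, `b` the recovery rate and `c` the bleach
#' floor. The half-time is `t_half = ln(2) / b` and the diffusion
#' coefficient `D = 0.224 * r^2 / t_half` (Soumpasis; 0.224 is the
#' numerically determined coefficient for a circular bleach spot). Starting
#' values are `c0` = first post-bleach value, `a0` = last value minus `c0`,
#' and `b0` from the time to half-way between them; bounds are
#' `a, c` in `[0, 1.5]`, `b > 0`. The fit is `minpack.lm::nlsLM`
#' (Levenberg-Marquardt); non-convergence yields a flagged result with
#' diagnostics, never silent defaults.
#'
#' @param trace a [frap_trace()].
#' @param f optional pre-computed normalized series (defaults to
#'   [frap_normalize()] of `trace`).
#' @return a `frap_fit`: list with `a`, `b`, `c`, `t_half`, `D`,
#'   `mobile_fraction` (`a / (1 - c)`), `residual_rms`, `status`.
#' @export
fit_recovery <- function(trace, f = NULL) {
  if (!inherits(trace, "frap_trace")) stopf("`trace` must be a frap_trace")
  if (is.null(f)) f <- frap_normalize(trace)
  post <- (trace$n_prebleach + 1L):length(trace$t)
  if (length(post) < 5L) stopf("need at least 5 post-bleach frames")
  tp <- trace$t[post] - trace$t[post[1]]
  fp <- f[post]
  c0 <- fp[1]
  a0 <- max(fp[length(fp)] - c0, 0.05)
  half_level <- c0 + a0 / 2
  i_half <- match(TRUE, fp >= half_level)
  b0 <- if (!is.na(i_half) && tp[i_half] > 0) log(2) / tp[i_half] else 1
  fit <- tryCatch(
    minpack.lm::nlsLM(
      fp ~ a * (1 - exp(-b * tp)) + c,
      start = list(a = a0, b = b0, c = max(c0, 0)),
      lower = c(0, 1e-8, 0), upper = c(1.5, Inf, 1.5),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    return(structure(list(a = NA_real_, b = NA_real_, c = NA_real_,
                          t_half = NA_real_, D = NA_real_,
                          mobile_fraction = NA_real_, residual_rms = NA_real_,
                          status = paste("failed:", conditionMessage(fit))),
                     class = "frap_fit"))
  }
  cf <- stats::coef(fit)
  a <- unname(cf["a"]); b <- unname(cf["b"]); cc <- unname(cf["c"])
  t_half <- log(2) / b
  D <- 0.224 * trace$radius^2 / t_half
  structure(list(a = a, b = b, c = cc, t_half = t_half, D = D,
                 mobile_fraction = a / (1 - cc),
                 residual_rms = sqrt(mean(stats::resid(fit)^2)),
                 status = "ok"),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(
    "frap_fit [%s]: a=%.4g b=%.4g /s c=%.4g t_half=%.4g s D=%.4g um^2/s\n",
    x$status, x$a, x$b, x$c, x$t_half, x$D))
  invisible(x)
}

#' Aggregate replicate FRAP fits
#'
#' Arithmetic mean and sample standard deviation of the diffusion
#' coefficient and mean mobile fraction over replicate fits (conditions are
#' measured in triplicate).
#'
#' @param fits list of `frap_fit` objects (failed fits are dropped with a
#'   warning).
#' @return list with `mean_D`, `sd_D`, `mean_mobile_fraction`, `n`.
#' @export
frap_aggregate <- function(fits) {
  if (inherits(fits, "frap_fit")) fits <- list(fits)
  if (!length(fits)) stopf("need at least one fit")
  ok <- vapply(fits, function(f) identical(f$status, "ok"), logical(1))
  if (!all(ok)) warning(sprintf("dropping %d failed fit(s)", sum(!ok)), call. = FALSE)
  fits <- fits[ok]
  if (!length(fits)) stopf("no converged fits to aggregate")
  D <- vapply(fits, `[[`, numeric(1), "D")
  mf <- vapply(fits, `[[`, numeric(1), "mobile_fraction")
  list(mean_D = mean(D), sd_D = if (length(D) > 1L) stats::sd(D) else 0,
       mean_mobile_fraction = mean(mf), n = length(fits))
}

#' Read a FRAP ROI TSV (`frame, t_s, I, N, B`)
#'
#' @param path TSV path.
#' @param n_prebleach number of pre-bleach frames.
#' @param radius bleach radius, micrometers.
#' @return a [frap_trace()].
#' @export
read_frap_tsv <- function(path, n_prebleach, radius) {
  df <- utils::read.delim(path)
  need <- c("t_s", "I", "N", "B")
  if (!all(need %in% names(df))) {
    stopf("FRAP table must have columns frame, t_s, I, N, B")
  }
  frap_trace(df$t_s, df$I, df$N, df$B, n_prebleach, radius)
}

#' @rdname read_frap_tsv
#' @param trace a [frap_trace()] to write.
#' @export
write_frap_tsv <- function(trace, path) {
  write_tsv(data.frame(frame = seq_along(trace$t), t_s = trace$t,
                       I = trace$I, N = trace$N, B = trace$B), path)
}
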