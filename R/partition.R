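#' Total droplet volume from segmented areas
#'
#' Converts segmented droplet cross-section areas to volumes assuming
#' spherical droplets of circular-equivalent radius `r = sqrt(A / pi)`,
#' sums them, and reports the volume fraction relative to the spherical
#' water-in-oil microreactor of the given diameter.
#'
#' @param areas droplet areas, square micrometers (all > 0; may be empty).
#' @param reactor_diameter microreactor diameter, micrometers (> 0).
#' @return list with `areas`, `reactor_diameter`, `total_droplet_volume`
#'   (cubic micrometers), `reactor_volume` and `volume_fraction` (percent).
#' @export
droplet_volume <- function(areas, reactor_diameter) {
  if (length(areas) && any(areas <= 0)) stopf("all areas must be positive")
  if (reactor_diameter <= 0) stopf("`reactor_diameter` must be positive")
  r <- sqrt(areas / pi)
  v_drop <- sum(4 / 3 * pi * r^3)
  v_reactor <- pi * reactor_diameter^3 / 6
  list(areas = areas, reactor_diameter = reactor_diameter,
       total_droplet_volume = v_drop, reactor_volume = v_reactor,
       volume_fraction = 100 * v_drop / v_reactor)
}

#' Partition coefficient from supernatant concentration and droplet volume
#'
#' Mass-balance estimate of the partition coefficient: the DNA amount inside
#' droplets is the total amount minus what the supernatant holds,
#' `n_drop = c_total * v_total - c_sup * (v_total - v_drop)`; the droplet
#' concentration is `n_drop / v_drop` and `K_P = c_drop / c_sup`. Replicate
#' supernatant concentrations and droplet volumes enter through their means;
#' the standard deviation of `K_P` is first-order (delta-method) propagation
#' from the replicate standard deviations of the two measured quantities,
#' with zero covariance.
#'
#' When the measured supernatant holds at least the total amount the
#' droplet amount would be negative; the result is then flagged
#' (`status = "supernatant_exceeds_total"`) with `k_p` clamped to 0.
#'
#' @param c_total total DNA concentration, micromolar.
#' @param v_total total sample volume, microliters.
#' @param c_supernatant replicate supernatant concentrations, micromolar.
#' @param v_droplet replicate total droplet volumes, microliters.
#' @return list with `k_p`, `k_p_sd`, `c_droplet`, `fraction_in_droplets`
#'   (share of the total amount inside droplets) and `status`.
#' @export
#' @examples
#' k_p(c_total = 50, v_total = 20, c_supernatant = 45, v_droplet = 0.1)
k_p <- function(c_total, v_total, c_supernatant, v_droplet) {
  if (c_total < 0 || v_total <= 0) stopf("need c_total >= 0 and v_total > 0")
  if (!length(c_supernatant) || !length(v_droplet)) {
    stopf("replicate lists must be non-empty")
  }
  cbar <- mean(c_supernatant)
  vbar <- mean(v_droplet)
  if (cbar <= 0) stopf("mean supernatant concentration must be positive")
  if (vbar <= 0 || vbar >= v_total) {
    stopf("mean droplet volume must be in (0, v_total)")
  }
  n_total <- c_total * v_total
  n_drop <- n_total - cbar * (v_total - vbar)
  if (n_drop < 0) {
    return(list(k_p = 0, k_p_sd = NA_real_, c_droplet = 0,
                fraction_in_droplets = 0,
                status = "supernatant_exceeds_total"))
  }
  c_drop <- n_drop / vbar
  kp <- c_drop / cbar
  # f(c, v) = (C V) / (c v) - V / v + 1 ; partials for the delta method
  dfdc <- -n_total / (cbar^2 * vbar)
  dfdv <- (v_total / vbar^2) * (1 - c_total / cbar)
  sc <- if (length(c_supernatant) > 1L) stats::sd(c_supernatant) else 0
  sv <- if (length(v_droplet) > 1L) stats::sd(v_droplet) else 0
  kp_sd <- sqrt(dfdc^2 * sc^2 + dfdv^2 * sv^2)
  list(k_p = kp, k_p_sd = kp_sd, c_droplet = c_drop,
       fraction_in_droplets = n_drop / n_total, status = "ok")
}

#' Fraction of solute residing in the droplet phase
#'
#' For partition coefficient `k_p` and droplet volume fraction `phi`,
#' `f = k_p * phi / (k_p * phi + 1 - phi)`; monotone increasing in both
#' arguments. `volume_fraction_for_fraction()` inverts it for `phi`.
#'
#' @param k_p partition coefficient (>= 0).
#' @param phi droplet volume fraction in `[0, 1)`.
#' @return the fraction in droplets, in `[0, 1]`.
#' @export
#' @examples
#' fraction_in_droplets(11, 1 / 210)   # 0.05
fraction_in_droplets <- function(k_p, phi) {
  if (any(k_p < 0)) stopf("`k_p` must be >= 0")
  if (any(phi < 0) || any(phi >= 1)) stopf("`phi` must be in [0, 1)")
  k_p * phi / (k_p * phi + 1 - phi)
}

#' @rdname fraction_in_droplets
#' @param f target fraction in droplets, in `[0, 1)`.
#' @export
volume_fraction_for_fraction <- function(k_p, f) {
  if (any(k_p <= 0)) stopf("`k_p` must be positive to invert")
  if (any(f < 0) || any(f >= 1)) stopf("`f` must be in [0, 1)")
  f / (f + k_p * (1 - f))
}
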