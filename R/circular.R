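#' Circular mean and resultant length of an azimuth sample
#'
#' Vector-sum mean direction: each azimuth contributes a unit vector; the
#' mean is the azimuth of the summed vector, and the mean resultant length
#' `R` in `[0, 1]` measures concentration (1 = all angles identical). The
#' mean is undefined when the resultant is numerically zero (perfectly
#' balanced sample).
#'
#' @param angles numeric vector of azimuths in degrees (any real values;
#'   normalized internally).
#' @return list with `mean` (azimuth, degrees) and `resultant_length`.
#' @examples
#' circular_mean(c(10, 350))  # mean 0, R = cos(10 deg)
#' @export
circular_mean <- function(angles) {
  stopifnot(length(angles) >= 1, all(is.finite(angles)))
  rad <- normalize_azimuth(angles) * pi / 180
  S <- mean(sin(rad)); C <- mean(cos(rad))
  R <- sqrt(S^2 + C^2)
  if (R < 1e-12) stop("circular mean undefined: resultant length ~ 0")
  list(mean = normalize_azimuth(atan2(S, C) * 180 / pi), resultant_length = R)
}

# Kuiper V_n for angles mapped to [0, 1) against the uniform circular CDF.
kuiper_statistic_raw <- function(angles) {
  u <- sort(normalize_azimuth(angles) / 360)
  n <- length(u)
  i <- seq_len(n)
  dplus <- max(i / n - u)
  dminus <- max(u - (i - 1) / n)
  dplus + dminus
}

kuiper_standardize <- function(v_raw, n) {
  v_raw * (sqrt(n) + 0.155 + 0.24 / sqrt(n))
}

# Upper-tail probability of the standardized Kuiper statistic
# (asymptotic series; Stephens' modification makes it accurate for n >= 5).
kuiper_p_asymptotic <- function(lambda, terms = 120) {
  if (lambda < 0.4) return(1)
  j <- seq_len(terms)
  p <- 2 * sum((4 * j^2 * lambda^2 - 1) * exp(-2 * j^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Kuiper test of circular uniformity
#'
#' Rotation-invariant goodness-of-fit test of a circular sample against the
#' uniform distribution, based on `V_n = D+ + D-`, the sum of the maximal
#' positive and negative deviations of the empirical CDF from the uniform
#' CDF. Both the raw statistic (bounded by 2) and the standardized
#' statistic `V_n (sqrt(n) + 0.155 + 0.24/sqrt(n))` are reported; the
#' standardized form is what published orientation analyses print, and its
#' asymptotic upper tail gives the p-value. For very small samples
#' (`n < 5`), or on request, the p-value is computed by Monte Carlo
#' resampling from the uniform circle instead. Asymptotic probabilities
#' below 1e-12 are floored and labelled `"< 1e-12"`: the tail series loses
#' meaning there and the honest statement is a bound.
#'
#' @param angles numeric vector of azimuths in degrees.
#' @param p_method `"auto"` (asymptotic for `n >= 5`, Monte Carlo below),
#'   `"asymptotic"`, or `"monte_carlo"`.
#' @param n_mc Monte Carlo resamples when used (default 10000).
#' @param seed optional integer seed for the Monte Carlo p-value.
#' @return an object of class `kuiper_result`: `statistic_raw`,
#'   `statistic_standardized`, `n`, `p_value`, `p_label`, `p_method`.
#' @export
kuiper_uniformity <- function(angles, p_method = c("auto", "asymptotic",
                                                   "monte_carlo"),
                              n_mc = 10000, seed = NULL) {
  p_method <- match.arg(p_method)
  n <- length(angles)
  if (n == 0) stop("empty sample")
  v <- kuiper_statistic_raw(angles)
  lambda <- kuiper_standardize(v, n)
  if (p_method == "auto") p_method <- if (n >= 5) "asymptotic" else "monte_carlo"
  if (p_method == "asymptotic") {
    p <- kuiper_p_asymptotic(lambda)
    floored <- p < 1e-12
    p <- max(p, 1e-12)
    label <- if (floored) "< 1e-12" else sprintf("%g", p)
  } else {
    p <- with_rng(seed, {
      exceed <- sum(replicate(n_mc,
        kuiper_statistic_raw(stats::runif(n, 0, 360)) >= v))
      (exceed + 1) / (n_mc + 1)
    })
    label <- sprintf("%g", p)
  }
  structure(list(statistic_raw = v, statistic_standardized = lambda, n = n,
                 p_value = p, p_label = label, p_method = p_method),
            class = "kuiper_result")
}

#' @export
print.kuiper_result <- function(x, ...) {
  cat(sprintf("Kuiper uniformity test: V = %.4f, standardized = %.2f, n = %d, p %s (%s)\n",
              x$statistic_raw, x$statistic_standardized, x$n,
              if (startsWith(x$p_label, "<")) x$p_label else paste("=", x$p_label),
              x$p_method))
  invisible(x)
}

# Maximum-likelihood-style inverse of A(kappa) = I1/I0 (Fisher's
# approximation), mapping a mean resultant length to a von Mises kappa.
a1_inv <- function(r) {
  if (r < 0) r <- 0
  if (r >= 1) return(Inf)
  if (r < 0.53) {
    2 * r + r^3 + 5 * r^5 / 6
  } else if (r < 0.85) {
    -0.4 + 1.39 * r + 0.43 / (1 - r)
  } else {
    1 / (r^3 - 4 * r^2 + 3 * r)
  }
}

#' Watson-Williams test for equal mean directions
#'
#' One-way F-type test that two circular samples share a mean direction,
#' assuming both are von Mises with a common concentration. The F statistic
#' `((N - 2)(R1 + R2 - R)) / (N - R1 - R2)` (resultant lengths of the two
#' samples and of the pooled sample) is multiplied by the standard
#' small-kappa correction `1 + 3/(8 kappa_hat)`, with `kappa_hat` obtained
#' from the within-sample mean resultant length via the inverse-A
#' approximation. The test is reliable for `kappa_hat` roughly in `[1, 10]`;
#' outside that range a warning string is attached to the result.
#'
#' @param angles_a,angles_b the two azimuth samples, degrees (`n >= 5` each).
#' @return an object of class `watson_williams_result`: `F`, `df1`, `df2`,
#'   `p_value`, `kappa_hat`, `correction_applied`, `warning` (`NA` if none).
#' @export
watson_williams <- function(angles_a, angles_b) {
  na <- length(angles_a); nb <- length(angles_b)
  if (na < 5 || nb < 5) stop("each sample needs n >= 5")
  stopifnot(all(is.finite(angles_a)), all(is.finite(angles_b)))
  to_res <- function(a) {
    rad <- normalize_azimuth(a) * pi / 180
    sqrt(sum(sin(rad))^2 + sum(cos(rad))^2)
  }
  N <- na + nb
  R1 <- to_res(angles_a); R2 <- to_res(angles_b)
  R <- to_res(c(angles_a, angles_b))
  rw <- (R1 + R2) / N  # within-sample mean resultant length
  kappa <- a1_inv(rw)
  denom <- N - R1 - R2
  Fstat <- if (denom <= .Machine$double.eps * N) Inf else
    ((N - 2) * (R1 + R2 - R)) / denom
  Fstat <- max(Fstat, 0)
  correction <- 1 + 3 / (8 * kappa)
  Fcorr <- Fstat * correction
  warn <- if (kappa < 1) {
    "kappa_hat < 1: samples too dispersed for the Watson-Williams assumptions"
  } else if (kappa > 10) {
    "kappa_hat > 10: correction negligible; F essentially uncorrected"
  } else NA_character_
  structure(list(
    F = Fcorr, df1 = 1, df2 = N - 2,
    p_value = stats::pf(Fcorr, 1, N - 2, lower.tail = FALSE),
    kappa_hat = kappa, correction_applied = TRUE, warning = warn
  ), class = "watson_williams_result")
}

#' @export
print.watson_williams_result <- function(x, ...) {
  cat(sprintf("Watson-Williams test: F(%d, %d) = %.4f, p = %g, kappa_hat = %.2f\n",
              x$df1, x$df2, x$F, x$p_value, x$kappa_hat))
  if (!is.na(x$warning)) cat("  note:", x$warning, "\n")
  invisible(x)
}

#' Does an azimuth fall within a sub-basin's flow-direction interval?
#'
#' The plausible high-water flow directions of a sub-basin form a clockwise
#' circular interval; this tests membership, handling wrap-around.
#'
#' @param angle azimuth(s), degrees.
#' @param basin a `sub_basin` (or list with `flow_azimuth_min`/`_max`).
#' @return logical vector.
#' @export
within_flow_interval <- function(angle, basin) {
  azimuth_in_interval(angle, basin$flow_azimuth_min, basin$flow_azimuth_max)
}

#' Berm arc extent and arc accumulation
#'
#' A berm arc is the clockwise azimuth interval of a pond rim covered by
#' woody vegetation (the proxy for raised earth). `arc_extent()` returns its
#' clockwise span in degrees; a start equal to the end is a zero-extent arc
#' unless `full_circle` marks a rim entirely covered. `cumulate_arcs()`
#' overlays many arcs on a common 360-degree circle divided into bins of
#' `resolution` degrees and counts, for each bin, how many arcs cover the
#' bin's midpoint.
#'
#' @param start,end arc endpoints, degrees clockwise from north.
#' @param full_circle logical: the arc covers the whole rim.
#' @param arcs data frame with columns `start`, `end` and optionally
#'   `full_circle`.
#' @param resolution bin width in degrees (default 1).
#' @return `arc_extent()`: degrees in `[0, 360]`. `cumulate_arcs()`: data
#'   frame with `bin_start`, `bin_mid`, `count`.
#' @examples
#' arc_extent(350, 10)  # 20
#' @export
arc_extent <- function(start, end, full_circle = FALSE) {
  n <- max(length(start), length(end), length(full_circle))
  ext <- clockwise_span(rep_len(start, n), rep_len(end, n))
  ext[rep_len(full_circle, n)] <- 360
  ext
}

#' @rdname arc_extent
#' @export
cumulate_arcs <- function(arcs, resolution = 1) {
  stopifnot(resolution > 0, 360 %% resolution == 0)
  nb <- as.integer(360 / resolution)
  mids <- (seq_len(nb) - 1) * resolution + resolution / 2
  counts <- integer(nb)
  if (nrow(arcs) > 0) {
    fc <- if ("full_circle" %in% names(arcs)) arcs$full_circle else
      rep(FALSE, nrow(arcs))
    for (i in seq_len(nrow(arcs))) {
      covered <- if (isTRUE(fc[i])) rep(TRUE, nb) else {
        ext <- clockwise_span(arcs$start[i], arcs$end[i])
        clockwise_span(arcs$start[i], mids) < ext
      }
      counts <- counts + as.integer(covered)
    }
  }
  data.frame(bin_start = (seq_len(nb) - 1) * resolution, bin_mid = mids,
             count = counts)
}

#' Draw from a von Mises distribution on azimuths
#'
#' Best-Fisher rejection sampler. Used by the synthetic landscape generator
#' for V orientations and berm azimuths concentrated about the flow
#' direction; `kappa = 0` degenerates to the uniform circle.
#'
#' @param n sample size.
#' @param mu mean direction, degrees clockwise from north.
#' @param kappa concentration (`>= 0`).
#' @param seed optional integer seed.
#' @return azimuths in degrees, `[0, 360)`.
#' @export
rvonmises_azimuth <- function(n, mu, kappa, seed = NULL) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  with_rng(seed, {
    if (kappa == 0) return(stats::runif(n, 0, 360))
    a <- 1 + sqrt(1 + 4 * kappa^2)
    b <- (a - sqrt(2 * a)) / (2 * kappa)
    r <- (1 + b^2) / (2 * b)
    out <- numeric(n)
    for (i in seq_len(n)) {
      repeat {
        u1 <- stats::runif(1); u2 <- stats::runif(1)
        z <- cos(pi * u1)
        f <- (1 + r * z) / (r + z)
        c0 <- kappa * (r - f)
        if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) {
          u3 <- stats::runif(1)
          theta <- sign(u3 - 0.5) * acos(f)
          out[i] <- theta
          break
        }
      }
    }
    normalize_azimuth(mu + out * 180 / pi)
  })
}
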