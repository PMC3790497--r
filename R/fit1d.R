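# 1-D Gaussian and double-Gaussian fits to projected axial profiles.
# Fits are unweighted least squares on the binned histogram (counts vs bin
# centre), Levenberg-Marquardt. Rejection is always via the `accepted`
# flag, never an exception, so unusable regions can be excluded upstream
# and tallied.

#' Fit a single Gaussian plus constant baseline to an axial profile
#'
#' @param profile a `projection_profile` (see [project_region()]).
#' @param min_positions minimum localization count for a fit (default 20).
#' @param sd_accept acceptance range for the fitted SD in nm; default
#'   `c(5, depth/2)`.
#' @return list with `mean`, `sd`, `amplitude`, `baseline`, `residual`,
#'   `accepted`, `reason`, `n`.
#' @export
fit_gaussian1d <- function(profile, min_positions = 20,
                           sd_accept = NULL) {
  if (is.null(sd_accept)) sd_accept <- c(5, profile$depth / 2)
  rejected <- function(reason) {
    list(mean = NA_real_, sd = NA_real_, amplitude = NA_real_,
         baseline = NA_real_, residual = NA_real_, accepted = FALSE,
         reason = reason, n = profile$n)
  }
  if (profile$empty || profile$n < min_positions) {
    return(rejected("too few localizations"))
  }
  x <- profile$centers
  z <- as.numeric(profile$counts)
  w <- z / sum(z)
  mu0 <- sum(w * x)
  sd0 <- sqrt(max(sum(w * (x - mu0)^2), (profile$bin / 2)^2))
  p0 <- c(mu = mu0, sd = sd0, A = max(z), b = 0)
  lower <- c(mu = min(x) - profile$bin, sd = profile$bin / 4, A = 0, b = 0)
  upper <- c(mu = max(x) + profile$bin, sd = profile$depth, A = Inf,
             b = Inf)
  fit <- lm_fit(p0, lower, upper, function(p) {
    p["A"] * exp(-(x - p["mu"])^2 / (2 * p["sd"]^2)) + p["b"] - z
  })
  if (!fit$converged) return(rejected("no convergence"))
  p <- fit$par
  accepted <- p["sd"] >= sd_accept[1L] && p["sd"] <= sd_accept[2L]
  list(mean = unname(p["mu"]), sd = unname(p["sd"]),
       amplitude = unname(p["A"]), baseline = unname(p["b"]),
       residual = fit$residual,
       accepted = accepted,
       reason = if (accepted) "ok" else "sd outside acceptance range",
       n = profile$n)
}

#' Fit a double Gaussian plus constant baseline to an axial profile
#'
#' The two components are ordered `mean_lo < mean_hi`. The fit is rejected
#' (flagged, not an error) when it does not converge, when the component
#' separation falls below `min_separation`, when the components are not
#' resolved (separation below `min_resolution * (sd_lo + sd_hi)` — a
#' Rayleigh-like gate: least squares will happily split a single broad
#' mode into two strongly overlapping components whose separation is about
#' 1.3 times the sum of their SDs, whereas genuine two-layer GBM profiles
#' sit well above 2), or when either component carries less than
#' `min_amp_frac` of the total component area. These gates are what
#' exclude regions without a usable two-layer structure.
#'
#' @param profile a `projection_profile`.
#' @param min_separation minimum peak-to-peak distance in nm (default 40).
#' @param min_positions minimum localization count (default 40).
#' @param min_amp_frac minimum fraction of total component area per
#'   component (default 0.1).
#' @param min_resolution minimum ratio of separation to `sd_lo + sd_hi`
#'   (default 1.5).
#' @return object of class `double_gaussian_fit`: `mean_lo`, `mean_hi`,
#'   `sd_lo`, `sd_hi`, `amp_lo`, `amp_hi`, `baseline`, `midpoint`,
#'   `peak_to_peak`, `residual`, `accepted`, `reason`, `n`.
#' @export
fit_double_gaussian1d <- function(profile, min_separation = 40,
                                  min_positions = 40, min_amp_frac = 0.1,
                                  min_resolution = 1.5) {
  rejected <- function(reason) {
    structure(list(mean_lo = NA_real_, mean_hi = NA_real_,
                   sd_lo = NA_real_, sd_hi = NA_real_,
                   amp_lo = NA_real_, amp_hi = NA_real_,
                   baseline = NA_real_, midpoint = NA_real_,
                   peak_to_peak = NA_real_, residual = NA_real_,
                   accepted = FALSE, reason = reason, n = profile$n),
              class = "double_gaussian_fit")
  }
  if (profile$empty || profile$n < min_positions) {
    return(rejected("too few localizations"))
  }
  x <- profile$centers
  z <- as.numeric(profile$counts)
  pos <- profile$positions
  med <- stats::median(pos)
  lo <- pos[pos < med]
  hi <- pos[pos >= med]
  if (length(lo) < 2L || length(hi) < 2L) {
    return(rejected("degenerate split"))
  }
  sd_floor <- profile$bin / 2
  p0 <- c(m1 = mean(lo), m2 = mean(hi),
          s1 = max(stats::sd(lo), sd_floor),
          s2 = max(stats::sd(hi), sd_floor),
          A1 = max(amp_near(x, z, mean(lo)), 1),
          A2 = max(amp_near(x, z, mean(hi)), 1),
          b = 0)
  lower <- c(m1 = min(x) - profile$bin, m2 = min(x) - profile$bin,
             s1 = profile$bin / 4, s2 = profile$bin / 4,
             A1 = 0, A2 = 0, b = 0)
  upper <- c(m1 = max(x) + profile$bin, m2 = max(x) + profile$bin,
             s1 = profile$depth, s2 = profile$depth,
             A1 = Inf, A2 = Inf, b = Inf)
  fit <- lm_fit(p0, lower, upper, function(p) {
    p["A1"] * exp(-(x - p["m1"])^2 / (2 * p["s1"]^2)) +
      p["A2"] * exp(-(x - p["m2"])^2 / (2 * p["s2"]^2)) + p["b"] - z
  })
  if (!fit$converged) return(rejected("no convergence"))
  p <- fit$par
  ord <- if (p["m1"] <= p["m2"]) c(1L, 2L) else c(2L, 1L)
  means <- unname(p[c("m1", "m2")][ord])
  sds <- unname(p[c("s1", "s2")][ord])
  amps <- unname(p[c("A1", "A2")][ord])
  area <- amps * sds
  sep <- means[2L] - means[1L]
  out <- structure(list(mean_lo = means[1L], mean_hi = means[2L],
                        sd_lo = sds[1L], sd_hi = sds[2L],
                        amp_lo = amps[1L], amp_hi = amps[2L],
                        baseline = unname(p["b"]),
                        midpoint = mean(means), peak_to_peak = sep,
                        residual = fit$residual, accepted = TRUE,
                        reason = "ok", n = profile$n),
                   class = "double_gaussian_fit")
  if (sep < min_separation) {
    out$accepted <- FALSE
    out$reason <- "separation below minimum"
  } else if (sep < min_resolution * (sds[1L] + sds[2L])) {
    out$accepted <- FALSE
    out$reason <- "components not resolved"
  } else if (sum(area) <= 0 ||
             min(area) / sum(area) < min_amp_frac) {
    out$accepted <- FALSE
    out$reason <- "component amplitude imbalance"
  }
  out
}

amp_near <- function(x, z, mu) {
  z[which.min(abs(x - mu))]
}

# Shared Levenberg-Marquardt wrapper; convergence is nls.lm info 1..4.
lm_fit <- function(p0, lower, upper, resid_fn) {
  fit <- tryCatch(
    minpack.lm::nls.lm(par = p0, fn = resid_fn, lower = lower,
                       upper = upper,
                       control = minpack.lm::nls.lm.control(
                         ftol = 1e-10, ptol = 1e-10, maxiter = 200L)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4) {
    return(list(converged = FALSE, par = p0, residual = Inf))
  }
  p <- stats::coef(fit)
  list(converged = TRUE, par = p, residual = sum(resid_fn(p)^2))
}

#' @export
print.double_gaussian_fit <- function(x, ...) {
  if (x$accepted) {
    cat(sprintf(paste0("<double_gaussian_fit> means %.1f / %.1f nm, ",
                       "peak-to-peak %.1f nm, midpoint %.1f nm (n = %d)\n"),
                x$mean_lo, x$mean_hi, x$peak_to_peak, x$midpoint, x$n))
  } else {
    cat(sprintf("<double_gaussian_fit> rejected: %s (n = %d)\n",
                x$reason, x$n))
  }
  invisible(x)
}

#' Midpoint-zero reference frame from a reference-channel fit
#'
#' Returns the axial offset that moves the midpoint between the two fitted
#' reference layers to zero; adding it to any axial coordinate expresses
#' that coordinate in the region's reference frame.
#'
#' @param fit an accepted [fit_double_gaussian1d()] result.
#' @return offset in nm (`-midpoint`).
#' @export
build_reference_frame <- function(fit) {
  if (!isTRUE(fit$accepted)) {
    stop("reference fit was not accepted (", fit$reason,
         "); exclude this region upstream", call. = FALSE)
  }
  -fit$midpoint
}
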