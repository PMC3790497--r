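# Independent brute-force oracles and small fixture builders shared by the
# test files. The oracles deliberately share no code with the package's
# fitting routines: amplitudes/baseline are solved by linear least squares
# on a parameter grid, and the grid optimum is the reference the
# Levenberg-Marquardt fits are checked against.

# Brute-force double-Gaussian fit: exhaustive search over component means
# (grid step `mean_step`) and SDs (grid step `sd_step`); for every
# candidate shape the amplitudes and baseline are the exact linear
# least-squares solution (clamped at zero). Returns the SSR-minimising
# parameters.
oracle_double_gaussian <- function(centers, counts,
                                   mean_lo_grid, mean_hi_grid, sd_grid) {
  best <- list(ssr = Inf)
  z <- as.numeric(counts)
  for (m1 in mean_lo_grid) {
    for (m2 in mean_hi_grid) {
      if (m2 <= m1) next
      for (s1 in sd_grid) {
        g1 <- exp(-(centers - m1)^2 / (2 * s1^2))
        for (s2 in sd_grid) {
          g2 <- exp(-(centers - m2)^2 / (2 * s2^2))
          X <- cbind(g1, g2, 1)
          beta <- tryCatch(qr.solve(crossprod(X), crossprod(X, z)),
                           error = function(e) NULL)
          if (is.null(beta)) next
          beta <- pmax(as.numeric(beta), 0)
          ssr <- sum((X %*% beta - z)^2)
          if (ssr < best$ssr) {
            best <- list(ssr = ssr, mean_lo = m1, mean_hi = m2,
                         sd_lo = s1, sd_hi = s2,
                         amp_lo = beta[1L], amp_hi = beta[2L],
                         baseline = beta[3L])
          }
        }
      }
    }
  }
  best
}

# Brute-force axis-aligned 2-D Gaussian fit on a pixel patch: grid over
# centre and widths (pixel units), amplitude/offset by weighted linear LS
# using the same inverse-variance (Poisson) weighting as the package fit.
oracle_gaussian2d <- function(patch, x0_grid, y0_grid, sd_grid) {
  nr <- nrow(patch)
  nc <- ncol(patch)
  cx <- rep(seq_len(nc) - 0.5, each = nr)
  cy <- rep(seq_len(nr) - 0.5, times = nc)
  z <- as.vector(patch)
  w <- 1 / pmax(z, 1)
  best <- list(ssr = Inf)
  for (x0 in x0_grid) {
    for (y0 in y0_grid) {
      for (sx in sd_grid) {
        for (sy in sd_grid) {
          g <- exp(-(cx - x0)^2 / (2 * sx^2) - (cy - y0)^2 / (2 * sy^2))
          X <- cbind(g, 1)
          XtWX <- crossprod(X, w * X)
          beta <- qr.solve(XtWX, crossprod(X, w * z))
          ssr <- sum(w * (X %*% beta - z)^2)
          if (ssr < best$ssr) {
            best <- list(ssr = ssr, x0 = x0, y0 = y0, sd_x = sx,
                         sd_y = sy, amplitude = beta[1L],
                         offset = beta[2L])
          }
        }
      }
    }
  }
  best
}

# Flat-membrane axial profile from raw positions (no loop geometry).
flat_profile <- function(positions, bin = 10, depth = 600,
                         id = "flat", channel = "test") {
  gbmstorm:::new_projection_profile(positions, id, channel, bin, depth)
}

# Minimal localization table around given coordinates.
loc_table <- function(x, y, channel = "test", ...) {
  localization_table(data.frame(frame = integer(length(x)), x = x, y = y,
                                channel = rep_len(channel,
                                                  length(x)), ...))
}

# Noise-free pixel-integrated Gaussian spot (photon units).
synthetic_spot <- function(nr, nc, x, y, photons, psf_sd, pixel_size) {
  img <- matrix(0, nr, nc)
  gbmstorm:::add_psf(img, x, y, photons, psf_sd, pixel_size,
                     half_px = max(nr, nc))
}

# Rigid motion helpers: rotate by angle `a` then translate by `t`.
rigid_point <- function(xy, a, t) {
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L)
  sweep(xy %*% t(R), 2L, t, `+`)
}
rigid_table <- function(tab, a, t) {
  xy <- rigid_point(cbind(tab$x, tab$y), a, t)
  tab$x <- xy[, 1L]
  tab$y <- xy[, 2L]
  tab
}
rigid_region <- function(reg, a, t) {
  gbm_region(center = as.numeric(rigid_point(rbind(reg$center), a, t)),
             normal = as.numeric(rigid_point(rbind(reg$normal), a, c(0, 0))),
             width = reg$width, depth = reg$depth, id = reg$id,
             curvature = reg$curvature)
}
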