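# Independent oracles used by the tests. These deliberately re-derive
# quantities by brute force / dense search, independent of the package's
# optimized code paths.

# Brute-force gamma pass/fail: exhaustive candidate search on a `step` mm
# lattice inside a |r| <= dta ball (beyond dta the distance term alone
# exceeds 1, so pass/fail is fully determined there). Returns pass rate %.
gamma_pass_rate_brute <- function(ref, eval, dose_criterion = 0.01, dta = 1,
                                  cutoff = 0.05, step = 0.1) {
  dmax <- max(ref$data)
  sel <- which(ref$data > cutoff * dmax)
  dref <- ref$data[sel]
  denom <- dose_criterion * dref
  pts <- voxel_centers(ref)[sel, , drop = FALSE]
  k <- seq(-floor(dta / step), floor(dta / step))
  off <- as.matrix(expand.grid(x = k * step, y = k * step, z = k * step))
  off <- off[rowSums(off^2) <= dta^2, , drop = FALSE]
  passed <- rep(FALSE, length(sel))
  for (j in seq_len(nrow(off))) {
    todo <- which(!passed)
    if (!length(todo)) break
    p <- pts[todo, , drop = FALSE]
    p[, 1] <- p[, 1] + off[j, 1]
    p[, 2] <- p[, 2] + off[j, 2]
    p[, 3] <- p[, 3] + off[j, 3]
    dv <- interp_trilinear(eval, p)
    g2 <- sum(off[j, ]^2) / dta^2 + ((dv - dref[todo]) / denom[todo])^2
    ok <- !is.na(g2) & g2 <= 1
    passed[todo[ok]] <- TRUE
  }
  100 * mean(passed)
}

# Dense-resampling range search: linearly resample the profile at `fine` mm
# and take the most distal sample at or above the threshold.
extract_range_dense <- function(profile, level, reference, fine = 0.01) {
  thr <- level * reference
  g <- seq(min(profile$depth), max(profile$depth), by = fine)
  dd <- stats::approx(profile$depth, profile$dose, xout = g)$y
  i <- which(dd >= thr)
  if (!length(i)) return(NA_real_)
  g[max(i)]
}

# random small dose volume for gamma tests: smooth trigonometric field plus
# voxel noise, so both dose and distance terms matter
random_dose_volume <- function(dims, spacing = 1, seed = 1,
                               noise_sd = 0.01) {
  set.seed(seed)
  ph <- stats::runif(6, 0, 2 * pi)
  fr <- stats::runif(3, 0.15, 0.45)
  x <- seq_len(dims[1]); y <- seq_len(dims[2]); z <- seq_len(dims[3])
  f <- outer(outer(sin(fr[1] * x + ph[1]), sin(fr[2] * y + ph[2])),
             sin(fr[3] * z + ph[3]))
  arr <- 1 + 0.25 * array(f, dim = dims) +
    array(stats::rnorm(prod(dims), 0, noise_sd), dim = dims)
  scalar_volume(arr, rep(spacing, 3), c(0, 0, 0))
}

# a simple all-water phantom geometry: one ellipsoid of water in air
water_geometry <- function(semi = c(30, 30, 30)) {
  list(body = list(name = "body", tissue = "water", priority = 1,
                   type = "ellipsoid", center = c(0, 0, 0), semi = semi))
}

make_uniform_volume <- function(value, dims = c(40, 24, 24), spacing = 4) {
  origin <- -(dims - 1) / 2 * spacing
  scalar_volume(array(value, dim = dims), rep(spacing, 3), origin)
}
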