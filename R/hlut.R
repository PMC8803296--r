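# SECT chain: two-parameter stoichiometric CT-number model, calibration from
# insert readings, piecewise-linear Hounsfield look-up table (HLUT)
# construction and application.

#' Stoichiometric CT-number model parameters
#'
#' Two-parameter attenuation parametrization: relative attenuation is
#' \deqn{\mu/\mu_w = \rho_e (k_1 \tilde Z_1^{e_1} + k_2 \tilde Z_2^{e_2} + 1)
#'  / (k_1 \tilde Z_{1,w}^{e_1} + k_2 \tilde Z_{2,w}^{e_2} + 1)}
#' with \eqn{\tilde Z_j} the electron-fraction-weighted power means of the
#' atomic numbers at exponents e1 (photoelectric) and e2 (coherent scatter).
#' The exponents default to the customary 3.62 and 1.86 and are configurable.
#'
#' @param k1 Photoelectric weight (>= 0).
#' @param k2 Coherent-scatter weight (>= 0).
#' @param e1,e2 Power-mean exponents.
#' @return An object of class `stoich_params`.
#' @export
stoich_params <- function(k1, k2, e1 = 3.62, e2 = 1.86) {
  if (k1 < 0 || k2 < 0) stop("k1 and k2 must be >= 0")
  structure(list(k1 = k1, k2 = k2, e1 = e1, e2 = e2), class = "stoich_params")
}

# electron-fraction-weighted power mean of Z at exponent e
.z_power_mean <- function(comp, e) {
  lam <- electron_fractions(comp)
  Z <- .ELEMENTS[names(lam), "Z"]
  sum(lam * Z^e)^(1 / e)
}

# per-composition attenuation factors a = Z1^e1, b = Z2^e2 (numerator terms)
.stoich_terms <- function(comp, sp) {
  c(a = .z_power_mean(comp, sp$e1)^sp$e1, b = .z_power_mean(comp, sp$e2)^sp$e2)
}

#' Predict the CT number of a composition
#'
#' Theoretical Hounsfield value HU = 1000 (mu/mu_w - 1) under the
#' two-parameter stoichiometric model. Water maps to 0 HU for any parameters
#' by construction.
#'
#' @param comp A [tissue_composition()] object.
#' @param sp A [stoich_params()] object.
#' @return Hounsfield units.
#' @export
predict_hu <- function(comp, sp) {
  stopifnot(inherits(sp, "stoich_params"))
  ed <- relative_electron_density(comp)
  tm <- .stoich_terms(comp, sp)
  tw <- .stoich_terms(water_composition(), sp)
  mu <- ed * (sp$k1 * tm["a"] + sp$k2 * tm["b"] + 1) /
    (sp$k1 * tw["a"] + sp$k2 * tw["b"] + 1)
  unname(1000 * (mu - 1))
}

#' An insert reading for stoichiometric calibration
#'
#' @param comp A [tissue_composition()] object (the surrogate material).
#' @param measured_hu Mean Hounsfield value over the insert ROI.
#' @return An object of class `insert_reading`.
#' @export
insert_reading <- function(comp, measured_hu) {
  stopifnot(inherits(comp, "tissue_comp"),
            measured_hu >= -1024, measured_hu <= 3071)
  structure(list(comp = comp, measured_hu = measured_hu),
            class = "insert_reading")
}

#' Fit the stoichiometric parameters from insert readings
#'
#' Rearranging the attenuation model makes it linear in (k1, k2):
#' \eqn{k_1(\rho_e a_i - m_i a_w) + k_2(\rho_e b_i - m_i b_w) = m_i - \rho_e}
#' with \eqn{m_i = HU_i/1000 + 1}. The system is solved by non-negative
#' least squares; noise-free readings generated from known parameters are
#' recovered exactly.
#'
#' @param readings List of [insert_reading()] objects (>= 3, spanning
#'   lung-equivalent to bone-equivalent materials).
#' @param e1,e2 Model exponents (fixed during the fit).
#' @return A [stoich_params()] object with per-insert HU residuals attached
#'   as attribute `"residuals"`.
#' @export
fit_stoichiometric <- function(readings, e1 = 3.62, e2 = 1.86) {
  stopifnot(length(readings) >= 3)
  sp0 <- stoich_params(0, 0, e1, e2)
  tw <- .stoich_terms(water_composition(), sp0)
  ed <- vapply(readings, function(r) relative_electron_density(r$comp), 0)
  ab <- t(vapply(readings, function(r) .stoich_terms(r$comp, sp0), c(a = 0, b = 0)))
  m <- vapply(readings, function(r) r$measured_hu, 0) / 1000 + 1
  A <- cbind(ed * ab[, "a"] - m * tw["a"], ed * ab[, "b"] - m * tw["b"])
  b <- m - ed
  if (max(ed) - min(ed) < 0.15)
    warning("degenerate insert design (all near-soft-tissue); ",
            "parameter estimates will be poorly constrained")
  k <- pracma::lsqnonneg(A, b)$x
  sp <- stoich_params(k[1], k[2], e1, e2)
  pred <- vapply(readings, function(r) predict_hu(r$comp, sp), 0)
  attr(sp, "residuals") <- vapply(readings, function(r) r$measured_hu, 0) - pred
  sp
}

#' Hounsfield look-up table (HLUT)
#'
#' Continuous piecewise-linear CT-number-to-SPR conversion curve defined by
#' strictly increasing HU vertices with non-decreasing SPR values.
#'
#' @param hu,spr Vertex coordinates.
#' @return An object of class `hlut`.
#' @export
hlut <- function(hu, spr) {
  stopifnot(length(hu) == length(spr), length(hu) >= 2,
            all(diff(hu) > 0))
  if (any(diff(spr) < -1e-12)) stop("HLUT SPR values must be non-decreasing")
  structure(list(breakpoints = data.frame(hu = as.numeric(hu),
                                          spr = as.numeric(spr))),
            class = "hlut")
}

#' @export
print.hlut <- function(x, ...) {
  cat(sprintf("<hlut> %d segments over HU [%g, %g]\n",
              nrow(x$breakpoints) - 1L, min(x$breakpoints$hu),
              max(x$breakpoints$hu)))
  print(x$breakpoints, row.names = FALSE)
  invisible(x)
}

#' One-to-one (identity) conversion curve
#'
#' The workaround curve that lets a treatment-planning system consume SPR
#' images directly through its CT-number-to-SPR conversion slot:
#' SPR = HU/1000 + 1, so an SPR map encoded as 1000 (SPR - 1) passes through
#' unchanged.
#'
#' @return An `hlut`.
#' @export
hlut_identity <- function() hlut(c(-1000, 3071), c(0, 3071 / 1000 + 1))

#' Build an HLUT from stoichiometric predictions of reference tissues
#'
#' For every reference tissue the theoretical CT number
#' ([predict_hu()]) and ground-truth SPR ([ground_truth_spr()]) give one
#' calibration point. Two construction modes:
#'
#' * `segments` (default 10): fixed HU knots (default spanning air to dense
#'   bone); each segment's points are fitted by least squares and vertex
#'   values at interior knots average the adjacent segment fits; segments
#'   with fewer than two points are filled by interpolating neighboring
#'   vertices (a message is emitted). The curve is anchored at
#'   (-1000, `spr_air`) and, when `anchor_water`, forced through (0, 1).
#' * `interpolate`: vertices directly at the (HU, SPR) points of the
#'   reference tissues (air mapped to `spr_air`); the curve reproduces every
#'   reference tissue exactly.
#'
#' Monotonicity is enforced by a running maximum.
#'
#' @param sp A [stoich_params()] object (the scanner model).
#' @param tissues List of `tissue_comp` reference tissues.
#' @param knots HU knot positions (`segments` mode); default 10 segments.
#' @param method `"segments"` or `"interpolate"`.
#' @param anchor_water Force the curve through (0 HU, SPR 1); default TRUE.
#' @param spr_air SPR assigned at/below the air vertex (default 0.001,
#'   matching the DLCT air floor).
#' @param params A [bethe_params()] object for the ground-truth SPR.
#' @return An `hlut`.
#' @export
build_hlut <- function(sp, tissues,
                       knots = c(-1000, -120, -80, -30, 0, 50, 100, 300,
                                 800, 1600, 3071),
                       method = c("segments", "interpolate"),
                       anchor_water = TRUE, spr_air = 0.001,
                       params = bethe_params()) {
  method <- match.arg(method)
  is_air <- vapply(tissues, function(t) t$name == "air", TRUE)
  pts_hu <- vapply(tissues[!is_air], predict_hu, 0, sp = sp)
  pts_spr <- vapply(tissues[!is_air], ground_truth_spr, 0, params = params)

  if (method == "interpolate") {
    air_hu <- if (any(is_air)) predict_hu(tissues[is_air][[1]], sp) else -1000
    hu <- c(air_hu, pts_hu)
    sv <- c(spr_air, pts_spr)
    o <- order(hu)
    hu <- hu[o]; sv <- sv[o]
    keep <- c(TRUE, diff(hu) > 1e-6)
    hu <- hu[keep]; sv <- sv[keep]
    if (hu[1] > -1000) { hu <- c(-1000, hu); sv <- c(spr_air, sv) }
    sv <- cummax(sv)
    return(hlut(hu, sv))
  }

  knots <- sort(unique(knots))
  nk <- length(knots)
  seg_fit <- vector("list", nk - 1L)
  for (j in seq_len(nk - 1L)) {
    inj <- if (j < nk - 1L) which(pts_hu >= knots[j] & pts_hu < knots[j + 1])
           else which(pts_hu >= knots[j] & pts_hu <= knots[j + 1])
    if (length(inj) >= 2) {
      cf <- stats::lm.fit(cbind(1, pts_hu[inj]), pts_spr[inj])$coefficients
      seg_fit[[j]] <- cf
    }
  }
  verts <- rep(NA_real_, nk)
  for (i in seq_len(nk)) {
    est <- c()
    if (i > 1 && !is.null(seg_fit[[i - 1]]))
      est <- c(est, sum(seg_fit[[i - 1]] * c(1, knots[i])))
    if (i < nk && !is.null(seg_fit[[i]]))
      est <- c(est, sum(seg_fit[[i]] * c(1, knots[i])))
    if (length(est)) verts[i] <- mean(est)
  }
  verts[1] <- spr_air
  if (anchor_water && any(knots == 0)) verts[knots == 0] <- 1
  if (anyNA(verts)) {
    message("HLUT: ", sum(is.na(verts)),
            " knot(s) without enough reference points; interpolating neighbors")
    ok <- !is.na(verts)
    verts <- stats::approx(knots[ok], verts[ok], xout = knots, rule = 2)$y
  }
  hlut(knots, cummax(verts))
}

#' Apply an HLUT to CT numbers
#'
#' Per-voxel linear interpolation between vertices; CT numbers beyond the
#' terminal vertices are extrapolated with the terminal segment slopes and
#' the result is clamped to SPR >= 0.
#'
#' @param hu A `scalar_volume`, array or numeric vector of CT numbers.
#' @param lut An `hlut`.
#' @return SPR with the shape of `hu`.
#' @export
apply_hlut <- function(hu, lut) {
  stopifnot(inherits(lut, "hlut"))
  vol_in <- inherits(hu, "scalar_volume")
  x <- if (vol_in) hu$data else hu
  bp <- lut$breakpoints
  n <- nrow(bp)
  y <- stats::approx(bp$hu, bp$spr, xout = as.numeric(x), rule = 2)$y
  lo <- x < bp$hu[1]; hi <- x > bp$hu[n]
  if (any(lo)) {
    s <- (bp$spr[2] - bp$spr[1]) / (bp$hu[2] - bp$hu[1])
    y[lo] <- bp$spr[1] + s * (x[lo] - bp$hu[1])
  }
  if (any(hi)) {
    s <- (bp$spr[n] - bp$spr[n - 1]) / (bp$hu[n] - bp$hu[n - 1])
    y[hi] <- bp$spr[n] + s * (x[hi] - bp$hu[n])
  }
  y <- pmax(y, 0)
  if (!is.null(dim(x))) dim(y) <- dim(x)
  if (vol_in) vol_like(hu, y) else y
}

#' Write / read an HLUT as CSV (vertices) plus JSON metadata
#'
#' @param lut An `hlut`.
#' @param path CSV path; metadata goes to `paste0(path, ".json")`.
#' @param meta Optional named list of metadata to store.
#' @return `write_hlut` returns `path` invisibly; `read_hlut` the `hlut`.
#' @export
write_hlut <- function(lut, path, meta = list()) {
  utils::write.csv(lut$breakpoints, path, row.names = FALSE)
  meta$n_segments <- nrow(lut$breakpoints) - 1L
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_hlut
#' @export
read_hlut <- function(path) {
  df <- utils::read.csv(path)
  hlut(df$hu, df$spr)
}
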