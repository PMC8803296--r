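# Synthetic labeled head phantom and scanner simulation: the stand-in for
# patient scans. A concentric-ellipsoid head with brain, cranial bone shell,
# skull-base bone slab, eyes, lateral ventricles (CSF) and a nasal air
# cavity; ground-truth ED/EAN/SPR volumes follow from the assigned
# compositions.

#' Default head phantom geometry
#'
#' Nested ellipsoids and slabs (mm, origin at head center). Each structure
#' has a unique priority; a voxel takes the label of the highest-priority
#' structure containing its center. `scale` applies an anatomy "jitter"
#' factor per axis for synthetic inter-patient variability.
#'
#' @param scale Length-3 multiplicative factors on all structure dimensions.
#' @return A list of structure definitions (name, tissue, priority, shape).
#' @export
head_geometry <- function(scale = c(1, 1, 1)) {
  ell <- function(name, tissue, priority, center, semi)
    list(name = name, tissue = tissue, priority = priority, type = "ellipsoid",
         center = center * scale, semi = semi * scale)
  slab <- function(name, tissue, priority, zlim, within)
    list(name = name, tissue = tissue, priority = priority, type = "slab",
         zlim = zlim * scale[3], within = within)
  list(
    head      = ell("head", "soft_tissue", 1, c(0, 0, 0), c(72, 90, 80)),
    cranium   = ell("cranium", "cranial_bone", 2, c(0, 0, 2), c(64, 81, 72)),
    brain     = ell("brain", "brain", 3, c(0, 0, 2), c(58, 75, 66)),
    skull_base = slab("skull_base", "skull_base_bone", 4, c(-58, -44),
                      within = "cranium"),
    ventricle_l = ell("ventricle_l", "csf", 5, c(-14, -8, 6), c(8, 22, 10)),
    ventricle_r = ell("ventricle_r", "csf", 6, c(14, -8, 6), c(8, 22, 10)),
    eye_l     = ell("eye_l", "eye", 7, c(-27, 68, -16), c(11, 11, 11)),
    eye_r     = ell("eye_r", "eye", 8, c(27, 68, -16), c(11, 11, 11)),
    nasal_cavity = ell("nasal_cavity", "air", 9, c(0, 58, -44), c(11, 16, 14))
  )
}

#' Build a labeled head phantom with ground-truth property volumes
#'
#' Rasterizes the geometry onto a regular grid (highest priority wins per
#' voxel center) and computes per-voxel ground-truth relative electron
#' density, effective atomic number and SPR from the assigned compositions.
#' Background (label 0) is air. Rasterization is deterministic.
#'
#' @param geometry Structure list from [head_geometry()].
#' @param label_table Named list of `tissue_comp` covering every tissue name
#'   referenced by `geometry` plus `"air"`; default [reference_tissues()].
#' @param spacing Isotropic voxel spacing in mm (default 2).
#' @param dims Grid dimensions; default covers the default head with margin.
#' @param exponent EAN power-mean exponent (default 2.94).
#' @param params [bethe_params()] for ground-truth SPR.
#' @param spr_floor Ground-truth SPR assigned to air-like voxels (ED below
#'   0.05), matching the prediction chains' air handling.
#' @return An object of class `labeled_phantom`: grid metadata, integer
#'   `labels` volume, `label_table`, per-label property table, and
#'   `truth_ed`, `truth_ean`, `truth_spr` scalar volumes.
#' @export
build_head_phantom <- function(geometry = head_geometry(),
                               label_table = reference_tissues(),
                               spacing = 2, dims = NULL,
                               exponent = 2.94, params = bethe_params(),
                               spr_floor = 0.001) {
  prio <- vapply(geometry, `[[`, 0, "priority")
  if (anyDuplicated(prio))
    stop("structure priorities must be unique (overlap resolution undefined)")
  tissues <- unique(c("air", vapply(geometry, `[[`, "", "tissue")))
  missing <- setdiff(tissues, names(label_table))
  if (length(missing))
    stop("label_table lacks composition(s): ", paste(missing, collapse = ", "))

  if (is.null(dims)) {
    ext <- 2 * apply(vapply(geometry, function(s) {
      if (s$type == "ellipsoid") abs(s$center) + s$semi else c(0, 0, 0)
    }, numeric(3)), 1, max) + 8
    dims <- as.integer(ceiling(ext / spacing))
  }
  spacing3 <- rep(spacing, length.out = 3)
  origin <- -(dims - 1) / 2 * spacing3
  ax <- list(x = origin[1] + (seq_len(dims[1]) - 1) * spacing3[1],
             y = origin[2] + (seq_len(dims[2]) - 1) * spacing3[2],
             z = origin[3] + (seq_len(dims[3]) - 1) * spacing3[3])

  X <- rep(ax$x, times = dims[2] * dims[3])
  Y <- rep(rep(ax$y, each = dims[1]), times = dims[3])
  Z <- rep(ax$z, each = dims[1] * dims[2])

  geometry <- geometry[order(prio)]
  inside_of <- list()
  labels <- integer(length(X))       # 0 = background air
  label_names <- c("air", vapply(geometry, `[[`, "", "name"))
  label_tissue <- c("air", vapply(geometry, `[[`, "", "tissue"))
  for (i in seq_along(geometry)) {
    s <- geometry[[i]]
    if (s$type == "ellipsoid") {
      inside <- ((X - s$center[1]) / s$semi[1])^2 +
        ((Y - s$center[2]) / s$semi[2])^2 +
        ((Z - s$center[3]) / s$semi[3])^2 <= 1
    } else if (s$type == "slab") {
      host <- inside_of[[s$within]]
      if (is.null(host)) stop("slab '", s$name, "' references unknown host '",
                              s$within, "'")
      inside <- host & Z >= s$zlim[1] & Z <= s$zlim[2]
    } else stop("unknown structure type: ", s$type)
    inside_of[[s$name]] <- inside
    labels[inside] <- i
  }

  comps <- label_table[label_tissue]
  prop <- data.frame(
    label = seq_along(label_names) - 1L,
    structure = label_names,
    tissue = label_tissue,
    ed = vapply(comps, relative_electron_density, 0),
    ean = vapply(comps, ean_from_composition, 0, exponent = exponent),
    spr = vapply(comps, ground_truth_spr, 0, params = params),
    row.names = NULL
  )
  prop$spr[prop$ed < 0.05] <- spr_floor

  lut <- function(col) prop[[col]][labels + 1L]
  mk <- function(v) scalar_volume(array(v, dim = dims), spacing3, origin)
  labels_arr <- array(as.integer(labels), dim = dims)

  structure(list(
    labels = scalar_volume(labels_arr, spacing3, origin),
    label_table = label_table,
    properties = prop,
    geometry = geometry,
    truth_ed = mk(lut("ed")),
    truth_ean = mk(lut("ean")),
    truth_spr = mk(lut("spr")),
    exponent = exponent
  ), class = "labeled_phantom")
}

#' @export
print.labeled_phantom <- function(x, ...) {
  cat(sprintf("<labeled_phantom> %s voxels @ %g mm\n",
              paste(dim(x$labels$data), collapse = "x"), x$labels$spacing[1]))
  print(x$properties, row.names = FALSE)
  invisible(x)
}

#' Logical mask of a phantom structure
#'
#' @param phantom A `labeled_phantom`.
#' @param structure Structure name (or `"air"` for background).
#' @return Logical array on the phantom grid.
#' @export
structure_mask <- function(phantom, structure) {
  lab <- phantom$properties$label[phantom$properties$structure == structure]
  if (!length(lab)) stop("unknown structure: ", structure)
  phantom$labels$data == lab
}

#' Scanner error model
#'
#' Multiplicative per-volume biases plus additive Gaussian noise for the
#' simulated DLCT (ED/EAN) and SECT (HU) outputs. Biases may be global
#' scalars or named per-tissue vectors; noise is seeded and fully
#' reproducible. Magnitudes are user-set: percent-level ED biases reproduce
#' the percent-level inter-modality SPR discrepancies observed clinically.
#'
#' @param ed_bias,ean_bias Fractional bias (scalar or named per-tissue).
#' @param hu_bias Additive HU bias (scalar or named per-tissue).
#' @param ed_noise_sd,ean_noise_sd,hu_noise_sd Gaussian noise SDs (>= 0).
#' @param seed Integer master seed; sub-streams per output volume are
#'   derived deterministically.
#' @return An object of class `scanner_model`.
#' @export
scanner_model <- function(ed_bias = 0, ean_bias = 0, hu_bias = 0,
                          ed_noise_sd = 0, ean_noise_sd = 0, hu_noise_sd = 0,
                          seed = 1L) {
  stopifnot(ed_noise_sd >= 0, ean_noise_sd >= 0, hu_noise_sd >= 0)
  structure(list(ed_bias = ed_bias, ean_bias = ean_bias, hu_bias = hu_bias,
                 ed_noise_sd = ed_noise_sd, ean_noise_sd = ean_noise_sd,
                 hu_noise_sd = hu_noise_sd, seed = as.integer(seed)),
            class = "scanner_model")
}

# expand a scalar-or-named-per-tissue bias to a per-voxel field
.bias_field <- function(bias, phantom) {
  if (length(bias) == 1L && is.null(names(bias))) {
    return(bias)
  }
  out <- numeric(nrow(phantom$properties))
  idx <- match(names(bias), phantom$properties$tissue)
  for (i in seq_along(bias)) {
    hit <- phantom$properties$tissue == names(bias)[i]
    out[hit] <- bias[i]
  }
  array(out[phantom$labels$data + 1L], dim = dim(phantom$labels$data))
}

.sub_seed <- function(seed, k) as.integer((as.numeric(seed) * 1009 + k) %% 2147483647)

#' Simulate a DLCT acquisition
#'
#' Spectral output: `ed = truth_ed (1 + ed_bias) + noise` and
#' `ean = truth_ean (1 + ean_bias) + noise`, clipped to physical minima.
#' Deterministic given the scanner seed.
#'
#' @param phantom A `labeled_phantom`.
#' @param scanner A [scanner_model()].
#' @return List with `scalar_volume`s `ed` and `ean`.
#' @export
simulate_dlct <- function(phantom, scanner = scanner_model()) {
  stopifnot(inherits(phantom, "labeled_phantom"),
            inherits(scanner, "scanner_model"))
  d <- dim(phantom$truth_ed$data)
  ed <- phantom$truth_ed$data * (1 + .bias_field(scanner$ed_bias, phantom))
  ean <- phantom$truth_ean$data * (1 + .bias_field(scanner$ean_bias, phantom))
  if (scanner$ed_noise_sd > 0) {
    set.seed(.sub_seed(scanner$seed, 1L))
    ed <- ed + stats::rnorm(length(ed), 0, scanner$ed_noise_sd)
  }
  if (scanner$ean_noise_sd > 0) {
    set.seed(.sub_seed(scanner$seed, 2L))
    ean <- ean + stats::rnorm(length(ean), 0, scanner$ean_noise_sd)
  }
  ed <- pmax(ed, 1e-4); ean <- pmax(ean, 1)
  dim(ed) <- d; dim(ean) <- d
  list(ed = vol_like(phantom$truth_ed, ed),
       ean = vol_like(phantom$truth_ean, ean))
}

#' Simulate a SECT acquisition
#'
#' Per-voxel CT numbers from the assigned compositions via the
#' stoichiometric model ([predict_hu()]) acting as the "true" scanner
#' physics, plus bias and seeded Gaussian noise. Water maps to 0 HU and air
#' to approximately -1000 HU in the noise-free case.
#'
#' @param phantom A `labeled_phantom`.
#' @param sp A [stoich_params()] object (the truth scanner spectrum).
#' @param scanner A [scanner_model()].
#' @return A `scalar_volume` of Hounsfield numbers.
#' @export
simulate_sect <- function(phantom, sp, scanner = scanner_model()) {
  stopifnot(inherits(phantom, "labeled_phantom"),
            inherits(sp, "stoich_params"))
  comps <- phantom$label_table[phantom$properties$tissue]
  hu_label <- vapply(comps, predict_hu, 0, sp = sp)
  hu <- hu_label[phantom$labels$data + 1L]
  hu <- hu + .bias_field(scanner$hu_bias, phantom)
  if (scanner$hu_noise_sd > 0) {
    set.seed(.sub_seed(scanner$seed, 3L))
    hu <- hu + stats::rnorm(length(hu), 0, scanner$hu_noise_sd)
  }
  hu <- pmin(pmax(hu, -1024), 3071)
  dim(hu) <- dim(phantom$labels$data)
  vol_like(phantom$truth_ed, hu)
}

#' Default truth scanner spectrum parameters
#'
#' Model constants for the simulated 120 kVp-like scanner used as ground
#' truth by [simulate_sect()]; chosen once to give conventional Hounsfield
#' values (adipose slightly negative, cortical bone above 1400 HU).
#'
#' @return A [stoich_params()] object.
#' @export
default_stoich_params <- function() stoich_params(k1 = 3.46e-5, k2 = 5e-4)
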