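# Elemental constants and tissue compositions.
#
# Z and A are standard atomic weights; elemental mean excitation energies
# (eV) follow the standard stopping-power tabulation (ICRU Report 37 style
# values as used throughout proton-therapy CT calibration work).

.ELEMENTS <- data.frame(
  symbol = c("H", "C", "N", "O", "Na", "Mg", "P", "S", "Cl", "Ar", "K", "Ca"),
  Z      = c(1, 6, 7, 8, 11, 12, 15, 16, 17, 18, 19, 20),
  A      = c(1.008, 12.011, 14.007, 15.999, 22.990, 24.305, 30.974, 32.06,
             35.45, 39.948, 39.098, 40.078),
  I_eV   = c(19.2, 78.0, 82.0, 95.0, 149.0, 156.0, 173.0, 180.0, 174.0,
             188.0, 190.0, 191.0),
  stringsAsFactors = FALSE
)
rownames(.ELEMENTS) <- .ELEMENTS$symbol

#' Supported chemical elements
#'
#' Returns the table of elements the package can handle, with atomic number
#' `Z`, standard atomic weight `A` and elemental mean excitation energy
#' `I_eV` used for Bragg-additivity ground truth.
#'
#' @return A data frame with columns `symbol`, `Z`, `A`, `I_eV`.
#' @export
element_table <- function() .ELEMENTS

#' Define a tissue or material composition
#'
#' A named material with mass density and elemental mass fractions. Mass
#' fractions must sum to one (within 1e-6) and may only use elements with
#' tabulated atomic data (see [element_table()]).
#'
#' @param name Material name.
#' @param density Mass density in g/cm^3 (> 0).
#' @param fractions Named numeric vector of elemental mass fractions,
#'   names are element symbols (e.g. `c(H = 0.112, O = 0.888)`).
#' @return An object of class `tissue_comp`.
#' @export
tissue_composition <- function(name, density, fractions) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(density) || length(density) != 1L || density <= 0)
    stop("density must be a single positive number")
  fractions <- fractions[fractions > 0]
  if (length(fractions) == 0L)
    stop("composition must contain at least one element")
  bad <- setdiff(names(fractions), .ELEMENTS$symbol)
  if (length(bad))
    stop("no tabulated atomic data for element(s): ", paste(bad, collapse = ", "))
  if (abs(sum(fractions) - 1) > 1e-6)
    stop("mass fractions must sum to 1 (got ", format(sum(fractions)), ")")
  structure(list(name = name, density = density,
                 fractions = fractions[order(match(names(fractions), .ELEMENTS$symbol))]),
            class = "tissue_comp")
}

#' @export
print.tissue_comp <- function(x, ...) {
  cat(sprintf("<tissue_comp> %s (%.4f g/cm^3)\n", x$name, x$density))
  print(round(x$fractions, 4))
  invisible(x)
}

# Z/A-weighted electron count per gram relative quantities for a composition.
.comp_zoa <- function(comp) {
  el <- .ELEMENTS[names(comp$fractions), ]
  sum(comp$fractions * el$Z / el$A)
}

#' Electron fractions of a composition
#'
#' Fraction of electrons contributed by each element:
#' \eqn{\lambda_i = w_i Z_i / A_i / \sum_j w_j Z_j / A_j}.
#'
#' @param comp A [tissue_composition()] object.
#' @return Named numeric vector summing to 1.
#' @export
electron_fractions <- function(comp) {
  stopifnot(inherits(comp, "tissue_comp"))
  el <- .ELEMENTS[names(comp$fractions), ]
  x <- comp$fractions * el$Z / el$A
  x / sum(x)
}

#' Relative electron density of a composition
#'
#' Electron density relative to water:
#' \eqn{\rho_e = \rho \sum_i w_i Z_i/A_i / (\rho_w \sum w Z/A)_{water}}.
#'
#' @param comp A [tissue_composition()] object.
#' @return Dimensionless relative electron density.
#' @export
relative_electron_density <- function(comp) {
  stopifnot(inherits(comp, "tissue_comp"))
  comp$density * .comp_zoa(comp) / .comp_zoa(water_composition())
}

#' Reference water composition
#'
#' @return A `tissue_comp` for liquid water at 1.000 g/cm^3.
#' @export
water_composition <- function() {
  .CACHE$water
}

#' Mix two compositions by mass
#'
#' Mass fractions combine linearly with mixing fraction `f` of material `b`;
#' density follows volume additivity (1/rho = (1-f)/rho_a + f/rho_b).
#' Used to build density/mineral-graded bone surrogates for calibration.
#'
#' @param a,b `tissue_comp` objects.
#' @param f Mass fraction of `b` in the mixture, in \[0, 1\].
#' @param name Optional name for the mixture.
#' @return A `tissue_comp`.
#' @export
tissue_mixture <- function(a, b, f, name = NULL) {
  stopifnot(inherits(a, "tissue_comp"), inherits(b, "tissue_comp"),
            f >= 0, f <= 1)
  syms <- union(names(a$fractions), names(b$fractions))
  wa <- wb <- stats::setNames(numeric(length(syms)), syms)
  wa[names(a$fractions)] <- a$fractions
  wb[names(b$fractions)] <- b$fractions
  w <- (1 - f) * wa + f * wb
  rho <- 1 / ((1 - f) / a$density + f / b$density)
  if (is.null(name)) name <- sprintf("%s_%02.0f_%s", a$name, 100 * f, b$name)
  tissue_composition(name, rho, w / sum(w))
}

#' Read material compositions from CSV
#'
#' The CSV must have columns `name`, `density` and one column per element
#' symbol holding mass fractions (zeros allowed).
#'
#' @param path CSV file path.
#' @return Named list of `tissue_comp` objects.
#' @export
read_compositions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("name", "density") %in% names(df)))
  el_cols <- intersect(names(df), .ELEMENTS$symbol)
  out <- lapply(seq_len(nrow(df)), function(i) {
    w <- unlist(df[i, el_cols])
    tissue_composition(df$name[i], df$density[i], w[w > 0])
  })
  stats::setNames(out, df$name)
}

#' Write material compositions to CSV
#'
#' @param comps List of `tissue_comp` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_compositions <- function(comps, path) {
  syms <- .ELEMENTS$symbol
  rows <- lapply(comps, function(cc) {
    w <- stats::setNames(numeric(length(syms)), syms)
    w[names(cc$fractions)] <- cc$fractions
    c(list(name = cc$name, density = cc$density), as.list(w))
  })
  df <- do.call(rbind, lapply(rows, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Embedded reference tissue table
#'
#' Adult reference tissues (ICRU-44/ICRP style compositions) used as ground
#' truth for the synthetic head phantom and as the reference set for the
#' CT-number-to-SPR calibrations: water, air, lung (deflated), adipose,
#' breast, soft tissue, muscle, brain, liver, eye, cerebrospinal fluid,
#' spongiosa, skull-base bone, cranial bone and cortical bone.
#'
#' @return Named list of `tissue_comp` objects.
#' @export
reference_tissues <- function() {
  .CACHE$reference
}

#' Synthetic calibration insert set
#'
#' A synthetic stand-in for a tissue-surrogate electron-density calibration
#' phantom: lung-equivalent materials at two densities, soft tissues, and a
#' density/mineral-graded series of soft-tissue/cortical-bone mixtures
#' spanning the clinical Hounsfield range. No measured surrogate data are
#' used; all materials derive from the embedded reference compositions.
#'
#' @return Named list of `tissue_comp` objects (12 inserts).
#' @export
synthetic_inserts <- function() {
  tis <- reference_tissues()
  lung <- tis$lung_deflated
  lung300 <- tissue_composition("lung_300", 0.30, lung$fractions)
  lung450 <- tissue_composition("lung_450", 0.45, lung$fractions)
  mixes <- lapply(c(0.15, 0.3, 0.45, 0.6, 0.8), function(f)
    tissue_mixture(tis$soft_tissue, tis$cortical_bone, f,
                   name = sprintf("bone_mix_%02.0f", 100 * f)))
  out <- c(list(lung300, lung450, tis$adipose, tis$breast, tis$water,
                tis$brain, tis$muscle), mixes)
  stats::setNames(out, vapply(out, `[[`, "", "name"))
}

#' Extended tissue set for HLUT construction
#'
#' The reference tissues augmented with density-graded lung and graded
#' soft-tissue/cortical-bone mixtures so every Hounsfield segment of a
#' many-segment look-up table is populated.
#'
#' @return Named list of `tissue_comp` objects.
#' @export
hlut_reference_tissues <- function() {
  tis <- reference_tissues()
  lung <- tis$lung_deflated
  lungs <- lapply(c(0.2, 0.4, 0.6, 0.8), function(r)
    tissue_composition(sprintf("lung_%02.0f", 100 * r), r, lung$fractions))
  mixes <- lapply(seq(0.1, 0.9, by = 0.1), function(f)
    tissue_mixture(tis$soft_tissue, tis$cortical_bone, f,
                   name = sprintf("bone_mix_%02.0f", 100 * f)))
  out <- c(tis, lungs, mixes)
  stats::setNames(out, vapply(out, `[[`, "", "name"))
}

# Composition cache, filled at load time from the packaged CSV.
.CACHE <- new.env(parent = emptyenv())

.onLoad <- function(libname, pkgname) {
  path <- system.file("extdata", "reference_tissues.csv", package = pkgname)
  comps <- read_compositions(path)
  .CACHE$reference <- comps
  .CACHE$water <- comps$water
  invisible()
}
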