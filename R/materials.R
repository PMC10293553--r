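# Material registry: elemental weight fractions + mass density for the
# HU-binned training tissues and the ICRP-style testing tissues, plus
# effective-Z/A and electron-range evaluation.

# Fixed element set supported by the registry. Z and A (g/mol).
DPK_ELEMENTS <- data.frame(
  symbol = c("H", "C", "N", "O", "Na", "Mg", "P", "S", "Cl", "Ar", "K", "Ca"),
  Z = c(1, 6, 7, 8, 11, 12, 15, 16, 17, 18, 19, 20),
  A = c(1.008, 12.011, 14.007, 15.999, 22.990, 24.305, 30.974, 32.06,
        35.45, 39.948, 39.098, 40.078),
  stringsAsFactors = FALSE
)

.dpk_env <- new.env(parent = emptyenv())

.materials_table <- function() {
  if (is.null(.dpk_env$materials)) {
    path <- system.file("extdata", "materials.csv", package = "dpkchain")
    tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    .dpk_env$materials <- tab
  }
  .dpk_env$materials
}

#' Registered material labels
#'
#' @param set `"all"`, `"training"` (HU-binned tissues) or `"testing"`
#'   (ICRP-style air, lung, soft tissue, cortical bone).
#' @return Character vector of labels usable with [material_lookup()].
#' @export
material_labels <- function(set = c("all", "training", "testing")) {
  set <- match.arg(set)
  tab <- .materials_table()
  testing <- c("Air", "Lung", "Soft Tissue", "Cortical Bone")
  labs <- c(tab$label, names(.dpk_env$user_materials))
  switch(set,
    all = labs,
    training = setdiff(tab$label, testing),
    testing = intersect(labs, testing)
  )
}

new_material <- function(label, weights, density) {
  w <- stats::setNames(numeric(nrow(DPK_ELEMENTS)), DPK_ELEMENTS$symbol)
  w[names(weights)] <- as.numeric(weights)
  if (any(w < 0)) stop("weight fractions must be non-negative")
  s <- sum(w)
  if (s < 0.98 || s > 1.02)
    stop(sprintf("weight fractions of '%s' sum to %.4f, outside [0.98, 1.02]",
                 label, s))
  if (!is.finite(density) || density <= 0) stop("density must be positive")
  structure(list(label = label, weights = w, density = density),
            class = "dpk_material")
}

#' Look up a material by label
#'
#' Returns the elemental composition (weight fractions over H, C, N, O, Na,
#' Mg, P, S, Cl, Ar, K, Ca) and mass density of one of the registered
#' materials: the Hounsfield-unit-binned training tissues, the four ICRP-style
#' testing tissues, or a user-registered material.
#'
#' @param label Material label, e.g. `"HU18"`, `"Soft Tissue"`.
#' @return An object of class `dpk_material`: list with `label`, `weights`
#'   (named numeric over the 12-element set) and `density` (g/cm^3).
#' @seealso [register_material()], [material_labels()], [effective_za()]
#' @export
material_lookup <- function(label) {
  stopifnot(is.character(label), length(label) == 1L)
  user <- .dpk_env$user_materials
  if (!is.null(user) && label %in% names(user)) return(user[[label]])
  tab <- .materials_table()
  i <- match(label, tab$label)
  if (is.na(i)) {
    stop(sprintf("unknown material '%s'; available labels: %s", label,
                 paste(material_labels(), collapse = ", ")))
  }
  row <- tab[i, ]
  new_material(label, unlist(row[DPK_ELEMENTS$symbol]), row$density)
}

#' Register a user-defined material
#'
#' Only the 12 elements of the built-in tables are supported; compositions
#' containing other elements are rejected (documented limitation of the
#' effective-Z parameterization used downstream).
#'
#' @param label Label for later lookup.
#' @param weights Named numeric vector of weight fractions (subset of the
#'   supported element symbols); must sum to within \[0.98, 1.02\].
#' @param density Mass density in g/cm^3.
#' @return The registered `dpk_material`, invisibly.
#' @export
register_material <- function(label, weights, density) {
  bad <- setdiff(names(weights), DPK_ELEMENTS$symbol)
  if (length(bad))
    stop("unsupported elements: ", paste(bad, collapse = ", "),
         " (supported: ", paste(DPK_ELEMENTS$symbol, collapse = ", "), ")")
  m <- new_material(label, weights, density)
  if (is.null(.dpk_env$user_materials)) .dpk_env$user_materials <- list()
  .dpk_env$user_materials[[label]] <- m
  invisible(m)
}

#' @export
print.dpk_material <- function(x, ...) {
  cat(sprintf("<dpk_material> %s (density %.4f g/cm^3)\n", x$label, x$density))
  w <- x$weights[x$weights > 0]
  cat("  ", paste(sprintf("%s=%.4g", names(w), w), collapse = " "), "\n")
  invisible(x)
}

#' Effective atomic number and weight of a compound
#'
#' Electron-fraction (Tabata-style) compound rule: with weight fractions
#' \eqn{w_i}, \eqn{Z_{eff} = \sum_i w_i (Z_i/A_i) Z_i / \sum_i w_i (Z_i/A_i)}
#' and \eqn{A_{eff} = Z_{eff} / \sum_i w_i (Z_i/A_i)}, so that
#' \eqn{Z_{eff}/A_{eff}} equals the electron density per unit mass of the
#' mixture. Alternative rules can be supplied via `rule`.
#'
#' @param material A `dpk_material`.
#' @param rule Optional function `(w, Z, A) -> list(z_eff, a_eff)` replacing
#'   the default electron-fraction weighting.
#' @return List with `z_eff` (dimensionless) and `a_eff` (g/mol).
#' @export
effective_za <- function(material, rule = NULL) {
  stopifnot(inherits(material, "dpk_material"))
  w <- material$weights
  if (all(w == 0)) stop("all-zero weight fractions")
  Z <- DPK_ELEMENTS$Z
  A <- DPK_ELEMENTS$A
  if (!is.null(rule)) return(rule(w, Z, A))
  za <- sum(w * Z / A)           # electrons per g (in units of 1/A)
  z_eff <- sum(w * Z^2 / A) / za
  list(z_eff = z_eff, a_eff = z_eff / za)
}

# Tabata, Ito & Okabe generalized analytic fit for the electron range
# (coefficients as published for the extrapolated-range fit; see vignette for
# the relation to CSDA-range tabulations and the table-override mechanism).
.TABATA_B <- c(b1 = 0.2335, b2 = 1.209, b3 = 1.78e-4, b4 = 0.9891,
               b5 = 3.01e-4, b6 = 1.468, b7 = 1.180e-2, b8 = 1.232,
               b9 = 0.109)
.MEC2_MEV <- 0.51099895

tabata_range_areal <- function(energy_kev, z_eff, a_eff) {
  b <- .TABATA_B
  tau <- (energy_kev / 1000) / .MEC2_MEV
  a1 <- b["b1"] * a_eff / z_eff^b["b2"]
  a2 <- b["b3"] * z_eff
  a3 <- b["b4"] - b["b5"] * z_eff
  a4 <- b["b6"] - b["b7"] * z_eff
  a5 <- b["b8"] / z_eff^b["b9"]
  unname(a1 * (log(1 + a2 * tau) / a2 - a3 * tau / (1 + a4 * tau^a5)))
}

#' Electron range in a material
#'
#' Evaluates the Tabata et al. analytic range fit using the material's
#' effective atomic number and weight, returning both the areal (g/cm^2) and
#' linear (cm) range. A user-supplied tabulation (two-column data frame or CSV
#' with `energy_keV`, `range_g_cm2`) can override the analytic fit, in which
#' case the range is log-log interpolated from the table.
#'
#' @param energy_kev Electron kinetic energy in keV (vectorized), within
#'   \[1, 30000\].
#' @param material A `dpk_material`.
#' @param range_table Optional override table (data frame with columns
#'   `energy_keV` and `range_g_cm2`, or path to such a CSV).
#' @return List with `r0_areal` (g/cm^2) and `r0_linear` (cm), each the same
#'   length as `energy_kev`.
#' @export
csda_range <- function(energy_kev, material, range_table = NULL) {
  stopifnot(inherits(material, "dpk_material"))
  if (any(!is.finite(energy_kev)) || any(energy_kev <= 0))
    stop("energy must be positive and finite")
  if (any(energy_kev < 1 | energy_kev > 30000))
    stop("energy outside supported domain [1, 30000] keV")
  if (is.null(range_table)) {
    za <- effective_za(material)
    areal <- tabata_range_areal(energy_kev, za$z_eff, za$a_eff)
  } else {
    if (is.character(range_table))
      range_table <- utils::read.csv(range_table)
    stopifnot(all(c("energy_keV", "range_g_cm2") %in% names(range_table)))
    areal <- exp(stats::approx(log(range_table$energy_keV),
                               log(range_table$range_g_cm2),
                               xout = log(energy_kev), rule = 2)$y)
  }
  list(r0_areal = areal, r0_linear = areal / material$density)
}
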