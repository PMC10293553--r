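# Synthetic shell-scoring emulator: a documented parametric stand-in for
# full Monte Carlo transport, producing per-shell energy deposition around a
# central monoenergetic electron point source in a homogeneous sphere, with
# statistical noise calibrated to ~1% at the kernel peak for 1e7 primaries.

#' Concentric-shell scoring grid
#'
#' Scaled-distance grid of concentric spherical shells around a central point
#' source. The monoenergetic scoring geometry uses 60 shells of thickness
#' R_CSDA/40 (outer radius 1.5 R_CSDA); the beta-kernel geometry uses 120
#' shells of thickness r_N/100 (outer radius 1.2 r_N).
#'
#' @param n_shells Number of shells.
#' @param thickness Shell thickness in scaled units (fraction of the range).
#' @return List of class `shell_grid` with `n_shells`, `thickness`,
#'   `midpoints` (scaled shell-midpoint distances) and `outer` radius.
#' @export
shell_grid <- function(n_shells = 60, thickness = 1 / 40) {
  stopifnot(n_shells >= 1, thickness > 0)
  structure(list(
    n_shells = as.integer(n_shells),
    thickness = thickness,
    midpoints = (seq_len(n_shells) - 0.5) * thickness,
    outer = n_shells * thickness
  ), class = "shell_grid")
}

#' Beta-kernel scoring grid (120 shells of thickness r_N/100)
#' @param r_n_cm Linear range at the spectrum maximum energy, cm.
#' @return A `shell_grid` with 120 shells, thickness 1/100, outer radius 1.2,
#'   and attribute `r_n_cm`.
#' @export
beta_grid <- function(r_n_cm) {
  g <- shell_grid(120, 1 / 100)
  attr(g, "r_n_cm") <- r_n_cm
  g
}

# Noiseless emulator family. Shape g(x) = x^a exp(-b x^c) with c = 2.2,
# a and the mode tied to log-energy and effective Z so kernels vary smoothly
# across the (energy, material) plane; eta = 1 - Y is a radiative-loss proxy.
.emulator_params <- function(energy0, z_eff) {
  cc <- 2.2
  a <- min(max(0.6 + 0.25 * log(energy0 / 100), 0.2), 1.8)
  m <- min(max(0.35 + 0.05 * log(energy0 / 100) + 0.01 * (z_eff - 7),
               0.2), 0.7)
  b <- a / (cc * m^cc)
  t_mev <- energy0 / 1000
  q <- 6e-4 * z_eff * t_mev
  list(a = a, b = b, c = cc, eta = 1 - q / (1 + q))
}

.emulator_noiseless <- function(energy0, z_eff, grid) {
  p <- .emulator_params(energy0, z_eff)
  g <- grid$midpoints^p$a * exp(-p$b * grid$midpoints^p$c)
  p$eta * g / sum(g)
}

#' Emulate per-shell energy deposition for a monoenergetic point source
#'
#' Draws a seeded, noisy realization of the documented parametric deposition
#' family on the scoring grid. The noiseless shape is normalized so the total
#' deposited fraction equals the absorbed fraction eta (1 minus a
#' radiative-loss proxy); multiplicative Gaussian noise per shell has relative
#' standard deviation `0.01 * sqrt(f_peak / max(f_i, 1e-4)) *
#' sqrt(1e7 / n_primaries)`, i.e. 1% at the peak shell for 1e7 primaries,
#' growing in the tail. Negative samples are clipped to zero. Setting
#' `n_primaries = Inf` disables noise and returns the closed-form family.
#'
#' @param energy0 Source kinetic energy in keV, within \[10, 3000\].
#' @param material A `dpk_material`.
#' @param n_primaries Emulated number of primary histories (>= 1, or `Inf`).
#' @param seed Integer seed; identical arguments give identical output.
#' @param grid A `shell_grid` (default: the 60-shell monoenergetic grid).
#' @return Object of class `shell_edep`: list with `energy0`, `material`,
#'   `grid`, `edep_fraction` (per-shell deposited fraction of E0),
#'   `n_primaries`, `seed`.
#' @export
emulate_shell_edep <- function(energy0, material, n_primaries = 1e7,
                               seed = 1L, grid = shell_grid()) {
  if (!is.finite(energy0) || energy0 < 10 || energy0 > 3000)
    stop("energy0 outside supported domain [10, 3000] keV")
  if (is.na(n_primaries) || n_primaries < 1)
    stop("n_primaries must be >= 1")
  stopifnot(inherits(material, "dpk_material"), inherits(grid, "shell_grid"))
  z_eff <- effective_za(material)$z_eff
  f <- .emulator_noiseless(energy0, z_eff, grid)
  if (is.finite(n_primaries)) {
    sigma <- 0.01 * sqrt(max(f) / pmax(f, 1e-4)) * sqrt(1e7 / n_primaries)
    f <- .with_seed(seed, {
      pmax(f * (1 + sigma * stats::rnorm(length(f))), 0)
    })
    # guard energy conservation against extreme low-statistics draws
    if (sum(f) > 1) f <- f / sum(f)
  }
  structure(list(energy0 = energy0, material = material, grid = grid,
                 edep_fraction = f, n_primaries = n_primaries,
                 seed = as.integer(seed)),
            class = "shell_edep")
}

# Evaluate expr with a temporary RNG state seeded at `seed`, restoring any
# pre-existing state afterwards.
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Convert per-shell energy deposition to a scaled dose point kernel
#'
#' Applies the defining identity of the scaled DPK on a shell grid:
#' `F_i = (deltaE_i / E0) / (deltar / R)`, so that `sum(F_i) * deltax` equals
#' the total deposited energy fraction exactly.
#'
#' @param edep A `shell_edep`.
#' @return Object of class `sdpk`.
#' @export
edep_to_sdpk <- function(edep) {
  stopifnot(inherits(edep, "shell_edep"))
  g <- edep$grid
  if (g$thickness <= 0) stop("grid thickness must be positive")
  new_sdpk(g, edep$edep_fraction / g$thickness,
           energy0 = edep$energy0, material_label = edep$material$label,
           scale = "rcsda")
}

new_sdpk <- function(grid, values, energy0 = NA_real_,
                     material_label = NA_character_, scale = "rcsda",
                     r_n_cm = NULL) {
  stopifnot(inherits(grid, "shell_grid") || is.list(grid))
  if (any(!is.finite(values)) || any(values < 0))
    stop("sDPK values must be finite and non-negative")
  if (sum(values) * grid$thickness > 1.02)
    stop("sDPK integral exceeds 1.02: energy conservation violated")
  structure(list(x = grid$midpoints, dx = grid$thickness, F = values,
                 energy0 = energy0, material_label = material_label,
                 scale = scale, r_n_cm = r_n_cm),
            class = "sdpk")
}

#' @export
print.sdpk <- function(x, ...) {
  cat(sprintf(
    "<sdpk> %d shells, dx = %.4g, scale = %s, integral = %.4f\n",
    length(x$F), x$dx, x$scale, sum(x$F) * x$dx))
  if (!is.na(x$energy0)) cat(sprintf("  E0 = %g keV", x$energy0))
  if (!is.na(x$material_label)) cat(sprintf("  material = %s", x$material_label))
  cat("\n")
  invisible(x)
}

#' @export
plot.sdpk <- function(x, ...) {
  graphics::plot(x$x, x$F, type = "l", xlab = "scaled distance",
                 ylab = "F", ...)
}

# Feature order used throughout: energy, areal range, density, then the ten
# tabulated weight fractions (N and O intentionally not part of the feature
# vector; see the methods vignette).
DPK_FEATURES <- c("E0_keV", "R_CSDA_g_cm2", "density",
                  paste0("w_", c("H", "C", "Na", "Mg", "P", "S", "Cl",
                                 "Ar", "K", "Ca")))

.row_seed <- function(master_seed, i) {
  as.integer((as.numeric(master_seed) * 48271 + 7919 * i) %% 2147483647)
}

#' Generate a training/testing dataset of emulated scaled DPKs
#'
#' One row per (material, energy): 13 features (source energy, areal range,
#' density, and ten elemental weight fractions) and 60 targets `F1..F60`
#' from [emulate_shell_edep()] followed by [edep_to_sdpk()]. Row-level seeds
#' are derived deterministically from `seed`.
#'
#' @param materials List of `dpk_material` (or character labels).
#' @param energies Numeric vector of source energies in keV.
#' @param n_primaries Emulated histories per row (`Inf` disables noise).
#' @param seed Master integer seed.
#' @return A data frame with columns `material_label`, the 13 features and
#'   `F1..F60`; attributes `feature_cols` and `target_cols` give the column
#'   names in model order.
#' @export
generate_dataset <- function(materials, energies, n_primaries = 1e7,
                             seed = 1L) {
  if (!length(materials) || !length(energies)) stop("empty materials/energies")
  if (is.character(materials)) materials <- lapply(materials, material_lookup)
  labs <- vapply(materials, function(m) m$label, character(1))
  key <- paste(rep(labs, each = length(energies)),
               rep(energies, times = length(labs)))
  if (anyDuplicated(key)) stop("duplicate (material, energy) pairs")
  grid <- shell_grid()
  rows <- vector("list", length(key))
  i <- 0L
  for (m in materials) {
    r0 <- csda_range(energies, m)$r0_areal
    for (j in seq_along(energies)) {
      i <- i + 1L
      ed <- emulate_shell_edep(energies[j], m, n_primaries,
                               seed = .row_seed(seed, i), grid = grid)
      k <- edep_to_sdpk(ed)
      feats <- c(energies[j], r0[j], m$density,
                 m$weights[c("H", "C", "Na", "Mg", "P", "S", "Cl",
                             "Ar", "K", "Ca")])
      rows[[i]] <- c(feats, k$F)
    }
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c(DPK_FEATURES, paste0("F", seq_len(grid$n_shells)))
  out <- cbind(material_label = rep(labs, each = length(energies)), out,
               stringsAsFactors = FALSE)
  attr(out, "feature_cols") <- DPK_FEATURES
  attr(out, "target_cols") <- paste0("F", seq_len(grid$n_shells))
  out
}

#' Import a table of monoenergetic scaled DPKs
#'
#' Reads Monte Carlo kernels in the interchange schema
#' `material_label,energy_keV,shell_index,x_mid,F`, allowing externally
#' simulated kernels to replace the emulator everywhere downstream.
#'
#' @param path CSV path (or a data frame already in the schema).
#' @return Object of class `kernel_table`: list of `sdpk` keyed by
#'   `material_label` and `energy_keV`, with an index data frame.
#' @export
read_kernel_table <- function(path) {
  tab <- if (is.character(path)) utils::read.csv(path) else path
  need <- c("material_label", "energy_keV", "shell_index", "x_mid", "F")
  if (!all(need %in% names(tab)))
    stop("kernel table must have columns: ", paste(need, collapse = ", "))
  sp <- split(tab, list(tab$material_label, tab$energy_keV), drop = TRUE)
  kernels <- lapply(sp, function(d) {
    d <- d[order(d$shell_index), ]
    dx <- if (nrow(d) > 1) d$x_mid[2] - d$x_mid[1] else 2 * d$x_mid[1]
    g <- structure(list(n_shells = nrow(d), thickness = dx,
                        midpoints = d$x_mid, outer = nrow(d) * dx),
                   class = "shell_grid")
    new_sdpk(g, d$F, energy0 = d$energy_keV[1],
             material_label = d$material_label[1], scale = "rcsda")
  })
  idx <- data.frame(
    material_label = vapply(kernels, function(k) k$material_label, ""),
    energy_keV = vapply(kernels, function(k) k$energy0, 0),
    stringsAsFactors = FALSE
  )
  structure(list(kernels = kernels, index = idx), class = "kernel_table")
}

#' Write scaled DPKs in the interchange CSV schema
#' @param kernels A list of `sdpk` objects (or a single one).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_kernel_table <- function(kernels, path) {
  if (inherits(kernels, "sdpk")) kernels <- list(kernels)
  rows <- do.call(rbind, lapply(kernels, function(k) {
    data.frame(material_label = k$material_label, energy_keV = k$energy0,
               shell_index = seq_along(k$F), x_mid = k$x, F = k$F)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
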