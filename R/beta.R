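# Beta-emitter kernel synthesis: a beta-emitter scaled DPK is the
# intensity-weighted superposition of monoenergetic kernels,
#   F_beta(r/r_N) = r_N * sum_j I_j E_j F_j(r/r_0j) / r_0j / E_eff,
# with unit-sum line intensities I_j, E_eff = sum_j I_j E_j, r_0j the range at
# line energy E_j and r_N the range at the spectrum endpoint.

#' Construct a beta emission spectrum
#'
#' Intensities are normalized to unit sum; the effective energy is the
#' intensity-weighted mean line energy and the endpoint is the last (largest)
#' energy. This direct constructor is the no-spline path; use
#' [resample_spectrum()] to regrid a raw tabulation.
#'
#' @param energies Ascending line energies in keV.
#' @param intensities Non-negative per-decay emission weights.
#' @return Object of class `beta_spectrum` with `energies`, `intensities`
#'   (unit sum), `e_max`, `e_eff` (keV).
#' @export
beta_spectrum <- function(energies, intensities) {
  stopifnot(length(energies) == length(intensities))
  if (is.unsorted(energies, strictly = TRUE)) stop("energies must be ascending")
  if (any(intensities < 0) || sum(intensities) <= 0)
    stop("intensities must be non-negative with positive sum")
  intensities <- intensities / sum(intensities)
  structure(list(energies = energies, intensities = intensities,
                 e_max = energies[length(energies)],
                 e_eff = sum(intensities * energies)),
            class = "beta_spectrum")
}

#' @export
print.beta_spectrum <- function(x, ...) {
  cat(sprintf("<beta_spectrum> %d lines, E_max = %.1f keV, E_eff = %.1f keV\n",
              length(x$energies), x$e_max, x$e_eff))
  invisible(x)
}

#' Resample a raw beta spectrum onto a fine energy grid
#'
#' Fits a degree-3 smoothing spline through the raw (energy, intensity) pairs
#' and evaluates it at `n` equally spaced energies from 10 keV up to the raw
#' endpoint. Negative spline values are clipped to zero and the intensities
#' renormalized to unit sum.
#'
#' @param raw A `beta_spectrum`, a data frame with columns
#'   `energy_keV`/`intensity`, or a 2-column matrix.
#' @param n Number of resampled pairs (default 1000).
#' @return A `beta_spectrum` on the resampled grid.
#' @export
resample_spectrum <- function(raw, n = 1000) {
  if (inherits(raw, "beta_spectrum")) {
    e <- raw$energies; y <- raw$intensities
  } else if (is.data.frame(raw)) {
    stopifnot(all(c("energy_keV", "intensity") %in% names(raw)))
    e <- raw$energy_keV; y <- raw$intensity
  } else {
    raw <- as.matrix(raw); e <- raw[, 1]; y <- raw[, 2]
  }
  if (length(e) < 4) stop("need at least 4 raw spectrum points")
  if (is.unsorted(e, strictly = TRUE)) stop("energies must be ascending")
  e_max <- e[length(e)]
  if (e_max <= 10) stop("spectrum endpoint must exceed 10 keV")
  grid <- seq(10, e_max, length.out = n)
  if (stats::sd(y) == 0) {
    yi <- rep(y[1], n)  # spline of a constant is the constant
  } else {
    fit <- stats::smooth.spline(e, y)
    yi <- pmax(stats::predict(fit, grid)$y, 0)
  }
  if (sum(yi) <= 0) stop("resampled spectrum vanishes on [10, E_max]")
  beta_spectrum(grid, yi)
}

#' Read a spectrum CSV (`energy_keV,intensity` with header)
#' @param path CSV path.
#' @return A `beta_spectrum` (intensities normalized; no resampling applied).
#' @export
read_spectrum_csv <- function(path) {
  tab <- utils::read.csv(path)
  if (!all(c("energy_keV", "intensity") %in% names(tab)))
    stop("spectrum CSV must have header columns energy_keV,intensity")
  beta_spectrum(tab$energy_keV, tab$intensity)
}

#' Bundle a spectrum with decay data
#' @param name Nuclide label.
#' @param half_life_hours Physical half-life in hours (> 0).
#' @param spectrum A `beta_spectrum`.
#' @return Object of class `radionuclide`.
#' @export
radionuclide <- function(name, half_life_hours, spectrum) {
  stopifnot(half_life_hours > 0, inherits(spectrum, "beta_spectrum"))
  structure(list(name = name, half_life_hours = half_life_hours,
                 spectrum = spectrum), class = "radionuclide")
}

#' Read a nuclide registry entry (JSON with name, half_life_hours,
#' spectrum path relative to the JSON file)
#' @param path JSON path.
#' @return A `radionuclide`.
#' @export
read_nuclide_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  sp <- doc$spectrum
  if (!file.exists(sp)) sp <- file.path(dirname(path), sp)
  radionuclide(doc$name, doc$half_life_hours, read_spectrum_csv(sp))
}

#' Parametric allowed-shape beta spectrum
#'
#' Synthetic spectrum with the allowed Fermi shape
#' \eqn{N(E) \propto \sqrt{E^2 + 2 E m_e c^2} (Q - E)^2} sampled on a uniform
#' grid; a stand-in for evaluated decay data in tests and examples.
#'
#' @param q_kev Endpoint (Q-value) in keV.
#' @param n Number of sampled points.
#' @return A `beta_spectrum`.
#' @export
fermi_beta_spectrum <- function(q_kev, n = 200) {
  stopifnot(q_kev > 20)
  e <- seq(q_kev / n, q_kev, length.out = n)
  w <- sqrt(e^2 + 2 * e * 511) * (q_kev - e)^2
  beta_spectrum(e, pmax(w, 0))
}

#' Synthetic example nuclides
#'
#' Three fictitious beta emitters with allowed-shape spectra spanning low,
#' medium, and high endpoint energies, with half-lives typical of therapy
#' nuclides. These are synthetic stand-ins; evaluated decay data (e.g.
#' ICRP 107) should be supplied via [read_spectrum_csv()] for real studies.
#'
#' @return Named list of `radionuclide` objects (`SynHE`, `SynME`, `SynLE`).
#' @export
example_nuclides <- function() {
  list(
    SynHE = radionuclide("SynHE", 64.2, fermi_beta_spectrum(2280)),
    SynME = radionuclide("SynME", 192.5, fermi_beta_spectrum(800)),
    SynLE = radionuclide("SynLE", 159.5, fermi_beta_spectrum(500))
  )
}

# Evaluate the monoenergetic kernel F(x) for each spectrum line energy.
# Returns a function (j, x) -> F values, plus the per-line linear ranges.
.mono_kernel_source <- function(model_or_table, spectrum, material,
                                range_table = NULL) {
  e <- spectrum$energies
  if (inherits(model_or_table, "dpk_chain")) {
    feats <- dpk_features(material, e, range_table = range_table)
    K <- predict(model_or_table, feats)           # n_lines x 60
    xg <- shell_grid(ncol(K), 1 / 40)$midpoints
  } else if (inherits(model_or_table, "kernel_table")) {
    idx <- model_or_table$index
    sel <- idx$material_label == material$label
    if (!any(sel)) stop("kernel table has no entries for ", material$label)
    ks <- model_or_table$kernels[sel]
    eg <- idx$energy_keV[sel]
    o <- order(eg); ks <- ks[o]; eg <- eg[o]
    if (any(e < min(eg) * (1 - 1e-9)) || any(e > max(eg) * (1 + 1e-9)))
      stop("spectrum lines outside tabulated kernel energies [",
           min(eg), ", ", max(eg), "] keV")
    xg <- ks[[1]]$x
    Kt <- do.call(rbind, lapply(ks, function(k) k$F))  # n_tab x shells
    # linear interpolation of kernel values in log energy
    K <- matrix(0, length(e), length(xg))
    le <- log(e); leg <- log(eg)
    i2 <- pmin(pmax(findInterval(le, leg), 1), length(eg) - 1)
    t <- (le - leg[i2]) / (leg[i2 + 1] - leg[i2])
    t <- pmin(pmax(t, 0), 1)
    K <- Kt[i2, , drop = FALSE] * (1 - t) + Kt[i2 + 1, , drop = FALSE] * t
  } else stop("model_or_table must be a dpk_chain or kernel_table")
  r0 <- csda_range(e, material, range_table = range_table)$r0_linear
  list(K = K, xgrid = xg, r0_linear = r0)
}

#' Synthesize the scaled DPK of a beta emitter
#'
#' Combines monoenergetic kernels (predicted by a fitted [dpk_chain()] or
#' taken from an imported [read_kernel_table()] table) over the resampled
#' emission spectrum. Each line's kernel is evaluated at the 120 shell
#' midpoints of the beta grid (thickness r_N/100, outer radius 1.2 r_N) by
#' linear interpolation in scaled distance, with F = 0 beyond the
#' monoenergetic grid's outer radius.
#'
#' @param model_or_table A `dpk_chain` or `kernel_table`.
#' @param spectrum A `beta_spectrum` (typically from [resample_spectrum()]).
#' @param material A `dpk_material` or label.
#' @param range_table Optional range override (see [csda_range()]).
#' @return An `sdpk` on the beta grid, scale `"rN"`, with `r_n_cm` set.
#' @export
beta_sdpk <- function(model_or_table, spectrum, material, range_table = NULL) {
  stopifnot(inherits(spectrum, "beta_spectrum"))
  if (is.character(material)) material <- material_lookup(material)
  bad <- spectrum$energies < 10 | spectrum$energies > 3000
  if (any(bad))
    stop("spectrum lines outside model validity [10, 3000] keV: ",
         paste(utils::head(signif(spectrum$energies[bad], 4), 5),
               collapse = ", "))
  src <- .mono_kernel_source(model_or_table, spectrum, material, range_table)
  r_n <- csda_range(spectrum$e_max, material,
                    range_table = range_table)$r0_linear
  grid <- beta_grid(r_n)
  r_cm <- grid$midpoints * r_n
  xmax <- max(src$xgrid) + 0.5 * (src$xgrid[2] - src$xgrid[1])
  Fb <- numeric(grid$n_shells)
  w <- spectrum$intensities * spectrum$energies / spectrum$e_eff
  for (j in seq_along(spectrum$energies)) {
    x <- r_cm / src$r0_linear[j]
    fj <- stats::approx(src$xgrid, src$K[j, ], xout = x, rule = 2)$y
    fj[x > xmax] <- 0
    Fb <- Fb + w[j] * fj / src$r0_linear[j]
  }
  new_sdpk(grid, pmax(Fb * r_n, 0), energy0 = NA_real_,
           material_label = material$label, scale = "rN", r_n_cm = r_n)
}

#' Rescale a kernel to the X90 abscissa
#'
#' X90 is the (linearly interpolated) distance within which 90% of the
#' kernel's own absorbed-energy integral is contained. The abscissae are
#' divided by X90 and the values multiplied by it, preserving the integral.
#' Applying the rescale twice is the identity (X90 of the result is 1).
#'
#' @param kernel An `sdpk`.
#' @return An `sdpk` with `scale = "x90"` and attribute `x90` (the pivot in
#'   the input's scaled units).
#' @export
x90_rescale <- function(kernel) {
  stopifnot(inherits(kernel, "sdpk"))
  total <- sum(kernel$F) * kernel$dx
  if (total <= 0) stop("kernel integral is zero; X90 undefined")
  target <- 0.9 * total
  cum <- cumsum(kernel$F) * kernel$dx
  k <- which(cum >= target)[1]
  if (is.na(k)) stop("cumulative energy never reaches the 90% threshold")
  cprev <- if (k == 1) 0 else cum[k - 1]
  x90 <- (k - 1) * kernel$dx + (target - cprev) / kernel$F[k]
  g <- structure(list(n_shells = length(kernel$F),
                      thickness = kernel$dx / x90,
                      midpoints = kernel$x / x90,
                      outer = length(kernel$F) * kernel$dx / x90),
                 class = "shell_grid")
  out <- new_sdpk(g, kernel$F * x90, energy0 = kernel$energy0,
                  material_label = kernel$material_label, scale = "x90",
                  r_n_cm = kernel$r_n_cm)
  attr(out, "x90") <- x90
  out
}

#' Mean absolute percentage error against a reference kernel
#'
#' Interpolates the reference onto the kernel's abscissae and averages
#' `100 |F_ref - F| / |F_ref|` over the shells where the reference is defined
#' and nonzero.
#'
#' @param kernel,reference `sdpk` objects on a common abscissa scale.
#' @return MAPE in percent.
#' @export
mape_vs_reference <- function(kernel, reference) {
  stopifnot(inherits(kernel, "sdpk"), inherits(reference, "sdpk"))
  fr <- stats::approx(reference$x, reference$F, xout = kernel$x)$y
  ok <- !is.na(fr) & fr != 0
  if (!any(ok)) stop("no overlapping support between kernel and reference")
  100 * mean(abs(fr[ok] - kernel$F[ok]) / abs(fr[ok]))
}

#' Write a kernel as CSV with metadata header
#' @param kernel An `sdpk`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sdpk_csv <- function(kernel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# material: %s", kernel$material_label),
               sprintf("# r_N_cm: %.12g",
                       if (is.null(kernel$r_n_cm)) NA else kernel$r_n_cm),
               sprintf("# scale: %s", kernel$scale)), con)
  utils::write.csv(data.frame(x = kernel$x, F = kernel$F), con,
                   row.names = FALSE)
  invisible(path)
}

#' Read a kernel written by [write_sdpk_csv()]
#' @param path CSV path.
#' @return An `sdpk`.
#' @export
read_sdpk_csv <- function(path) {
  hdr <- readLines(path, n = 3)
  meta <- sub("^# [^:]+: ", "", hdr)
  tab <- utils::read.csv(path, comment.char = "#")
  dx <- if (nrow(tab) > 1) tab$x[2] - tab$x[1] else 2 * tab$x[1]
  g <- structure(list(n_shells = nrow(tab), thickness = dx,
                      midpoints = tab$x, outer = nrow(tab) * dx),
                 class = "shell_grid")
  r_n <- suppressWarnings(as.numeric(meta[2]))
  new_sdpk(g, tab$F, material_label = meta[1], scale = meta[3],
           r_n_cm = if (is.na(r_n)) NULL else r_n)
}
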