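# Shared fixtures. Datasets are memoized per test run; everything is built
# in code from small, fixed seeds.

.fixture_env <- new.env(parent = emptyenv())

water_material <- function() {
  register_material("water", c(H = 0.1119, O = 0.8881), 1.0)
}

# Small noiseless dataset (6 materials x 12 energies) for fast chain tests.
noiseless_dataset <- function() {
  if (is.null(.fixture_env$noiseless)) {
    mats <- c("HU-120", "HU18", "HU200", "HU500", "HU1000", "HU1600")
    energies <- exp(seq(log(20), log(2500), length.out = 12))
    .fixture_env$noiseless <- generate_dataset(mats, energies,
                                               n_primaries = Inf, seed = 1)
  }
  .fixture_env$noiseless
}

# Noiseless kernel table for one material over a dense energy grid, for
# beta-kernel synthesis tests.
mono_kernel_table <- function(material_label = "Soft Tissue", n_e = 40) {
  key <- paste(material_label, n_e)
  if (is.null(.fixture_env$ktab)) .fixture_env$ktab <- list()
  if (is.null(.fixture_env$ktab[[key]])) {
    m <- material_lookup(material_label)
    energies <- exp(seq(log(10), log(3000), length.out = n_e))
    ks <- lapply(energies, function(e)
      edep_to_sdpk(emulate_shell_edep(e, m, n_primaries = Inf)))
    .fixture_env$ktab[[key]] <- read_kernel_table(do.call(rbind, lapply(
      ks, function(k) data.frame(material_label = k$material_label,
                                 energy_keV = k$energy0,
                                 shell_index = seq_along(k$F),
                                 x_mid = k$x, F = k$F))))
  }
  .fixture_env$ktab[[key]]
}

# Independent re-evaluation of the documented emulator family (oracle).
emulator_family_oracle <- function(energy0, z_eff, x) {
  a <- min(max(0.6 + 0.25 * log(energy0 / 100), 0.2), 1.8)
  m <- min(max(0.35 + 0.05 * log(energy0 / 100) + 0.01 * (z_eff - 7), 0.2),
           0.7)
  b <- a / (2.2 * m^2.2)
  g <- x^a * exp(-b * x^2.2)
  q <- 6e-4 * z_eff * energy0 / 1000
  (1 - q / (1 + q)) * g / sum(g)
}

make_shell_edep <- function(edep_fraction, energy0 = 100,
                            material = material_lookup("HU18"),
                            grid = shell_grid()) {
  structure(list(energy0 = energy0, material = material, grid = grid,
                 edep_fraction = edep_fraction, n_primaries = Inf,
                 seed = 0L),
            class = "shell_edep")
}
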