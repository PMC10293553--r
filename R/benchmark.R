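# Held-out-materials benchmark: train on the HU-binned tissues, evaluate on
# the ICRP-style testing tissues.

#' Benchmark chain models on the held-out testing materials
#'
#' For each seed: generates emulator datasets for the training tissues and
#' the four testing tissues (disjoint seed substreams), fits a chain per base
#' objective with hyperparameters tuned on a 20% validation split, and
#' records the pooled coefficient of determination on the testing materials.
#'
#' @param seeds Integer vector of replicate seeds.
#' @param bases Base objectives to benchmark.
#' @param n_energies Number of log-spaced energies in \[10, 3000\] keV.
#' @param n_primaries Emulated histories per kernel (noise scale).
#' @return Data frame with columns `base`, `seed`, `r2`, `rmse`, `mape`.
#' @export
chain_benchmark <- function(seeds = 1:5,
                            bases = c("ridge", "lasso", "elasticnet"),
                            n_energies = 30, n_primaries = 1e7) {
  energies <- exp(seq(log(10), log(3000), length.out = n_energies))
  out <- list()
  for (s in seeds) {
    d_tr <- generate_dataset(material_labels("training"), energies,
                             n_primaries = n_primaries, seed = 2L * s)
    d_te <- generate_dataset(material_labels("testing"), energies,
                             n_primaries = n_primaries, seed = 2L * s + 1L)
    y_te <- as.matrix(d_te[, .target_cols(d_te)])
    for (b in bases) {
      fit <- dpk_chain(d_tr, base = b, seed = s)
      m <- regression_metrics(y_te, predict(fit, d_te))
      out[[length(out) + 1L]] <- data.frame(base = b, seed = s, r2 = m$r2,
                                            rmse = m$rmse, mape = m$mape)
    }
  }
  do.call(rbind, out)
}
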