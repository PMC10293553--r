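# Voxel dosimetry tests use a medium-endpoint synthetic nuclide so the whole
# kernel support fits inside the voxelized box at sub-millimetre voxels.

beta_kernel_fixture <- function() {
  if (is.null(.fixture_env$beta_kernel)) {
    kt <- mono_kernel_table()
    sp <- resample_spectrum(fermi_beta_spectrum(800), n = 120)
    .fixture_env$beta_kernel <- list(
      kernel = beta_sdpk(kt, sp, material_lookup("Soft Tissue")),
      e_eff = sp$e_eff)
  }
  .fixture_env$beta_kernel
}

test_that("voxel kernels are reproducible, centered, and non-negative", {
  fx <- beta_kernel_fixture()
  v1 <- build_vdk(fx$kernel, "Soft Tissue", fx$e_eff, voxel_size = 0.5,
                  n_pair_samples = 400, seed = 21, size = 11)
  v2 <- build_vdk(fx$kernel, "Soft Tissue", fx$e_eff, voxel_size = 0.5,
                  n_pair_samples = 400, seed = 21, size = 11)
  expect_identical(v1$values, v2$values)
  expect_true(all(v1$values >= 0))
  # central dominance: the self-dose voxel is the global maximum
  expect_equal(v1$values[6, 6, 6], max(v1$values))
  expect_gt(v1$values[6, 6, 6], sort(v1$values, decreasing = TRUE)[2])
  expect_error(build_vdk(fx$kernel, "Soft Tissue", fx$e_eff,
                         n_pair_samples = 10), "n_pair_samples")
  mono <- edep_to_sdpk(emulate_shell_edep(500, material_lookup("HU18"),
                                          n_primaries = Inf))
  expect_error(build_vdk(mono, "HU18", 200), "rN scale")
})

test_that("voxel kernel energy bookkeeping matches the shell-integral oracle", {
  fx <- beta_kernel_fixture()
  k <- fx$kernel
  # box must contain the kernel support: 1.2 r_N < half-width
  vs <- 0.6                                     # mm
  expect_gt(11.5 * vs / 10, 1.2 * k$r_n_cm)
  vdk <- build_vdk(k, "Soft Tissue", fx$e_eff, voxel_size = vs,
                   n_pair_samples = 4000, seed = 3)
  rho <- material_lookup("Soft Tissue")$density
  voxel_mass_kg <- rho * (vs / 10)^3 / 1000
  total_j <- sum(vdk$values) * voxel_mass_kg
  oracle_j <- fx$e_eff * 1.602176634e-16 * sum(k$F) * k$dx
  expect_lt(abs(total_j - oracle_j) / oracle_j, 0.05)
})

test_that("mirror symmetry holds within Monte Carlo error and errors shrink like sqrt(n)", {
  fx <- beta_kernel_fixture()
  k <- fx$kernel
  reps <- lapply(1:6, function(s)
    build_vdk(k, "Soft Tissue", fx$e_eff, voxel_size = 0.8,
              n_pair_samples = 1000, seed = 100 + s, size = 9)$values)
  arr <- simplify2array(reps)
  mean_k <- apply(arr, 1:3, mean)
  se_k <- apply(arr, 1:3, sd) / sqrt(length(reps))
  kmax <- max(mean_k)
  for (ax in 1:3) {
    flip <- switch(ax,
                   mean_k[9:1, , ], mean_k[, 9:1, ], mean_k[, , 9:1])
    se_f <- switch(ax, se_k[9:1, , ], se_k[, 9:1, ], se_k[, , 9:1])
    pooled <- sqrt(se_k^2 + se_f^2)
    # standardized mirror differences behave like noise, not a systematic bias
    z <- (mean_k - flip)[pooled > 0] / pooled[pooled > 0]
    expect_lt(abs(mean(z)), 0.5)
    expect_lt(mean(abs(z) > 4), 0.02)
    # and the asymmetry is a small fraction of the kernel maximum everywhere
    expect_lt(max(abs(mean_k - flip)) / kmax, 0.05)
  }
  # replicate-variance estimate: doubling the samples shrinks the SE ~ sqrt(2)
  reps2 <- lapply(1:6, function(s)
    build_vdk(k, "Soft Tissue", fx$e_eff, voxel_size = 0.8,
              n_pair_samples = 2000, seed = 200 + s, size = 9)$values)
  sd1 <- apply(arr, 1:3, sd)
  sd2 <- apply(simplify2array(reps2), 1:3, sd)
  sel <- mean_k > 0.01 * kmax & sd2 > 0
  ratio <- median(sd1[sel] / sd2[sel])
  expect_gt(ratio, sqrt(2) * 0.75)
  expect_lt(ratio, sqrt(2) * 1.35)
})

test_that("counts convert to activity with exact in-mask conservation", {
  counts <- array(0, c(4, 4, 4))
  counts[1:3, 1, 1] <- c(1, 1, 2)
  counts[4, 4, 4] <- 9            # outside the mask
  mask <- array(FALSE, c(4, 4, 4)); mask[1:3, 1, 1] <- TRUE
  act <- activity_from_counts(dpk_volume(counts, 1), mask, a_liver = 4)
  expect_equal(act$values[1:3, 1, 1], c(1, 1, 2))
  expect_equal(act$values[4, 4, 4], 0)
  expect_equal(sum(act$values[mask]), 4, tolerance = 1e-9)
  kept <- activity_from_counts(dpk_volume(counts, 1), mask, 4,
                               keep_outside = TRUE)
  expect_equal(kept$values[4, 4, 4], 9)
  # uniform counts split the activity evenly
  cu <- array(1, c(3, 3, 3))
  au <- activity_from_counts(dpk_volume(cu, 1), array(TRUE, c(3, 3, 3)), 27)
  expect_true(all(au$values == 1))
  expect_error(activity_from_counts(dpk_volume(array(0, c(2, 2, 2)), 1),
                                    array(TRUE, c(2, 2, 2)), 1), "counts")
})

test_that("cumulated activity follows the permanent-trapping arithmetic", {
  a <- dpk_volume(array(1, c(2, 2, 2)), 1)
  cum <- cumulated_activity(a, 64.2)
  expect_equal(cum$values[1], 1.443 * 64.2 * 3600, tolerance = 1e-12)
  expect_equal(cum$values[1], 3.335e5, tolerance = 2e-4)
  expect_equal(cumulated_activity(dpk_volume(array(0, c(2, 2, 2)), 1),
                                  64.2)$values,
               array(0, c(2, 2, 2)))
  c3 <- cumulated_activity(dpk_volume(array(3, c(2, 2, 2)), 1), 64.2)
  expect_equal(c3$values, 3 * cum$values)
  expect_error(cumulated_activity(a, -1), "positive")
})

fake_vdk <- function(size = 5, voxel_size = 1) {
  half <- (size - 1) / 2
  g <- expand.grid(i = -half:half, j = -half:half, k = -half:half)
  vals <- exp(-(g$i^2 + g$j^2 + g$k^2) / 2) * 1e-9
  structure(list(values = array(vals, rep(size, 3)),
                 voxel_size = voxel_size, material_label = "test",
                 e_eff_kev = 100, n_pair_samples = 0, seed = 0L),
            class = "voxel_kernel")
}

test_that("dose convolution matches the impulse, superposition, and brute-force oracles", {
  K <- fake_vdk(5)
  A <- array(0, c(12, 12, 12)); A[6, 6, 6] <- 1
  D <- dose_convolve(dpk_volume(A, 1), K)
  expect_equal(D$values[4:8, 4:8, 4:8], K$values,
               tolerance = 1e-10)
  # superposition
  B <- array(0, c(12, 12, 12)); B[3, 9, 5] <- 2.5
  D2 <- dose_convolve(dpk_volume(B, 1), K)
  D12 <- dose_convolve(dpk_volume(A + B, 1), K)
  expect_lt(max(abs(D12$values - (D$values + D2$values))),
            1e-9 * max(D12$values))
  # translation equivariance for an interior shift
  As <- array(0, c(12, 12, 12)); As[7, 6, 6] <- 1
  Ds <- dose_convolve(dpk_volume(As, 1), K)
  expect_equal(Ds$values[5:9, 4:8, 4:8], K$values, tolerance = 1e-10)
  # brute-force spatial oracle on an 8^3 map
  set.seed(31)
  A8 <- array(runif(512), c(8, 8, 8))
  Dfft <- dose_convolve(dpk_volume(A8, 1), K)$values
  Dref <- array(0, c(8, 8, 8))
  for (i in 1:8) for (j in 1:8) for (k in 1:8) {
    acc <- 0
    for (di in -2:2) for (dj in -2:2) for (dk in -2:2) {
      si <- i - di; sj <- j - dj; sk <- k - dk
      if (si >= 1 && si <= 8 && sj >= 1 && sj <= 8 && sk >= 1 && sk <= 8)
        acc <- acc + A8[si, sj, sk] * K$values[di + 3, dj + 3, dk + 3]
    }
    Dref[i, j, k] <- acc
  }
  expect_lt(max(abs(Dfft - Dref)) / max(Dref), 1e-8)
  # spacing mismatch is an error naming both spacings
  expect_error(dose_convolve(dpk_volume(A, 2), K), "2.*1|spacing")
})

test_that("gamma index satisfies its identity and boundary cases", {
  set.seed(41)
  ref <- dpk_volume(array(runif(10 * 10 * 8, 1, 10), c(10, 10, 8)), 3)
  g0 <- gamma_index(ref, ref)
  expect_equal(max(g0$gamma, na.rm = TRUE), 0)
  expect_equal(g0$pass_rate, 100)
  # uniform reference, +3% of maximum everywhere: gamma exactly 1
  uni <- dpk_volume(array(5, c(8, 8, 8)), 3)
  up <- dpk_volume(array(5 * 1.03, c(8, 8, 8)), 3)
  g1 <- gamma_index(uni, up)
  expect_equal(min(g1$gamma, na.rm = TRUE), 1, tolerance = 1e-9)
  expect_equal(max(g1$gamma, na.rm = TRUE), 1, tolerance = 1e-9)
  expect_equal(g1$pass_rate, 100)
  # a one-voxel shift at 3 mm spacing passes on the distance criterion
  sm <- array(0, c(10, 10, 8))
  for (i in 1:10) sm[i, , ] <- i
  a <- dpk_volume(sm, 3)
  b <- dpk_volume(sm[c(1, 1:9), , ], 3)   # shifted by one voxel along x
  g2 <- gamma_index(a, b)
  expect_true(all(g2$gamma[2:9, , ] <= 1 + 1e-9, na.rm = TRUE))
  # asymmetry: both directions compute without error and may differ
  g_ab <- gamma_index(a, b)$pass_rate
  g_ba <- gamma_index(b, a)$pass_rate
  expect_true(is.finite(g_ab) && is.finite(g_ba))
  expect_error(gamma_index(a, dpk_volume(sm[1:5, , ], 3)), "grid")
  # local normalization mode is available
  gl <- gamma_index(uni, up, normalization = "local")
  expect_equal(gl$pass_rate, 100)
})

test_that("region statistics aggregate exactly", {
  vals <- array(0, c(6, 6, 6))
  vals[1:3, , ] <- 2
  vals[4:6, , ] <- 5
  dose <- dpk_volume(vals, 1)
  m1 <- array(FALSE, c(6, 6, 6)); m1[1:3, , ] <- TRUE
  m2 <- array(FALSE, c(6, 6, 6)); m2[4:6, , ] <- TRUE
  whole <- m1 | m2
  st <- region_stats(dose, list(a = m1, b = m2, all = whole))
  expect_equal(st$sd[1], 0)
  expect_equal(st$mean[1], st$min[1])
  expect_equal(st$mean[1], st$max[1])
  # additivity: voxel-count-weighted means agree
  expect_equal(st$mean[3],
               (st$n_voxels[1] * st$mean[1] + st$n_voxels[2] * st$mean[2]) /
                 (st$n_voxels[1] + st$n_voxels[2]), tolerance = 1e-12)
  expect_error(region_stats(dose, list(bad = array(FALSE, c(6, 6, 6)))),
               "empty")
  g <- gamma_index(dpk_volume(vals + 1, 1), dpk_volume(vals + 1, 1),
                   delta_r = 3, delta_d = 3)
  stg <- region_stats(dose, list(a = m1), gamma = g)
  expect_equal(stg$gamma_pass, 100)
})

test_that("the synthetic phantom is reproducible and anatomically consistent", {
  ph <- synthetic_liver_phantom(shape = c(24, 24, 16), seed = 5)
  ph2 <- synthetic_liver_phantom(shape = c(24, 24, 16), seed = 5)
  expect_identical(ph$counts$values, ph2$counts$values)
  expect_true(any(ph$liver))
  expect_true(all(ph$voi1[ph$voi1] & ph$liver[ph$voi1]))
  expect_gt(mean(ph$counts$values[ph$voi1]), mean(ph$counts$values[ph$liver]))
  expect_equal(sum(ph$counts$values[!ph$liver]), 0)
})

test_that("voxel kernels persist through the raw+JSON pair", {
  fx <- beta_kernel_fixture()
  vdk <- build_vdk(fx$kernel, "Soft Tissue", fx$e_eff, voxel_size = 1,
                   n_pair_samples = 200, seed = 77, size = 7)
  base <- file.path(withr::local_tempdir(), "vdk")
  write_vdk(vdk, base)
  back <- read_vdk(base)
  expect_identical(back$values, vdk$values)
  expect_equal(back$voxel_size, 1)
  expect_identical(back$material_label, "Soft Tissue")
})
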