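# Response-matrix calibration: depth-response tables, matrix assembly and
# normalization, inversion with conditioning guards, and energy-pair
# selection.

test_that("matrix inversion matches the adjugate closed form", {
  set.seed(1)
  for (i in 1:20) {
    A <- matrix(runif(4, 0.2, 1), 2)
    rm <- tryCatch(invert_response(response_matrix(A, c(1, 1.4), 12.5)),
                   error = function(e) NULL)
    if (is.null(rm)) next  # ill-conditioned draw, rejected by design
    adj <- matrix(c(A[2, 2], -A[2, 1], -A[1, 2], A[1, 1]), 2) /
      (A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1])
    expect_equal(rm$A_inv, adj, tolerance = 1e-12)
    expect_lt(max(abs(rm$A %*% rm$A_inv - diag(2))), 1e-10)
  }
  id <- invert_response(response_matrix(diag(2), c(1, 1.4), 12.5))
  expect_equal(id$A_inv, diag(2))
  expect_equal(id$condition, 1)
})

test_that("ill-conditioned matrices are refused with a conditioning error", {
  A <- matrix(c(1, 0.99, 1, 0.991), 2, byrow = TRUE) * 1e-3
  expect_error(invert_response(response_matrix(A, c(1, 1.4), 12.5)),
               "ill-conditioned")
  # threshold is configurable
  expect_s3_class(invert_response(response_matrix(A, c(1, 1.4), 12.5),
                                  max_condition = 1e6),
                  "response_matrix")
  expect_error(response_matrix(-ref_A(), c(1, 1.4), 12.5),
               "nonnegative")
})

test_that("depth response: zero stain gives null signals; layer 2 grows from 1.0 to 1.4 keV", {
  tab0 <- compute_depth_response(c(1.0), n_layers = 2, stain_density = 0,
                                 n_electrons = 4000, seed = 3)
  expect_true(all(abs(tab0$signal) < 4 * tab0$se))
  tab <- compute_depth_response(c(1.0, 1.4), n_layers = 2,
                                n_electrons = 3e4, seed = 4)
  s10 <- tab$signal[tab$energy == 1.0]
  s14 <- tab$signal[tab$energy == 1.4]
  # at 1.0 keV layer 2 contributes, but much less than layer 1
  expect_gt(s10[2], 3 * tab$se[tab$energy == 1.0][2])
  expect_lt(s10[2], 0.5 * s10[1])
  # at 1.4 keV the two layers contribute almost equally
  expect_gt(s14[2] / s14[1], 0.5)
  expect_lt(s14[2] / s14[1], 1.2)
})

test_that("calibrated matrix has the benchmark ordering and S-normalization", {
  rm <- build_response_matrix(1.0, 1.4, n_electrons = 2e4, seed = 5)
  A <- rm$A
  # A11 > A21 > A22 > A12: surface layer dominates at both energies,
  # the deep layer is nearly invisible at the low energy
  expect_gt(A[1, 1], A[2, 1])
  expect_gt(A[2, 1], A[2, 2])
  expect_gt(A[2, 2], A[1, 2])
  expect_gt(rm$condition, 1)
  expect_lt(max(abs(A %*% rm$A_inv - diag(2))), 1e-10)
  # A is normalized by S: doubling the calibration stain density changes
  # the coefficients far less than the factor-2 an unnormalized signal
  # would show (residual drift reflects multiple-scattering saturation of
  # the strongly scattering stain; see the methods vignette)
  rm2 <- build_response_matrix(1.0, 1.4, stain_density = 2 * 3.24,
                               n_electrons = 2e4, seed = 5)
  expect_true(all(rm2$A / A > 0.5 & rm2$A / A < 1.2))
  expect_error(build_response_matrix(1.4, 1.0), "E_low")
  expect_error(build_response_matrix(1.0, 1.0), "E_low")
})

test_that("swapping the energy order permutes the matrix rows", {
  t1 <- compute_depth_response(c(1.0, 1.4), n_layers = 2,
                               n_electrons = 5000, seed = 6)
  # same seeds per (energy index, layer); row order follows energy order
  A1 <- matrix(t1$signal, nrow = 2, byrow = TRUE)
  expect_identical(A1[1, ], t1$signal[t1$energy == 1.0])
  expect_identical(A1[2, ], t1$signal[t1$energy == 1.4])
})

test_that("cuboid-geometry calibration yields comparable, smaller coefficients", {
  slab <- compute_depth_response(c(1.0), n_layers = 1,
                                 n_electrons = 1.5e4, seed = 7)
  cub <- compute_depth_response(c(1.0), n_layers = 1,
                                n_electrons = 1.5e4, seed = 7,
                                geometry = "cuboid")
  # finite-cuboid and extended-slab calibrations agree to well within
  # the lateral point-spread scale (the 50-nm cuboid is much wider than
  # the ~1-nm elastic mean free path in the stained material)
  expect_gt(cub$signal, 0.7 * slab$signal)
  expect_lt(cub$signal, 1.3 * slab$signal)
})

test_that("energy-pair selection implements dominance + balance on a benchmark-shaped table", {
  # signals shaped like the benchmark 1.0/1.4 keV matrix column pattern:
  # layer-2/layer-1 balance closest to 1 at 1.4 keV, overshooting beyond
  signals <- list(
    "0.8" = c(1.10, 0.020, 0.001, 0.000),
    "0.9" = c(1.08, 0.080, 0.004, 0.001),
    "1.0" = c(1.043, 0.130, 0.010, 0.002),
    "1.2" = c(0.96, 0.40, 0.04, 0.008),
    "1.4" = c(0.898, 0.648, 0.120, 0.020),
    "1.6" = c(0.70, 0.95, 0.30, 0.060),
    "1.8" = c(0.55, 0.90, 0.50, 0.150),
    "2.2" = c(0.40, 0.70, 0.60, 0.400))
  signals <- lapply(signals, function(s) s * 1e-3)
  tab <- synthetic_response_table(signals)
  expect_equal(suggest_energy_pair(tab, E_min_feasible = 1.0),
               c(E_low = 1.0, E_high = 1.4))
  # with a lower feasibility floor the dominant low energies win
  pair <- suggest_energy_pair(tab, E_min_feasible = 0.8)
  expect_true(pair["E_low"] %in% c(0.8, 0.9))
  expect_error(suggest_energy_pair(tab, E_min_feasible = 3.0), "no cand")
  one <- synthetic_response_table(list("1.0" = c(1, 0.1) * 1e-3))
  expect_error(suggest_energy_pair(one), "two energies")
})

test_that("response matrices round-trip through JSON", {
  rm <- ref_rmat()
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  write_response_matrix(rm, f)
  rm2 <- read_response_matrix(f)
  expect_equal(rm2$A, rm$A, tolerance = 1e-12)
  expect_equal(rm2$A_inv, rm$A_inv, tolerance = 1e-12)
  expect_equal(rm2$energies, rm$energies)
  expect_equal(rm2$layer_thickness, rm$layer_thickness)
})
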