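# The linear reconstruction chain: forward projection, shot noise,
# background subtraction, low/high scaling, per-pixel inversion, noise
# clipping, lower-sub-slice smoothing, and recovery metrics.  Most
# checks are exact linear algebra against the reference benchmark
# matrix; statistical checks use wide bands.

test_that("forward projection matches the discretized model by hand", {
  rm <- ref_rmat()
  p <- make_block(c(50, 50, 25), 12.5)
  p$stain[2, 2, 1] <- 3.24          # S1 = 3.24, S2 = 0 in one pixel
  st <- forward_project(p, rm, electrons_per_pixel = 1e4)
  # B1/J0 = A11 * S1 * dz = 1.043e-3 * 3.24 * 12.5 = 4.224e-2
  expect_equal(st$low[2, 2, 1], 1e4 * 12.5 * 1.043e-3 * 3.24,
               tolerance = 1e-12)
  expect_equal(st$high[2, 2, 1], 1e4 * 12.5 * 0.898e-3 * 3.24,
               tolerance = 1e-12)
  expect_equal(st$low[2, 2, 1] / 1e4, 4.224e-2, tolerance = 1e-3)
  # all other pixels carry no stain signal
  expect_equal(sum(st$low > 0), 1)
  # zero-stain phantom projects to exactly zero
  p0 <- make_block(c(50, 50, 25), 12.5)
  st0 <- forward_project(p0, rm)
  expect_true(all(st0$low == 0) && all(st0$high == 0))
  # linearity: doubling S doubles B
  p2 <- p; p2$stain <- 2 * p$stain
  st2 <- forward_project(p2, rm, electrons_per_pixel = 1e4)
  expect_equal(st2$low, 2 * st$low, tolerance = 1e-12)
  # background enters as a per-energy constant
  stb <- forward_project(p0, rm, electrons_per_pixel = 1000,
                         background_eta = c(0.05, 0.04))
  expect_true(all(stb$low == 50) && all(stb$high == 40))
  # grid mismatches are rejected
  bad <- make_block(c(50, 50, 30), c(12.5, 12.5, 15))
  expect_error(forward_project(bad, rm), "layer thickness")
  odd <- make_block(c(50, 50, 37.5), 12.5)
  expect_error(forward_project(odd, rm), "multiple")
})

test_that("shot noise is Poisson with unit variance/mean ratio and reproducible", {
  rm <- ref_rmat()
  p <- make_block(c(1250, 1250, 25), 12.5)
  st <- forward_project(p, rm, electrons_per_pixel = 1000,
                        background_eta = c(1, 1))  # flat mean 1000
  n1 <- apply_shot_noise(st, seed = 9)
  n2 <- apply_shot_noise(st, seed = 9)
  expect_identical(n1$low, n2$low)
  x <- as.vector(n1$low)
  expect_lt(abs(mean(x) - 1000), 3 * sqrt(1000 / length(x)))
  vm <- var(x) / mean(x)
  expect_lt(abs(vm - 1), 3 * sqrt(2 / length(x)))
  expect_error(apply_shot_noise(forward_project(p, rm,
    background_eta = c(-1, 0))))
})

test_that("background subtraction centers the background on zero", {
  rm <- ref_rmat()
  sc <- small_three_cuboid()
  st <- forward_project(sc$truth, rm, electrons_per_pixel = 1000,
                        background_eta = c(0.05, 0.045))
  st <- apply_shot_noise(st, seed = 10)
  sub <- subtract_background(st, roi = sc$bg_roi)
  expect_true(sub$background_subtracted)
  # constant-plus-noise background: estimates near the planted constants
  expect_equal(as.numeric(sub$background[1, ]), c(50, 45),
               tolerance = 0.15)
  # stain-free pixels center on zero after subtraction
  far <- st$low[1:10, 1:10, 1] - sub$background[1, 1]
  expect_lt(abs(mean(sub$low[1:10, 1:10, 1])), 3 * sd(far) / 10)
  # percentile method agrees with roi_mean on a background-dominated image
  sub2 <- subtract_background(st, method = "percentile", p = 50)
  expect_lt(abs(sub2$background[1, 1] - sub$background[1, 1]),
            3 * sqrt(1000) / 3)
  expect_error(subtract_background(st, roi = list(x = integer(), y = 1)),
               "empty")
  expect_error(subtract_background(st, roi = list(x = 1:2000, y = 1:2)),
               "outside")
  # constant image subtracts to exactly zero
  flat <- forward_project(make_block(c(125, 125, 25), 12.5), rm,
                          background_eta = c(0.05, 0.05))
  fs <- subtract_background(flat, roi = list(x = 1:4, y = 1:4))
  expect_true(all(fs$low == 0) && all(fs$high == 0))
})

test_that("low-to-high scaling targets the matrix row-sum ratio", {
  rm <- ref_rmat()
  # target ratio from the benchmark matrix: (A11+A12)/(A21+A22) = 0.759
  sc <- small_three_cuboid()
  st <- forward_project(sc$truth, rm, electrons_per_pixel = 1000)
  st <- subtract_background(st, roi = sc$bg_roi)
  scl <- scale_low_to_high(st, rm, roi = sc$scale_roi)
  expect_equal(as.numeric(scl$scale_factor["target_ratio"]),
               (1.043e-3 + 0.130e-3) / (0.898e-3 + 0.648e-3),
               tolerance = 1e-12)
  expect_equal(as.numeric(scl$scale_factor["target_ratio"]), 0.7588,
               tolerance = 1e-3)
  # a stack already in matched units scales by exactly 1 (noiseless) ...
  expect_equal(as.numeric(scl$scale_factor["factor"]), 1,
               tolerance = 1e-12)
  # ... and by ~1 under shot noise
  stn <- apply_shot_noise(forward_project(sc$truth, rm,
                                          electrons_per_pixel = 1000,
                                          background_eta = c(0.05, 0.045)),
                          seed = 12)
  stn <- subtract_background(stn, roi = sc$bg_roi)
  scln <- scale_low_to_high(stn, rm, roi = sc$scale_roi)
  # noise floor: shot noise in the ROI means plus the uncertainty of the
  # background estimate propagated into both means (~3 sigma band)
  expect_equal(as.numeric(scln$scale_factor["factor"]), 1,
               tolerance = 0.1)
  # equal row sums give a target ratio of exactly 1
  rm1 <- invert_response(response_matrix(
    matrix(c(2, 1, 1, 2), 2) * 1e-3, c(1, 1.4), 12.5))
  scl1 <- scale_low_to_high(st, rm1, roi = sc$scale_roi)
  expect_equal(as.numeric(scl1$scale_factor["target_ratio"]), 1)
  # state and degenerate-ROI errors
  expect_error(scale_low_to_high(forward_project(sc$truth, rm), rm,
                                 roi = sc$scale_roi), "background")
  expect_error(scale_low_to_high(st, rm, roi = sc$bg_roi), "zero")
})

test_that("noiseless forward -> inverse round trip is exact (1e-10)", {
  for (rmat in list(ref_rmat(),
                    invert_response(response_matrix(
                      matrix(c(7.0, 1.9, 6.3, 4.6), 2, byrow = TRUE) *
                        1e-3, c(1, 1.4), 12.5)))) {
    sc <- small_three_cuboid()
    st <- forward_project(sc$truth, rmat, electrons_per_pixel = 1000)
    st <- subtract_background(st, roi = sc$bg_roi)
    st <- scale_low_to_high(st, rmat, roi = sc$scale_roi)
    vol <- solve_subslices(st, rmat)
    expect_equal(dim(vol$S), dim(sc$truth$stain))
    err <- abs(vol$S - sc$truth$stain)
    rel <- max(err) / max(sc$truth$stain)
    expect_lt(rel, 1e-10)
  }
})

test_that("single-pixel inversion matches the hand-computed matrix product", {
  rm <- ref_rmat()
  B <- c(422.415, 363.69)   # counts for S = (3.24, 0), J0 = 1e4, dz 12.5
  st <- dual_energy_stack(array(B[1], c(1, 1, 1)), array(B[2], c(1, 1, 1)),
                          c(1.0, 1.4), 25, 12.5, 1e4)
  st$background_subtracted <- TRUE; st$scaled <- TRUE
  vol <- solve_subslices(st, rm)
  S_hand <- rm$A_inv %*% B / (1e4 * 12.5)
  expect_equal(as.numeric(vol$S[1, 1, ]), as.numeric(S_hand),
               tolerance = 1e-12)
  expect_equal(as.numeric(vol$S[1, 1, 1]), 3.24, tolerance = 1e-9)
  expect_lt(abs(vol$S[1, 1, 2]), 1e-9)
  # zero input -> zero output
  z <- dual_energy_stack(array(0, c(2, 2, 1)), array(0, c(2, 2, 1)),
                         c(1.0, 1.4), 25, 12.5, 1e3)
  z$background_subtracted <- TRUE; z$scaled <- TRUE
  expect_true(all(solve_subslices(z, rm)$S == 0))
  # unscaled stacks are refused
  raw <- dual_energy_stack(array(1, c(2, 2, 1)), array(1, c(2, 2, 1)),
                           c(1.0, 1.4), 25, 12.5, 1e3)
  expect_error(solve_subslices(raw, rm), "scaled")
})

test_that("noise amplification through the inverse matches analytic propagation", {
  rm <- ref_rmat()
  # uniform two-layer stain, Poisson counts, many pixels
  p <- make_block(c(1250, 1250, 25), 12.5)
  p$stain[, , 1] <- 3.24; p$stain[, , 2] <- 3.24
  epp <- 1000
  st <- forward_project(p, rm, electrons_per_pixel = epp,
                        background_eta = c(0.05, 0.045))
  mu1 <- st$low[1, 1, 1]; mu2 <- st$high[1, 1, 1]
  st <- apply_shot_noise(st, seed = 13)
  st$background_subtracted <- TRUE; st$scaled <- TRUE  # flat field: no-op
  vol <- solve_subslices(st, rm)
  s1 <- as.vector(vol$S[, , 1])
  pred_var <- (rm$A_inv[1, 1]^2 * mu1 + rm$A_inv[1, 2]^2 * mu2) /
    (epp * 12.5)^2
  expect_lt(abs(var(s1) / pred_var - 1), 0.1)
  # amplification relative to plain count noise is substantial
  expect_gt(pred_var, (sqrt(mu1) / (epp * 12.5 * sum(rm$A[1, ])))^2)
})

test_that("clipping zeroes sub-threshold voxels at the predicted rate", {
  rm <- ref_rmat()
  vol <- list(S = array(stats::rnorm(4e4), c(200, 200, 1)), dz = 12.5,
              n_sub = 2, pixel_nm = 12.5, provenance = list())
  class(vol) <- "subslice_volume"
  clipped <- clip_noise(vol, background_sd = 1)
  # standard-normal noise: P(x < +1 sd) ~ 84% zeroed
  expect_equal(clipped$clip_info$fraction_clipped, pnorm(1),
               tolerance = 0.02)
  expect_true(all(clipped$S >= 0))
  expect_true(all(clipped$S == 0 | clipped$S >= 1))
  # all-negative volume clips to all zeros
  neg <- vol; neg$S <- -abs(neg$S)
  expect_true(all(clip_noise(neg, background_sd = 1)$S == 0))
  # planted signal far above the threshold survives untouched
  sig <- vol; sig$S[1:5, 1:5, 1] <- 50
  expect_equal(clip_noise(sig, background_sd = 1)$S[1:5, 1:5, 1],
               array(50, c(5, 5)), ignore_attr = TRUE)
  # ROI-based and MAD-based SD estimates are close to the truth
  est <- clip_noise(vol, roi = list(x = 1:50, y = 1:50))
  expect_equal(est$clip_info$background_sd, 1, tolerance = 0.1)
  est2 <- clip_noise(vol)
  expect_equal(est2$clip_info$background_sd, 1, tolerance = 0.1)
})

test_that("lower-sub-slice smoothing averages with the neighboring upper slices", {
  mk_vol <- function(S) structure(list(S = S, dz = 12.5, n_sub = 2,
                                       pixel_nm = 12.5,
                                       provenance = list()),
                                  class = "subslice_volume")
  # constant upper u and lower l: interior lower slices become (l+u)/2
  S <- array(0, c(4, 4, 6))
  S[, , c(1, 3, 5)] <- 2; S[, , c(2, 4, 6)] <- 6
  sm <- smooth_lower_subslice(mk_vol(S))
  expect_equal(sm$S[, , 2], matrix(4, 4, 4))   # (6 + (2+2)/2)/2
  expect_equal(sm$S[, , 4], matrix(4, 4, 4))
  # last cut uses its single upper neighbor
  expect_equal(sm$S[, , 6], matrix(4, 4, 4))   # (6 + 2)/2
  # upper slices untouched
  expect_equal(sm$S[, , 1], matrix(2, 4, 4))
  # single-cut volume: warning, no-op
  one <- mk_vol(array(1, c(4, 4, 2)))
  expect_warning(same <- smooth_lower_subslice(one), "no-op")
  expect_equal(same$S, one$S)
  # variance reduction on iid noise: var -> var/4 + var_of_upper_mean/4
  set.seed(21)
  Sn <- array(stats::rnorm(4 * 4 * 40), c(4, 4, 40))
  smn <- smooth_lower_subslice(mk_vol(Sn))
  low_idx <- seq(2, 38, by = 2)
  v <- var(as.vector(smn$S[, , low_idx]))
  # Var[(l + (u1+u2)/2)/2] = 1/4 + 1/8 = 0.375 for unit-variance iid
  expect_equal(v, 0.375, tolerance = 0.15)
})

test_that("recovery metrics find planted peaks and flag misaligned grids", {
  rm <- ref_rmat()
  sc <- small_three_cuboid()
  st <- forward_project(sc$truth, rm, electrons_per_pixel = 1000)
  st <- subtract_background(st, roi = sc$bg_roi)
  st <- scale_low_to_high(st, rm, roi = sc$scale_roi)
  vol <- solve_subslices(st, rm)
  met <- evaluate_recovery(vol, sc$truth)
  # noiseless: peaks exactly at the planted densities
  expect_equal(met$regions$peak, met$regions$planted, tolerance = 1e-6)
  expect_equal(met$regions$relative_error, c(0, 0), tolerance = 1e-6)
  expect_equal(met$background$peak, 0, tolerance = 1e-9)
  expect_equal(met$regions$n_vox, c(5000, 5000))
  # random volume has near-zero correlation with the truth
  set.seed(31)
  rnd <- vol; rnd$S <- array(stats::rnorm(length(vol$S)), dim(vol$S))
  expect_lt(abs(cor(as.vector(rnd$S), as.vector(sc$truth$stain))), 0.05)
  # shape mismatch
  small <- vol; small$S <- vol$S[1:10, 1:10, , drop = FALSE]
  expect_error(evaluate_recovery(small, sc$truth), "aligned")
})
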