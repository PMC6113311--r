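# Forward projection of stain volumes into dual-energy BSE stacks, the
# pre-processing chain (background subtraction -> low/high scaling ->
# per-pixel inversion -> noise clipping -> lower-sub-slice smoothing),
# and recovery metrics.  The order of operations is enforced by state
# flags on the stack.

#' Dual-energy BSE image stack
#'
#' Container for per-cut image pairs acquired (or simulated) at a low and
#' a high landing energy. Pixel values are electron counts per pixel.
#'
#' @param low,high Numeric arrays `(npx, npy, n_cuts)` of counts.
#' @param energies `c(E_low, E_high)` in keV.
#' @param cut_nm Physical cutting increment, nm.
#' @param pixel_nm Pixel size, nm.
#' @param electrons_per_pixel Incident electrons per pixel per image.
#' @param interleave Acquisition page order, `"low_first"` or
#'   `"high_first"`.
#' @return A `dual_energy_stack` with pre-processing state flags.
#' @export
dual_energy_stack <- function(low, high, energies, cut_nm, pixel_nm,
                              electrons_per_pixel,
                              interleave = "low_first") {
  if (length(dim(low)) == 2) low <- array(low, c(dim(low), 1))
  if (length(dim(high)) == 2) high <- array(high, c(dim(high), 1))
  stopifnot(identical(dim(low), dim(high)), length(energies) == 2,
            energies[1] < energies[2], cut_nm > 0, pixel_nm > 0,
            electrons_per_pixel > 0,
            interleave %in% c("low_first", "high_first"))
  structure(list(low = low, high = high,
                 energies = as.numeric(energies),
                 cut_nm = cut_nm, pixel_nm = pixel_nm,
                 electrons_per_pixel = electrons_per_pixel,
                 interleave = interleave,
                 background_subtracted = FALSE,
                 scaled = FALSE,
                 background = NULL, scale_factor = NULL),
            class = "dual_energy_stack")
}

#' @export
print.dual_energy_stack <- function(x, ...) {
  d <- dim(x$low)
  cat(sprintf(
    "<dual_energy_stack> %d x %d px, %d cut(s) at %g nm, E = %.2f/%.2f keV\n",
    d[1], d[2], d[3], x$cut_nm, x$energies[1], x$energies[2]))
  cat(sprintf("  background_subtracted: %s, scaled: %s\n",
              x$background_subtracted, x$scaled))
  invisible(x)
}

#' Forward-project a phantom into a noiseless dual-energy stack
#'
#' Expected stain-only counts per pixel from the discretized linear
#' model: `B_m = J0_px * dz * sum_n A[m, n] * S_n`, summed over the N
#' sub-slice layers of each cut. Backscatter from the uniform embedding
#' matrix enters as a per-energy constant (`background_eta * J0_px`)
#' added on top, mirroring how a real image carries a flat background
#' that pre-processing later removes.
#'
#' @param phantom A `voxel_phantom` whose voxel dz equals the matrix's
#'   layer thickness and whose depth is a multiple of `N * dz`.
#' @param rmat A `response_matrix`.
#' @param electrons_per_pixel Incident electrons per pixel per image.
#' @param background_eta Length-2 per-energy matrix backscatter yields
#'   added as constants (default 0).
#' @return A `dual_energy_stack` of expected (non-integer) counts.
#' @export
forward_project <- function(phantom, rmat, electrons_per_pixel = 1e3,
                            background_eta = c(0, 0)) {
  stopifnot(inherits(phantom, "voxel_phantom"),
            inherits(rmat, "response_matrix"))
  dz <- rmat$layer_thickness
  N <- ncol(rmat$A)
  if (abs(phantom$voxel_nm[3] - dz) > 1e-9)
    stop("phantom voxel dz (", phantom$voxel_nm[3],
         " nm) must equal the response-matrix layer thickness (", dz,
         " nm)", call. = FALSE)
  nz <- dim(phantom$stain)[3]
  if (nz %% N != 0)
    stop("phantom depth must be a multiple of ", N, " layers",
         call. = FALSE)
  n_cuts <- nz %/% N
  d <- dim(phantom$stain)
  low <- array(0, c(d[1], d[2], n_cuts))
  high <- array(0, c(d[1], d[2], n_cuts))
  for (cc in seq_len(n_cuts)) {
    S <- phantom$stain[, , (cc - 1) * N + seq_len(N), drop = FALSE]
    for (n in seq_len(N)) {
      low[, , cc] <- low[, , cc] +
        electrons_per_pixel * dz * rmat$A[1, n] * S[, , n]
      high[, , cc] <- high[, , cc] +
        electrons_per_pixel * dz * rmat$A[2, n] * S[, , n]
    }
    low[, , cc] <- low[, , cc] + background_eta[1] * electrons_per_pixel
    high[, , cc] <- high[, , cc] + background_eta[2] * electrons_per_pixel
  }
  dual_energy_stack(low, high, rmat$energies, cut_nm = N * dz,
                    pixel_nm = phantom$voxel_nm[1],
                    electrons_per_pixel = electrons_per_pixel)
}

#' Apply Poisson shot noise to a stack
#'
#' Replaces each expected count by a Poisson draw with that mean;
#' optional additive Gaussian detector noise.
#'
#' @param stack A `dual_energy_stack` of nonnegative expected counts.
#' @param seed Optional integer seed (R RNG state is restored on exit).
#' @param gaussian_sd Additive detector noise standard deviation in
#'   counts (default 0 = off).
#' @return The stack with noisy counts.
#' @export
apply_shot_noise <- function(stack, seed = NULL, gaussian_sd = 0) {
  stopifnot(inherits(stack, "dual_energy_stack"),
            all(stack$low >= 0), all(stack$high >= 0))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  dl <- dim(stack$low)
  stack$low <- array(rpois(length(stack$low), stack$low), dl)
  stack$high <- array(rpois(length(stack$high), stack$high), dl)
  if (gaussian_sd > 0) {
    stack$low <- stack$low +
      array(stats::rnorm(length(stack$low), 0, gaussian_sd), dl)
    stack$high <- stack$high +
      array(stats::rnorm(length(stack$high), 0, gaussian_sd), dl)
  }
  stack
}

.roi_index <- function(roi, d) {
  stopifnot(is.list(roi), !is.null(roi$x), !is.null(roi$y))
  if (length(roi$x) == 0 || length(roi$y) == 0)
    stop("empty background ROI", call. = FALSE)
  if (min(roi$x) < 1 || max(roi$x) > d[1] ||
      min(roi$y) < 1 || max(roi$y) > d[2])
    stop("background ROI outside the image", call. = FALSE)
  roi
}

#' Subtract the local image background
#'
#' Estimates a flat background per image (per cut and energy) either as
#' the mean over a stain-free ROI or as a percentile of the whole image,
#' and subtracts it. Output may contain negative values; they are
#' removed later by [clip_noise()].
#'
#' @param stack A `dual_energy_stack`.
#' @param method `"roi_mean"` or `"percentile"`.
#' @param roi For `"roi_mean"`: list with integer pixel index vectors
#'   `x` and `y`.
#' @param p Percentile in (0, 100) for `"percentile"`.
#' @return The background-subtracted stack; estimates are stored in
#'   `$background` (n_cuts x 2 matrix).
#' @export
subtract_background <- function(stack, method = c("roi_mean",
                                                  "percentile"),
                                roi = NULL, p = 50) {
  stopifnot(inherits(stack, "dual_energy_stack"))
  method <- match.arg(method)
  d <- dim(stack$low)
  bg <- matrix(0, d[3], 2, dimnames = list(NULL, c("low", "high")))
  for (cc in seq_len(d[3])) {
    if (method == "roi_mean") {
      roi <- .roi_index(roi, d)
      bg[cc, 1] <- mean(stack$low[roi$x, roi$y, cc])
      bg[cc, 2] <- mean(stack$high[roi$x, roi$y, cc])
    } else {
      stopifnot(p > 0, p < 100)
      bg[cc, 1] <- quantile(stack$low[, , cc], p / 100, names = FALSE)
      bg[cc, 2] <- quantile(stack$high[, , cc], p / 100, names = FALSE)
    }
    stack$low[, , cc] <- stack$low[, , cc] - bg[cc, 1]
    stack$high[, , cc] <- stack$high[, , cc] - bg[cc, 2]
  }
  stack$background <- bg
  stack$background_subtracted <- TRUE
  stack
}

#' Scale the low-energy images to the high-energy images
#'
#' Uses a structure assumed to extend homogeneously through the full cut
#' (both sub-slice layers): for such a structure the ratio of stain
#' signals is `(A[1,1] + A[1,2]) / (A[2,1] + A[2,2])`, so the low-energy
#' images are multiplied by the factor that brings the ROI mean of the
#' low stack to that ratio times the ROI mean of the high stack. For
#' stacks already expressed in matched units (e.g. simulated counts) the
#' factor comes out ~1.
#'
#' @param stack A background-subtracted `dual_energy_stack`.
#' @param rmat The `response_matrix` in use.
#' @param roi List with pixel index vectors `x`, `y` over the
#'   homogeneous structure.
#' @return The scaled stack; `$scale_factor` records the factor and the
#'   target ratio.
#' @export
scale_low_to_high <- function(stack, rmat, roi) {
  stopifnot(inherits(stack, "dual_energy_stack"),
            inherits(rmat, "response_matrix"))
  if (!stack$background_subtracted)
    stop("subtract the background before scaling", call. = FALSE)
  d <- dim(stack$low)
  roi <- .roi_index(roi, d)
  target <- sum(rmat$A[1, ]) / sum(rmat$A[2, ])
  m_low <- mean(stack$low[roi$x, roi$y, ])
  m_high <- mean(stack$high[roi$x, roi$y, ])
  if (abs(m_low) < .Machine$double.eps * 1e3 || m_high == 0)
    stop("ROI mean is (near) zero; choose a stained homogeneous ",
         "structure", call. = FALSE)
  f <- target * m_high / m_low
  stack$low <- stack$low * f
  stack$scale_factor <- c(factor = f, target_ratio = target)
  stack$scaled <- TRUE
  stack
}

#' Reconstructed sub-slice stain volume
#'
#' Created by [solve_subslices()]; a 3D array of stain densities at
#' sub-slice z-spacing.
#' @name subslice_volume
NULL

#' Per-pixel inversion to sub-slice stain densities
#'
#' Applies `S = A^-1 B / (J0_px * dz)` at every pixel of every cut and
#' interleaves the N recovered layers into a volume with z-spacing equal
#' to the sub-slice thickness. The stack must be background-subtracted
#' and scaled first.
#'
#' @param stack A pre-processed `dual_energy_stack`.
#' @param rmat An inverted `response_matrix`.
#' @param electrons_per_pixel Incident electrons per pixel per image;
#'   defaults to the stack's value.
#' @return A `subslice_volume`: `S` array `(npx, npy, N * n_cuts)` in
#'   atoms/nm^3, `dz`, `n_sub`, provenance.
#' @export
solve_subslices <- function(stack, rmat,
                            electrons_per_pixel =
                              stack$electrons_per_pixel) {
  stopifnot(inherits(stack, "dual_energy_stack"),
            inherits(rmat, "response_matrix"))
  if (is.null(rmat$A_inv))
    stop("response matrix has no inverse; call invert_response() first",
         call. = FALSE)
  if (!stack$background_subtracted || !stack$scaled)
    stop("stack must be background-subtracted and scaled before ",
         "inversion (see subtract_background(), scale_low_to_high())",
         call. = FALSE)
  dz <- rmat$layer_thickness
  N <- ncol(rmat$A)
  if (abs(stack$cut_nm - N * dz) > 1e-9)
    stop("stack cut increment (", stack$cut_nm, " nm) does not equal ",
         N, " x ", dz, " nm", call. = FALSE)
  d <- dim(stack$low)
  S <- array(0, c(d[1], d[2], N * d[3]))
  Ai <- rmat$A_inv
  for (cc in seq_len(d[3])) {
    B1 <- stack$low[, , cc]; B2 <- stack$high[, , cc]
    for (n in seq_len(N)) {
      S[, , (cc - 1) * N + n] <-
        (Ai[n, 1] * B1 + Ai[n, 2] * B2) / (electrons_per_pixel * dz)
    }
  }
  structure(list(S = S, dz = dz, n_sub = N,
                 pixel_nm = stack$pixel_nm,
                 provenance = list(energies = rmat$energies,
                                   electrons_per_pixel =
                                     electrons_per_pixel,
                                   scale_factor = stack$scale_factor,
                                   condition = rmat$condition)),
            class = "subslice_volume")
}

#' @export
print.subslice_volume <- function(x, ...) {
  d <- dim(x$S)
  cat(sprintf(
    "<subslice_volume> %d x %d px, %d sub-slices at %g nm (%d per cut)\n",
    d[1], d[2], d[3], x$dz, x$n_sub))
  invisible(x)
}

#' Clip sub-threshold and negative densities to zero
#'
#' Values below one background standard deviation, and all negative
#' values, are set to zero. The SD is taken from `background_sd`, or
#' estimated from a stain-free ROI, or - failing both - robustly from
#' the volume's negative tail (`mad` of values <= 0 mirrored around 0).
#'
#' @param volume A `subslice_volume`.
#' @param background_sd Known background SD in density units.
#' @param roi Stain-free ROI (list of pixel index vectors `x`, `y`) used
#'   to estimate the SD across all sub-slices.
#' @param n_sd Threshold in units of the background SD (default 1).
#' @return The clipped volume; the fraction of voxels zeroed and the SD
#'   used are stored in `$clip_info`.
#' @export
clip_noise <- function(volume, background_sd = NULL, roi = NULL,
                       n_sd = 1) {
  stopifnot(inherits(volume, "subslice_volume"))
  if (is.null(background_sd)) {
    if (!is.null(roi)) {
      roi <- .roi_index(roi, dim(volume$S))
      background_sd <- sd(volume$S[roi$x, roi$y, ])
    } else {
      neg <- volume$S[volume$S <= 0]
      background_sd <- if (length(neg) > 10)
        mad(c(neg, -neg), center = 0) else sd(volume$S)
    }
  }
  thr <- n_sd * background_sd
  frac <- mean(volume$S < thr)
  volume$S[volume$S < thr] <- 0
  volume$clip_info <- list(background_sd = background_sd,
                           threshold = thr, fraction_clipped = frac)
  volume
}

#' Average each lower sub-slice with its neighboring upper sub-slices
#'
#' Noise in the lower sub-slice of each cut is reduced by replacing it
#' with the average of itself and the mean of the two adjacent upper
#' sub-slices (the one above in the same cut and the one below in the
#' next cut). The last cut, which has no following upper sub-slice, uses
#' its single available upper neighbor.
#'
#' @param volume A `subslice_volume` with 2 sub-slices per cut.
#' @return The smoothed volume.
#' @export
smooth_lower_subslice <- function(volume) {
  stopifnot(inherits(volume, "subslice_volume"), volume$n_sub == 2)
  nz <- dim(volume$S)[3]
  n_cuts <- nz %/% 2
  if (n_cuts < 2) {
    warning("fewer than 2 cuts: lower-sub-slice smoothing is a no-op")
    return(volume)
  }
  S <- volume$S
  for (cc in seq_len(n_cuts)) {
    up_here <- S[, , 2 * cc - 1]
    upper_mean <- if (cc < n_cuts)
      (up_here + S[, , 2 * cc + 1]) / 2 else up_here
    volume$S[, , 2 * cc] <- (S[, , 2 * cc] + upper_mean) / 2
  }
  volume$smoothed <- TRUE
  volume
}

.density_peak <- function(v) {
  if (length(v) < 8 || sd(v) <= 1e-10 * (abs(mean(v)) + 1))
    return(mean(v))
  dd <- density(v)
  dd$x[which.max(dd$y)]
}

#' Compare a reconstructed volume against the ground-truth phantom
#'
#' Produces per-region value histogramming: for every distinct planted
#' density, the recovered values over that region's voxels, their modal
#' peak, and the separation from the unstained background peak; plus a
#' line profile along x through the first region for each sub-slice.
#'
#' @param volume A `subslice_volume`.
#' @param truth The `voxel_phantom` the data were generated from (same
#'   lateral grid; at least as deep as the volume).
#' @return A `recovery_metrics` list: `regions` data frame (`planted`,
#'   `n_vox`, `peak`, `mean`, `sd`, `separation`, `relative_error`),
#'   `background` stats, `values` (per-region recovered values), and
#'   `profiles`.
#' @export
evaluate_recovery <- function(volume, truth) {
  stopifnot(inherits(volume, "subslice_volume"),
            inherits(truth, "voxel_phantom"))
  dv <- dim(volume$S); dt <- dim(truth$stain)
  if (dv[1] != dt[1] || dv[2] != dt[2] || dv[3] > dt[3])
    stop("volume and truth grids are not aligned", call. = FALSE)
  truthS <- truth$stain[, , seq_len(dv[3]), drop = FALSE]
  bg_mask <- truthS == 0
  bg_vals <- volume$S[bg_mask]
  bg_peak <- .density_peak(bg_vals)
  lev <- sort(unique(truthS[truthS > 0]))
  values <- list()
  rows <- lapply(seq_along(lev), function(i) {
    m <- truthS == lev[i]
    v <- volume$S[m]
    values[[i]] <<- v
    pk <- .density_peak(v)
    data.frame(planted = lev[i], n_vox = sum(m), peak = pk,
               mean = mean(v), sd = sd(v),
               separation = pk - bg_peak,
               relative_error = (pk - lev[i]) / lev[i])
  })
  # line profile through the center row of each sub-slice
  iy <- which(apply(truthS > 0, 2, any))
  iy <- if (length(iy)) round(mean(range(iy))) else round(dv[2] / 2)
  profiles <- lapply(seq_len(dv[3]), function(z) volume$S[, iy, z])
  structure(list(regions = do.call(rbind, rows),
                 background = list(peak = bg_peak, mean = mean(bg_vals),
                                   sd = sd(bg_vals), n_vox = sum(bg_mask)),
                 values = values, profiles = profiles,
                 profile_row = iy),
            class = "recovery_metrics")
}

#' @export
print.recovery_metrics <- function(x, ...) {
  cat("<recovery_metrics>\n")
  print(x$regions, row.names = FALSE)
  cat(sprintf("background: peak %.3g, sd %.3g over %d voxels\n",
              x$background$peak, x$background$sd, x$background$n_vox))
  invisible(x)
}
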