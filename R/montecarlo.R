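# R-level drivers for the compiled Monte Carlo engine: beam/detector
# parameter containers, single trajectories, bulk backscatter yields and
# full BSE image simulation over a voxel phantom.

#' Electron beam parameters
#'
#' @param landing_energy Landing energy in keV (supported range 0.5-5).
#' @param electrons_per_pixel Incident electrons per beam position.
#' @param pixel_nm Pixel size (beam step) in nm.
#' @param cutoff Tracking cutoff energy in keV; electrons below it are
#'   deemed absorbed.
#' @param probe `"delta"` (point probe at pixel centers). A Gaussian
#'   probe profile is not implemented; the benchmark geometries use a
#'   point probe.
#' @return A `beam_parameters` object; `fluence` is the per-area dose
#'   `electrons_per_pixel / pixel_nm^2` in e/nm^2.
#' @export
beam_parameters <- function(landing_energy, electrons_per_pixel = 1e4,
                            pixel_nm = 12.5, cutoff = 0.05,
                            probe = "delta") {
  stopifnot(landing_energy >= 0.5, landing_energy <= 5,
            electrons_per_pixel >= 1, pixel_nm > 0,
            cutoff > 0, cutoff < landing_energy,
            identical(probe, "delta"))
  structure(list(landing_energy = landing_energy,
                 electrons_per_pixel = as.integer(electrons_per_pixel),
                 pixel_nm = pixel_nm,
                 cutoff = cutoff,
                 probe = probe,
                 fluence = electrons_per_pixel / pixel_nm^2),
            class = "beam_parameters")
}

#' Backscattered-electron detector model
#'
#' Any electron exiting through the top surface with energy above the
#' tracking cutoff counts as backscattered; detected with probability
#' `efficiency` (no angular restriction).
#'
#' @param efficiency Detection efficiency in (0, 1].
#' @return A `detector_model` object.
#' @export
detector_model <- function(efficiency = 1.0) {
  stopifnot(efficiency > 0, efficiency <= 1)
  structure(list(efficiency = efficiency), class = "detector_model")
}

.outcome_levels <- c("backscattered", "absorbed", "escaped_side_or_bottom")

#' Simulate a single electron trajectory in a phantom
#'
#' @param phantom A `voxel_phantom`.
#' @param beam [beam_parameters()].
#' @param entry `(x, y)` entry position in nm (inside the block face).
#' @param seed Integer seed; the same seed reproduces the trajectory
#'   exactly.
#' @param record_path Keep the substep vertices.
#' @param k Joy-Luo correction constant.
#' @return A `trajectory_record`: `outcome` (one of `"backscattered"`,
#'   `"absorbed"`, `"escaped_side_or_bottom"`), `exit_energy` (keV, NA
#'   unless backscattered), `exit_direction`, and optionally `path`
#'   (n x 3 matrix of nm positions).
#' @export
simulate_trajectory <- function(phantom, beam, entry, seed = 1,
                                record_path = TRUE, k = 0.77) {
  stopifnot(inherits(phantom, "voxel_phantom"),
            inherits(beam, "beam_parameters"), length(entry) == 2)
  if (entry[1] < 0 || entry[1] >= phantom$extent_nm[1] ||
      entry[2] < 0 || entry[2] >= phantom$extent_nm[2])
    stop("entry point outside the block face", call. = FALSE)
  pm <- .phantom_materials(phantom)
  res <- mc_trajectory_cpp(pm$index, dim(phantom$stain),
                           phantom$voxel_nm, pm$materials,
                           beam$landing_energy, entry[1], entry[2],
                           beam$cutoff, k, seed, record_path)
  res$outcome <- .outcome_levels[res$outcome + 1L]
  class(res) <- "trajectory_record"
  res
}

#' Bulk backscatter yield of a semi-infinite material
#'
#' Simulates normally incident electrons on a half-space of `material`
#' and returns the backscattering coefficient (fraction of incident
#' electrons re-emerging through the surface with energy above the
#' cutoff).
#'
#' @param material A [material()].
#' @param E Landing energy in keV.
#' @param n_electrons Number of trajectories (>= 1000).
#' @param seed Integer seed.
#' @param cutoff Tracking cutoff, keV.
#' @param k Joy-Luo correction constant.
#' @param collect_exits Also return exit energies and directions of the
#'   backscattered electrons.
#' @return A list with `eta`, binomial `se = sqrt(eta(1-eta)/n)`,
#'   `n_backscattered`, `n_electrons`, and optionally exit records.
#' @examples
#' \donttest{
#' bulk_yield(epon812_pb(0.03, 1.52), 1.0, n_electrons = 2e4, seed = 1)
#' }
#' @export
bulk_yield <- function(material, E, n_electrons = 1e4, seed = 1,
                       cutoff = 0.05, k = 0.77, collect_exits = FALSE) {
  stopifnot(inherits(material, "material"), n_electrons >= 1e3)
  .check_energy(E, lo = max(0.1, 2 * cutoff))
  res <- mc_bulk_cpp(.material_clist(material), E, as.integer(n_electrons),
                     cutoff, k, seed, collect_exits)
  eta <- res$n_backscattered / res$n_electrons
  out <- list(eta = eta,
              se = sqrt(eta * (1 - eta) / res$n_electrons),
              n_backscattered = res$n_backscattered,
              n_electrons = res$n_electrons,
              energy = E, material = material$name, seed = seed)
  if (collect_exits) {
    out$exit_energy <- res$exit_energy
    out$exit_direction <- cbind(ux = res$exit_ux, uy = res$exit_uy,
                                uz = res$exit_uz)
  }
  class(out) <- "bse_yield"
  out
}

#' @export
print.bse_yield <- function(x, ...) {
  cat(sprintf("<bse_yield> eta = %.4f +/- %.4f (%s at %.2f keV, n = %d)\n",
              x$eta, x$se, x$material, x$energy, x$n_electrons))
  invisible(x)
}

#' Simulate a backscattered-electron image of a phantom
#'
#' One beam position per pixel over a rectangular region of interest;
#' per-pixel counts are realized by trajectory outcomes thinned by the
#' detector efficiency. Per-pixel random substreams are derived
#' deterministically from `seed`, so the image is reproducible and
#' independent of pixel evaluation order.
#'
#' @param phantom A `voxel_phantom`.
#' @param beam [beam_parameters()].
#' @param detector [detector_model()].
#' @param roi Region of interest: list with `x0`, `y0` (nm, lower-left
#'   corner) and `npx`, `npy` (pixel counts). Default: the full block
#'   face.
#' @param seed Integer root seed.
#' @param k Joy-Luo correction constant.
#' @return A `bse_image`: `counts` matrix (npx x npy), `eta` per pixel,
#'   and acquisition metadata.
#' @export
simulate_image <- function(phantom, beam, detector = detector_model(),
                           roi = NULL, seed = 1, k = 0.77) {
  stopifnot(inherits(phantom, "voxel_phantom"),
            inherits(beam, "beam_parameters"),
            inherits(detector, "detector_model"))
  if (is.null(roi))
    roi <- list(x0 = 0, y0 = 0,
                npx = floor(phantom$extent_nm[1] / beam$pixel_nm),
                npy = floor(phantom$extent_nm[2] / beam$pixel_nm))
  if (roi$x0 < 0 || roi$y0 < 0 ||
      roi$x0 + roi$npx * beam$pixel_nm > phantom$extent_nm[1] + 1e-9 ||
      roi$y0 + roi$npy * beam$pixel_nm > phantom$extent_nm[2] + 1e-9)
    stop("requested ROI lies outside the block face", call. = FALSE)
  pm <- .phantom_materials(phantom)
  counts <- mc_image_cpp(pm$index, dim(phantom$stain), phantom$voxel_nm,
                         pm$materials, beam$landing_energy,
                         beam$electrons_per_pixel,
                         roi$x0, roi$y0, beam$pixel_nm,
                         as.integer(roi$npx), as.integer(roi$npy),
                         beam$cutoff, k, detector$efficiency, seed)
  structure(list(counts = counts,
                 eta = counts / beam$electrons_per_pixel,
                 energy = beam$landing_energy,
                 electrons_per_pixel = beam$electrons_per_pixel,
                 pixel_nm = beam$pixel_nm,
                 roi = roi, seed = seed,
                 detector_efficiency = detector$efficiency),
            class = "bse_image")
}

#' @export
print.bse_image <- function(x, ...) {
  cat(sprintf(
    "<bse_image> %d x %d px at %.3g nm, E = %.2f keV, mean eta = %.4f\n",
    nrow(x$counts), ncol(x$counts), x$pixel_nm, x$energy, mean(x$eta)))
  invisible(x)
}
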