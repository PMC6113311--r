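# Calibration of the depth-response matrix A(z_n, E_m): Monte Carlo
# backscatter signals from single-layer stained slabs, normalized to
# per-atom scattering cross sections, plus inversion and energy-pair
# selection.

.mix_seed_r <- function(seed, a, b = 0) {
  # deterministic sub-seed, kept under 2^31
  (as.numeric(seed) * 2654435 + a * 40503 + b * 97) %% 2147483647
}

#' Depth response of stained layers versus landing energy
#'
#' For each landing energy, simulates the backscatter yield of a
#' laterally extended stained slab occupying a single sub-slice layer
#' (one slab per depth) plus an unstained reference block, and tabulates
#' the background-subtracted stain signal per incident electron.
#'
#' Laterally extended slabs suppress edge losses from the finite lateral
#' point-spread function; `geometry = "cuboid"` instead images a 50-nm
#' cuboid per layer, matching the benchmark calibration geometry at the
#' cost of edge effects and slower convergence.
#'
#' @param energies Landing energies in keV, sorted ascending.
#' @param layer_thickness Sub-slice thickness (delta z) in nm.
#' @param n_layers Number of layers to probe.
#' @param stain_density Stain density in the slabs, atoms/nm^3.
#' @param n_electrons Trajectories per (energy, layer) simulation.
#' @param seed Integer root seed.
#' @param cutoff,k Tracking cutoff (keV) and Joy-Luo constant.
#' @param base Matrix [material()].
#' @param geometry `"slab"` (default) or `"cuboid"`.
#' @param cuboid_xy Lateral cuboid edge for `geometry = "cuboid"`, nm.
#' @return A `depth_response_table`: data frame with columns `energy`,
#'   `layer`, `z_top`, `z_bottom`, `signal` (stained eta minus background
#'   eta), `se`; background yields per energy in the `"background"`
#'   attribute. Parameters travel in attributes.
#' @export
compute_depth_response <- function(energies, layer_thickness = 12.5,
                                   n_layers = 4,
                                   stain_density = .S_REF,
                                   n_electrons = 2e4, seed = 1,
                                   cutoff = 0.05, k = 0.77,
                                   base = epon812(),
                                   geometry = c("slab", "cuboid"),
                                   cuboid_xy = 50) {
  geometry <- match.arg(geometry)
  stopifnot(!is.unsorted(energies), n_layers >= 1, layer_thickness > 0,
            stain_density >= 0, n_electrons >= 1e3)
  stained <- stain_material(stain_density, base)
  bgm <- .material_clist(base)
  stm <- .material_clist(stained)
  cap <- layer_thickness / 4
  rows <- list(); bg <- numeric(length(energies)); bg_se <- bg
  for (ei in seq_along(energies)) {
    E <- energies[ei]
    rb <- mc_slab_cpp(bgm, bgm, 0, layer_thickness, E,
                      as.integer(n_electrons), cutoff, k,
                      .mix_seed_r(seed, ei, 0), cap)
    bg[ei] <- rb$n_backscattered / rb$n_electrons
    bg_se[ei] <- sqrt(bg[ei] * (1 - bg[ei]) / rb$n_electrons)
    for (li in seq_len(n_layers)) {
      z0 <- (li - 1) * layer_thickness; z1 <- li * layer_thickness
      if (geometry == "slab") {
        rs <- mc_slab_cpp(bgm, stm, z0, z1, E, as.integer(n_electrons),
                          cutoff, k, .mix_seed_r(seed, ei, li), cap)
        eta <- rs$n_backscattered / rs$n_electrons
        se <- sqrt(eta * (1 - eta) / rs$n_electrons)
      } else {
        eta_se <- .cuboid_layer_eta(E, z0, z1, stain_density, base,
                                    cuboid_xy, n_electrons, cutoff, k,
                                    .mix_seed_r(seed, ei, li))
        eta <- eta_se[1]; se <- eta_se[2]
      }
      rows[[length(rows) + 1]] <- data.frame(
        energy = E, layer = li, z_top = z0, z_bottom = z1,
        signal = eta - bg[ei], se = sqrt(se^2 + bg_se[ei]^2))
    }
  }
  tab <- do.call(rbind, rows)
  low_n <- tab$signal > 0 & tab$signal < 2 * tab$se
  if (any(tab$signal > 0) && any(low_n))
    warning(sum(low_n), " layer signal(s) are within 2 standard errors ",
            "of zero; increase n_electrons for a tighter calibration")
  structure(tab,
            background = data.frame(energy = energies, eta = bg,
                                    se = bg_se),
            layer_thickness = layer_thickness,
            stain_density = stain_density,
            n_electrons = n_electrons, seed = seed,
            geometry = geometry,
            class = c("depth_response_table", "data.frame"))
}

# mean stained-pixel eta for a single 50-nm cuboid buried in layer
# [z0, z1): image the cuboid footprint and average
.cuboid_layer_eta <- function(E, z0, z1, S, base, cuboid_xy,
                              n_electrons, cutoff, k, seed) {
  vox <- z1 - z0
  ext <- max(8 * cuboid_xy, 400)
  ext <- ceiling(ext / vox) * vox
  block <- make_block(c(ext, ext, max(16 * vox, 8 * (z1 + vox))), vox)
  ctr <- floor(ext / 2 / vox) * vox
  block <- add_cuboid(block, cuboid(
    c(ctr, ctr, (z0 + z1) / 2), c(cuboid_xy, cuboid_xy, z1 - z0), S))
  npx <- max(1L, floor(cuboid_xy / vox))
  epp <- max(1000L, as.integer(ceiling(n_electrons / npx^2)))
  beam <- beam_parameters(E, electrons_per_pixel = epp, pixel_nm = vox,
                          cutoff = cutoff)
  img <- simulate_image(block, beam,
                        roi = list(x0 = ctr - cuboid_xy / 2,
                                   y0 = ctr - cuboid_xy / 2,
                                   npx = npx, npy = npx),
                        seed = seed, k = k)
  eta <- mean(img$eta)
  c(eta, sqrt(eta * (1 - eta) / (npx^2 * epp)))
}

#' Construct a response matrix from known coefficients
#'
#' Rows index landing energies, columns index sub-slice layers;
#' coefficients have units of nm^2 (per-atom scattering cross section per
#' layer).
#'
#' @param A Square numeric matrix (N x N), `A[m, n]` for energy m and
#'   layer n.
#' @param energies Landing energies (keV), one per row.
#' @param layer_thickness Sub-slice thickness delta z, nm.
#' @param provenance Optional list recorded with the matrix.
#' @return A `response_matrix` (inverse not yet populated; see
#'   [invert_response()]).
#' @export
response_matrix <- function(A, energies, layer_thickness,
                            provenance = list()) {
  A <- as.matrix(A)
  stopifnot(nrow(A) == ncol(A), nrow(A) == length(energies),
            layer_thickness > 0)
  if (any(A < 0)) stop("response coefficients must be nonnegative",
                       call. = FALSE)
  structure(list(A = A, energies = as.numeric(energies),
                 layer_thickness = layer_thickness,
                 A_inv = NULL, condition = NULL,
                 provenance = provenance),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix> %d layers x %.3g nm at %s keV (nm^2)\n",
              ncol(x$A), x$layer_thickness,
              paste(x$energies, collapse = "/")))
  print(x$A)
  if (!is.null(x$A_inv))
    cat(sprintf("inverse populated; condition number %.2f\n", x$condition))
  invisible(x)
}

#' Calibrate the two-layer response matrix by Monte Carlo
#'
#' Runs [compute_depth_response()] at the two landing energies for two
#' layers of thickness `layer_thickness` and converts background-
#' subtracted per-electron signals to per-atom cross sections:
#' `A[m, n] = signal(m, n) / (stain_density * layer_thickness)` (nm^2).
#'
#' @param E_low,E_high Landing energies in keV, `E_low < E_high`.
#' @param layer_thickness Sub-slice thickness, nm.
#' @param stain_density Calibration stain density, atoms/nm^3 (default:
#'   the 3 at% lead benchmark value 3.24).
#' @param n_electrons Trajectories per (energy, layer) simulation.
#' @param seed Integer seed.
#' @param ... Passed to [compute_depth_response()] (`cutoff`, `k`,
#'   `base`, `geometry`, ...).
#' @return An inverted `response_matrix` (see [invert_response()]).
#' @export
build_response_matrix <- function(E_low, E_high, layer_thickness = 12.5,
                                  stain_density = .S_REF,
                                  n_electrons = 1e5, seed = 1, ...) {
  if (!(E_low < E_high))
    stop("E_low must be smaller than E_high (a repeated energy gives a ",
         "singular response matrix)", call. = FALSE)
  stopifnot(stain_density > 0)
  tab <- compute_depth_response(c(E_low, E_high),
                                layer_thickness = layer_thickness,
                                n_layers = 2,
                                stain_density = stain_density,
                                n_electrons = n_electrons,
                                seed = seed, ...)
  if (any(tab$signal <= 0))
    stop("a layer signal is consistent with zero or negative: this ",
         "energy pair cannot resolve that layer at this electron count",
         call. = FALSE)
  A <- matrix(tab$signal / (stain_density * layer_thickness),
              nrow = 2, byrow = TRUE)
  se_A <- matrix(tab$se / (stain_density * layer_thickness),
                 nrow = 2, byrow = TRUE)
  rm <- response_matrix(A, c(E_low, E_high), layer_thickness,
                        provenance = list(
                          stain_density = stain_density,
                          n_electrons = n_electrons, seed = seed,
                          se = se_A,
                          background = attr(tab, "background"),
                          geometry = attr(tab, "geometry"),
                          cross_section_model = "screened-Rutherford"))
  invert_response(rm)
}

#' Invert a response matrix
#'
#' Stores the inverse (nm^-2) and the 2-norm condition number; refuses
#' ill-conditioned matrices, for which deeper-layer coefficients approach
#' zero and the inversion is not well defined.
#'
#' @param rm A `response_matrix`.
#' @param max_condition Condition-number threshold (default 50).
#' @return The `response_matrix` with `A_inv` and `condition` populated;
#'   `A %*% A_inv` equals the identity to 1e-10.
#' @export
invert_response <- function(rm, max_condition = 50) {
  stopifnot(inherits(rm, "response_matrix"))
  sv <- svd(rm$A)$d
  cond <- max(sv) / min(sv)
  if (!is.finite(cond) || cond >= max_condition)
    stop(sprintf(paste0(
      "response matrix is ill-conditioned (condition number %.3g >= %g):",
      " coefficients for deeper layers approach zero and the inverse is",
      " not well defined at this energy pair"), cond, max_condition),
      call. = FALSE)
  rm$A_inv <- solve(rm$A)
  rm$condition <- cond
  resid <- max(abs(rm$A %*% rm$A_inv - diag(nrow(rm$A))))
  if (resid > 1e-10)
    stop("inversion residual ", format(resid), " exceeds 1e-10",
         call. = FALSE)
  rm
}

#' Recommend a dual-energy pair from a depth-response table
#'
#' `E_low` is the smallest feasible energy whose layer-1 share of the
#' total stain signal exceeds `dominance` (the low-energy image should
#' see essentially only the surface layer); `E_high` is the energy at
#' which the first two layers contribute most equally (layer-2/layer-1
#' signal ratio closest to one).
#'
#' @param table A `depth_response_table` spanning candidate energies.
#' @param E_min_feasible Smallest practicable landing energy, keV.
#' @param dominance Required layer-1 signal share for `E_low`.
#' @return Named numeric vector `c(E_low, E_high)`.
#' @export
suggest_energy_pair <- function(table, E_min_feasible = 1.0,
                                dominance = 0.8) {
  stopifnot(inherits(table, "depth_response_table"))
  energies <- unique(table$energy)
  if (length(energies) < 2)
    stop("need a table spanning at least two energies", call. = FALSE)
  share1 <- vapply(energies, function(E) {
    s <- pmax(table$signal[table$energy == E], 0)
    if (sum(s) <= 0) return(NA_real_)
    s[1] / sum(s)
  }, numeric(1))
  feas <- energies >= E_min_feasible & !is.na(share1) & share1 >= dominance
  if (!any(feas))
    stop("no candidate energy at or above ", E_min_feasible,
         " keV has a layer-1 signal share >= ", dominance,
         "; lower the dominance threshold or extend the table",
         call. = FALSE)
  E_low <- min(energies[feas])
  cand <- energies[energies > E_low]
  ratio <- vapply(cand, function(E) {
    s <- table$signal[table$energy == E]
    if (length(s) < 2 || s[1] <= 0) return(Inf)
    abs(s[2] / s[1] - 1)
  }, numeric(1))
  if (all(!is.finite(ratio)))
    stop("no usable higher energy in the table", call. = FALSE)
  E_high <- cand[which.min(ratio)]
  c(E_low = E_low, E_high = E_high)
}

#' Read/write a response matrix as JSON
#'
#' @param rm A `response_matrix`.
#' @param path File path.
#' @return `path` invisibly ([write_response_matrix()]); a
#'   `response_matrix` ([read_response_matrix()]).
#' @export
write_response_matrix <- function(rm, path) {
  stopifnot(inherits(rm, "response_matrix"))
  obj <- list(format = "subslicer-response-matrix-v1",
              energies_keV = rm$energies,
              layer_thickness_nm = rm$layer_thickness,
              A_nm2 = rm$A,
              inverted = !is.null(rm$A_inv),
              provenance = rm$provenance)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_response_matrix
#' @export
read_response_matrix <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "subslicer-response-matrix-v1"))
    stop("not a subslicer response-matrix file: ", path, call. = FALSE)
  A <- obj$A_nm2
  if (is.list(A)) A <- do.call(rbind, lapply(A, unlist))
  rm <- response_matrix(as.matrix(A), obj$energies_keV,
                        obj$layer_thickness_nm,
                        provenance = as.list(obj$provenance %||% list()))
  if (isTRUE(obj$inverted)) rm <- invert_response(rm)
  rm
}
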