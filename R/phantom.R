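# Voxelized specimen models: stain-density grids over an epoxy block,
# including the two benchmark geometries used for calibration and for the
# end-to-end sensitivity experiment.
#
# Coordinate convention: the block face is the z = 0 plane, +z points into
# the block, voxel n along z spans [ (n-1)*dz, n*dz ).  Stain density is
# stored in heavy atoms per nm^3.

#' Convert a stain atomic fraction to a number density
#'
#' Two conventions are supported. `"added_to_matrix"` adds stain atoms at
#' a fraction of the matrix atom count, leaving the matrix untouched:
#' `S = fraction * n_total(material)`. `"of_total_atoms"` takes the
#' fraction of all atoms of the matrix-composition material that are
#' stain. For dilute stain the two differ by O(fraction).
#'
#' @param atomic_fraction Stain atomic fraction in `[0, 0.5)`.
#' @param material Matrix [material()] (default [epon812()]).
#' @param convention `"of_total_atoms"` or `"added_to_matrix"`.
#' @return Stain density in atoms/nm^3, with the convention recorded in
#'   the `"convention"` attribute.
#' @examples
#' at_percent_to_density(0.03)                      # ~3.3 atoms/nm^3
#' @export
at_percent_to_density <- function(atomic_fraction, material = epon812(),
                                  convention = c("of_total_atoms",
                                                 "added_to_matrix")) {
  convention <- match.arg(convention)
  stopifnot(atomic_fraction >= 0, atomic_fraction < 0.5,
            inherits(material, "material"))
  S <- switch(convention,
    # stain is the stated fraction of all atoms after staining
    of_total_atoms = atomic_fraction / (1 - atomic_fraction) *
      material$number_density,
    # stain atoms added at the stated fraction of the matrix atom count
    added_to_matrix = atomic_fraction * material$number_density)
  structure(S, convention = convention)
}

#' Material realized by a given stain density
#'
#' Builds the compound obtained by adding `S` heavy atoms per nm^3 of
#' `stain` to the unchanged matrix material; the bulk density increases by
#' the added stain mass. This mapping is exactly linear in `S`, which is
#' what makes the forward model and the calibration normalization
#' consistent.
#'
#' @param S Stain density, atoms/nm^3 (>= 0).
#' @param base Matrix [material()].
#' @param stain Element symbol of the stain (default `"Pb"`).
#' @return A [material()].
#' @export
stain_material <- function(S, base = epon812(), stain = "Pb") {
  stopifnot(S >= 0)
  if (S == 0) return(base)
  e <- .lookup_element(stain)
  n_tot <- base$number_density + S
  f_stain <- S / n_tot
  els <- base$elements
  els$atomic_fraction <- els$atomic_fraction * (1 - f_stain)
  els <- rbind(els[, c("symbol", "Z", "A_w", "atomic_fraction")],
               data.frame(symbol = e$symbol, Z = e$Z, A_w = e$A_w,
                          atomic_fraction = f_stain))
  rho <- base$mass_density + S * 1e21 * e$A_w / .AVOGADRO
  material(els, mass_density = rho,
           name = sprintf("%s+%s(S=%.4g/nm^3)", base$name, e$symbol, S))
}

.grid_dims <- function(extent_nm, voxel_nm) {
  r <- extent_nm / voxel_nm
  if (any(abs(r - round(r)) > 1e-6))
    stop("block extent must be an integer multiple of the voxel size ",
         "(got extent ", paste(extent_nm, collapse = "x"), " nm at voxel ",
         paste(voxel_nm, collapse = "x"), " nm)", call. = FALSE)
  as.integer(round(r))
}

#' Create an empty voxel phantom
#'
#' @param extent_nm Block dimensions `(X, Y, Z)` in nm; must be integer
#'   multiples of the voxel size.
#' @param voxel_nm Voxel size `(dx, dy, dz)` in nm (a scalar is recycled).
#' @param material Base (unstained) matrix [material()].
#' @return A `voxel_phantom`: stain-density array (atoms/nm^3, all zero)
#'   plus grid metadata.
#' @examples
#' p <- make_block(c(800, 800, 800), 12.5)   # 64 x 64 x 64 voxels
#' @export
make_block <- function(extent_nm, voxel_nm = 12.5, material = epon812()) {
  if (length(voxel_nm) == 1) voxel_nm <- rep(voxel_nm, 3)
  stopifnot(length(extent_nm) == 3, length(voxel_nm) == 3,
            all(extent_nm > 0), all(voxel_nm > 0),
            inherits(material, "material"))
  dims <- .grid_dims(extent_nm, voxel_nm)
  structure(list(stain = array(0, dim = dims),
                 voxel_nm = as.numeric(voxel_nm),
                 extent_nm = as.numeric(extent_nm),
                 material = material,
                 cuboids = list()),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  d <- dim(x$stain)
  cat(sprintf(
    "<voxel_phantom> %d x %d x %d voxels (%g x %g x %g nm), %d stained (max S = %.3g atoms/nm^3)\n",
    d[1], d[2], d[3], x$extent_nm[1], x$extent_nm[2], x$extent_nm[3],
    sum(x$stain > 0), max(x$stain)))
  invisible(x)
}

#' Define a stained cuboid
#'
#' @param center `(x, y, z)` of the cuboid center in nm (z measured from
#'   the block face into the block).
#' @param dims `(wx, wy, wz)` edge lengths in nm.
#' @param stain_density Stain density inside the cuboid, atoms/nm^3.
#'   Alternatively give `atomic_fraction`, converted with
#'   [at_percent_to_density()].
#' @param atomic_fraction Stain atomic fraction (used when
#'   `stain_density` is missing).
#' @return A `cuboid` object.
#' @export
cuboid <- function(center, dims, stain_density = NULL,
                   atomic_fraction = NULL) {
  if (is.null(stain_density)) {
    if (is.null(atomic_fraction))
      stop("give either stain_density or atomic_fraction", call. = FALSE)
    stain_density <- as.numeric(at_percent_to_density(atomic_fraction))
  }
  stopifnot(length(center) == 3, length(dims) == 3, all(dims > 0),
            stain_density >= 0)
  structure(list(center = as.numeric(center), dims = as.numeric(dims),
                 stain_density = stain_density),
            class = "cuboid")
}

.cuboid_index_range <- function(lo, hi, d, n, snap, what) {
  ilo <- lo / d; ihi <- hi / d
  if (!snap && (abs(ilo - round(ilo)) > 1e-6 || abs(ihi - round(ihi)) > 1e-6))
    stop("cuboid ", what, " faces at ", lo, "/", hi,
         " nm are not aligned to the ", d,
         " nm voxel grid (use snap = TRUE to snap)", call. = FALSE)
  ilo <- round(ilo); ihi <- round(ihi)
  if (ilo < 0 || ihi > n)
    stop("cuboid extends outside the block along ", what, call. = FALSE)
  if (ihi <= ilo) stop("cuboid has zero voxel extent along ", what,
                       call. = FALSE)
  (ilo + 1):ihi
}

#' Add a stained cuboid to a phantom
#'
#' Cuboids must be aligned to the voxel grid (the benchmark geometries
#' all are); `snap = TRUE` snaps faces to the nearest voxel boundary with
#' a warning instead.
#'
#' @param phantom A `voxel_phantom`.
#' @param cub A [cuboid()].
#' @param allow_overlap Permit overwriting already-stained voxels.
#' @param snap Snap non-aligned faces to the grid.
#' @return The updated phantom.
#' @export
add_cuboid <- function(phantom, cub, allow_overlap = FALSE, snap = FALSE) {
  stopifnot(inherits(phantom, "voxel_phantom"), inherits(cub, "cuboid"))
  d <- phantom$voxel_nm; n <- dim(phantom$stain)
  lo <- cub$center - cub$dims / 2
  hi <- cub$center + cub$dims / 2
  if (snap && any(abs(c(lo, hi) / rep(d, 2) -
                      round(c(lo, hi) / rep(d, 2))) > 1e-6))
    warning("snapping cuboid faces to the voxel grid")
  ix <- .cuboid_index_range(lo[1], hi[1], d[1], n[1], snap, "x")
  iy <- .cuboid_index_range(lo[2], hi[2], d[2], n[2], snap, "y")
  iz <- .cuboid_index_range(lo[3], hi[3], d[3], n[3], snap, "z")
  if (!allow_overlap && any(phantom$stain[ix, iy, iz] > 0) &&
      cub$stain_density > 0)
    stop("cuboid overlaps an existing stained region ",
         "(set allow_overlap = TRUE to permit)", call. = FALSE)
  if (cub$stain_density > 0)
    phantom$stain[ix, iy, iz] <- cub$stain_density
  phantom$cuboids <- c(phantom$cuboids, list(cub))
  phantom
}

#' Ladder of identical cuboids at increasing depth
#'
#' The calibration benchmark: identical stained cuboids whose center
#' depths increase in steps of one sub-slice thickness, offset along x so
#' they never overlap laterally. Defaults give eight 50 x 50 x 12.5 nm
#' cuboids at 3 at% lead with center depths 6.25, 18.75, ..., 93.75 nm in
#' an 800 nm cube, with 50-nm edge-to-edge gaps along x.
#'
#' @param n_cuboids Number of cuboids.
#' @param cuboid_dims `(wx, wy, wz)` in nm.
#' @param x_gap Edge-to-edge gap along x in nm.
#' @param z_start Center depth of the first (shallowest) cuboid, nm.
#' @param z_step Center-depth increment, nm.
#' @param stain_density Stain density in each cuboid, atoms/nm^3.
#' @param block Optional pre-built block; defaults to an 800-nm cube at
#'   12.5-nm voxels.
#' @return A `voxel_phantom` whose `cuboids` field records the geometry.
#' @export
cuboid_ladder <- function(n_cuboids = 8,
                          cuboid_dims = c(50, 50, 12.5),
                          x_gap = 50,
                          z_start = 6.25, z_step = 12.5,
                          stain_density = .S_REF,
                          block = NULL) {
  stopifnot(n_cuboids >= 1)
  if (is.null(block))
    block <- make_block(c(800, 800, 800), c(12.5, 12.5, 12.5))
  X <- block$extent_nm[1]; Y <- block$extent_nm[2]
  pitch <- cuboid_dims[1] + x_gap
  span <- n_cuboids * cuboid_dims[1] + (n_cuboids - 1) * x_gap
  if (span > X) stop("ladder of ", n_cuboids,
                     " cuboids does not fit in the block along x",
                     call. = FALSE)
  # snap the first center to the voxel grid so all faces stay aligned
  x0 <- (X - span) / 2 + cuboid_dims[1] / 2
  x0 <- round(x0 / block$voxel_nm[1]) * block$voxel_nm[1]
  y_c <- round(Y / 2 / block$voxel_nm[2]) * block$voxel_nm[2]
  zmax <- z_start + (n_cuboids - 1) * z_step + cuboid_dims[3] / 2
  if (zmax > block$extent_nm[3])
    stop("ladder exceeds the block depth", call. = FALSE)
  for (kk in seq_len(n_cuboids) - 1) {
    block <- add_cuboid(block,
      cuboid(center = c(x0 + kk * pitch, y_c, z_start + kk * z_step),
             dims = cuboid_dims, stain_density = stain_density))
  }
  attr(block, "ladder") <- list(
    centers_x = x0 + (seq_len(n_cuboids) - 1) * pitch,
    center_y = y_c,
    centers_z = z_start + (seq_len(n_cuboids) - 1) * z_step,
    dims = cuboid_dims)
  block
}

#' Three-cuboid sensitivity benchmark
#'
#' Two full-density cuboids (625 x 625 x 12.5 nm, one per sub-slice
#' layer) and one half-density cuboid (625 x 625 x 25 nm) spanning both
#' layers, laterally separated in a wide epoxy block. All three contain
#' the same total amount of stain: 2,500 / 2,500 / 5,000 stained voxels
#' of 12.5 nm, at densities S, S, S/2.
#'
#' The block depth defaults to 50 nm (four 12.5-nm layers): the benchmark
#' geometry confines all stain to the top two layers and a deep block
#' only adds empty voxels, so the grid is truncated to the region of
#' interest to keep memory proportional to the useful volume. The lateral
#' extent is configurable for reduced-size runs.
#'
#' @param stain_density Full cuboid stain density, atoms/nm^3.
#' @param lateral_nm Lateral block extent (x and y), nm.
#' @param depth_nm Block depth, nm (multiple of 2*voxel_nm).
#' @param cuboid_xy Lateral cuboid edge, nm.
#' @param cuboid_z Thickness of the full-density cuboids, nm (the
#'   half-density cuboid is twice as thick).
#' @param voxel_nm Isotropic voxel size, nm.
#' @return A `voxel_phantom`; the `"regions"` attribute maps cuboid index
#'   to its planted density and voxel extent.
#' @export
three_cuboid_model <- function(stain_density = .S_REF,
                               lateral_nm = 10000, depth_nm = 50,
                               cuboid_xy = 625, cuboid_z = 12.5,
                               voxel_nm = 12.5) {
  block <- make_block(c(lateral_nm, lateral_nm, depth_nm), voxel_nm)
  stopifnot(3 * cuboid_xy <= lateral_nm, depth_nm >= 2 * cuboid_z)
  gap <- (lateral_nm - 3 * cuboid_xy) / 4
  gap <- floor(gap / voxel_nm) * voxel_nm
  x1 <- gap + cuboid_xy / 2
  x2 <- x1 + cuboid_xy + gap
  x3 <- x2 + cuboid_xy + gap
  y_c <- round(lateral_nm / 2 / voxel_nm) * voxel_nm
  cubs <- list(
    cuboid(c(x1, y_c, cuboid_z / 2), c(cuboid_xy, cuboid_xy, cuboid_z),
           stain_density),
    cuboid(c(x2, y_c, 1.5 * cuboid_z), c(cuboid_xy, cuboid_xy, cuboid_z),
           stain_density),
    cuboid(c(x3, y_c, cuboid_z), c(cuboid_xy, cuboid_xy, 2 * cuboid_z),
           stain_density / 2))
  for (cb in cubs) block <- add_cuboid(block, cb)
  attr(block, "regions") <- cubs
  block
}

#' Serialize a phantom to a JSON file
#'
#' Densities are stored sparsely (linear index + value) at full double
#' precision so a written phantom reads back bit-identical.
#'
#' @param phantom A `voxel_phantom`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_phantom <- function(phantom, path) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  nz <- which(phantom$stain != 0)
  obj <- list(
    format = "subslicer-phantom-v1",
    dims = dim(phantom$stain),
    voxel_nm = phantom$voxel_nm,
    extent_nm = phantom$extent_nm,
    material = list(
      name = phantom$material$name,
      mass_density = phantom$material$mass_density,
      elements = phantom$material$elements[
        , c("symbol", "Z", "A_w", "atomic_fraction")]),
    stained_index = nz,
    stained_value = phantom$stain[nz])
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read a phantom written by [write_phantom()]
#'
#' @param path File path.
#' @return A `voxel_phantom`.
#' @export
read_phantom <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "subslicer-phantom-v1"))
    stop("not a subslicer phantom file: ", path, call. = FALSE)
  mat <- material(obj$material$elements,
                  mass_density = obj$material$mass_density,
                  name = obj$material$name)
  p <- make_block(obj$extent_nm, obj$voxel_nm, mat)
  p$stain[obj$stained_index] <- obj$stained_value
  p
}

# Distinct-density material table for the Monte Carlo engine:
# material index array (0-based) + list of realized materials.
.phantom_materials <- function(phantom, k = 0.77) {
  vals <- sort(unique(as.numeric(phantom$stain)))
  if (vals[1] != 0) vals <- c(0, vals)
  mats <- lapply(vals, function(S) stain_material(S, phantom$material))
  idx <- array(match(phantom$stain, vals) - 1L, dim = dim(phantom$stain))
  list(index = idx, materials = lapply(mats, .material_clist),
       stain_levels = vals, material_objects = mats)
}
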