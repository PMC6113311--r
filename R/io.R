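# Stack and volume I/O: multi-page grayscale TIFF for pixel data plus a
# JSON metadata sidecar (energies, cut increment, pixel size, page
# interleaving, value scaling).  32-bit TIFF samples give a relative
# precision of 2^-32 of full scale; integer counts round-trip exactly.

.SIDECAR_REQUIRED <- c("energies_keV", "cut_increment_nm", "pixel_nm",
                       "interleave")

.sidecar_path <- function(path) paste0(path, ".json")

.to_pages <- function(stack) {
  d <- dim(stack$low)
  pages <- vector("list", 2 * d[3])
  for (cc in seq_len(d[3])) {
    lo <- stack$low[, , cc]; hi <- stack$high[, , cc]
    if (stack$interleave == "low_first") {
      pages[[2 * cc - 1]] <- lo; pages[[2 * cc]] <- hi
    } else {
      pages[[2 * cc - 1]] <- hi; pages[[2 * cc]] <- lo
    }
  }
  pages
}

#' Write a dual-energy stack as multi-page TIFF plus JSON sidecar
#'
#' Pages are interleaved per cut in the stack's declared order. Values
#' are affinely mapped to `[0, 1]` for storage; the offset and scale are
#' recorded in the sidecar and undone on read. Integer counts are
#' flagged and restored exactly.
#'
#' @param stack A `dual_energy_stack`.
#' @param path Output TIFF path; the sidecar goes to `<path>.json`.
#' @param extra Optional named list merged into the sidecar (e.g.
#'   `probe_current_pA`, `dwell_us`, `seed`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, extra = list()) {
  stopifnot(inherits(stack, "dual_energy_stack"))
  pages <- .to_pages(stack)
  all_v <- unlist(pages)
  offset <- min(0, floor(min(all_v)))
  scale <- 2^ceiling(log2(max(max(all_v) - offset, 1) + 1))
  pages <- lapply(pages, function(p) (p - offset) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  sidecar <- c(list(
    format = "subslicer-stack-v1",
    energies_keV = stack$energies,
    cut_increment_nm = stack$cut_nm,
    pixel_nm = stack$pixel_nm,
    electrons_per_pixel = stack$electrons_per_pixel,
    interleave = stack$interleave,
    n_cuts = dim(stack$low)[3],
    value_offset = offset,
    value_scale = scale,
    integer_counts = all(all_v == round(all_v)),
    background_subtracted = stack$background_subtracted,
    scaled = stack$scaled), extra)
  jsonlite::write_json(sidecar, .sidecar_path(path), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read a dual-energy stack written by [write_stack()]
#'
#' @param path TIFF path.
#' @param sidecar Sidecar path (default `<path>.json`).
#' @return A `dual_energy_stack`.
#' @export
read_stack <- function(path, sidecar = .sidecar_path(path)) {
  if (!file.exists(sidecar))
    stop("missing metadata sidecar: ", sidecar, call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  missing <- setdiff(.SIDECAR_REQUIRED, names(meta))
  if (length(missing))
    stop("sidecar is missing required field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) %% 2 != 0)
    stop("stack has an odd number of pages; cannot deinterleave",
         call. = FALSE)
  offset <- meta$value_offset %||% 0
  scale <- meta$value_scale %||% 1
  pages <- lapply(pages, function(p) p * scale + offset)
  if (isTRUE(meta$integer_counts))
    pages <- lapply(pages, round)
  n_cuts <- length(pages) / 2
  d <- dim(pages[[1]])
  low <- array(0, c(d, n_cuts)); high <- array(0, c(d, n_cuts))
  for (cc in seq_len(n_cuts)) {
    a <- pages[[2 * cc - 1]]; b <- pages[[2 * cc]]
    if (identical(meta$interleave, "low_first")) {
      low[, , cc] <- a; high[, , cc] <- b
    } else {
      low[, , cc] <- b; high[, , cc] <- a
    }
  }
  st <- dual_energy_stack(low, high, meta$energies_keV,
                          meta$cut_increment_nm, meta$pixel_nm,
                          meta$electrons_per_pixel %||% 1,
                          interleave = meta$interleave)
  st$background_subtracted <- isTRUE(meta$background_subtracted)
  st$scaled <- isTRUE(meta$scaled)
  st
}

#' Write a reconstructed sub-slice volume (TIFF + provenance JSON)
#'
#' One TIFF page per sub-slice, shallowest first, with an affine value
#' mapping recorded in the sidecar.
#'
#' @param volume A `subslice_volume`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "subslice_volume"))
  nz <- dim(volume$S)[3]
  pages <- lapply(seq_len(nz), function(z) volume$S[, , z])
  all_v <- unlist(pages)
  offset <- min(0, min(all_v))
  scale <- max(max(all_v) - offset, 1e-12) * (1 + 1e-9)
  pages <- lapply(pages, function(p) (p - offset) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  sidecar <- list(format = "subslicer-volume-v1",
                  dz_nm = volume$dz, n_sub = volume$n_sub,
                  pixel_nm = volume$pixel_nm,
                  value_offset = offset, value_scale = scale,
                  provenance = volume$provenance)
  jsonlite::write_json(sidecar, .sidecar_path(path), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' Read a sub-slice volume written by [write_volume()]
#'
#' @param path TIFF path.
#' @return A `subslice_volume` (values at 32-bit storage precision).
#' @export
read_volume <- function(path) {
  meta <- jsonlite::read_json(.sidecar_path(path), simplifyVector = TRUE)
  if (!identical(meta$format, "subslicer-volume-v1"))
    stop("not a subslicer volume file: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- dim(pages[[1]])
  S <- array(0, c(d, length(pages)))
  for (z in seq_along(pages))
    S[, , z] <- pages[[z]] * meta$value_scale + meta$value_offset
  structure(list(S = S, dz = meta$dz_nm, n_sub = meta$n_sub,
                 pixel_nm = meta$pixel_nm,
                 provenance = as.list(meta$provenance)),
            class = "subslice_volume")
}
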