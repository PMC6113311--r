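# Shared fixtures: the reference benchmark response matrix for the
# 1.0/1.4 keV, 12.5-nm-layer configuration, and small builders used
# across test files.

# Benchmark 2x2 depth-response matrix (nm^2); rows = energies 1.0/1.4 keV,
# columns = layers 1/2 of 12.5 nm.
ref_A <- function() {
  matrix(c(1.043e-3, 0.130e-3,
           0.898e-3, 0.648e-3), nrow = 2, byrow = TRUE)
}

# Its reference inverse (nm^-2).
ref_A_inv <- function() {
  matrix(c(1.166e3, -0.227e3,
           -1.620e3, 1.879e3), nrow = 2, byrow = TRUE)
}

ref_rmat <- function() {
  invert_response(response_matrix(ref_A(), c(1.0, 1.4), 12.5))
}

# Hand-built depth-response table (class depth_response_table) from given
# per-energy layer signals, for exercising energy-pair selection logic.
synthetic_response_table <- function(signals, layer_thickness = 12.5) {
  rows <- do.call(rbind, lapply(names(signals), function(E) {
    s <- signals[[E]]
    data.frame(energy = as.numeric(E), layer = seq_along(s),
               z_top = (seq_along(s) - 1) * layer_thickness,
               z_bottom = seq_along(s) * layer_thickness,
               signal = s, se = pmax(abs(s) * 0.01, 1e-5))
  }))
  structure(rows,
            background = data.frame(energy = as.numeric(names(signals)),
                                    eta = 0.05, se = 1e-3),
            layer_thickness = layer_thickness, stain_density = 3.24,
            n_electrons = 1e5, seed = 1, geometry = "slab",
            class = c("depth_response_table", "data.frame"))
}

# Small three-cuboid phantom + the pixel ROIs used by the pre-processing
# chain (stain-free corner; half-density cuboid footprint for scaling).
small_three_cuboid <- function(lateral_nm = 2500) {
  truth <- three_cuboid_model(lateral_nm = lateral_nm)
  regions <- attr(truth, "regions")
  vox <- truth$voxel_nm[1]
  roi_of <- function(cb, shrink = 0.4) {
    px <- round((cb$center[1] + c(-shrink, shrink) * cb$dims[1]) / vox)
    py <- round((cb$center[2] + c(-shrink, shrink) * cb$dims[2]) / vox)
    list(x = px[1]:px[2], y = py[1]:py[2])
  }
  list(truth = truth,
       bg_roi = list(x = 1:12, y = 1:12),
       scale_roi = roi_of(regions[[3]]),
       region_roi = lapply(regions, roi_of))
}
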