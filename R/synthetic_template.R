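#' Generate a synthetic template
#'
#' Builds a small labeled template emulating an anatomically parcellated
#' brain: a 3-D integer label volume (0 = background, 1..R = ROI ids) with an
#' accompanying intensity volume, and a cortical vertex table with smooth
#' per-ROI thickness. Within each ROI the intensity is a mixture of 1-3
#' Gaussian modes so that intensity-based k-means subdivision is
#' non-degenerate.
#'
#' @param n_volume_rois number of volumetric ROIs (study default 87).
#' @param n_cortical_rois number of cortical ROIs with vertices (default 68).
#' @param roi_size_range integer range; ROI voxel/vertex counts are drawn
#'   uniformly from it.
#' @param voxel_size_mm isotropic voxel edge length, mm.
#' @param seed integer seed; generation is deterministic.
#' @return object of class `synthetic_template` with `label_volume`,
#'   `intensity_volume` (3-D arrays), `voxel_size_mm`, `vertex_table`
#'   (data.frame: vertex_id, x, y, z, thickness, roi_id) and `roi_modes`
#'   (list of injected intensity mode means per ROI).
#' @export
generate_template <- function(n_volume_rois = 10, n_cortical_rois = 8,
                              roi_size_range = c(800, 1500),
                              voxel_size_mm = 1, seed = 1L) {
  stopifnot(n_volume_rois >= 1, n_cortical_rois >= 1,
            roi_size_range[1] >= 1, roi_size_range[2] >= roi_size_range[1])
  set.seed(seed)
  sizes <- sample(roi_size_range[1]:roi_size_range[2], n_volume_rois,
                  replace = TRUE)
  total <- sum(sizes)
  side <- ceiling((total * 1.3)^(1 / 3))
  dims <- c(side, side, side)
  if (prod(dims) < total) stop("infeasible volume dimensions")
  lab <- integer(prod(dims))
  # ROIs occupy consecutive runs of voxels in array order: compact enough for
  # patch bookkeeping, and trivially disjoint/exhaustive.
  pos <- 1L
  for (r in seq_len(n_volume_rois)) {
    lab[pos:(pos + sizes[r] - 1L)] <- r
    pos <- pos + sizes[r]
  }
  inten <- numeric(prod(dims))
  roi_modes <- vector("list", n_volume_rois)
  for (r in seq_len(n_volume_rois)) {
    idx <- which(lab == r)
    n_modes <- sample(1:3, 1)
    means <- sort(stats::runif(n_modes, 0.15, 0.85))
    # keep modes separated so the mixture is resolvable
    if (n_modes > 1) means <- seq(0.2, 0.8, length.out = n_modes) +
        stats::runif(n_modes, -0.03, 0.03)
    assign_mode <- sample(n_modes, length(idx), replace = TRUE)
    inten[idx] <- stats::rnorm(length(idx), means[assign_mode], 0.04)
    roi_modes[[r]] <- means
  }
  lab_volume <- array(lab, dims)
  inten_volume <- array(inten, dims)

  vsizes <- sample(roi_size_range[1]:roi_size_range[2], n_cortical_rois,
                   replace = TRUE)
  vt <- do.call(rbind, lapply(seq_len(n_cortical_rois), function(r) {
    n <- vsizes[r]
    t_idx <- seq_len(n)
    # smooth thickness profile: slow sinusoids + small roughness
    th <- 2.5 + 0.6 * sin(2 * pi * t_idx / n * stats::runif(1, 1, 3)) +
      0.2 * sin(2 * pi * t_idx / n * stats::runif(1, 4, 8)) +
      stats::rnorm(n, 0, 0.02)
    data.frame(x = stats::runif(n, 0, side), y = stats::runif(n, 0, side),
               z = stats::runif(n, 0, side), thickness = th, roi_id = r)
  }))
  vt <- cbind(vertex_id = seq_len(nrow(vt)) - 1L, vt)
  structure(list(label_volume = lab_volume, intensity_volume = inten_volume,
                 voxel_size_mm = voxel_size_mm, vertex_table = vt,
                 roi_modes = roi_modes, seed = as.integer(seed)),
            class = "synthetic_template")
}

#' Write / read a synthetic template as plain text
#'
#' Serializes the labeled voxels (linear index, label, intensity) and the
#' vertex table as CSV files plus a small JSON manifest with the array
#' dimensions. NIfTI output is deliberately not used: the synthetic template
#' is the only volumetric object in the pipeline and a text serialization
#' keeps the toolchain dependency-free.
#'
#' @param template a `synthetic_template`.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_template <- function(template, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- which(template$label_volume != 0)
  data.table::fwrite(
    data.table::data.table(linear_index = idx,
                           label = as.integer(template$label_volume[idx]),
                           intensity = template$intensity_volume[idx]),
    file.path(dir, "template_voxels.csv"))
  data.table::fwrite(template$vertex_table, file.path(dir, "template_vertices.csv"))
  jsonlite::write_json(list(dims = dim(template$label_volume),
                            voxel_size_mm = template$voxel_size_mm,
                            seed = template$seed),
                       file.path(dir, "template_manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_template
#' @export
read_template <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "template_manifest.json"),
                             simplifyVector = TRUE)
  vox <- data.table::fread(file.path(dir, "template_voxels.csv"))
  lab <- integer(prod(man$dims)); lab[vox$linear_index] <- vox$label
  inten <- numeric(prod(man$dims)); inten[vox$linear_index] <- vox$intensity
  vt <- as.data.frame(data.table::fread(file.path(dir, "template_vertices.csv")))
  structure(list(label_volume = array(lab, man$dims),
                 intensity_volume = array(inten, man$dims),
                 voxel_size_mm = man$voxel_size_mm, vertex_table = vt,
                 roi_modes = NULL, seed = man$seed),
            class = "synthetic_template")
}
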