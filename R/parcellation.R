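# One-dimensional k-means with k-means++ seeding and restarts.
# Patch subdivision operates on a single scalar per member (voxel intensity
# or vertex thickness), so the clustering is 1-D throughout.
kmeans_1d <- function(values, k, seed = 1L, restarts = 10L, max_iter = 100L) {
  n <- length(values)
  stopifnot(n >= 1, k >= 1)
  if (k == 1) return(list(cluster = rep(1L, n), inertia = sum((values - mean(values))^2)))
  if (k >= n) {
    # every point its own cluster (duplicates share by nearest-centre rule)
    centers <- sort(unique(values))
    k2 <- min(k, length(centers))
    cl <- max.col(-abs(outer(values, centers[seq_len(k2)], `-`)), ties.method = "first")
    return(list(cluster = cl, inertia = 0))
  }
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- numeric(k)
    centers[1] <- values[sample.int(n, 1)]
    d2 <- (values - centers[1])^2
    for (j in 2:k) {  # k-means++: sample proportional to squared distance
      if (all(d2 == 0)) centers[j] <- values[sample.int(n, 1)]
      else centers[j] <- values[sample.int(n, 1, prob = d2)]
      d2 <- pmin(d2, (values - centers[j])^2)
    }
    cl <- integer(n)
    for (it in seq_len(max_iter)) {
      dm <- abs(outer(values, centers, `-`))
      new_cl <- max.col(-dm, ties.method = "first")
      if (identical(new_cl, cl)) break
      cl <- new_cl
      for (j in seq_len(k)) {
        m <- values[cl == j]
        if (length(m)) centers[j] <- mean(m)
      }
    }
    inertia <- sum((values - centers[cl])^2)
    if (is.null(best) || inertia < best$inertia)  # ties keep earliest restart
      best <- list(cluster = cl, inertia = inertia)
  }
  # relabel clusters contiguously in order of first appearance
  u <- unique(best$cluster)
  best$cluster <- match(best$cluster, u)
  best
}

n_patches_for <- function(roi_size, scale) max(1L, as.integer(round(roi_size / scale)))

#' Subdivide one volumetric ROI into patches
#'
#' Clusters the ROI's voxels into `k = max(1, round(size / scale))` patches by
#' k-means on voxel intensity (k-means++ seeding, 10 restarts, best inertia).
#' Only the intensity value is used; spatial contiguity is not enforced.
#'
#' @param members integer voxel ids (0-based linear indices into the template).
#' @param intensities numeric, one value per member.
#' @param scale target voxels per patch (500, 1000 or 2000).
#' @param seed integer seed for reproducible clustering.
#' @return integer vector of 0-based patch indices, contiguous from 0, one
#'   per member.
#' @export
subdivide_roi_volume <- function(members, intensities, scale, seed = 1L) {
  if (length(members) == 0) stop("empty ROI")
  stopifnot(length(intensities) == length(members))
  k <- n_patches_for(length(members), scale)
  kmeans_1d(intensities, k, seed = seed)$cluster - 1L
}

#' Subdivide one cortical ROI into patches
#'
#' As [subdivide_roi_volume()] but on vertices, clustering the scalar
#' thickness values (Euclidean distance on thickness).
#'
#' @param vertex_ids integer vertex ids (0-based).
#' @param thicknesses numeric mm, one per vertex.
#' @param scale target vertices per patch.
#' @param seed integer seed.
#' @return integer vector of 0-based patch indices per vertex.
#' @export
subdivide_roi_surface <- function(vertex_ids, thicknesses, scale, seed = 1L) {
  if (length(vertex_ids) == 0) stop("empty ROI")
  stopifnot(length(thicknesses) == length(vertex_ids))
  k <- n_patches_for(length(vertex_ids), scale)
  kmeans_1d(thicknesses, k, seed = seed)$cluster - 1L
}

#' Build a patch atlas for a template at one scale
#'
#' @param template a `synthetic_template` (or any list with the same fields).
#' @param feature_type `"volume"` (cluster voxel intensities) or
#'   `"thickness"` (cluster vertex thicknesses).
#' @param scale target members per patch.
#' @param seed integer seed.
#' @return object of class `patch_atlas`: `entries` is a list (one element
#'   per ROI id, in increasing order) of lists of member-id vectors (0-based
#'   voxel linear indices or vertex ids), one per patch.
#' @export
build_patch_atlas <- function(template, feature_type = c("volume", "thickness"),
                              scale = 500, seed = 1L) {
  feature_type <- match.arg(feature_type)
  entries <- list()
  if (feature_type == "volume") {
    lab <- as.integer(template$label_volume)
    rois <- sort(unique(lab[lab > 0]))
    for (r in rois) {
      idx <- which(lab == r)                    # 1-based linear indices
      members <- idx - 1L                       # stored 0-based
      pidx <- subdivide_roi_volume(members, template$intensity_volume[idx],
                                   scale, seed = seed + r)
      entries[[as.character(r)]] <- unname(split(members, pidx))
    }
  } else {
    vt <- template$vertex_table
    rois <- sort(unique(vt$roi_id))
    for (r in rois) {
      sel <- vt$roi_id == r
      pidx <- subdivide_roi_surface(vt$vertex_id[sel], vt$thickness[sel],
                                    scale, seed = seed + r)
      entries[[as.character(r)]] <- unname(split(as.integer(vt$vertex_id[sel]), pidx))
    }
  }
  structure(list(feature_type = feature_type, scale = scale, entries = entries),
            class = "patch_atlas")
}

#' @export
print.patch_atlas <- function(x, ...) {
  np <- sum(lengths(x$entries))
  cat(sprintf("<patch_atlas> %s @ scale %s: %d ROIs, %d patches\n",
              x$feature_type, x$scale, length(x$entries), np))
  invisible(x)
}

#' Number of patches in an atlas
#' @param atlas a `patch_atlas`.
#' @return integer.
#' @export
n_patches <- function(atlas) sum(lengths(atlas$entries))

#' Correspondence map between template and target member ids
#'
#' Wraps a (template_id, target_id) relation; one-to-many is allowed. The
#' identity map stands in for the deformation-field propagation of the
#' original registration pipeline, which is external input here.
#'
#' @param template_id,target_id integer vectors of equal length.
#' @return object of class `correspondence_map`.
#' @export
correspondence_map <- function(template_id, target_id) {
  stopifnot(length(template_id) == length(target_id))
  structure(list(template_id = as.integer(template_id),
                 target_id = as.integer(target_id), identity = FALSE),
            class = "correspondence_map")
}

#' @rdname correspondence_map
#' @export
identity_map <- function() {
  structure(list(template_id = integer(0), target_id = integer(0),
                 identity = TRUE), class = "correspondence_map")
}

#' Propagate a patch atlas through a correspondence map
#'
#' Target patch membership is the image of the template membership under the
#' map. The identity map returns an equal atlas. Template members without any
#' map entry are an error (a registration must cover the template).
#'
#' @param atlas a `patch_atlas`.
#' @param map a [correspondence_map()].
#' @return a `patch_atlas` in target space.
#' @export
propagate <- function(atlas, map) {
  if (map$identity) return(atlas)
  lut <- split(map$target_id, map$template_id)
  out <- atlas
  unmapped <- character(0)
  out$entries <- lapply(atlas$entries, function(patches) {
    lapply(patches, function(members) {
      hits <- lut[as.character(members)]
      miss <- members[vapply(hits, is.null, logical(1))]
      if (length(miss)) unmapped <<- c(unmapped, as.character(miss))
      sort(unique(unlist(hits, use.names = FALSE)))
    })
  })
  if (length(unmapped))
    stop("unmapped template members: ",
         paste(utils::head(unmapped, 10), collapse = ", "))
  out
}

#' Compose two correspondence maps
#'
#' @param m1,m2 [correspondence_map()]s; the result maps through `m1` then `m2`.
#' @return a `correspondence_map` equal to `m2 o m1`.
#' @export
compose_maps <- function(m1, m2) {
  if (m1$identity) return(m2)
  if (m2$identity) return(m1)
  lut2 <- split(m2$target_id, m2$template_id)
  tpl <- integer(0); tgt <- integer(0)
  for (i in seq_along(m1$template_id)) {
    hits <- lut2[[as.character(m1$target_id[i])]]
    if (!is.null(hits)) {
      tpl <- c(tpl, rep(m1$template_id[i], length(hits)))
      tgt <- c(tgt, hits)
    }
  }
  correspondence_map(tpl, tgt)
}

#' Extract patch features for a set of scans
#'
#' Volume features are `member_count * voxel_volume` (mm^3); thickness
#' features are the mean thickness over member vertices (mm). Per-scan
#' correspondence maps (template to target space) are applied before
#' counting; a patch left empty after propagation yields 0 with a warning.
#' Patch identity always comes from the template atlases so features are
#' comparable across scans.
#'
#' @param atlases list of `patch_atlas` objects in canonical block order
#'   (volume 500/1000/2000, thickness 500/1000/2000).
#' @param scans list of per-scan descriptors: `subject_id`, `visit_id`,
#'   optional `map_volume` / `map_surface` ([correspondence_map()], identity
#'   by default) and `thickness` (numeric indexed by `vertex_id + 1`;
#'   defaults to the template thickness).
#' @param template the template (source of default thickness values).
#' @param voxel_size_mm isotropic voxel edge, mm.
#' @return a raw [feature_table()]; one block per atlas, columns named
#'   `<type>_<scale>_<roi>_<patch>`.
#' @export
extract_patch_features <- function(atlases, scans, template,
                                   voxel_size_mm = template$voxel_size_mm) {
  voxvol <- voxel_size_mm^3
  vt <- template$vertex_table[order(template$vertex_table$vertex_id), ]
  tpl_thick <- vt$thickness        # position = vertex_id + 1 (ids contiguous)
  sets <- lapply(atlases, function(a)
    feature_set_spec(a$feature_type, a$scale, n_patches(a)))
  colnm <- unlist(lapply(atlases, function(a) {
    unlist(lapply(names(a$entries), function(r)
      sprintf("%s_%s_%s_%d", a$feature_type, a$scale, r,
              seq_along(a$entries[[r]]) - 1L)), use.names = FALSE)
  }), use.names = FALSE)
  rows <- lapply(scans, function(sc) {
    vals <- unlist(lapply(atlases, function(a) {
      m <- if (a$feature_type == "volume") sc$map_volume else sc$map_surface
      at <- if (is.null(m)) a else propagate(a, m)
      unlist(lapply(at$entries, function(patches) {
        vapply(patches, function(members) {
          if (length(members) == 0) {
            warning("empty patch after propagation; feature set to 0")
            return(0)
          }
          if (a$feature_type == "volume") length(members) * voxvol
          else {
            th <- if (is.null(sc$thickness)) tpl_thick else sc$thickness
            mean(th[members + 1L])
          }
        }, numeric(1))
      }), use.names = FALSE)
    }), use.names = FALSE)
    vals
  })
  X <- do.call(rbind, rows)
  colnames(X) <- colnm
  ids <- data.frame(
    subject_id = vapply(scans, function(s) s$subject_id, character(1)),
    visit_id = vapply(scans, function(s) s$visit_id, character(1)),
    stringsAsFactors = FALSE)
  feature_table(ids, X, sets, kind = "raw")
}

#' Serialize / read a patch atlas as CSV
#'
#' Long format: feature_type, scale, roi_id, patch_idx, member_id.
#'
#' @param atlas a `patch_atlas`.
#' @param path CSV path.
#' @return invisibly `path` (write) or a `patch_atlas` (read).
#' @export
write_patch_atlas <- function(atlas, path) {
  rows <- do.call(rbind, lapply(names(atlas$entries), function(r) {
    patches <- atlas$entries[[r]]
    do.call(rbind, lapply(seq_along(patches), function(p)
      data.frame(feature_type = atlas$feature_type, scale = atlas$scale,
                 roi_id = as.integer(r), patch_idx = p - 1L,
                 member_id = patches[[p]])))
  }))
  data.table::fwrite(rows, path)
  invisible(path)
}

#' @rdname write_patch_atlas
#' @export
read_patch_atlas <- function(path) {
  df <- data.table::fread(path)
  entries <- lapply(split(df, df$roi_id), function(d)
    unname(lapply(split(d$member_id, d$patch_idx), as.integer)))
  # split() orders roi ids lexicographically; restore numeric order
  entries <- entries[order(as.integer(names(entries)))]
  structure(list(feature_type = df$feature_type[1],
                 scale = as.character(df$scale[1]), entries = entries),
            class = "patch_atlas")
}
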