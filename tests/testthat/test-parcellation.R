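test_that("patch counts follow max(1, round(size/scale))", {
  set.seed(1)
  a <- subdivide_roi_volume(0:999, rnorm(1000), scale = 500, seed = 2)
  expect_identical(sort(unique(a)), 0:1)          # 2 patches, contiguous from 0
  expect_identical(length(a), 1000L)
  b <- subdivide_roi_volume(0:299, rnorm(300), scale = 500, seed = 2)
  expect_identical(unique(b), 0L)                 # k = 1 degenerate
  expect_error(subdivide_roi_volume(integer(0), numeric(0), 500), "empty")
})

test_that("bimodal inputs split exactly at the modes (brute-force optimum)", {
  # volume: two intensity point-masses; unique k = 2 optimum is the mode split
  members <- 0:199
  inten <- c(rep(0, 100), rep(1, 100))
  a <- subdivide_roi_volume(members, inten, scale = 100, seed = 5)
  expect_identical(length(unique(a)), 2L)
  expect_identical(length(unique(a[1:100])), 1L)
  expect_identical(length(unique(a[101:200])), 1L)
  expect_false(a[1] == a[101])
  # surface: two thickness modes
  th <- c(rep(2.0, 250), rep(3.5, 250))
  s <- subdivide_roi_surface(0:499, th, scale = 250, seed = 5)
  expect_identical(length(unique(s)), 2L)
  expect_false(s[1] == s[251])
  # 500 vertices at scale 500 -> one patch
  s1 <- subdivide_roi_surface(0:499, rnorm(500, 2.5, 0.3), scale = 500, seed = 1)
  expect_identical(unique(s1), 0L)
})

test_that("atlases partition every ROI at every scale, monotonically in scale", {
  tpl <- generate_template(n_volume_rois = 4, n_cortical_rois = 3,
                           roi_size_range = c(600, 1400), seed = 21)
  lab <- as.integer(tpl$label_volume)
  prev <- NULL
  for (sc in c(500, 1000, 2000)) {
    at <- build_patch_atlas(tpl, "volume", sc, seed = 8)
    for (r in names(at$entries)) {
      roi_members <- which(lab == as.integer(r)) - 1L
      got <- sort(unlist(at$entries[[r]], use.names = FALSE))
      expect_identical(got, sort(roi_members))    # disjoint + exhaustive
      expect_identical(length(at$entries[[r]]),
                       max(1L, as.integer(round(length(roi_members) / sc))))
    }
    if (!is.null(prev)) expect_true(n_patches(at) <= n_patches(prev))
    prev <- at
  }
  # determinism
  a1 <- build_patch_atlas(tpl, "thickness", 500, seed = 8)
  a2 <- build_patch_atlas(tpl, "thickness", 500, seed = 8)
  expect_identical(a1$entries, a2$entries)
})

test_that("propagation maps membership and composes", {
  tpl <- generate_template(n_volume_rois = 2, n_cortical_rois = 2,
                           roi_size_range = c(60, 90), seed = 2)
  at <- build_patch_atlas(tpl, "volume", 30, seed = 1)
  expect_identical(propagate(at, identity_map())$entries, at$entries)

  ids <- sort(unlist(at$entries[["1"]], use.names = FALSE))
  # merge two template voxels onto one target id
  tgt <- seq_along(ids); tgt[2] <- tgt[1]
  all_ids <- sort(unlist(lapply(at$entries, unlist), use.names = FALSE))
  m <- correspondence_map(all_ids, match(all_ids, all_ids) * 10L)
  p <- propagate(at, m)
  expect_identical(sort(unlist(p$entries[["1"]], use.names = FALSE)),
                   sort(match(ids, all_ids) * 10L))
  # unmapped member errors with ids
  m_bad <- correspondence_map(all_ids[-1], all_ids[-1])
  expect_error(propagate(at, m_bad), "unmapped")

  # composition property on random small maps
  set.seed(33)
  m1 <- correspondence_map(all_ids, sample(500:999, length(all_ids)))
  m2 <- correspondence_map(sort(unique(m1$target_id)),
                           sample(2000:2999, length(unique(m1$target_id))))
  lhs <- propagate(propagate(at, m1), m2)
  rhs <- propagate(at, compose_maps(m1, m2))
  expect_identical(lhs$entries, rhs$entries)
})

test_that("feature extraction: count x volume, mean thickness, conservation", {
  tpl <- generate_template(n_volume_rois = 3, n_cortical_rois = 2,
                           roi_size_range = c(400, 900), seed = 13)
  atlases <- c(lapply(c(500, 1000), function(sc)
    build_patch_atlas(tpl, "volume", sc, seed = 3)),
    lapply(c(500, 1000), function(sc)
      build_patch_atlas(tpl, "thickness", sc, seed = 3)))
  scans <- list(list(subject_id = "s1", visit_id = "V01"),
                list(subject_id = "s2", visit_id = "V01"))
  tab <- extract_patch_features(atlases, scans, tpl)
  expect_s3_class(tab, "feature_table")
  expect_identical(nrow(tab$X), 2L)
  # identity maps + shared template thickness -> identical rows
  expect_identical(tab$X[1, ], tab$X[2, ])
  # conservation: patch volumes of one ROI sum to the ROI volume
  lab <- as.integer(tpl$label_volume)
  b1 <- feature_block(tab, 1)
  roi1_cols <- grepl("^volume_500_1_", colnames(b1))
  expect_equal(sum(b1[1, roi1_cols]), sum(lab == 1) * tpl$voxel_size_mm^3)
  # hand values: thickness patch mean
  a <- atlases[[3]]
  members <- a$entries[[1]][[1]]
  vt <- tpl$vertex_table[order(tpl$vertex_table$vertex_id), ]
  expect_equal(unname(tab$X[1, ncol(feature_block(tab, 1)) +
                              ncol(feature_block(tab, 2)) + 1]),
               mean(vt$thickness[members + 1]))
})

test_that("atlas CSV serialization round-trips", {
  tpl <- generate_template(n_volume_rois = 12, n_cortical_rois = 2,
                           roi_size_range = c(50, 120), seed = 4)
  at <- build_patch_atlas(tpl, "volume", 30, seed = 6)
  f <- withr::local_tempfile(fileext = ".csv")
  write_patch_atlas(at, f)
  back <- read_patch_atlas(f)
  expect_identical(back$feature_type, at$feature_type)
  expect_identical(names(back$entries), names(at$entries))
  for (r in names(at$entries))
    expect_identical(lapply(back$entries[[r]], sort),
                     lapply(at$entries[[r]], sort))
})
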