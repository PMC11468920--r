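# Small synthetic volume with the anchor code planted in a contiguous blob.
make_blob_volume <- function(gt, map, dims = c(8, 8, 4), blob,
                             n_runs = 6, seed = 1) {
  n_vox <- prod(dims)
  blob_idx <- which(blob)
  conds <- anchorsearch:::condition_table()
  cond_anchor <- anchor_for(map, conds$context, conds$target)
  vals <- anchorsearch:::with_seed(seed, {
    a <- array(rnorm(n_runs * 4 * n_vox, sd = gt$noise_sd),
               dim = c(n_runs, 4, n_vox))
    pat <- sapply(c("anchor_1", "anchor_2"), function(x) rnorm(n_vox))
    for (ci in 1:4) {
      mu <- numeric(n_vox)
      mu[blob_idx] <- gt$anchor_amp * pat[blob_idx, cond_anchor[ci]]
      a[, ci, ] <- sweep(a[, ci, , drop = FALSE], 3, mu, "+")
    }
    a
  })
  volume_betas(vals, dims)
}

test_that("sphere offsets match exhaustive lattice enumeration", {
  for (r in 0:5) {
    expect_equal(sphere_offsets(r)$n_voxels, sphere_count_oracle(r))
    expect_equal(sphere_offsets(r, "euclidean_lt")$n_voxels,
                 sphere_count_oracle(r, strict = TRUE))
  }
  s1 <- sphere_offsets(1)
  expect_equal(s1$n_voxels, 7L) # center + 6 face neighbors
  expect_equal(sphere_offsets(0)$n_voxels, 1L)
  expect_equal(sphere_offsets(5)$n_voxels, 515L)
  # symmetric under negation and contains the origin
  off <- sphere_offsets(3)$offsets
  expect_true(any(rowSums(abs(off)) == 0))
  neg <- -off
  expect_equal(nrow(merge(as.data.frame(off), as.data.frame(neg))),
               nrow(off))
  expect_error(sphere_offsets(-1), "non-negative")
})

test_that("feature mask unions the two group tests inside cortex", {
  set.seed(21)
  n_vox <- 400
  n_sub <- 20
  tmap <- matrix(rnorm(n_sub * n_vox, 0, 0.1), n_sub)
  amap <- matrix(rnorm(n_sub * n_vox, 0, 0.1), n_sub)
  tmap[, 1:40] <- tmap[, 1:40] + 1   # target signal voxels
  amap[, 31:80] <- amap[, 31:80] + 1 # anchor signal voxels (overlap 31:40)
  cortex <- rep(TRUE, n_vox); cortex[81:100] <- FALSE
  mask <- make_feature_mask(tmap, amap, cortex, alpha = 0.05)
  expect_true(all(mask[1:80]))
  expect_true(all(!mask[81:100])) # cortex intersection respected
  expect_lt(mean(mask[101:400]), 0.2)
  # alpha = 1 keeps the whole cortex mask
  expect_equal(make_feature_mask(tmap, amap, cortex, alpha = 1), cortex)
  # chance-level maps: expected fraction near alpha * (2 - alpha)
  null_frac <- mean(make_feature_mask(
    matrix(rnorm(n_sub * n_vox), n_sub),
    matrix(rnorm(n_sub * n_vox), n_sub),
    rep(TRUE, n_vox), alpha = 0.05))
  expect_lt(abs(null_frac - 0.05 * (2 - 0.05)), 0.06)
  expect_error(make_feature_mask(tmap, amap, rep(FALSE, n_vox)), "empty")
})

test_that("searchlight scores equal the standalone decoder per sphere", {
  gt <- test_gt(anchor_amp = 0.7)
  map <- make_association_map(0)
  dims <- c(6, 6, 3)
  blob <- array(TRUE, dims)
  vb <- make_blob_volume(gt, map, dims, blob, seed = 3)
  mask <- array(FALSE, dims); mask[3, 3, 2] <- TRUE
  nb <- sphere_offsets(1)
  sl <- run_searchlight(vb, mask | TRUE, nb, map)
  # recompute the center sphere by hand with the module-level decoder
  center <- which(array(seq_len(prod(dims)), dims) ==
                    (3 + 6 * 2 + 36 * 1))
  pts <- sweep(nb$offsets, 2, c(3, 3, 2), "+")
  lin <- pts[, 1] + dims[1] * (pts[, 2] - 1) + dims[1] * dims[2] * (pts[, 3] - 1)
  b <- anchorsearch:::new_beta_patterns(
    vb$values[, , lin, drop = FALSE], vb$condition_labels, "left", "sphere",
    lin)
  standalone <- run_scheme(list(left = b), "anchor_cross_scene", map)
  expect_equal(sl[3, 3, 2], standalone$info, tolerance = 1e-12)
  # translation equivariance: shifting volume and mask shifts the map
  shift <- array(NA_real_, dims)
  perm <- array(seq_len(prod(dims)), dims)
  vb2 <- vb
  reindex <- as.vector(perm[c(2:6, 1), , ]) # cyclic shift along x
  vb2$values <- vb$values[, , reindex]
  sl2 <- run_searchlight(vb2, array(TRUE, dims), nb, map)
  expect_equal(sl2[2, 3, 2], sl[3, 3, 2], tolerance = 1e-12)
})

test_that("spheres clip at borders and skip undersized neighborhoods", {
  gt <- test_gt()
  map <- make_association_map(0)
  dims <- c(4, 4, 2)
  vb <- make_blob_volume(gt, map, dims, array(TRUE, dims), seed = 5)
  # corner center: sphere clipped but still scored
  sl <- run_searchlight(vb, array(TRUE, dims), sphere_offsets(1), map)
  expect_true(is.finite(sl[1, 1, 1]))
  # isolated voxel with radius 0: fewer than 2 usable voxels -> NA
  mask1 <- array(FALSE, dims); mask1[2, 2, 1] <- TRUE
  sl0 <- run_searchlight(vb, mask1, sphere_offsets(0), map)
  expect_true(is.na(sl0[2, 2, 1]))
  expect_equal(attr(sl0, "n_skipped"), 1L)
})

test_that("group searchlight finds a planted cluster and rejects destroyed signal", {
  gt <- test_gt(anchor_amp = 1.2)
  map <- make_association_map(0)
  dims <- c(7, 7, 3)
  blob <- array(FALSE, dims); blob[2:4, 2:4, 2] <- TRUE
  maps <- lapply(1:10, function(p) {
    vb <- make_blob_volume(gt, map, dims, blob, seed = 100 + p)
    run_searchlight(vb, array(TRUE, dims), sphere_offsets(1), map)
  })
  tp <- tfce_params(n_permutations = 200, seed = 9,
                    tail = "one_sided_positive")
  grp <- group_searchlight(maps, array(TRUE, dims), tp)
  expect_gte(nrow(grp$clusters), 1)
  # peak of the top cluster falls inside the blob dilated by the sphere
  # radius (centers adjacent to the blob also see planted signal)
  top <- grp$clusters[which.max(grp$clusters$peak_z), ]
  peak_ijk <- c(top$peak_x_mm, top$peak_y_mm, top$peak_z_mm) / 2 + 1
  blob_ijk <- which(blob, arr.ind = TRUE)
  min_d <- min(sqrt(rowSums(sweep(blob_ijk, 2, peak_ijk)^2)))
  expect_lte(min_d, 1)
  # cluster volume arithmetic at 2-mm isotropic voxels
  expect_equal(grp$clusters$volume_mm3, grp$clusters$n_voxels * 8)
  # flipping half the participants' maps destroys the cluster
  maps_flip <- maps
  for (i in 1:5) maps_flip[[i]] <- -maps_flip[[i]]
  grp2 <- group_searchlight(maps_flip, array(TRUE, dims), tp)
  expect_equal(nrow(grp2$clusters), 0L)
})

test_that("information maps round-trip through NIfTI with their affine", {
  arr <- array(rnorm(60), c(5, 4, 3))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_nifti_map(arr, path)
  back <- read_nifti_map(path)
  expect_equal(back, arr, ignore_attr = TRUE, tolerance = 1e-6)
  expect_equal(attr(back, "affine")[1, 1], 2, tolerance = 1e-6)
})
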