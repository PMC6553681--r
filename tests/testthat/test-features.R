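test_that("the feature set is exactly 114 names partitioned 13/11/40/26/24", {
  nm <- feature_names()
  expect_length(nm, 114)
  expect_false(anyDuplicated(nm) > 0)
  expect_equal(unname(table(feature_family(nm))[c("GLCM", "GLRLM", "LBP",
                                                  "WSF", "WCF")]),
               c(13L, 11L, 40L, 26L, 24L),
               ignore_attr = TRUE)
  # spellings used in serialized tables
  expect_true(all(c("GLCM_FIMC", "GLRLM_SRLGE", "LBP_17", "WSF_Mean_HL2",
                    "WCF_Entropy_HH1") %in% nm))
})

test_that("volume aggregation takes the per-feature median over finite slices", {
  vol <- tiny_volume(shape = c(12, 12, 3), seed = 21)
  fv <- extract_volume_features(vol, texture_config(min_mask_pixels = 16))
  per_slice <- sapply(1:3, function(k)
    extract_slice_features(vol$intensities[, , k], vol$mask[, , k] > 0,
                           texture_config(),
                           range = range(vol$intensities[vol$mask > 0])))
  want <- apply(per_slice, 1, function(v) {
    v <- v[is.finite(v)]
    if (length(v)) median(v) else NA_real_
  })
  expect_equal(unname(fv$values), unname(want))
  expect_equal(fv$n_slices_used, 3L)
})

test_that("aggregation is permutation-invariant in slice order", {
  vol <- tiny_volume(shape = c(12, 12, 4), seed = 22)
  perm <- volume_with_mask(vol$intensities[, , c(3, 1, 4, 2)],
                           vol$mask[, , c(3, 1, 4, 2)], "P")
  expect_equal(extract_volume_features(vol)$values,
               extract_volume_features(perm)$values)
})

test_that("median skips non-finite slice values", {
  # constant slices make Correlation NA; mixing constant and textured slices
  # must aggregate Correlation over the textured ones only
  set.seed(23)
  x <- array(runif(12 * 12 * 3), c(12, 12, 3))
  x[, , 2] <- 1
  vol <- volume_with_mask(x, array(1L, dim(x)), "M")
  fv <- extract_volume_features(vol)
  s1 <- extract_slice_features(x[, , 1], matrix(TRUE, 12, 12),
                               range = range(x))
  s3 <- extract_slice_features(x[, , 3], matrix(TRUE, 12, 12),
                               range = range(x))
  expect_equal(unname(fv$values["GLCM_Correlation"]),
               median(c(s1["GLCM_Correlation"], s3["GLCM_Correlation"])))
  expect_true(fv$validity["GLCM_Correlation"])
})

test_that("degenerate volumes drive the documented invalid path, not errors", {
  # constant volume: defined features finite, correlation-type features NA
  vc <- tiny_volume(shape = c(12, 12, 3), seed = 24, constant = TRUE)
  fv <- extract_volume_features(vc)
  expect_equal(unname(fv$values["GLCM_Energy"]), 1)
  expect_false(fv$validity["GLCM_Correlation"])

  # single-voxel mask: below min_mask_pixels everywhere -> all invalid
  m1 <- array(0L, c(12, 12, 3)); m1[6, 6, 2] <- 1L
  v1 <- volume_with_mask(array(runif(432), c(12, 12, 3)), m1, "S1")
  fv1 <- extract_volume_features(v1)
  expect_true(all(!fv1$validity))
  expect_equal(fv1$n_slices_used, 0L)

  # mask empty on some slices: those slices are skipped, the rest aggregate
  m2 <- array(1L, c(12, 12, 3)); m2[, , 2] <- 0L
  v2 <- volume_with_mask(array(runif(432), c(12, 12, 3)), m2, "S2")
  expect_equal(extract_volume_features(v2)$n_slices_used, 2L)
})

test_that("slices below min_mask_pixels are skipped", {
  m <- array(1L, c(12, 12, 2)); m[, , 2] <- 0L; m[1:3, 1:5, 2] <- 1L  # 15 px
  v <- volume_with_mask(array(runif(288), c(12, 12, 2)), m, "S3")
  expect_equal(extract_volume_features(v, texture_config(min_mask_pixels = 16))$n_slices_used, 1L)
  expect_equal(extract_volume_features(v, texture_config(min_mask_pixels = 10))$n_slices_used, 2L)
})
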