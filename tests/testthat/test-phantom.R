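spec_small <- phantom_spec(volume_shape = c(16, 16, 8), mask_fraction = 0.1,
                           effect_size = 1)

test_that("generation is deterministic and seed-sensitive", {
  a <- generate_phantom(spec_small, 1L, seed = 5)
  b <- generate_phantom(spec_small, 1L, seed = 5)
  c <- generate_phantom(spec_small, 1L, seed = 6)
  expect_identical(a$intensities, b$intensities)
  expect_identical(a$mask, b$mask)
  expect_false(identical(a$intensities, c$intensities))
})

test_that("phantom volumes satisfy the container invariants", {
  v <- generate_phantom(spec_small, 0L, seed = 7)
  expect_identical(dim(v$intensities), dim(v$mask))
  expect_gte(sum(v$mask), 1)
  expect_true(all(is.finite(v$intensities)))
  expect_true(all(v$intensities >= 0))
})

test_that("mask fraction is honoured within 20% for every mask kind", {
  for (kind in c("blob", "shell", "scatter")) {
    sp <- phantom_spec(volume_shape = c(24, 24, 12), mask_kind = kind,
                       mask_fraction = 0.1)
    counts <- vapply(1:10, function(s)
      sum(generate_phantom(sp, 0L, seed = s)$mask), numeric(1))
    target <- 0.1 * prod(sp$volume_shape)
    expect_true(all(abs(counts - target) / target < 0.2), label = kind)
  }
})

test_that("effect_size = 0 makes the two classes share one distribution", {
  sp0 <- phantom_spec(volume_shape = c(16, 16, 8), effect_size = 0)
  a <- generate_phantom(sp0, 0L, seed = 11)
  b <- generate_phantom(sp0, 1L, seed = 11)
  expect_identical(a$intensities, b$intensities)
})

test_that("invalid specs are rejected", {
  expect_error(phantom_spec(volume_shape = c(4, 16, 16)),
               class = "radtex_invalid_spec")
  expect_error(phantom_spec(mask_fraction = 0), class = "radtex_invalid_spec")
  expect_error(phantom_spec(mask_fraction = 0.7), class = "radtex_invalid_spec")
  expect_error(phantom_spec(effect_size = -1), class = "radtex_invalid_spec")
  expect_error(generate_cohort(spec_small, 0, 1), class = "radtex_invalid_spec")
})

test_that("cohorts are balanced with the requested arity", {
  coh <- generate_cohort(spec_small, 3, base_seed = 31)
  expect_length(coh$volumes, 6)
  expect_equal(sum(coh$labels == 0L), 3)
  expect_equal(sum(coh$labels == 1L), 3)
  expect_equal(nrow(coh$covariates), 6)
  coh1 <- generate_cohort(spec_small, 1, base_seed = 31)
  expect_length(coh1$volumes, 2)
})

test_that("the texture covariate carries the configured correlation", {
  # strong rho on a moderately sized cohort: sample correlation must be high
  sp <- phantom_spec(volume_shape = c(8, 8, 8), effect_size = 1,
                     subject_jitter_sd = 0.2)
  coh <- generate_cohort(sp, 40, base_seed = 41, covariate_rho = 0.9)
  true_param <- log(ifelse(coh$labels == 1L,
                           sp$smoothing_scale * 2, sp$smoothing_scale))
  expect_gt(cor(coh$covariates$cov_texture, true_param), 0.5)
  # rho = 0: independent of the class parameter
  coh0 <- generate_cohort(sp, 40, base_seed = 41, covariate_rho = 0)
  expect_lt(abs(cor(coh0$covariates$cov_texture, coh0$labels)), 0.35)
})

test_that("zero-correlation covariate: bootstrap CI covers 0 most of the time", {
  sp <- phantom_spec(volume_shape = c(8, 8, 8))
  hits <- 0L
  reps <- 40L
  for (r in seq_len(reps)) {
    coh <- generate_cohort(sp, 15, base_seed = 600 + r, covariate_rho = 0)
    bp <- bootstrap_pearson(coh$covariates$cov_texture,
                            as.numeric(coh$labels), B = 200,
                            seed = r)
    if (bp$ci[1] <= 0 && bp$ci[2] >= 0) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.9)
})
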