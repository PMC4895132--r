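# The 15/26/41 feature vectors.

test_that("feature vectors have the canonical cardinalities and names", {
  cs <- generate_case(1, seed = 3)
  fc <- microcalc_features(cs$image, cs$calc_mask)
  fm <- mass_features(cs$image, cs$mass_mask)
  fb <- combined_features(fc, fm)
  expect_length(fc, 15)
  expect_length(fm, 26)
  expect_length(fb, 41)
  expect_identical(names(fc), calc_feature_names())
  expect_identical(names(fm), mass_feature_names())
  expect_identical(names(fb), combined_feature_names())
  expect_identical(as.numeric(fb), c(as.numeric(fc), as.numeric(fm)))
  expect_true(all(is.finite(fb)))
  expect_error(combined_features(fm, fc), class = "mammocad_input_error")
})

test_that("the count feature equals the number of inserted calcifications", {
  bg <- generate_background(128, 128, 2, seed = 8)
  sp <- phantom_spec(width = 128, height = 128, calc_count_range = c(5, 5))
  out <- insert_microcalcifications(bg, sp, seed = 4)
  fv <- microcalc_features(out$image, out$mask)
  expect_equal(fv[["calc_number"]], 5)
  expect_gt(fv[["calc_mean_gray"]], mean(bg))  # calcs are bright
})

test_that("empty masks give the documented degenerate zero vectors", {
  img <- generate_background(64, 64, 0, seed = 2)
  zero <- matrix(0L, 64, 64)
  fc <- microcalc_features(img, zero)
  expect_identical(as.numeric(fc), rep(0, 15))
  fm <- mass_features(img, zero)
  expect_identical(as.numeric(fm), rep(0, 26))
})

test_that("mask containment and multi-component masses are rejected", {
  img <- generate_background(64, 64, 0, seed = 2)
  m <- matrix(0L, 64, 64); m[5:10, 5:10] <- 1L
  roi <- matrix(0L, 64, 64); roi[20:40, 20:40] <- 1L
  expect_error(microcalc_features(img, m, roi),
               class = "mammocad_input_error")
  two <- matrix(0L, 64, 64); two[5:10, 5:10] <- 1L; two[30:35, 30:35] <- 1L
  expect_error(mass_features(img, two), class = "mammocad_input_error")
})

test_that("a filled rectangle on a constant image is solid and entropy-free", {
  img <- matrix(100, 64, 64)
  m <- matrix(0L, 64, 64); m[20:40, 15:45] <- 1L
  fv <- mass_features(img, m)
  expect_equal(fv[["mass_solidity"]], 1)
  expect_equal(fv[["mass_heterogeneity"]], 0)
  expect_equal(fv[["mass_entropy"]], 0)
  expect_equal(fv[["mass_energy"]], 1)
})

test_that("spiculated masses score higher spiculation than their smooth twins", {
  bg <- generate_background(192, 192, 2, seed = 6)
  sp0 <- phantom_spec(mass_spiculation_level = 0)
  sp4 <- phantom_spec(mass_spiculation_level = 4)
  m0 <- insert_mass(bg, sp0, seed = 9)
  m4 <- insert_mass(bg, sp4, seed = 9)
  f0 <- mass_features(m0$image, m0$mask)
  f4 <- mass_features(m4$image, m4$mask)
  expect_gt(f4[["mass_spiculation"]], f0[["mass_spiculation"]])
  expect_lt(f4[["mass_solidity"]], f0[["mass_solidity"]])
})
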