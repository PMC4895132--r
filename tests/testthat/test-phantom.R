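# Phantom generator: backgrounds, lesion insertion, cases, feature tables.

test_that("background generation is seeded, bounded and smoothness-controlled", {
  bg <- generate_background(256, 256, 0, seed = 1)
  expect_identical(bg, generate_background(256, 256, 0, seed = 1))
  expect_true(all(bg >= 0 & bg <= 255))
  expect_gt(mean(bg), 96)
  expect_lt(mean(bg), 160)
  lag1 <- function(m) cor(as.vector(m[, -ncol(m)]), as.vector(m[, -1]))
  expect_lt(abs(lag1(bg)), 0.1)              # sigma 0: i.i.d. pixels
  bg8 <- generate_background(256, 256, 8, seed = 1)
  expect_gt(lag1(bg8), lag1(bg))             # smoothing raises autocorrelation
  expect_error(generate_background(16, 256), class = "mammocad_input_error")
})

test_that("microcalcification insertion honours count, disjointness and brightness", {
  bg <- generate_background(128, 128, 2, seed = 5)
  sp0 <- phantom_spec(width = 128, height = 128, calc_count_range = c(0, 0))
  out0 <- insert_microcalcifications(bg, sp0, seed = 1)
  expect_identical(out0$image, bg)
  expect_identical(sum(out0$mask), 0L)

  sp5 <- phantom_spec(width = 128, height = 128, calc_count_range = c(5, 5))
  out5 <- insert_microcalcifications(bg, sp5, seed = 2)
  expect_length(label_components(out5$mask), 5)
  sel <- out5$mask == 1
  expect_true(all(out5$image[sel] > bg[sel]))   # strictly brighter
  expect_true(all(out5$image >= bg))            # soft skirts only add
  expect_lte(max(out5$image), 255)

  spbig <- phantom_spec(width = 128, height = 128,
                        calc_diameter_range = c(18, 20))
  tiny <- generate_background(32, 32, 0, seed = 1)
  expect_error(insert_microcalcifications(tiny, spbig, seed = 1),
               class = "mammocad_input_error")
})

test_that("pure elongated shape mix yields components with axis ratio >= 2", {
  sp <- phantom_spec(calc_shape_mix = c(round = 0, elongated = 1,
                                        irregular = 0),
                     calc_count_range = c(8, 8))
  for (s in 1:5) {
    bg <- generate_background(256, 256, 2, seed = s)
    out <- insert_microcalcifications(bg, sp, seed = s)
    for (m in label_components(out$mask)) {
      g <- component_geometry(m)
      expect_gte(g$major_axis / g$minor_axis, 2)
    }
  }
})

test_that("mass insertion is solid when smooth and loses solidity with spiculation", {
  bg <- generate_background(192, 192, 2, seed = 3)
  off <- phantom_spec(mass_present = FALSE)
  out_off <- insert_mass(bg, off, seed = 1)
  expect_identical(out_off$image, bg)
  expect_identical(sum(out_off$mask), 0L)

  sp0 <- phantom_spec(mass_axes = c(40, 25), mass_spiculation_level = 0)
  out0 <- insert_mass(bg, sp0, seed = 4)
  expect_length(label_components(out0$mask), 1)
  g0 <- component_geometry(out0$mask)
  expect_gte(g0$area / g0$convex_area, 0.98)

  sp5 <- phantom_spec(mass_axes = c(40, 25), mass_spiculation_level = 5)
  out5 <- insert_mass(bg, sp5, seed = 4)
  g5 <- component_geometry(out5$mask)
  expect_lt(g5$area / g5$convex_area, g0$area / g0$convex_area)

  huge <- phantom_spec(mass_axes = c(120, 80))
  expect_error(insert_mass(generate_background(64, 64, 0, seed = 1), huge,
                           seed = 1),
               class = "mammocad_input_error")
})

test_that("generated cases are deterministic with consistent truth masks", {
  a <- generate_case(1, seed = 11)
  b <- generate_case(1, seed = 11)
  expect_identical(a, b)
  expect_identical(dim(a$image), dim(a$calc_mask))
  expect_identical(dim(a$image), dim(a$mass_mask))
  expect_true(all(a$calc_mask %in% c(0L, 1L)))
  expect_equal(length(label_components(a$calc_mask)), a$n_calcs)
})

test_that("mask component count equals the drawn count across many cases", {
  for (s in 1:40) {
    cs <- generate_case(s %% 2, seed = 1000 + s)
    expect_equal(length(label_components(cs$calc_mask)), cs$n_calcs)
  }
})

test_that("malignant cases have more linear calcifications and less solid masses", {
  f <- function(lab, seeds) t(vapply(seeds, function(s) {
    cs <- generate_case(lab, seed = s)
    as.numeric(case_features(cs, "combined"))
  }, numeric(41)))
  f0 <- f(0, 1:40)
  f1 <- f(1, 101:140)
  nm <- combined_feature_names()
  lin <- which(nm == "calc_linear_proportion")
  sol <- which(nm == "mass_solidity")
  expect_gt(mean(f1[, lin]), mean(f0[, lin]))
  expect_lt(mean(f1[, sol]), mean(f0[, sol]))
  expect_gt(mean(f1[, 1]), mean(f0[, 1]))  # calc count higher in malignant
})

test_that("simulated feature tables have the declared structure", {
  expect_error(simulate_feature_table(100, 20, "linear", 1),
               class = "mammocad_input_error")
  expect_error(simulate_feature_table(15, 15, "linear", 1),
               class = "mammocad_input_error")
  tab <- simulate_feature_table(400, 41, "linear", 3, seed = 1)
  expect_identical(colnames(tab$x), combined_feature_names())
  expect_equal(sum(tab$y == 1), 200)        # balanced by default
  expect_identical(tab, simulate_feature_table(400, 41, "linear", 3, seed = 1))
  # linear: means differ by ~effect on informative dims, ~0 elsewhere
  d <- colMeans(tab$x[tab$y == 1, ]) - colMeans(tab$x[tab$y == 0, ])
  expect_true(all(abs(d[1:2] - 3) < 0.5))
  expect_true(all(abs(d[-(1:2)]) < 0.3))
  # xor: no mean difference on any dim, but sign-product separates
  tx <- simulate_feature_table(400, 41, "xor", 3, seed = 2)
  dx <- colMeans(tx$x[tx$y == 1, ]) - colMeans(tx$x[tx$y == 0, ])
  expect_true(all(abs(dx) < 0.5))
  agree <- mean((sign(tx$x[, 1]) * sign(tx$x[, 2]) > 0) == (tx$y == 1))
  expect_gt(agree, 0.8)
})
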