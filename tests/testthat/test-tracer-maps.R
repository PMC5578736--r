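make_test_image <- function(mat, px = 2) section_image(list(ch = mat), px)

test_that("fractional area counts masked pixels above threshold", {
  img <- make_test_image(matrix(10, 20, 20))
  expect_identical(fractional_area(img, "ch", 5), 1)
  half <- matrix(c(rep(0, 200), rep(10, 200)), 20, 20)
  expect_identical(fractional_area(make_test_image(half), 1, 5), 0.5)
  expect_error(fractional_area(img, "ch", 5, mask = matrix(FALSE, 20, 20)),
               "empty mask")
  # monotone nonincreasing threshold sweep on an arbitrary image
  set.seed(1)
  noisy <- make_test_image(matrix(rpois(400, 50), 20, 20))
  sweep <- fractional_area_sweep(noisy, 1, thresholds = seq(20, 90, by = 5))
  expect_true(all(diff(sweep$fraction) <= 0))
})

test_that("exposure bridging is linear, identity-preserving and multiplicative", {
  expect_identical(exposure_bridge(200, 1, 16), 3200)
  expect_identical(exposure_bridge(77, 4, 4), 77)
  expect_identical(exposure_bridge(exposure_bridge(13, 1, 4), 4, 16),
                   exposure_bridge(13, 1, 16))
  # linearity over a dilution series
  dil <- c(1, 0.5, 0.25, 0.125)
  expect_equal(exposure_bridge(200 * dil, 1, 16), 3200 * dil)
  expect_error(exposure_bridge(10, 0, 4), "exposures")
})

test_that("depth profile recovers analytic decay lengths", {
  # exp(-depth/L) image: half-distance is L ln 2
  L <- 50; px <- 2
  depth <- ((1:200) - 0.5) * px
  img <- make_test_image(matrix(rep(exp(-depth / L), 100), 200, 100), px)
  prof <- depth_profile(img, 1, surface = 0, max_depth = 380)
  expect_rel_equal(profile_decay_distance(prof, 0.5), L * log(2), 0.02)
  # flat image: no half-distance
  flat <- depth_profile(make_test_image(matrix(3, 50, 40)), 1,
                        surface = 0, max_depth = 80)
  expect_true(is.na(profile_decay_distance(flat, 0.5)))
})

test_that("depth profile against a slanted polyline surface uses Euclidean distance", {
  px <- 1
  n <- 80
  x <- ((1:n) - 0.5); y <- ((1:n) - 0.5)
  # surface along the diagonal y = x: distance = (y - x)/sqrt(2)
  dist <- pmax(outer(y, x, `-`), 0) / sqrt(2)
  img <- make_test_image(exp(-dist / 10), px)
  prof <- depth_profile(img, 1, surface = rbind(c(0, 0), c(n, n)),
                        max_depth = 30)
  expect_rel_equal(profile_decay_distance(prof, 0.5), 10 * log(2), 0.1)
})

test_that("radial profile recovers the Gaussian d10 and is rotation invariant", {
  px <- 2; sigma <- 30
  xy <- ((1:150) - 0.5) * px
  r2 <- outer((xy - 150)^2, (xy - 150)^2, `+`)
  img <- make_test_image(exp(-r2 / (2 * sigma^2)), px)
  prof <- radial_profile(img, 1, center = c(150, 150), max_radius = 140)
  expect_rel_equal(profile_decay_distance(prof, 0.1), sigma * sqrt(2 * log(10)),
                   0.05)
  rot <- make_test_image(t(img$channels[[1]]), px)
  prof_rot <- radial_profile(rot, 1, center = c(150, 150), max_radius = 140)
  expect_equal(prof$intensity, prof_rot$intensity, tolerance = 1e-12)
  expect_error(radial_profile(img, 1, center = c(-5, 0), max_radius = 10),
               "outside")
})

test_that("profiles are invariant to global intensity scaling", {
  px <- 2
  depth <- ((1:100) - 0.5) * px
  base <- matrix(rep(exp(-depth / 40), 50), 100, 50)
  p1 <- depth_profile(make_test_image(base, px), 1, 0, 180)
  p2 <- depth_profile(make_test_image(37.5 * base, px), 1, 0, 180)
  expect_equal(p1$intensity, p2$intensity, tolerance = 1e-12)
})

test_that("line profiles measure half-distances along drawn segments", {
  L <- 30; px <- 1
  x <- ((1:120) - 0.5)
  img <- make_test_image(matrix(rep(exp(-x / L), each = 60), 60, 120), px)
  prof <- line_profile(img, 1, from = c(0.5, 30), to = c(110, 30))
  expect_rel_equal(profile_decay_distance(prof, 0.5), L * log(2), 0.05)
  flat <- line_profile(make_test_image(matrix(2, 40, 40)), 1,
                       from = c(1, 20), to = c(70, 20))
  expect_true(is.na(profile_decay_distance(flat, 0.5)))
  # averaging four identical vessels reproduces the single-vessel value
  avg <- average_line_profiles(list(prof, prof, prof, prof))
  expect_equal(profile_decay_distance(avg, 0.5),
               profile_decay_distance(prof, 0.5))
  expect_error(line_profile(img, 1, from = c(5, 5), to = c(5, 5)),
               "zero-length")
})

test_that("two-way genotype ANOVA separates offset groups and not identical ones", {
  base <- tidyr::expand_grid(genotype = c("wt", "ko"), mouse = 1:6,
                             position = 1:4)
  set.seed(42)
  same <- dplyr::mutate(base, value = 0.3 + rnorm(dplyr::n(), 0, 0.01))
  g_same <- genotype_comparison(same)
  expect_gt(g_same$p_genotype, 0.01)
  offset <- dplyr::mutate(base,
                          value = 0.3 + 0.1 * (genotype == "ko") +
                            rnorm(dplyr::n(), 0, 0.01))
  g_off <- genotype_comparison(offset)
  expect_lt(g_off$p_genotype, 1e-3)
  expect_error(genotype_comparison(dplyr::filter(same, genotype == "wt")),
               "two genotype")
  # blinding hides labels in the summary only
  blind <- genotype_comparison(offset, blind = TRUE)
  expect_true(all(grepl("^group-", blind$summary$genotype)))
  expect_equal(blind$p_genotype, g_off$p_genotype)
  expect_equal(glance(g_off)$p_genotype, g_off$p_genotype)
})
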