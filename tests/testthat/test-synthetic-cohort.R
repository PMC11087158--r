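proto_a <- function() default_protocols()$A

test_that("dose model: saturation, half-dose at d = R, determinism", {
  ph <- phantom_spec(shape = c(21, 21, 21), spacing = c(2, 2, 2),
                     ptv_center = c(20, 20, 20), ptv_radius = 14,
                     gradient_width = 2, background_frac = 0.05,
                     oars = list(), noise_sd = 0)
  d <- generate_dose(ph, proto_a())
  rx <- proto_a()$prescription
  # center voxel: (R - 0)/w = 7 -> within 0.1% of prescription
  expect_equal(d$values[11, 11, 11], rx, tolerance = 1e-3)
  # voxel at exactly d = R (14 mm along z): sigma(0) = 1/2
  expect_equal(d$values[4, 11, 11], rx * (0.05 + 0.95 / 2), tolerance = 1e-12)
  # determinism with noise
  phn <- phantom_spec(shape = c(9, 9, 9), spacing = c(2, 2, 2),
                      ptv_center = c(8, 8, 8), ptv_radius = 6,
                      gradient_width = 2, noise_sd = 0.05)
  expect_identical(generate_dose(phn, proto_a(), seed = 5)$values,
                   generate_dose(phn, proto_a(), seed = 5)$values)
  expect_false(identical(generate_dose(phn, proto_a(), seed = 5)$values,
                         generate_dose(phn, proto_a(), seed = 6)$values))
})

test_that("noise-free dose is monotone non-increasing in distance from PTV", {
  ph <- tiny_phantom(noise_sd = 0)
  d <- generate_dose(ph, proto_a())
  ind <- as.matrix(expand.grid(1:dim(d$values)[1], 1:dim(d$values)[2],
                               1:dim(d$values)[3]))
  dist <- sqrt(colSums((t(sweep(ind - 1, 2, ph$spacing, "*")) -
                          ph$ptv_center)^2))
  ord <- order(dist)
  expect_true(all(diff(d$values[ind[ord, , drop = FALSE]]) <= 1e-9))
})

test_that("sphere rasterization approximates the analytic volume", {
  ph <- phantom_spec(shape = c(15, 15, 15), spacing = c(1, 1, 1),
                     ptv_center = c(7, 7, 7), ptv_radius = 3,
                     gradient_width = 1,
                     oars = list(s = oar_shape("sphere", c(7, 7, 7),
                                               radius = 5)),
                     noise_sd = 0)
  st <- generate_structures(ph)
  analytic <- 4 / 3 * pi * 5^3
  expect_lt(abs(sum(st$s$values) - analytic) / analytic, 0.10)
  # brute-force voxel-center-in-sphere count agrees exactly
  ind <- as.matrix(expand.grid(0:14, 0:14, 0:14))
  brute <- sum(colSums((t(ind) - 7)^2) <= 25)
  expect_equal(sum(st$s$values), brute)
})

test_that("disjoint primitives yield non-overlapping masks; roster has 13", {
  ph <- phantom_spec(shape = c(20, 20, 20), spacing = c(2, 2, 2),
                     ptv_center = c(19, 19, 19), ptv_radius = 5,
                     gradient_width = 2,
                     oars = list(a = oar_shape("sphere", c(10, 10, 10), radius = 4),
                                 b = oar_shape("sphere", c(28, 28, 28), radius = 4)),
                     noise_sd = 0)
  st <- generate_structures(ph)
  expect_false(any(st$a$values & st$b$values))
  expect_length(generate_structures(default_head_phantom()), 13L)
  expect_error(
    phantom_spec(shape = c(10, 10, 10), spacing = c(1, 1, 1),
                 ptv_center = c(5, 5, 5), ptv_radius = 3, gradient_width = 1,
                 oars = list(out = oar_shape("sphere", c(9, 9, 9), radius = 4))),
    "outside")
})

test_that("perturbations: identity at magnitude 0, mislocation, erosion-away", {
  st <- generate_structures(tiny_phantom())
  g <- st$brainstem
  for (k in c("dilate", "erode", "translate", "truncate")) {
    sp <- if (k == "translate") perturbation_spec(k, magnitude = c(0, 0, 0))
          else perturbation_spec(k, magnitude = 0)
    expect_identical(perturb(g, sp)$values, g$values, label = k)
  }
  mis <- perturb(g, perturbation_spec("mislocate"))
  expect_equal(dsc(g, mis), 0)
  expect_equal(sum(mis$values), sum(g$values))  # voxel count preserved
  tiny <- structure_mask(array(c(TRUE, rep(FALSE, 26)), c(3, 3, 3)),
                         c(1, 1, 1))
  gone <- perturb(tiny, perturbation_spec("erode", magnitude = 2))
  expect_false(gone$present)
  expect_identical(gone$status, "eroded-away")
  failed <- perturb(g, perturbation_spec("fail"))
  expect_identical(failed$status, "failed")
})

test_that("translating a cube inside uniform dose leaves D1% unchanged", {
  # uniform-dose region: deep inside the PTV plateau
  # R large enough that the logistic saturates to exactly 1 in doubles
  ph <- phantom_spec(shape = c(24, 24, 24), spacing = c(1, 1, 1),
                     ptv_center = c(11, 11, 11), ptv_radius = 200,
                     gradient_width = 2,
                     oars = list(cube = oar_shape("sphere", c(11, 11, 11),
                                                  radius = 4)),
                     noise_sd = 0)
  d <- generate_dose(ph, proto_a())
  g <- generate_structures(ph)$cube
  a <- perturb(g, perturbation_spec("translate", magnitude = c(0, 0, 1)))
  d1g <- dose_metric(d, g, "D1%")
  d1a <- dose_metric(d, a, "D1%")
  # brute-force check of both metrics on the constructed case
  expect_identical(d1g, dvh_oracle(d$values[g$values], 1))
  expect_identical(d1a, dvh_oracle(d$values[a$values], 1))
  expect_identical(d1a, d1g)
})

test_that("truncate removes the last k occupied slices along the stated axis", {
  occ <- array(FALSE, c(6, 4, 4)); occ[2:5, 2:3, 2:3] <- TRUE
  g <- structure_mask(occ, c(1, 1, 1))
  tr <- perturb(g, perturbation_spec("truncate", magnitude = 2, axis = "z"))
  expect_true(all(which(apply(tr$values, 1, any)) == 2:3))
  expect_equal(sum(tr$values), sum(occ) / 2)
})

test_that("cohort generation is a pure function of (spec, seed)", {
  ph <- tiny_phantom(noise_sd = 0.01)
  c1 <- simulate_cohort(3, ph, seed = 11)
  c2 <- simulate_cohort(3, ph, seed = 11)
  c3 <- simulate_cohort(3, ph, seed = 12)
  expect_identical(c1$cases, c2$cases)
  expect_false(identical(c1$cases, c3$cases))
  b1 <- case_bundle(c1, "case002"); b2 <- case_bundle(c2, "case002")
  expect_identical(b1$dose$values, b2$dose$values)
  expect_identical(lapply(b1$auto$edited, `[[`, "values"),
                   lapply(b2$auto$edited, `[[`, "values"))
})

test_that("degenerate profiles: all-fail and identity pipelines", {
  ph <- tiny_phantom(noise_sd = 0)
  all_fail <- list(m = error_profile("fail", 1))
  co <- simulate_cohort(4, ph, all_fail, seed = 3)
  pc <- evaluate_cohort(co, run_config())
  expect_true(all(pc$status == "failed"))
  agg <- aggregate_deltas(pc)
  expect_true(all(agg$n_star == 0))
  expect_true(all(is.na(agg$mean_abs_percent)))

  co_id <- simulate_cohort(4, ph, identity_profiles(), seed = 3)
  pc_id <- evaluate_cohort(co_id, run_config())
  expect_true(all(pc_id$dsc == 1))
  expect_true(all(pc_id$delta_cGy == 0))
  expect_error(simulate_cohort(3, ph, list(), seed = 1), "non-empty")
})

test_that("failure rates follow the profile within binomial error", {
  ph <- tiny_phantom(noise_sd = 0)
  pr <- list(m = error_profile(c("none", "fail"), c(0.7, 0.3)))
  co <- simulate_cohort(60, ph, pr, seed = 9)
  pc <- evaluate_cohort(co, run_config())
  rate <- mean(pc$status == "failed")
  n <- nrow(pc)
  expect_lt(abs(rate - 0.3), 3 * sqrt(0.3 * 0.7 / n))
})
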