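staircase <- function() {
  # 100 equal-volume voxels with doses 100, 200, ..., 10000 cGy
  v <- array(seq(100, 10000, by = 100), c(1, 10, 10))
  list(dose = dose_grid(v, c(1, 1, 1)),
       mask = structure_mask(array(TRUE, c(1, 10, 10)), c(1, 1, 1)))
}

test_that("staircase field: D50% = 5100, D1% = Dmax = 10000 cGy", {
  s <- staircase()
  expect_equal(dose_metric(s$dose, s$mask, "D50%"), 5100)
  expect_equal(dose_metric(s$dose, s$mask, "D1%"), 10000)
  expect_equal(dose_metric(s$dose, s$mask, "Dmax"), 10000)
  # against the independent oracle too
  doses <- s$dose$values[s$mask$values]
  expect_equal(dvh_oracle(doses, 50), 5100)
  expect_equal(dvh_oracle(doses, 1), 10000)
})

test_that("uniform field returns the constant for every metric", {
  d <- dose_grid(array(5000, c(3, 3, 3)), c(2, 2, 2))
  m <- structure_mask(array(TRUE, c(3, 3, 3)), c(2, 2, 2))
  for (mk in metric_kinds()) expect_equal(dose_metric(d, m, mk), 5000)
})

test_that("dose_metric matches the brute-force oracle on random fields", {
  set.seed(101)
  for (i in 1:300) {
    fm <- rand_field_mask()
    doses <- fm$dose$values[fm$mask$values]
    expect_identical(dose_metric(fm$dose, fm$mask, "D1%"), dvh_oracle(doses, 1))
    expect_identical(dose_metric(fm$dose, fm$mask, "D5%"), dvh_oracle(doses, 5))
    expect_identical(dose_metric(fm$dose, fm$mask, "D50%"), dvh_oracle(doses, 50))
    expect_identical(dose_metric(fm$dose, fm$mask, "Dmax"), max(doses))
  }
})

test_that("metric ordering, scale equivariance and traversal invariance", {
  set.seed(202)
  for (i in 1:50) {
    fm <- rand_field_mask()
    d1 <- dose_metric(fm$dose, fm$mask, "D1%")
    d5 <- dose_metric(fm$dose, fm$mask, "D5%")
    d50 <- dose_metric(fm$dose, fm$mask, "D50%")
    dmax <- dose_metric(fm$dose, fm$mask, "Dmax")
    expect_true(dmax >= d1 && d1 >= d5 && d5 >= d50)
    k <- runif(1, 0.1, 4)
    scaled <- dose_grid(fm$dose$values * k, fm$dose$spacing, fm$dose$origin)
    expect_equal(dose_metric(scaled, fm$mask, "D5%"), k * d5)
    # traversal order: permute the axes of field and mask jointly
    p <- sample(1:3)
    dp <- dose_grid(aperm(fm$dose$values, p), fm$dose$spacing[p])
    mp <- structure_mask(aperm(fm$mask$values, p), fm$dose$spacing[p])
    expect_identical(dose_metric(dp, mp, "D50%"), d50)
  }
})

test_that("failed or empty masks give 'metric unavailable', never 0", {
  d <- dose_grid(array(100, c(2, 2, 2)), c(1, 1, 1))
  failed <- structure_mask(array(FALSE, c(2, 2, 2)), c(1, 1, 1),
                           present = FALSE)
  expect_error(dose_metric(d, failed, "D1%"), "unavailable")
  mism <- structure_mask(array(TRUE, c(2, 2, 3)), c(1, 1, 1))
  expect_error(dose_metric(d, mism, "D1%"), "incompatible")
})

test_that("dvh_curve starts at 1 and is monotone non-increasing", {
  set.seed(7)
  fm <- rand_field_mask()
  crv <- dvh_curve(fm$dose, fm$mask)
  expect_equal(crv$volume_fraction[1], 1)
  expect_true(all(diff(crv$volume_fraction) <= 1e-12))
})

test_that("dose_delta: identity, worked arithmetic and failure propagation", {
  s <- staircase()
  idn <- dose_delta(s$dose, s$mask, s$mask, "D1%")
  expect_equal(idn$delta_cGy, 0)
  expect_equal(idn$percent, 0)
  expect_identical(idn$status, "ok")

  # gold D1% 5000, auto D1% 5500 -> +500 cGy, +10%, abs 10%
  d <- dose_grid(array(c(5000, 5500), c(1, 1, 2)), c(1, 1, 1))
  g <- structure_mask(array(c(TRUE, FALSE), c(1, 1, 2)), c(1, 1, 1))
  a <- structure_mask(array(c(FALSE, TRUE), c(1, 1, 2)), c(1, 1, 1))
  dd <- dose_delta(d, g, a, "D1%")
  expect_equal(dd$delta_cGy, 500)
  expect_equal(dd$percent, 10)
  expect_equal(dd$abs_percent, 10)

  failed <- structure_mask(array(FALSE, c(1, 1, 2)), c(1, 1, 1),
                           present = FALSE)
  df <- dose_delta(d, g, failed, "D1%")
  expect_identical(df$status, "failed")
  expect_true(is.na(df$delta_cGy))
  expect_false(is.na(df$gold_cGy))

  # gold dose 0: percent undefined, absolute delta still reported
  d0 <- dose_grid(array(c(0, 700), c(1, 1, 2)), c(1, 1, 1))
  du <- dose_delta(d0, g, a, "D1%")
  expect_identical(du$status, "undefined-percent")
  expect_equal(du$delta_cGy, 700)
  expect_true(is.na(du$percent))

  # prescription-relative normalization flag
  dp <- dose_delta(d, g, a, "D1%", percent_ref = 6000)
  expect_equal(dp$percent, 100 * 500 / 6000)
})

test_that("default constraint table reproduces the clinical defaults", {
  tb <- default_oar_table()
  expect_equal(nrow(tb), 13L)
  expect_equal(tb$tolerance_cGy[tb$organ == "brainstem"], 5400)
  expect_identical(tb$metric[tb$organ == "brainstem"], "D5%")
  expect_equal(tb$tolerance_cGy[tb$organ == "lens_l"], 600)
  expect_equal(tb$tolerance_cGy[tb$organ == "optic_chiasm"], 5400)
  expect_equal(tb$tolerance_cGy[tb$organ == "orbit_r"], 4500)
  expect_equal(tb$tolerance_cGy[tb$organ == "lacrimal_l"], 3000)
  expect_identical(tb$metric[tb$organ == "pituitary"], "Dmax")
  expect_identical(tb$metric[tb$organ == "cochlea_r"], "D50%")
  expect_setequal(tb$organ[tb$tier == "first_order"],
                  c("brainstem", "optic_chiasm", "optic_nerve_l",
                    "optic_nerve_r", "orbit_l", "orbit_r"))
  expect_setequal(tb$organ[tb$tier == "second_order_mean_like"],
                  c("cochlea_l", "cochlea_r"))
})
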