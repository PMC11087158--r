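test_that("headroom is tolerance minus gold dose, negatives allowed", {
  expect_equal(headroom(5000, 5400), 400)
  expect_equal(headroom(5400, 5400), 0)
  expect_equal(headroom(3200, 3000), -200)
  expect_error(headroom(1000, 0), "> 0")
})

test_that("compute_threshold: worked examples and negative-headroom exclusion", {
  avg <- compute_threshold(c(5000, 5200), 5400, "average_headroom")
  expect_equal(avg$threshold_cGy, 150)  # 0.5 * mean(c(400, 200))
  expect_false(avg$excluded)
  wc <- compute_threshold(c(5000, 5200), 5400, "worst_case_headroom")
  expect_equal(wc$threshold_cGy, 100)   # 0.5 * min
  neg <- compute_threshold(5600, 5400, "average_headroom")
  expect_true(neg$excluded)
  expect_identical(neg$excluded_reason, "negative headroom")
  expect_error(compute_threshold(numeric(0), 5400), "at least one")
})

test_that("average-mode threshold >= worst-case threshold on the same input", {
  set.seed(14)
  for (i in 1:20) {
    doses <- runif(sample(2:10, 1), 2000, 5300)
    a <- compute_threshold(doses, 5400, "average_headroom")$threshold_cGy
    w <- compute_threshold(doses, 5400, "worst_case_headroom")$threshold_cGy
    expect_gte(a, w)
  }
})

test_that("classify_case uses strict inequality in either direction", {
  thr <- compute_threshold(c(5000, 5200), 5400, "average_headroom") # 150 cGy
  expect_true(classify_case(180, thr))
  expect_false(classify_case(150, thr))   # tie -> not flagged
  expect_true(classify_case(-180, thr))   # either direction
  expect_true(is.na(classify_case(NA_real_, thr)))
  neg <- compute_threshold(5600, 5400, "average_headroom")
  expect_error(classify_case(100, neg), "excluded")
})

test_that("tier routing follows the organ tiers", {
  tb <- default_oar_table()
  expect_identical(tier_route(tb[tb$organ == "brainstem", ]),
                   "average_headroom")
  expect_identical(tier_route(tb[tb$organ == "cochlea_l", ]),
                   "worst_case_headroom")
  expect_identical(tier_route(tb[tb$organ == "lens_r", ]), "excluded")
  expect_error(tier_route("zeroth_order"), "unknown")
})

test_that("flag count is monotone non-increasing in threshold", {
  set.seed(21)
  deltas <- rnorm(40, 0, 300)
  counts <- vapply(seq(10, 900, by = 50), function(thr) {
    t_obj <- structure(list(threshold_cGy = thr, mode = "average_headroom",
                            n_cases_used = 40L, excluded = FALSE,
                            excluded_reason = NA_character_),
                       class = "significance_threshold")
    sum(classify_case(deltas, t_obj))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

# build a per-case table directly (units: cGy)
mk_per_case <- function(organ, proto, gold, delta, model = "m",
                        ids = sprintf("case%03d", seq_along(gold))) {
  data.frame(case_id = ids, protocol = proto, model = model, organ = organ,
             gold_cGy = gold, delta_cGy = delta,
             status = ifelse(is.na(delta), "failed", "ok"),
             stringsAsFactors = FALSE)
}

test_that("significance_report: exact flag recovery and protocol separation", {
  tb <- default_oar_table()
  # brainstem (average mode): protocol A threshold = 0.5*mean(400,200) = 150
  pa <- mk_per_case("brainstem", "A", gold = c(5000, 5200),
                    delta = c(200, -100))
  # protocol B gold doses differ: threshold = 0.5*mean(1000,800) = 450
  pb <- mk_per_case("brainstem", "B", gold = c(4400, 4600),
                    delta = c(500, 440), ids = c("case101", "case102"))
  rep <- significance_report(rbind(pa, pb), tb)
  ra <- rep[rep$protocol == "A", ]; rb <- rep[rep$protocol == "B", ]
  expect_equal(ra$threshold_cGy, 150)
  expect_equal(rb$threshold_cGy, 450)            # protocols never pooled
  expect_equal(ra$n_flagged, 1L)
  expect_identical(ra$flagged_case_ids, "case001")
  expect_equal(rb$n_flagged, 1L)
  expect_identical(rb$flagged_case_ids, "case101")
  expect_equal(ra$mean_abs_flagged_delta_cGy, 200)
  expect_equal(ra$mean_signed_flagged_delta_cGy, 200)
})

test_that("significance_report: tiers, exclusions and failed cases", {
  tb <- default_oar_table()
  pc <- rbind(
    mk_per_case("cochlea_l", "A", gold = c(3500, 4300), delta = c(120, 90)),
    mk_per_case("lens_l", "A", gold = c(500, 550), delta = c(400, 400)),
    mk_per_case("optic_chiasm", "A", gold = c(5600, 5700), delta = c(50, 60)),
    mk_per_case("orbit_l", "A", gold = c(4000, 4100), delta = c(300, NA)))
  rep <- significance_report(pc, tb)
  coch <- rep[rep$organ == "cochlea_l", ]
  expect_identical(coch$mode, "worst_case_headroom")
  expect_equal(coch$threshold_cGy, 0.5 * (4500 - 4300)) # least headroom case
  expect_equal(coch$n_flagged, 1L)                      # only |120| > 100
  lens <- rep[rep$organ == "lens_l", ]
  expect_identical(lens$excluded_reason, "tier-excluded")
  expect_true(is.na(lens$n_flagged))
  chiasm <- rep[rep$organ == "optic_chiasm", ]
  expect_identical(chiasm$excluded_reason, "negative headroom")
  orb <- rep[rep$organ == "orbit_l", ]
  expect_equal(orb$n_cases_used, 2L)   # gold doses of failed cases count
  expect_equal(orb$n_flagged, 1L)      # NA delta cannot be flagged
})

test_that("mean-like T/2 switch halves the effective cochlea threshold", {
  tb <- default_oar_table()
  pc <- mk_per_case("cochlea_l", "A", gold = c(3500, 4300), delta = c(60, 90))
  # threshold 100; |60|,|90| < 100 -> none flagged under T
  expect_equal(significance_report(pc, tb, "T")$n_flagged, 0L)
  # under T/2 the effective cut is 50 -> both flagged
  expect_equal(significance_report(pc, tb, "T/2")$n_flagged, 2L)
})
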