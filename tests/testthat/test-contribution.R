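test_that("AQ reproduces the printed reference quotients", {
  cipro <- aq_in_vivo(c(1.63, 1.85, 2.18))
  expect_equal(round(cipro$aq_bcrp, 2), 0.09)
  expect_true(cipro$estimable)
  topo <- aq_in_vivo(c(3.18, 5.18, 3.68))
  expect_equal(round(topo$aq_bcrp, 2), 0.35)
  eq <- aq_in_vivo(c(2, 2, 2))
  expect_equal(c(eq$aq_bcrp, eq$aq_pgp), c(0, 0))
})

test_that("a knockout that lowers ka makes AQ not estimable but reported", {
  sulfa <- aq_in_vivo(c(1.40, 0.49, 0.93))
  expect_false(sulfa$estimable)
  expect_true(all(c("negative_delta_bcrp", "negative_delta_pgp",
                    "not_estimable") %in% sulfa$flags))
  expect_true(is.finite(sulfa$aq_bcrp))  # raw quotient still reported
})

test_that("R reproduces the printed contribution scores", {
  expected <- list(
    ciprofloxacin = list(in_ = c(0.47, 0.51, 0.75), r = c(0.05, 0.36)),
    nitrofurantoin = list(in_ = c(0.64, 0.77, 0.75), r = c(0.15, 0.13)),
    topotecan = list(in_ = c(0.57, 1.03, 0.64), r = c(0.42, 0.06)),
    sulfasalazine = list(in_ = c(0.16, 1.30, 0.30), r = c(0.79, 0.09)))
  for (nm in names(expected)) {
    out <- r_contribution(expected[[nm]]$in_)
    expect_lte(abs(out$r_bcrp - expected[[nm]]$r[1]), 0.0105)
    expect_lte(abs(out$r_pgp - expected[[nm]]$r[2]), 0.0105)
  }
  flat <- r_contribution(c(0.5, 0.5, 0.5))
  expect_equal(c(flat$r_bcrp, flat$r_pgp), c(0, 0))
})

test_that("scores partition unity and respond monotonically", {
  set.seed(8)
  for (i in 1:50) {
    wt <- runif(1, 0.05, 1)
    trip <- c(wt, wt + runif(1, 0, 1), wt + runif(1, 0, 1))
    out <- r_contribution(trip)
    # normalization: R_bcrp + R_pgp + wt/D = 1 exactly
    expect_equal(out$r_bcrp + out$r_pgp + trip[1] / out$denominator, 1)
    # scale invariance
    s <- runif(1, 0.2, 5)
    out_s <- r_contribution(s * trip)
    expect_equal(out_s$r_bcrp, out$r_bcrp, tolerance = 1e-12)
    # monotonicity in the Bcrp arm
    up <- r_contribution(trip + c(0, 0.05, 0))
    expect_gt(up$r_bcrp, out$r_bcrp)
  }
})

test_that("zero denominator is flagged not estimable", {
  out <- r_contribution(c(0.5, 0.1, 0.1))
  expect_false(out$estimable)
  # wt + deltas = 0.5 - 0.4 - 0.4 < 0
  expect_true("zero_denominator" %in% out$flags)
  expect_true(is.na(out$r_bcrp))
})

test_that("quadrant classification applies a closed 0.4 criterion", {
  expect_equal(classify_quadrant(0.61, 0.42), "T_pos")
  expect_equal(classify_quadrant(0.03, 0.05), "T_neg")
  expect_equal(classify_quadrant(0.6, 0.1), "F_pos")
  expect_equal(classify_quadrant(0.1, 0.6), "F_neg")
  expect_equal(classify_quadrant(0.4, 0.4), "T_pos")   # boundary closed
  expect_error(classify_quadrant(NA_real_, 0.5), "not estimable")
  expect_error(classify_quadrant(0.5, 0.5, threshold = 1.2), "threshold")
})

test_that("contribution_table renders not-estimable cells as dashes", {
  ka <- read_fixture("ka_triplets.csv")
  fa <- read_fixture("fafg_triplets.csv")
  tab <- contribution_table(ka_triplets = ka, fafg_triplets = fa)
  expect_equal(tab$aq_display_bcrp[tab$compound == "sulfasalazine"], "-")
  expect_equal(tab$aq_display_bcrp[tab$compound == "topotecan"], "0.35")
  expect_equal(tab$r_display_bcrp[tab$compound == "sulfasalazine"], "0.79")
})

test_that("ivivc_table joins scores and classifies per transporter", {
  tab <- ivivc_table(read_fixture("invitro_aq.csv"),
                     read_fixture("invivo_scores.csv"))
  expect_equal(nrow(tab), 8)
  topo_bcrp <- tab[tab$compound == "topotecan" & tab$transporter == "BCRP", ]
  expect_equal(topo_bcrp$quadrant, "T_pos")
})
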