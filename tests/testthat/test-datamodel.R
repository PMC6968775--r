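test_that("read_study groups, sorts and averages rows into profiles", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(
    compound = "drugA", genotype = "WT", route = "oral", site = "systemic",
    time_h = c(0.17, 0.083, 0.5, 1, 2, 4, 8),
    conc_nM = c(20, 10, 30, 25, 12, 5, 1), dose_mg_per_kg = 1)
  write.csv(df, f, row.names = FALSE)
  study <- read_study(f)
  expect_length(study, 1)
  p <- study[[1]]
  expect_s3_class(p, "conc_profile")
  expect_equal(p$times, sort(df$time_h))
  expect_equal(p$concs[1], 10)  # sorted by time

  # two sites under oral become two profiles sharing compound/genotype
  df2 <- rbind(df, transform(df, site = "portal", conc_nM = conc_nM * 2))
  write.csv(df2, f, row.names = FALSE)
  study2 <- read_study(f)
  expect_length(study2, 2)
  expect_setequal(vapply(study2, `[[`, character(1), "site"),
                  c("systemic", "portal"))

  # replicate rows at one time are arithmetically averaged
  df3 <- rbind(df, df)
  df3$conc_nM[1:7] <- df$conc_nM + 2
  write.csv(df3, f, row.names = FALSE)
  p3 <- read_study(f)[[1]]
  expect_equal(p3$concs, df$conc_nM[order(df$time_h)] + 1)
})

test_that("read_study rejects schema and enum violations with clear errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(
    compound = "drugA", genotype = "WT", route = "oral", site = "plasma",
    time_h = 1:3, conc_nM = 3:1, dose_mg_per_kg = 1)
  write.csv(df, f, row.names = FALSE)
  expect_error(read_study(f), "plasma")

  write.csv(df[setdiff(names(df), "conc_nM")], f, row.names = FALSE)
  expect_error(read_study(f), "conc_nM")
})

test_that("study tables round-trip through write_study to full precision", {
  st <- simulate_study(n_animals = 1, cv_noise = 0.2, seed = 7)
  f <- withr::local_tempfile(fileext = ".csv")
  write_study(st, f)
  back <- read_study(f)
  orig <- profiles_from_table(st)
  expect_setequal(names(back), names(orig))
  for (nm in names(orig)) {
    expect_equal(back[[nm]]$times, orig[[nm]]$times)
    expect_equal(back[[nm]]$concs, orig[[nm]]$concs)
  }
})

test_that("conc_profile enforces its invariants", {
  expect_error(conc_profile("d", "WT", "oral", "systemic",
                            c(1, 1, 2), c(1, 2, 3), 1), "increasing")
  expect_error(conc_profile("d", "WT", "oral", "systemic",
                            c(1, 2), c(1, 2), 1), "3 time points")
  expect_error(conc_profile("d", "WT", "oral", "systemic",
                            1:3, c(1, -2, 3), 1), ">= 0")
  expect_error(conc_profile("d", "WT", "oral", "systemic",
                            1:3, 1:3, 0), "dose")
  p <- conc_profile("d", "WT", "iv", "portal", 1:3, 3:1, 1)
  expect_true(p$flag_iv_portal)
})

test_that("dose conversion is exact and linear in dose, inverse in MW", {
  expect_equal(dose_to_nmol_per_kg(1, 331.34), 1e6 / 331.34)
  expect_equal(round(dose_to_nmol_per_kg(1, 331.34)), 3018)
  expect_equal(round(dose_to_nmol_per_kg(1, 457.9)), 2184)
  expect_equal(dose_to_nmol_per_kg(5, 1e6), 5)
  expect_error(dose_to_nmol_per_kg(0, 100))
  expect_error(dose_to_nmol_per_kg(1, -5))
  set.seed(1)
  for (i in 1:20) {
    d <- runif(1, 0.1, 10); mw <- runif(1, 100, 900); a <- runif(1, 0.5, 4)
    expect_equal(dose_to_nmol_per_kg(a * d, mw),
                 a * dose_to_nmol_per_kg(d, mw))
    expect_equal(dose_to_nmol_per_kg(d, a * mw),
                 dose_to_nmol_per_kg(d, mw) / a)
  }
})

test_that("portal flow converts from mL/min/kg to L/h/kg", {
  expect_equal(qpv_to_L_per_h_per_kg(106.6), 6.396)
  expect_equal(qpv_to_L_per_h_per_kg(1000 / 60), 1.0)
  expect_error(qpv_to_L_per_h_per_kg(0))
})
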