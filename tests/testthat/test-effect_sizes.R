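make_record <- function(mu, su, nu, mn, sn, nn) {
  data.frame(record_id = "r1", study_id = "s1", population_pair_id = "p1",
             species = "Parus major", trait = "clutch_size", season = "2001",
             n_seasons = 1, mean_urban = mu, sd_urban = su, n_urban = nu,
             mean_nonurban = mn, sd_nonurban = sn, n_nonurban = nn,
             lat_urban = NA, lon_urban = NA, lat_nonurban = NA,
             lon_nonurban = NA, publication_year = 2010,
             stringsAsFactors = FALSE)
}

test_that("lnRR matches its defining formula and identities", {
  expect_equal(compute_lnRR(make_record(5, 1, 20, 5, 2, 30))$yi, 0)
  expect_equal(compute_lnRR(make_record(exp(1) * 4, 1, 20, 4, 1, 20))$yi, 1)
  es <- compute_lnRR(make_record(10, 2, 50, 12, 3, 40))
  expect_equal(es$yi, -0.182321556794, tolerance = 1e-10)
  expect_equal(es$vi, 0.0023625, tolerance = 1e-12)
  expect_error(compute_lnRR(make_record(-1, 1, 10, 5, 1, 10)), "non-positive mean")
})

test_that("lnCVR includes the small-sample corrections and stated variance", {
  expect_equal(compute_lnCVR(make_record(7, 1.4, 25, 7, 1.4, 25))$yi, 0)
  # CV ratio of 2 with equal n: corrections cancel
  expect_equal(compute_lnCVR(make_record(10, 4, 30, 10, 2, 30))$yi, log(2))
  es <- compute_lnCVR(make_record(10, 2, 50, 10, 1, 50))
  expect_equal(es$vi, 0.04 / 50 + 1 / 98 + 0.01 / 50 + 1 / 98, tolerance = 1e-12)
  expect_error(compute_lnCVR(make_record(10, 2, 1, 10, 1, 50)), "n < 2")
})

test_that("lnVR matches its defining formula", {
  expect_equal(compute_lnVR(make_record(9, 2, 30, 11, 2, 30))$yi, 0)
  expect_equal(compute_lnVR(make_record(5, 1, 51, 6, 1, 51))$vi, 0.02)
  es <- compute_lnVR(make_record(10, 3, 21, 10, 2, 11))
  expect_equal(es$yi, 0.380465108108, tolerance = 1e-10)
  expect_equal(es$vi, 0.075, tolerance = 1e-12)
})

test_that("SMDH applies the heteroscedastic variance and bias correction", {
  expect_equal(compute_SMDH(make_record(8, 2, 30, 8, 4, 25))$yi, 0)
  es <- compute_SMDH(make_record(12, 2, 30, 10, 4, 25))
  expect_equal(es$yi, 0.623456141019, tolerance = 1e-9)
  expect_equal(es$vi, 0.0859104715279, tolerance = 1e-9)
  # swapping arms negates yi, keeps vi
  sw <- compute_SMDH(make_record(10, 4, 25, 12, 2, 30))
  expect_equal(sw$yi, -es$yi)
  expect_equal(sw$vi, es$vi)
})

test_that("effect sizes agree with metafor::escalc across random records", {
  skip_if_not_installed("metafor")
  set.seed(42)
  for (i in 1:20) {
    mu <- runif(1, 2, 150); mn <- runif(1, 2, 150)
    su <- runif(1, 0.2, 15); sn <- runif(1, 0.2, 15)
    nu <- sample(3:80, 1); nn <- sample(3:80, 1)
    rec <- make_record(mu, su, nu, mn, sn, nn)
    for (pair in list(c("lnRR", "ROM"), c("lnCVR", "CVR"),
                      c("lnVR", "VR"), c("SMDH", "SMDH"))) {
      mine <- compute_effect_sizes(rec, pair[1])
      ref <- metafor::escalc(pair[2], m1i = mu, sd1i = su, n1i = nu,
                             m2i = mn, sd2i = sn, n2i = nn)
      expect_equal(mine$yi, as.numeric(ref$yi), tolerance = 1e-9,
                   label = pair[1])
      expect_equal(mine$vi, as.numeric(ref$vi), tolerance = 1e-9,
                   label = pair[1])
    }
  }
})

test_that("scale invariance and antisymmetry hold across random records", {
  set.seed(99)
  for (i in 1:25) {
    mu <- runif(1, 1, 100); mn <- runif(1, 1, 100)
    su <- runif(1, 0.1, 10); sn <- runif(1, 0.1, 10)
    n <- sample(5:60, 1)
    rec <- make_record(mu, su, n, mn, sn, n)
    c_ <- runif(1, 0.1, 8)
    scaled <- make_record(c_ * mu, c_ * su, n, c_ * mn, c_ * sn, n)
    # lnCVR and SMDH invariant to common rescaling; lnRR/lnVR too
    # (ratios cancel when both arms are rescaled)
    for (ms in c("lnRR", "lnCVR", "lnVR", "SMDH")) {
      expect_equal(compute_effect_sizes(scaled, ms)$yi,
                   compute_effect_sizes(rec, ms)$yi, tolerance = 1e-10)
    }
    # equal-n arm swap negates lnRR exactly, lnCVR and lnVR too
    sw <- make_record(mn, sn, n, mu, su, n)
    for (ms in c("lnRR", "lnCVR", "lnVR")) {
      expect_equal(compute_effect_sizes(sw, ms)$yi,
                   -compute_effect_sizes(rec, ms)$yi, tolerance = 1e-10)
    }
    # vi positive for all valid records
    for (ms in c("lnRR", "lnCVR", "lnVR", "SMDH")) {
      expect_gt(compute_effect_sizes(rec, ms)$vi, 0)
    }
  }
})

test_that("sampling variance vanishes as both arms grow at fixed CV", {
  small <- compute_lnCVR(make_record(10, 2, 10, 12, 3, 10))
  big <- compute_lnCVR(make_record(10, 2, 1e6, 12, 3, 1e6))
  expect_lt(big$vi, small$vi / 1e4)
})

test_that("arm rows carry lnSD, lnMean and 1/(2(n-1)) variances", {
  rec <- make_record(10, 4.2, 18, 8, 1, 2)
  rows <- arm_rows(rec)
  expect_equal(nrow(rows), 2)
  expect_equal(rows$habitat, c("urban", "nonurban"))
  expect_equal(rows$ln_sd[1], 1.43508452529, tolerance = 1e-10)
  expect_equal(rows$v_ln_sd[1], 1 / 34, tolerance = 1e-12)
  expect_equal(rows$ln_sd[2], 0)  # sd = 1
  expect_equal(rows$v_ln_sd[2], 0.5)  # n = 2
})

test_that("percent difference back-transforms magnitudes with sign alongside", {
  expect_equal(round(percent_difference(0.176)$percent, 1), 19.2)
  expect_equal(round(percent_difference(0.043)$percent, 1), 4.4)
  expect_equal(percent_difference(0)$percent, 0)
  neg <- percent_difference(-0.035)
  expect_equal(round(neg$percent, 1), 3.6)
  expect_equal(neg$direction, -1)
})

test_that("effective sample size is the two-group harmonic form", {
  expect_equal(effective_sample_size(50, 50), 100)
  expect_equal(effective_sample_size(10, 40), 32)
})
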