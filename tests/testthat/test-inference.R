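test_that("size regressions separate the allometric and relative indices", {
  pop <- cubic_population(g = 0.28)
  rt <- rate_table(pop, window = 2:5)
  # constant responses make lm warn about a perfect fit; that is the point
  fits <- suppressWarnings(size_dependence(rt, days = c(2, 3)))
  alo <- fits[fits$measure == "allometric", ]
  expect_true(all(abs(alo$slope) < 1e-10))     # flat to machine precision
  rel <- fits[fits$measure == "relative", ]
  expect_true(all(rel$slope < 0))
  abs_ <- fits[fits$measure == "absolute", ]
  expect_true(all(abs_$slope > 0))             # bigger larvae gain more mg/day
})

test_that("size regressions refuse underdetermined cells", {
  pop <- cubic_population(c0s = c(2.5, 3.0), g = 0.28)  # one larva per sex
  rt <- rate_table(pop, window = 2:3)
  expect_error(size_dependence(rt), "fewer than 3 points")
})

test_that("mixed descriptor ANOVA equals the fixed-effects oracle when brood variance is zero", {
  feats <- balanced_features(n_broods = 8, seed = 303)
  res <- feature_anova(feats, "y")
  oracle <- type3_F_oracle(y ~ sex + host, feats, c("sex", "host"))
  expect_equal(res$F, oracle, tolerance = 1e-8)
  expect_equal(res$term, c("sex", "host"))
  expect_equal(res$ddf, rep(nrow(feats) - 3, 2))
  expect_true(all(res$R2 >= 0 & res$R2 <= 1))
})

test_that("repeated-measures ANOVA equals its fixed-effects oracle under zero variance components", {
  recs <- balanced_records(seed = 404)
  res <- repeated_anova(recs)
  dat <- data.frame(value = recs$value,
                    sex = factor(recs$sex), host = factor(recs$host),
                    day_c = recs$day - mean(recs$day))
  oracle <- type3_F_oracle(value ~ sex + day_c + host + sex:day_c + sex:host,
                           dat, c("sex", "host"))
  expect_equal(res$F, oracle, tolerance = 1e-8)
})

test_that("denominator df come from larvae, not measurements", {
  recs <- balanced_records(n_broods = 6, per_brood = 4, days = 2:5)
  res <- repeated_anova(recs)
  n_larvae <- 24; n_obs <- 96
  expect_equal(res$ddf[res$term == "sex"], n_larvae - 4)
  expect_equal(res$ddf[res$term == "sex:host"], n_larvae - 4)
  expect_equal(res$ddf[res$term == "day"], n_obs - n_larvae - 2)
  expect_equal(res$ddf[res$term == "sex:day"], n_obs - n_larvae - 2)
})

test_that("the published ddf pattern is reproduced at 1275 larvae", {
  # 85 broods x (12 + 3) = 1275 larvae with complete day 2-5 records
  pop <- simulate_population(sim_params(n_broods = 85, seed = 19))
  rt <- rate_table(pop, measures = "allometric")
  res <- repeated_anova(rt)
  expect_equal(res$ddf[res$term == "sex"], 1271)
  expect_equal(res$ddf[res$term == "day"], 4 * 1275 - 1275 - 2)
})

test_that("degenerate layouts are rejected with informative errors", {
  feats <- balanced_features()
  feats$host <- "host1"
  expect_error(feature_anova(feats, "y"), "host")
  feats2 <- balanced_features()
  feats2$brood_id <- "b01"
  expect_error(feature_anova(feats2, "y"), "broods")
  expect_error(feature_anova(balanced_features(), "nope"), "column")

  recs <- balanced_records()
  expect_error(repeated_anova(recs[recs$day == 2, ]), "single day")
})

test_that("the method-of-moments fallback approximates the REML route", {
  set.seed(515)
  a <- 20; k <- 8
  dat <- data.frame(sex = rep(c("F", "M"), a * k / 2),
                    host = rep(c("host1", "host2"), each = k / 2),
                    brood_id = rep(sprintf("b%02d", 1:a), each = k))
  dat$y <- 50 + 3 * (dat$sex == "F") + rep(rnorm(a, 0, 2), each = k) +
    rnorm(a * k, 0, 2)
  reml <- feature_anova(dat, "y", method = "reml")
  mom <- feature_anova(dat, "y", method = "moments")
  expect_identical(attr(mom, "method"), "moments")
  expect_identical(attr(reml, "method"), "reml")
  fr <- reml$F[reml$term == "sex"]
  fm <- mom$F[mom$term == "sex"]
  expect_lt(abs(fm - fr) / fr, 0.2)
  expect_lt(mom$p[mom$term == "sex"], 0.01)
  vc <- attr(mom, "varcomp")
  expect_gt(vc[["brood"]], 0)
})

test_that("day-2 size regressions on noisy simulations keep the Fig-2 contrast", {
  # day 2 is the clean case: its covariate (the day-0 initial mass) shares no
  # generative component with the day-2 increment
  pop <- simulate_population(sim_params(n_broods = 400, seed = 83))
  rt <- rate_table(pop, window = 2:2, measures = c("allometric", "relative"))
  fits <- size_dependence(rt, days = 2)
  a2 <- fits[fits$measure == "allometric", ]
  expect_true(all(abs(a2$slope) < 2.6 * a2$slope_se))      # 99% CI covers zero
  rel <- fits[fits$measure == "relative", ]
  expect_true(all(rel$slope + 1.96 * rel$slope_se < 0))    # clearly negative
})
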