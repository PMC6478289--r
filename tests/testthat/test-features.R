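hand_trajectory <- function() {
  trajectory("L1", "b1", "host1", "F", 18, 25, c(30, 40, 55, 70, 80, 78, 60),
             final_larval_mass = 60, pupal_mass = 50)
}

test_that("descriptors match hand computation on a worked record", {
  f <- extract_features(hand_trajectory())
  expect_equal(f$maximal_mass, 80)
  expect_equal(f$time_to_max, 5)
  expect_equal(f$abs_increment_day_3, 15)   # 55 - 40
  expect_equal(f$abs_increment_day_2, 10)
  expect_equal(f$abs_increment_day_7, -18)
  expect_true(is.na(f$abs_increment_day_8)) # record ended on day 7
  expect_equal(f$ratio_max_final, 80 / 60)
  expect_equal(f$ratio_pupa_initial, 2.0)
  expect_equal(f$ratio_max_initial, 80 / 25)
})

test_that("tie and ordering rules for the mass peak", {
  flat <- extract_features(trajectory("L2", "b1", "host1", "M", 17, 20,
                                      rep(30, 4), final_larval_mass = 30,
                                      pupal_mass = 20))
  expect_equal(flat$time_to_max, 1)   # earliest attainment among equal days
  expect_true(all(unlist(flat[paste0("abs_increment_day_", 2:4)]) == 0))

  # never exceeding the day-0 initial mass puts the peak at day 0
  sinking <- extract_features(trajectory("L3", "b1", "host1", "M", 17, 50,
                                         c(50, 40, 30), final_larval_mass = 30,
                                         pupal_mass = 15))
  expect_equal(sinking$maximal_mass, 50)
  expect_equal(sinking$time_to_max, 0)
})

test_that("feature extraction is pure and order-invariant in summaries", {
  pop <- simulate_population(sim_params(n_broods = 5, seed = 41))
  f1 <- extract_features(pop)
  f2 <- extract_features(pop)
  expect_identical(f1, f2)
  s1 <- summarize_by_sex(f1)
  s2 <- summarize_by_sex(f1[sample.int(nrow(f1)), ])
  expect_equal(s1, s2)
})

test_that("per-sex summaries give mean and sd/sqrt(n)", {
  f <- dplyr::bind_rows(
    extract_features(trajectory("a", "b1", "host1", "F", 18, 25, c(30, 70),
                                final_larval_mass = 70, pupal_mass = 70)),
    extract_features(trajectory("b", "b1", "host1", "F", 18, 25, c(30, 80),
                                final_larval_mass = 80, pupal_mass = 80)),
    extract_features(trajectory("c", "b1", "host1", "M", 18, 25, c(30, 60),
                                final_larval_mass = 60, pupal_mass = 55)),
    extract_features(trajectory("d", "b1", "host1", "M", 18, 25, c(30, 60),
                                final_larval_mass = 60, pupal_mass = 55)))
  s <- summarize_by_sex(f)
  pupaF <- s[s$variable == "pupal_mass" & s$sex == "F", ]
  expect_equal(pupaF$mean, 75)
  expect_equal(pupaF$se, 5)            # sd sqrt(50), n = 2
  pupaM <- s[s$variable == "pupal_mass" & s$sex == "M", ]
  expect_equal(pupaM$se, 0)            # identical rows
  expect_error(summarize_by_sex(f[f$sex == "F", ]), "no rows for sex M")
})

test_that("SSD ratio and dimorphism index behave as published arithmetic", {
  expect_equal(round(ssd_ratio(73.57, 63.28), 2), 1.16)
  expect_equal(round(ssd_ratio(120.24, 98.91), 2), 1.22)
  expect_equal(round(ssd_ratio(29.18, 25.30), 2), 1.15)
  expect_equal(round(sdi(ssd_ratio(73.57, 63.28)), 2), 0.16)
  expect_equal(ssd_ratio(42, 42), 1.0)
  expect_equal(sdi(1.0), 0.0)
  expect_error(ssd_ratio(-1, 2), "positive")
  expect_error(ssd_ratio(1, 0), "positive")
})

test_that("default simulations reproduce the female-biased descriptor pattern", {
  pop <- simulate_population(sim_params(n_broods = 40, seed = 55))
  s <- summarize_by_sex(extract_features(pop))
  for (v in c("initial_mass", "maximal_mass", "pupal_mass", "time_to_instar5",
              "instar_duration", "time_to_max")) {
    mF <- s$mean[s$variable == v & s$sex == "F"]
    mM <- s$mean[s$variable == v & s$sex == "M"]
    expect_gt(mF, mM)
  }
})
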