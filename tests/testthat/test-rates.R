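test_that("the three rate indices agree with hand arithmetic", {
  expect_equal(absolute_rate(10, 22), 12)
  expect_equal(absolute_rate(7, 7), 0)
  expect_equal(relative_rate(10, 100), 1.0)
  expect_equal(relative_rate(7, 7), 0.0)
  expect_equal(relative_rate(50, 63.2), log10(1.264))
  expect_equal(allometric_rate(8, 27), 1.0)
  expect_equal(allometric_rate(7, 7), 0.0)
  expect_error(absolute_rate(-1, 5), "positive")
  expect_error(relative_rate(0, 5), "positive")
  expect_error(allometric_rate(5, -2), "positive")
})

test_that("rates interconvert exactly through (m_start, m_end)", {
  set.seed(8)
  m_start <- runif(50, 10, 80)
  m_end <- m_start * runif(50, 0.9, 1.6)
  abs_r <- absolute_rate(m_start, m_end)
  rel_r <- relative_rate(m_start, m_end)
  alo_r <- allometric_rate(m_start, m_end)
  # each index plus m_start recovers m_end, hence the others
  expect_equal(relative_rate(m_start, m_start + abs_r), rel_r)
  expect_equal(allometric_rate(m_start, m_start * 10^rel_r), alo_r)
  expect_equal(absolute_rate(m_start, (m_start^(1 / 3) + alo_r)^3), abs_r)
})

test_that("on exact cubic growth the allometric rate is the constant g", {
  g <- 0.28
  pop <- cubic_population(g = g)
  rt <- rate_table(pop, window = 2:5)
  alo <- rt[rt$measure == "allometric", ]
  expect_equal(alo$value, rep(g, nrow(alo)), tolerance = 1e-12)
  # and the relative rate strictly decreases with the size covariate
  rel <- rt[rt$measure == "relative", ]
  for (id in unique(rel$individual_id)) {
    v <- rel$value[rel$individual_id == id][order(rel$day[rel$individual_id == id])]
    expect_true(all(diff(v) < 0))
  }
})

test_that("rate_table yields one record per usable day and measure", {
  tr <- trajectory("L1", "b1", "host1", "F", 18, 25, c(35, 45, 60, 75, 90),
                   final_larval_mass = 90, pupal_mass = 60)
  rt <- rate_table(trajectory_table(list(tr)))
  expect_equal(nrow(rt), 4 * 3)     # days 2..5, three measures
  # day-2 covariate is the initial (day 0) mass
  expect_equal(unique(rt$covariate_mass[rt$day == 2]), 25)
  expect_equal(unique(rt$covariate_mass[rt$day == 4]), 45)

  gap <- trajectory("L2", "b1", "host1", "F", 18, 25, c(35, 45, 60, NA, 90),
                    final_larval_mass = 90, pupal_mass = 60)
  rtg <- rate_table(trajectory_table(list(gap)), measures = "allometric")
  # both the day-4 and day-5 increments need the missing day-4 mass
  expect_equal(sort(rtg$day), c(2, 3))

  expect_error(rate_table(trajectory_table(list(tr)), window = integer(0)),
               "empty")
})

test_that("integral growth rates match worked arithmetic and scale linearly", {
  f <- tibble::tibble(pupal_mass = 73.57, time_to_instar5 = 18.17,
                      instar_duration = 11.46)
  expect_equal(integral_rate(f, "pupa_over_total_time"), 73.57 / 29.63,
               tolerance = 1e-12)
  f2 <- tibble::tibble(pupal_mass = 63.28, time_to_instar5 = 17.58,
                       instar_duration = 10.10)
  expect_equal(integral_rate(f2, "pupa_over_instar_time"), 63.28 / 10.10)
  expect_equal(integral_rate(f2, "log_pupa_over_total_time"),
               log10(63.28) / 27.68)
  doubled <- dplyr::mutate(f, pupal_mass = pupal_mass * 2)
  for (v in c("pupa_over_total_time", "pupa_over_instar_time"))
    expect_equal(integral_rate(doubled, v), 2 * integral_rate(f, v))
  zero <- dplyr::mutate(f, instar_duration = 0, time_to_instar5 = 0)
  expect_error(integral_rate(zero, "pupa_over_instar_time"), "duration")
})

test_that("relative-rate summaries expose both daily-fold readings", {
  pop <- simulate_population(sim_params(n_broods = 10, seed = 61))
  sm <- summarize_rates(rate_table(pop, measures = "relative"))
  expect_true(all(is.finite(sm$fold_arith)))
  expect_true(all(sm$fold_arith >= sm$fold_geom))  # AM-GM
  expect_true(all(sm$fold_geom > 1))
  alo <- summarize_rates(rate_table(pop, measures = "allometric"))
  expect_true(all(is.na(alo$fold_arith)))
})

test_that("simulated mean allometric rates recover the generative values", {
  pop <- simulate_population(sim_params(n_broods = 45, seed = 71))
  sm <- summarize_rates(rate_table(pop, measures = "allometric"))
  for (sx in c("F", "M")) {
    row <- sm[sm$sex == sx, ]
    target <- if (sx == "F") 0.279 else 0.270
    expect_lt(abs(row$mean - target), 3 * row$se)
  }
})
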