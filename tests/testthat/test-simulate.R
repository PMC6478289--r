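test_that("noise-free simulator equals the closed-form cubic projection", {
  p <- cubic_params(g = 0.3, m0 = 27, n_days = 5)
  set.seed(1)
  tr <- simulate_trajectory(p, "F")
  expect_equal(tr$daily_masses, (3 + 0.3 * (1:5))^3)
  expect_equal(tr$daily_masses[5], 91.125)
  expect_equal(tr$initial_mass, 27)
  expect_equal(tr$final_larval_mass, tr$daily_masses[5])
})

test_that("with equal rates the sexes differ only through initial mass", {
  p <- cubic_params(g = 0.3, n_days = 5)
  p$mean_initial_mass_F <- 29.18
  p$mean_initial_mass_M <- 25.30
  set.seed(1)
  trF <- simulate_trajectory(p, "F")
  trM <- simulate_trajectory(p, "M")
  # identical cube-root increments, shifted starting points
  incF <- diff(c(trF$initial_mass, trF$daily_masses)^(1 / 3))
  incM <- diff(c(trM$initial_mass, trM$daily_masses)^(1 / 3))
  expect_equal(incF, incM)
  expect_equal(trF$initial_mass, 29.18)
  expect_equal(trM$initial_mass, 25.30)
})

test_that("the same seed reproduces a population bit for bit", {
  p <- sim_params(n_broods = 3, seed = 99)
  pop1 <- simulate_population(p)
  pop2 <- simulate_population(p)
  expect_identical(pop1$daily_masses, pop2$daily_masses)
  expect_identical(pop1$pupal_mass, pop2$pupal_mass)
  expect_identical(pop1$sex, pop2$sex)
})

test_that("population size follows the brood design", {
  pop <- simulate_population(sim_params(n_broods = 4, seed = 5))
  expect_equal(nrow(pop), 4 * (12 + 3))
  expect_equal(length(unique(pop$brood_id)), 4)
  expect_equal(as.vector(table(pop$host)[c("host1", "host2")]), c(48, 12))

  one <- simulate_population(sim_params(n_broods = 1, larvae_per_brood_host1 = 1,
                                        larvae_per_brood_host2 = 0,
                                        sex_ratio = 1, seed = 3))
  expect_equal(nrow(one), 1)
  expect_equal(one$sex, "F")

  expect_error(simulate_population(sim_params(larvae_per_brood_host1 = 0,
                                              larvae_per_brood_host2 = 0)),
               "zero larvae")
})

test_that("enlarging the design leaves earlier draws untouched", {
  base <- simulate_population(sim_params(n_broods = 2, seed = 17))
  more_broods <- simulate_population(sim_params(n_broods = 4, seed = 17))
  expect_identical(base$daily_masses, more_broods$daily_masses[seq_len(nrow(base))])
  expect_identical(base$sex, more_broods$sex[seq_len(nrow(base))])

  more_larvae <- simulate_population(sim_params(n_broods = 2,
                                                larvae_per_brood_host2 = 5,
                                                seed = 17))
  idx <- match(base$individual_id, more_larvae$individual_id)
  expect_identical(base$daily_masses, more_larvae$daily_masses[idx])
  expect_identical(base$pupal_mass, more_larvae$pupal_mass[idx])
})

test_that("every generated trajectory satisfies the growth-record invariants", {
  for (s in c(21, 22)) {
    pop <- simulate_population(sim_params(n_broods = 8, seed = s))
    expect_silent(validate_trajectory_table(pop))
    mx <- vapply(pop$daily_masses, max, numeric(1))
    expect_true(all(mx >= pop$initial_mass))
    expect_true(all(pop$pupal_mass <= mx))
    expect_true(all(pop$final_larval_mass <= mx))
    expect_true(all(unlist(pop$daily_masses) > 0))
    expect_true(all(lengths(pop$daily_masses) == pop$instar_duration))
  }
})

test_that("sample moments track the generative means", {
  pop <- simulate_population(sim_params(n_broods = 100, seed = 7))
  fem <- pop$initial_mass[pop$sex == "F"]
  se <- sd(fem) / sqrt(length(fem))
  expect_lt(abs(mean(fem) - 29.18), 3 * se)
  f <- extract_features(pop)
  ttmM <- f$time_to_max[f$sex == "M"]
  expect_lt(abs(mean(ttmM) - 8.67), 3 * sd(ttmM) / sqrt(length(ttmM)) + 0.5)
  # duration consistency (peak precedes cessation of feeding) right-shifts
  # durations slightly; the sex ordering must still hold
  expect_gt(mean(pop$instar_duration[pop$sex == "F"]),
            mean(pop$instar_duration[pop$sex == "M"]))
})

test_that("degenerate parameters fail loudly instead of looping", {
  p <- sim_params()
  set.seed(1)
  expect_error(simulate_trajectory(p, "F", brood_effect = -10),
               "degenerate")
})

test_that("dropout flags larvae without truncating their records", {
  pop <- simulate_population(sim_params(n_broods = 10, dropout_rate = 0.3,
                                        seed = 9))
  expect_true(any(pop$censored))
  expect_true(any(!pop$censored))
  expect_true(all(lengths(pop$daily_masses) == pop$instar_duration))
})
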