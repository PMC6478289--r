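# Shared fixtures and independent oracles, built in code.

# Degenerate noise-free parameters under which the simulator must reduce to
# the closed-form cubic projection m_d = (c0 + g * d)^3.
cubic_params <- function(g = 0.3, m0 = 27, n_days = 5) {
  sim_params(sd_time_to_instar5 = 0, sd_initial_cuberoot = 0,
             sd_rate_brood = 0, sd_rate_individual = 0, sd_rate_day = 0,
             sd_peak_day = 0, sd_instar_duration = 0, sd_pupa_lognoise = 0,
             gutfill_factor = 1, rate_F = g, rate_M = g,
             mean_initial_mass_F = m0, mean_initial_mass_M = m0,
             instar_duration_F = n_days, instar_duration_M = n_days,
             peak_day_F = n_days - 1, peak_day_M = n_days - 1,
             taper_start_F = Inf, taper_start_M = Inf,
             max_over_final_F = 1, max_over_final_M = 1)
}

# A trajectory table of exact cubic growers with a range of initial sizes and
# rates; no randomness.
cubic_population <- function(c0s = seq(2.5, 3.5, length.out = 11), g = 0.28,
                             n_days = 6) {
  trajs <- lapply(seq_along(c0s), function(i) {
    m <- (c0s[i] + g * seq_len(n_days))^3
    trajectory(individual_id = sprintf("c%02d", i),
               brood_id = sprintf("b%02d", (i - 1) %% 3 + 1),
               host = "host1", sex = if (i %% 2) "F" else "M",
               time_to_instar5 = 18, initial_mass = c0s[i]^3,
               daily_masses = m, final_larval_mass = m[n_days],
               pupal_mass = m[n_days] / 1.6)
  })
  trajectory_table(trajs)
}

# Independent Type III fixed-effects ANOVA oracle: F statistics by direct
# residual-sum-of-squares comparison (full vs term-deleted projections),
# never via the package's Wald machinery.
type3_F_oracle <- function(formula, dat, factor_vars) {
  contr <- stats::setNames(lapply(factor_vars, function(.) stats::contr.sum),
                           factor_vars)
  X <- stats::model.matrix(formula, dat, contrasts.arg = contr)
  asn <- attr(X, "assign")
  labels <- attr(stats::terms(formula), "term.labels")
  y <- stats::model.response(stats::model.frame(formula, dat))
  rss <- function(M) sum(stats::lm.fit(M, y)$residuals^2)
  rss_full <- rss(X)
  df_res <- nrow(X) - ncol(X)
  vapply(seq_along(labels), function(j) {
    Xr <- X[, asn != j, drop = FALSE]
    q <- sum(asn == j)
    ((rss(Xr) - rss_full) / q) / (rss_full / df_res)
  }, numeric(1))
}

# Balanced two-sex, two-host, multi-brood feature table with *no* brood
# variance (pure residual noise), for oracle-equivalence checks.
balanced_features <- function(n_broods = 8, seed = 101, sex_eff = 2,
                              host_eff = 1, sigma = 1) {
  set.seed(seed)
  grid <- expand.grid(sex = c("F", "M"), host = c("host1", "host2"),
                      rep = 1:2, brood_id = sprintf("b%02d", 1:n_broods),
                      stringsAsFactors = FALSE)
  e <- rnorm(nrow(grid), 0, sigma)
  e <- e - stats::ave(e, grid$brood_id)   # realized brood variance exactly 0
  grid$y <- 50 + sex_eff * (grid$sex == "F") + host_eff * (grid$host == "host2") + e
  grid
}

# Balanced repeated-measures rate records with no brood and no individual
# variance: day-level noise only.
balanced_records <- function(n_broods = 6, per_brood = 4, days = 2:5,
                             seed = 202, sex_eff = 0.01, sigma = 0.05) {
  set.seed(seed)
  rows <- list()
  k <- 0
  for (b in 1:n_broods) {
    for (i in 1:per_brood) {
      k <- k + 1
      sex <- if (i %% 2) "F" else "M"
      host <- if (i <= per_brood / 2) "host1" else "host2"
      id <- sprintf("b%02d_i%02d", b, i)
      e <- rnorm(length(days), 0, sigma)
      e <- e - mean(e)    # realized individual (and hence brood) variance 0
      rows[[k]] <- tibble::tibble(
        individual_id = id, sex = sex, brood_id = sprintf("b%02d", b),
        host = host, day = days, measure = "allometric",
        value = 0.27 + sex_eff * (sex == "F") + e,
        covariate_mass = 40 + 5 * days)
    }
  }
  dplyr::bind_rows(rows)
}
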