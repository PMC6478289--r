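#' Simulate one larval growth trajectory
#'
#' Generates a last-instar growth record on the cube-root mass scale
#' `c = m^(1/3)`, on which free larval growth is linear: the day-0 value `c0`
#' is drawn around the sex mean, day 1 adds `g * gutfill_factor` (gut filling
#' inflates the first day's gain), free-growth days add `g_i + eps_d` where
#' `g_i` is the individual's rate (sex mean + host shift + brood effect +
#' individual effect) and `eps_d` is day-level noise, taper days multiply the
#' increment by a factor decaying linearly to zero just past the individual's
#' peak day, and post-peak masses decline geometrically to the final
#' (last feeding-day) mass `max / max_over_final`. Pupal mass is the maximal
#' recorded mass divided by `max_over_pupa`, with small multiplicative noise.
#'
#' @param params A [sim_params()] object.
#' @param sex `"F"` or `"M"`.
#' @param brood_effect Brood-level shift (mg^(1/3)/day) added to the rate.
#' @param host `"host1"` or `"host2"`.
#' @param rng_state Optional `.Random.seed` state (e.g. an L'Ecuyer-CMRG
#'   substream); when supplied, draws come from that stream and the caller's
#'   RNG state is left untouched.
#' @param individual_id,brood_id Identifiers stored in the result.
#' @return A [trajectory()] object.
#' @export
simulate_trajectory <- function(params, sex, brood_effect = 0, host = "host1",
                                rng_state = NULL,
                                individual_id = "ind1", brood_id = "brood1") {
  validate_sim_params(params)
  stopifnot(sex %in% c("F", "M"), host %in% c("host1", "host2"))
  if (!is.null(rng_state)) {
    old <- get0(".Random.seed", envir = globalenv())
    assign(".Random.seed", rng_state, envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
            add = TRUE)
  }
  sx <- function(stem) params[[paste0(stem, "_", sex)]]

  for (attempt in seq_len(100L)) {
    t5 <- stats::rnorm(1, sx("mean_time_to_instar5"), params$sd_time_to_instar5)
    c0 <- stats::rnorm(1, sx("mean_initial_mass")^(1 / 3), params$sd_initial_cuberoot)
    ind_eff <- stats::rnorm(1, 0, params$sd_rate_individual)
    dur_draw <- stats::rnorm(1, sx("instar_duration"), params$sd_instar_duration)
    peak_draw <- stats::rnorm(1, sx("peak_day"), params$sd_peak_day)
    g_i <- sx("rate") + params$host_effect_on_rate * (host == "host2") +
      brood_effect + ind_eff
    if (!all(is.finite(c(t5, c0, dur_draw, peak_draw, g_i))) ||
        t5 <= 0 || c0 <= 0 || g_i <= 0) next

    n_days <- max(1L, as.integer(round(dur_draw)))
    t_start <- sx("taper_start")
    taper_on <- is.finite(t_start) && t_start <= n_days && t_start >= 2
    if (taper_on) {
      peak <- max(as.integer(round(peak_draw)), as.integer(t_start))
      n_days <- max(n_days, peak + 1L)
    } else {
      peak <- n_days
    }

    grow_end <- peak
    cc <- numeric(n_days)
    cc[1] <- c0 + g_i * params$gutfill_factor
    if (grow_end >= 2) {
      eps <- stats::rnorm(grow_end - 1L, 0, params$sd_rate_day)
      inc <- g_i + eps
      if (taper_on) {
        d <- 2:grow_end
        fac <- ifelse(d >= t_start,
                      sx("taper_initial") * (peak + 1 - d) / (peak + 1 - t_start),
                      1)
        inc <- inc * fac
      }
      cc[2:grow_end] <- cc[1] + cumsum(inc)
    }
    if (any(!is.finite(cc[1:grow_end])) || any(cc[1:grow_end] <= 0)) next

    m <- cc^3
    if (peak < n_days) {
      r <- sx("max_over_final")^(-1 / (n_days - peak))
      m[(peak + 1):n_days] <- m[peak] * r^(seq_len(n_days - peak))
    }
    max_rec <- max(c0^3, m)
    pupa <- max_rec / sx("max_over_pupa") *
      exp(stats::rnorm(1, 0, params$sd_pupa_lognoise))
    pupa <- min(pupa, max_rec)
    censored <- params$dropout_rate > 0 &&
      stats::runif(1) < params$dropout_rate
    if (!all(is.finite(c(m, pupa)))) next

    return(trajectory(individual_id = individual_id, brood_id = brood_id,
                      host = host, sex = sex,
                      time_to_instar5 = t5, initial_mass = c0^3,
                      daily_masses = m, instar_duration = n_days,
                      final_larval_mass = m[n_days], pupal_mass = pupa,
                      censored = censored))
  }
  stop("simulate_trajectory: rejected 100 consecutive draws; ",
       "parameters are degenerate (check means vs. sd magnitudes)",
       call. = FALSE)
}

#' Simulate a population of larval growth trajectories
#'
#' Generates `n_broods` broods, each contributing
#' `larvae_per_brood_host1 + larvae_per_brood_host2` larvae (assigned to the
#' two host plants in that order), with one brood-level rate effect per brood
#' and sexes drawn independently per larva with probability `sex_ratio` of
#' being female.
#'
#' Reproducibility: one L'Ecuyer-CMRG stream is derived per brood from
#' `params$seed`, and one substream per individual within the brood, so the
#' same seed yields bit-identical populations and enlarging the design (more
#' broods, or more larvae per brood) leaves previously generated individuals
#' unchanged. The caller's RNG state is restored on exit.
#'
#' @param params A [sim_params()] object.
#' @return A [trajectory_table()] with provenance attributes
#'   (`source = "simulated"`, `seed`, and the full `sim_params`).
#' @examples
#' pop <- simulate_population(sim_params(n_broods = 2, seed = 42))
#' nrow(pop) # 2 broods x (12 + 3) larvae
#' @export
simulate_population <- function(params = sim_params()) {
  validate_sim_params(params)
  h1 <- as.integer(params$larvae_per_brood_host1)
  h2 <- as.integer(params$larvae_per_brood_host2)
  total <- h1 + h2
  nb <- as.integer(params$n_broods)
  if (total < 1L) stop("design has zero larvae per brood", call. = FALSE)

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)

  set.seed(params$seed, kind = "L'Ecuyer-CMRG")
  stream <- get(".Random.seed", envir = globalenv())
  hosts <- rep(c("host1", "host2"), c(h1, h2))
  trajs <- vector("list", nb * total)
  k <- 0L
  for (b in seq_len(nb)) {
    stream <- parallel::nextRNGStream(stream)
    assign(".Random.seed", stream, envir = globalenv())
    brood_eff <- stats::rnorm(1, 0, params$sd_rate_brood)
    sexes <- ifelse(stats::runif(total) < params$sex_ratio, "F", "M")
    brood_id <- sprintf("b%03d", b)
    sub <- stream
    for (i in seq_len(total)) {
      sub <- parallel::nextRNGSubStream(sub)
      k <- k + 1L
      trajs[[k]] <- simulate_trajectory(
        params, sex = sexes[i], brood_effect = brood_eff, host = hosts[i],
        rng_state = sub,
        individual_id = sprintf("%s_i%02d", brood_id, i), brood_id = brood_id)
    }
  }
  out <- trajectory_table(trajs, source = "simulated", seed = params$seed)
  attr(out, "sim_params") <- params
  out
}
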