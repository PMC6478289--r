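#' Differential (instantaneous) growth-rate indices
#'
#' Three indices of daily growth computed from the masses at the start and
#' end of a 24 h period:
#' * `absolute_rate()` — the raw increment `m_end - m_start` (mg/day);
#'   increases with larval size.
#' * `relative_rate()` — `log10(m_end / m_start)` (1/day), the exponential-
#'   growth rate; decreases with larval size.
#' * `allometric_rate()` — `m_end^(1/3) - m_start^(1/3)` (mg^(1/3)/day), the
#'   daily gain in cube-root-transformed mass; constant across sizes when
#'   growth follows a cubic curve, which makes it the size-independent index
#'   suitable for comparing sexes of different average size.
#'
#' @param m_start,m_end Positive masses (mg) recorded 24 h apart.
#' @param base Logarithm base for `relative_rate()`; 10 by default (use
#'   `exp(1)` for natural log — never the default).
#' @return A numeric vector of rates.
#' @examples
#' allometric_rate(8, 27)    # 3 - 2 = 1
#' relative_rate(10, 100)    # 1
#' absolute_rate(10, 22)     # 12
#' @export
absolute_rate <- function(m_start, m_end) {
  check_masses(m_start, m_end)
  m_end - m_start
}

#' @rdname absolute_rate
#' @export
relative_rate <- function(m_start, m_end, base = 10) {
  check_masses(m_start, m_end)
  log(m_end / m_start, base = base)
}

#' @rdname absolute_rate
#' @export
allometric_rate <- function(m_start, m_end) {
  check_masses(m_start, m_end)
  m_end^(1 / 3) - m_start^(1 / 3)
}

check_masses <- function(m_start, m_end) {
  if (any(!is.na(m_start) & m_start <= 0) || any(!is.na(m_end) & m_end <= 0))
    stop("masses must be positive", call. = FALSE)
  invisible(NULL)
}

#' Day-specific growth-rate records over the free-growth window
#'
#' Computes, for every individual and every day `d` in `window`, the selected
#' differential growth-rate indices from the 24 h increment `m_(d-1) -> m_d`
#' (day 0 being the initial, intermolt-stasis mass). Days for which either
#' bounding mass is missing contribute no record. Each record carries
#' `covariate_mass`, the mass recorded one day *before* the 24 h period
#' (`m_(d-2)`; the initial mass for day 2), so that a size regression of the
#' rate shares no mass measurement with the rate itself — sharing one is a
#' known source of spurious correlation.
#'
#' The default window, days 2-5, covers the early free-growth phase: day 1 is
#' excluded because its gain is dominated by gut filling, and later days are
#' excluded because growth tapers towards pupation.
#'
#' @param table A [trajectory_table()].
#' @param window Integer vector of day indices (default `2:5`).
#' @param measures Subset of `c("absolute", "relative", "allometric")`.
#' @param base Log base for the relative rate (default 10).
#' @return A tibble with columns `individual_id, sex, brood_id, host, day,
#'   measure, value, covariate_mass`.
#' @export
rate_table <- function(table, window = 2:5,
                       measures = c("absolute", "relative", "allometric"),
                       base = 10) {
  measures <- match.arg(measures, several.ok = TRUE)
  if (length(window) == 0L) stop("`window` must not be empty", call. = FALSE)
  if (any(window < 1 | window != round(window)))
    stop("`window` must contain whole days >= 1", call. = FALSE)
  validate_trajectory_table(table)

  per_ind <- lapply(seq_len(nrow(table)), function(i) {
    dm <- table$daily_masses[[i]]
    masses <- c(table$initial_mass[i], dm)   # masses[d + 1] = m_d
    days <- window[window <= length(dm)]
    if (!length(days)) return(NULL)
    m_start <- masses[days]
    m_end <- masses[days + 1]
    cov <- ifelse(days >= 2, masses[days - 1], NA_real_)
    ok <- !is.na(m_start) & !is.na(m_end)
    if (!any(ok)) return(NULL)
    tibble::tibble(individual_id = table$individual_id[i],
                   sex = table$sex[i], brood_id = table$brood_id[i],
                   host = table$host[i], day = days[ok],
                   m_start = m_start[ok], m_end = m_end[ok],
                   covariate_mass = cov[ok])
  })
  base_tbl <- dplyr::bind_rows(per_ind)
  if (nrow(base_tbl) == 0L)
    return(tibble::tibble(individual_id = character(), sex = character(),
                          brood_id = character(), host = character(),
                          day = integer(), measure = character(),
                          value = numeric(), covariate_mass = numeric()))
  out <- lapply(measures, function(ms) {
    val <- switch(ms,
                  absolute = absolute_rate(base_tbl$m_start, base_tbl$m_end),
                  relative = relative_rate(base_tbl$m_start, base_tbl$m_end,
                                           base = base),
                  allometric = allometric_rate(base_tbl$m_start, base_tbl$m_end))
    dplyr::mutate(base_tbl[c("individual_id", "sex", "brood_id", "host", "day",
                             "covariate_mass")],
                  measure = ms, value = val,
                  .before = "covariate_mass")
  })
  dplyr::bind_rows(out)
}

#' Summaries of growth-rate records by sex and measure
#'
#' Mean rate per (measure, sex) with its SE over individual larvae (each
#' larva's rates are first averaged over days, so larvae — not measurements —
#' are the unit of replication). For the relative rate the daily fold gain
#' `m_end / m_start = 10^value` is summarized both ways that "grew x times
#' heavier per day" can be read: `fold_arith` (arithmetic mean of daily folds)
#' and `fold_geom` (the fold implied by the mean relative rate, i.e. the
#' geometric mean).
#'
#' @param records A tibble from [rate_table()].
#' @param base Log base with which the relative rates were computed.
#' @return A tibble with columns `measure, sex, n_larvae, mean, se,
#'   fold_arith, fold_geom`.
#' @export
summarize_rates <- function(records, base = 10) {
  stopifnot(all(c("individual_id", "sex", "measure", "value") %in% names(records)))
  per_larva <- dplyr::summarise(
    dplyr::group_by(records, .data$measure, .data$sex, .data$individual_id),
    value = mean(.data$value), fold = mean(base^.data$value),
    .groups = "drop")
  dplyr::summarise(
    dplyr::group_by(per_larva, .data$measure, .data$sex),
    n_larvae = dplyr::n(),
    mean = mean(.data$value),
    se = stats::sd(.data$value) / sqrt(dplyr::n()),
    fold_arith = ifelse(.data$measure[1] == "relative",
                        mean(.data$fold), NA_real_),
    fold_geom = ifelse(.data$measure[1] == "relative",
                       base^mean(.data$value), NA_real_),
    .groups = "drop")
}

#' Integral growth-rate measures
#'
#' Whole-phase growth rates computed from per-individual descriptors, for
#' comparison with the differential indices: pupal mass divided by total
#' development time (`pupa_over_total_time`), pupal mass divided by the
#' last-instar duration (`pupa_over_instar_time`), or `log10` pupal mass
#' divided by total development time (`log_pupa_over_total_time`). Integral
#' measures average over waiting phases and mass loss, which is why they can
#' misattribute a development-time difference to "growth rate".
#'
#' @param features A feature table from [extract_features()].
#' @param variant One of the three measures above.
#' @return A numeric vector aligned with the rows of `features`.
#' @export
integral_rate <- function(features,
                          variant = c("pupa_over_total_time",
                                      "pupa_over_instar_time",
                                      "log_pupa_over_total_time")) {
  variant <- match.arg(variant)
  total_time <- features$time_to_instar5 + features$instar_duration
  denom <- switch(variant,
                  pupa_over_total_time = total_time,
                  pupa_over_instar_time = features$instar_duration,
                  log_pupa_over_total_time = total_time)
  if (any(!is.na(denom) & denom <= 0))
    stop("integral_rate: zero or negative duration", call. = FALSE)
  num <- switch(variant,
                log_pupa_over_total_time = log10(features$pupal_mass),
                features$pupal_mass)
  num / denom
}
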