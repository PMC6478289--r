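#' Extract growth-curve descriptors from trajectories
#'
#' Computes, per individual, the standard last-instar growth-curve
#' descriptors: maximal mass (over the initial day-0 mass and all recorded
#' daily masses), the day on which it was first attained (`time_to_max`; ties
#' resolve to the earliest day, day 0 being the initial mass), the
#' pupal/initial, maximal/initial and maximal/final mass ratios, and the
#' absolute daily mass increments `m_d - m_(d-1)` for days 2..9 (the day-1
#' increment is excluded as gut filling dominates it; increments are `NA`
#' where either bounding mass is missing or the record ended earlier).
#'
#' @param x A [trajectory()] or a [trajectory_table()].
#' @return A tibble with one row per individual.
#' @examples
#' tr <- trajectory("a", "b1", "host1", "F", 18, 25,
#'                  c(30, 40, 55, 70, 80, 78, 60),
#'                  final_larval_mass = 60, pupal_mass = 50)
#' extract_features(tr)$maximal_mass # 80
#' @export
extract_features <- function(x) UseMethod("extract_features")

#' @export
extract_features.trajectory <- function(x) {
  validate_trajectory(x)
  dm <- x$daily_masses
  masses <- c(x$initial_mass, dm)          # index 1 = day 0
  maximal <- max(masses, na.rm = TRUE)
  time_to_max <- which(masses == maximal)[1] - 1L
  inc <- function(d) {
    if (d >= 1 && d <= length(dm) && !is.na(masses[d + 1]) && !is.na(masses[d]))
      masses[d + 1] - masses[d]
    else NA_real_
  }
  incs <- vapply(2:9, inc, numeric(1))
  names(incs) <- paste0("abs_increment_day_", 2:9)
  out <- tibble::tibble(
    individual_id = x$individual_id, sex = x$sex, brood_id = x$brood_id,
    host = x$host, time_to_instar5 = x$time_to_instar5,
    initial_mass = x$initial_mass, maximal_mass = maximal,
    pupal_mass = x$pupal_mass, final_larval_mass = x$final_larval_mass,
    instar_duration = x$instar_duration,
    ratio_pupa_initial = x$pupal_mass / x$initial_mass,
    ratio_max_initial = maximal / x$initial_mass,
    ratio_max_final = maximal / x$final_larval_mass,
    time_to_max = as.numeric(time_to_max))
  dplyr::bind_cols(out, tibble::as_tibble(as.list(incs)))
}

#' @export
extract_features.trajectory_table <- function(x) {
  dplyr::bind_rows(lapply(seq_len(nrow(x)), function(i)
    extract_features(row_to_trajectory(x, i))))
}

#' @export
extract_features.data.frame <- function(x) {
  extract_features.trajectory_table(x)
}

#' Per-sex mean and standard error of every growth descriptor
#'
#' Summarizes a feature table as mean +/- SE (`sd/sqrt(n)`) per variable and
#' sex, with the per-variable `n` (missing values excluded variable-wise).
#'
#' @param features A feature table from [extract_features()].
#' @return A tibble with columns `variable, sex, n, mean, se`.
#' @export
summarize_by_sex <- function(features) {
  stopifnot(is.data.frame(features), "sex" %in% names(features))
  present <- unique(features$sex)
  absent <- setdiff(c("F", "M"), present)
  if (length(absent))
    stop("no rows for sex ", paste(absent, collapse = ", "), call. = FALSE)
  counts <- table(features$sex)
  if (any(counts < 2))
    stop("need at least 2 rows per sex", call. = FALSE)
  num_cols <- names(features)[vapply(features, is.numeric, logical(1))]
  long <- tidyr::pivot_longer(features[c("sex", num_cols)],
                              cols = dplyr::all_of(num_cols),
                              names_to = "variable", values_to = "value")
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$variable, .data$sex),
    n = sum(!is.na(.data$value)),
    mean = mean(.data$value, na.rm = TRUE),
    se = stats::sd(.data$value, na.rm = TRUE) / sqrt(sum(!is.na(.data$value))),
    .groups = "drop")
  out$variable <- factor(out$variable, levels = num_cols)
  out <- dplyr::arrange(out, .data$variable, .data$sex)
  out$variable <- as.character(out$variable)
  out
}

#' Sexual size dimorphism ratio and dimorphism index
#'
#' `ssd_ratio()` is the female-to-male ratio of a mean size measure;
#' `sdi()` is the sexual dimorphism index, the ratio minus one.
#'
#' @param mean_F,mean_M Positive sex-specific means (any size measure).
#' @param ratio An SSD ratio.
#' @return A number.
#' @examples
#' ssd_ratio(73.57, 63.28) # ~1.16 in pupal masses
#' sdi(ssd_ratio(73.57, 63.28)) # ~0.16
#' @export
ssd_ratio <- function(mean_F, mean_M) {
  if (any(!is.finite(mean_F)) || any(!is.finite(mean_M)) ||
      any(mean_F <= 0) || any(mean_M <= 0))
    stop("ssd_ratio: means must be positive", call. = FALSE)
  mean_F / mean_M
}

#' @rdname ssd_ratio
#' @export
sdi <- function(ratio) {
  if (any(!is.finite(ratio)) || any(ratio <= 0))
    stop("sdi: ratio must be positive", call. = FALSE)
  ratio - 1
}
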