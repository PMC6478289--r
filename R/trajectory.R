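#' Construct a single larval growth trajectory
#'
#' A trajectory is one individual's full last-instar growth record: identity,
#' sex, brood, host plant, pre-last-instar development time, the day-0
#' (intermolt stasis) initial mass, the daily masses for days 1..n of the
#' instar, the final (last feeding-day) larval mass, and the pupal mass.
#'
#' Day convention: day 0 is the intermolt-stasis measurement (the instar's
#' initial mass); daily masses are indexed 1..n; the increment of day d is
#' `m_d - m_(d-1)`.
#'
#' @param individual_id,brood_id Non-empty identifier strings.
#' @param host `"host1"` or `"host2"`.
#' @param sex `"F"` or `"M"`.
#' @param time_to_instar5 Days from hatching to the start of the last instar.
#' @param initial_mass Day-0 mass (mg).
#' @param daily_masses Numeric vector of masses (mg) for days 1..n; `NA` marks
#'   a missing daily record.
#' @param instar_duration Length of the instar in days (= `length(daily_masses)`).
#' @param final_larval_mass Mass (mg) on the last feeding day.
#' @param pupal_mass Pupal mass (mg).
#' @param censored Logical dropout flag.
#' @return A list of class `"trajectory"`.
#' @export
trajectory <- function(individual_id, brood_id, host, sex,
                       time_to_instar5, initial_mass, daily_masses,
                       instar_duration = length(daily_masses),
                       final_larval_mass, pupal_mass, censored = FALSE) {
  tr <- list(individual_id = as.character(individual_id),
             brood_id = as.character(brood_id),
             host = as.character(host), sex = as.character(sex),
             time_to_instar5 = as.numeric(time_to_instar5),
             initial_mass = as.numeric(initial_mass),
             daily_masses = as.numeric(daily_masses),
             instar_duration = as.numeric(instar_duration),
             final_larval_mass = as.numeric(final_larval_mass),
             pupal_mass = as.numeric(pupal_mass),
             censored = isTRUE(censored))
  class(tr) <- "trajectory"
  validate_trajectory(tr)
  tr
}

validate_trajectory <- function(tr) {
  id <- tr$individual_id
  fail <- function(...) stop("trajectory ", id, ": ", ..., call. = FALSE)
  if (!nzchar(id)) stop("trajectory: empty individual_id", call. = FALSE)
  if (!nzchar(tr$brood_id)) fail("empty brood_id")
  if (!tr$sex %in% c("F", "M")) fail("unknown sex code '", tr$sex, "'")
  if (!tr$host %in% c("host1", "host2")) fail("unknown host '", tr$host, "'")
  dm <- tr$daily_masses
  if (length(dm) < 1L) fail("needs at least one daily mass")
  if (length(dm) != tr$instar_duration)
    fail("daily_masses length (", length(dm),
         ") inconsistent with instar_duration (", tr$instar_duration, ")")
  masses <- c(tr$initial_mass, dm, tr$final_larval_mass, tr$pupal_mass)
  if (any(!is.na(masses) & masses <= 0)) fail("all masses must be > 0")
  if (is.na(tr$initial_mass)) fail("initial_mass is missing")
  if (all(is.na(dm))) fail("all daily masses are missing")
  mx <- max(dm, na.rm = TRUE)
  if (mx < tr$initial_mass) fail("max daily mass below initial mass")
  if (!is.na(tr$pupal_mass) && tr$pupal_mass > mx)
    fail("pupal_mass exceeds maximal daily mass")
  if (!is.na(tr$final_larval_mass) && tr$final_larval_mass > mx)
    fail("final_larval_mass exceeds maximal daily mass")
  invisible(tr)
}

#' @exportS3Method base::print
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory %s> sex %s, brood %s, host %s\n",
              x$individual_id, x$sex, x$brood_id, x$host))
  cat(sprintf("  initial %.2f mg; %d daily masses (max %.2f); pupa %.2f mg\n",
              x$initial_mass, length(x$daily_masses),
              max(x$daily_masses, na.rm = TRUE), x$pupal_mass))
  invisible(x)
}

#' Bundle trajectories into a trajectory table
#'
#' A trajectory table is a tibble with one row per individual and a
#' list-column `daily_masses`, carrying provenance in attributes (`source`,
#' `dialect`, `seed` when simulated).
#'
#' @param trajectories List of `"trajectory"` objects.
#' @param source,dialect,seed Optional provenance metadata.
#' @return A tibble of class `"trajectory_table"`.
#' @export
trajectory_table <- function(trajectories, source = NA_character_,
                             dialect = NA_character_, seed = NA_integer_) {
  stopifnot(all(vapply(trajectories, inherits, logical(1), "trajectory")))
  tbl <- tibble::tibble(
    individual_id = vapply(trajectories, `[[`, character(1), "individual_id"),
    brood_id = vapply(trajectories, `[[`, character(1), "brood_id"),
    host = vapply(trajectories, `[[`, character(1), "host"),
    sex = vapply(trajectories, `[[`, character(1), "sex"),
    time_to_instar5 = vapply(trajectories, `[[`, numeric(1), "time_to_instar5"),
    initial_mass = vapply(trajectories, `[[`, numeric(1), "initial_mass"),
    daily_masses = lapply(trajectories, `[[`, "daily_masses"),
    instar_duration = vapply(trajectories, `[[`, numeric(1), "instar_duration"),
    final_larval_mass = vapply(trajectories, `[[`, numeric(1), "final_larval_mass"),
    pupal_mass = vapply(trajectories, `[[`, numeric(1), "pupal_mass"),
    censored = vapply(trajectories, `[[`, logical(1), "censored"))
  new_trajectory_table(tbl, source = source, dialect = dialect, seed = seed)
}

new_trajectory_table <- function(tbl, source = NA_character_,
                                 dialect = NA_character_, seed = NA_integer_) {
  attr(tbl, "source") <- source
  attr(tbl, "dialect") <- dialect
  attr(tbl, "seed") <- seed
  class(tbl) <- unique(c("trajectory_table", class(tbl)))
  validate_trajectory_table(tbl)
  tbl
}

#' Validate a trajectory table
#'
#' Checks identifier uniqueness, sex/host codes, mass positivity, and the
#' per-individual growth-record invariants (pupal and final masses cannot
#' exceed the maximal recorded mass; missing daily masses stay explicit).
#'
#' @param tbl A `"trajectory_table"`.
#' @return The table, invisibly; errors name the offending individual.
#' @export
validate_trajectory_table <- function(tbl) {
  required <- c("individual_id", "brood_id", "host", "sex", "time_to_instar5",
                "initial_mass", "daily_masses", "instar_duration",
                "final_larval_mass", "pupal_mass")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols))
    stop("trajectory table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  dup <- tbl$individual_id[duplicated(tbl$individual_id)]
  if (length(dup))
    stop("duplicate individual_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  for (i in seq_len(nrow(tbl))) validate_trajectory(row_to_trajectory(tbl, i))
  invisible(tbl)
}

#' Extract one row of a trajectory table as a trajectory object
#' @param tbl A `"trajectory_table"`. @param i Row index.
#' @return A `"trajectory"`.
#' @export
row_to_trajectory <- function(tbl, i) {
  tr <- list(individual_id = tbl$individual_id[i], brood_id = tbl$brood_id[i],
             host = tbl$host[i], sex = tbl$sex[i],
             time_to_instar5 = tbl$time_to_instar5[i],
             initial_mass = tbl$initial_mass[i],
             daily_masses = tbl$daily_masses[[i]],
             instar_duration = tbl$instar_duration[i],
             final_larval_mass = tbl$final_larval_mass[i],
             pupal_mass = tbl$pupal_mass[i],
             censored = if ("censored" %in% names(tbl)) isTRUE(tbl$censored[i]) else FALSE)
  class(tr) <- "trajectory"
  tr
}
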