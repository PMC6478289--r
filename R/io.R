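#' Write a trajectory table to a delimited text file
#'
#' Two dialects are supported. `wide` has one row per individual with columns
#' `individual_id, brood_id, host, sex, time_to_instar5, initial_mass,
#' day1..dayN, instar_duration, final_larval_mass, pupal_mass, censored`
#' (day columns beyond an individual's instar duration are left `NA`).
#' `long` has one row per (individual, day) with columns `individual_id, day,
#' mass`, plus a companion per-individual metadata file (written next to
#' `path` unless `meta_path` is given). Missing daily masses are written as
#' explicit `NA`, never dropped. Numbers are serialized with shortest
#' round-trip precision, so `read_trajectories()` recovers the table exactly.
#'
#' @param table A [trajectory_table()].
#' @param path Output path; `.csv` selects comma delimiting, anything else tab
#'   (override with `delim`).
#' @param dialect `"wide"` or `"long"`.
#' @param delim `"\t"` or `","`; default derived from the file extension.
#' @param meta_path Companion metadata path for `dialect = "long"`; defaults
#'   to `<path-sans-ext>_meta.<ext>`.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(table, path, dialect = c("wide", "long"),
                               delim = NULL, meta_path = NULL) {
  dialect <- match.arg(dialect)
  validate_trajectory_table(table)
  if (!dir.exists(dirname(path)))
    stop("cannot write to '", path, "': directory does not exist", call. = FALSE)
  delim <- delim %||% infer_delim_from_ext(path)

  if (dialect == "wide") {
    n_max <- if (nrow(table)) max(table$instar_duration) else 0L
    wide <- meta_cols(table)
    if (n_max > 0) {
      days <- vapply(table$daily_masses, function(m) {
        c(m, rep(NA_real_, n_max - length(m)))
      }, numeric(n_max))
      days <- if (n_max == 1L) matrix(days, nrow = 1L) else days
      day_df <- tibble::as_tibble(t(days), .name_repair = "minimal")
      names(day_df) <- paste0("day", seq_len(n_max))
      wide <- dplyr::bind_cols(wide[1:6], day_df, wide[7:10])
    }
    readr::write_delim(wide, path, delim = delim, na = "NA")
  } else {
    meta_path <- meta_path %||% default_meta_path(path)
    long <- tidyr::unnest(
      tibble::tibble(individual_id = table$individual_id,
                     mass = table$daily_masses),
      cols = "mass")
    long <- dplyr::mutate(
      dplyr::group_by(long, .data$individual_id),
      day = dplyr::row_number(), .before = "mass")
    long <- dplyr::ungroup(long)
    readr::write_delim(long, path, delim = delim, na = "NA")
    readr::write_delim(meta_cols(table), meta_path, delim = delim, na = "NA")
  }
  invisible(path)
}

meta_cols <- function(table) {
  tibble::tibble(individual_id = table$individual_id,
                 brood_id = table$brood_id, host = table$host, sex = table$sex,
                 time_to_instar5 = table$time_to_instar5,
                 initial_mass = table$initial_mass,
                 instar_duration = table$instar_duration,
                 final_larval_mass = table$final_larval_mass,
                 pupal_mass = table$pupal_mass,
                 censored = if ("censored" %in% names(table)) table$censored
                            else rep(FALSE, nrow(table)))
}

default_meta_path <- function(path) {
  ext <- tools::file_ext(path)
  base <- tools::file_path_sans_ext(path)
  if (nzchar(ext)) paste0(base, "_meta.", ext) else paste0(base, "_meta")
}

infer_delim_from_ext <- function(path) {
  if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a trajectory table from a delimited text file
#'
#' Counterpart of [write_trajectories()]; see there for the two dialects.
#' The delimiter is auto-detected (tab vs comma) unless forced, the dialect
#' is inferred from the header unless forced, sex codes are read
#' case-insensitively, and `NA` or empty cells mark missing daily masses
#' (which are preserved, never imputed). Validation rejects duplicate
#' individual identifiers, non-numeric masses (naming the offending row), and
#' unknown sex codes, and enforces the trajectory invariants.
#'
#' @param path Input path.
#' @param dialect `"auto"`, `"wide"` or `"long"`.
#' @param delim Forced delimiter, or `NULL` to sniff the header line.
#' @param meta_path Companion metadata file for the long dialect (defaults as
#'   in [write_trajectories()]).
#' @return A [trajectory_table()] with provenance attributes.
#' @export
read_trajectories <- function(path, dialect = c("auto", "wide", "long"),
                              delim = NULL, meta_path = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- delim %||% sniff_delim(path)
  raw <- readr::read_delim(path, delim = delim, na = c("", "NA"),
                           col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  if (dialect == "auto") {
    dialect <- if (any(grepl("^day[0-9]+$", names(raw)))) "wide"
               else if (all(c("individual_id", "day", "mass") %in% names(raw))) "long"
               else "wide"
  }
  tbl <- if (dialect == "wide") parse_wide(raw, path)
         else parse_long(raw, path, delim, meta_path)
  new_trajectory_table(tbl, source = path, dialect = dialect)
}

sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (length(header) && grepl("\t", header)) "\t" else ","
}

parse_numeric_col <- function(x, col, ids, what = "value") {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad))
    stop(sprintf("non-numeric %s '%s' in column `%s`, row %d (individual %s)",
                 what, x[bad[1]], col, bad[1], ids[bad[1]]), call. = FALSE)
  out
}

parse_sex_col <- function(x, ids) {
  out <- toupper(trimws(x))
  bad <- which(!is.na(out) & !out %in% c("F", "M"))
  if (length(bad))
    stop(sprintf("unknown sex code '%s' for individual %s (expected F or M)",
                 x[bad[1]], ids[bad[1]]), call. = FALSE)
  out
}

parse_meta <- function(raw, path) {
  required <- c("individual_id", "brood_id", "host", "sex", "time_to_instar5",
                "initial_mass", "final_larval_mass", "pupal_mass")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("file ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  ids <- raw$individual_id
  tibble::tibble(
    individual_id = ids,
    brood_id = raw$brood_id,
    host = raw$host,
    sex = parse_sex_col(raw$sex, ids),
    time_to_instar5 = parse_numeric_col(raw$time_to_instar5, "time_to_instar5",
                                        ids, "time"),
    initial_mass = parse_numeric_col(raw$initial_mass, "initial_mass", ids,
                                     "mass"),
    instar_duration = if ("instar_duration" %in% names(raw))
      parse_numeric_col(raw$instar_duration, "instar_duration", ids, "duration")
      else NA_real_,
    final_larval_mass = parse_numeric_col(raw$final_larval_mass,
                                          "final_larval_mass", ids, "mass"),
    pupal_mass = parse_numeric_col(raw$pupal_mass, "pupal_mass", ids, "mass"),
    censored = if ("censored" %in% names(raw))
      as.logical(raw$censored) %in% TRUE else FALSE)
}

parse_wide <- function(raw, path) {
  meta <- parse_meta(raw, path)
  day_cols <- names(raw)[grepl("^day[0-9]+$", names(raw))]
  day_idx <- as.integer(sub("^day", "", day_cols))
  day_cols <- day_cols[order(day_idx)]
  n_max <- length(day_cols)
  if (n_max == 0L && nrow(raw) > 0L)
    stop("file ", path, " has no day1..dayN mass columns", call. = FALSE)
  mass_mat <- vapply(day_cols, function(cl)
    parse_numeric_col(raw[[cl]], cl, meta$individual_id, "mass"),
    numeric(nrow(raw)))
  if (nrow(raw) == 1L) mass_mat <- matrix(mass_mat, nrow = 1L)
  daily <- lapply(seq_len(nrow(raw)), function(i) {
    m <- if (n_max) mass_mat[i, ] else numeric(0)
    dur <- meta$instar_duration[i]
    if (is.na(dur)) {
      keep <- which(!is.na(m))
      dur <- if (length(keep)) max(keep) else 0L
    }
    unname(m[seq_len(dur)])
  })
  build_table(meta, daily)
}

parse_long <- function(raw, path, delim, meta_path) {
  need <- c("individual_id", "day", "mass")
  if (!all(need %in% names(raw)))
    stop("long file ", path, " must have columns individual_id, day, mass",
         call. = FALSE)
  meta_path <- meta_path %||% default_meta_path(path)
  if (!file.exists(meta_path))
    stop("long dialect needs the per-individual metadata file ", meta_path,
         call. = FALSE)
  meta_raw <- readr::read_delim(meta_path, delim = delim, na = c("", "NA"),
                                col_types = readr::cols(.default = "c"),
                                progress = FALSE)
  meta <- parse_meta(meta_raw, meta_path)
  day <- parse_numeric_col(raw$day, "day", raw$individual_id, "day index")
  mass <- parse_numeric_col(raw$mass, "mass", raw$individual_id, "mass")
  if (any(is.na(day)) || any(day < 1 | day != round(day), na.rm = TRUE))
    stop("long file ", path, ": `day` must be whole numbers >= 1", call. = FALSE)
  split_mass <- split(mass, raw$individual_id)
  split_day <- split(day, raw$individual_id)
  daily <- lapply(seq_len(nrow(meta)), function(i) {
    id <- meta$individual_id[i]
    d <- split_day[[id]]
    m <- split_mass[[id]]
    dur <- meta$instar_duration[i]
    if (is.na(dur)) dur <- if (length(d)) max(d) else 0L
    out <- rep(NA_real_, dur)
    keep <- !is.na(d) & d <= dur
    out[d[keep]] <- m[keep]
    out
  })
  build_table(meta, daily)
}

build_table <- function(meta, daily) {
  tbl <- tibble::tibble(
    individual_id = meta$individual_id, brood_id = meta$brood_id,
    host = meta$host, sex = meta$sex,
    time_to_instar5 = meta$time_to_instar5, initial_mass = meta$initial_mass,
    daily_masses = daily,
    instar_duration = as.numeric(vapply(daily, length, integer(1))),
    final_larval_mass = meta$final_larval_mass, pupal_mass = meta$pupal_mass,
    censored = meta$censored)
  tbl
}
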