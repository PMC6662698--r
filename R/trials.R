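#' Trial tables
#'
#' A trial table is a tibble with one row per behavioral trial of a
#' delayed-estimation task:
#'
#' * `subject` — subject identifier (character)
#' * `load` — number of items held in memory (1, 2, or 3)
#' * `delay_s` — memory delay in seconds (> 0)
#' * `target_deg` — cued target hue, degrees in `[0, 360)`
#' * `nontarget1_deg`, `nontarget2_deg` — non-target hues (NA when absent;
#'   a load-`L` trial carries exactly `L - 1` non-targets)
#' * `report_deg` — reported hue, degrees
#' * `trial_index` — position within the session (used for epoch splits)
#'
#' `as_trials()` validates and normalizes a data frame into this shape;
#' [read_trials()]/[write_trials()] move it through CSV.
#'
#' @name trials
NULL

trial_cols <- c("subject", "load", "delay_s", "target_deg",
                "nontarget1_deg", "nontarget2_deg", "report_deg",
                "trial_index")

#' Coerce a data frame to a validated trial table
#'
#' Angles are wrapped into `[0, 360)`; loads must be 1-3; a load-`L` row
#' must carry exactly `L - 1` non-missing non-targets. Violations raise an
#' error naming the offending row.
#'
#' @param x a data frame with the columns documented in [trials].
#'   `nontarget1_deg`/`nontarget2_deg`/`trial_index` may be omitted and are
#'   filled with NA / row numbers.
#' @return a tibble of class `wm_trials`.
#' @export
as_trials <- function(x) {
  stopifnot(is.data.frame(x))
  needed <- c("subject", "load", "delay_s", "target_deg", "report_deg")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols)) {
    stop("trial table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- tibble::as_tibble(x)
  if (!"nontarget1_deg" %in% names(x)) x$nontarget1_deg <- NA_real_
  if (!"nontarget2_deg" %in% names(x)) x$nontarget2_deg <- NA_real_
  if (!"trial_index" %in% names(x)) x$trial_index <- seq_len(nrow(x))
  x <- x[trial_cols]
  x$subject <- as.character(x$subject)
  num_cols <- setdiff(trial_cols, "subject")
  x[num_cols] <- lapply(x[num_cols], as.numeric)

  bad <- which(!x$load %in% c(1, 2, 3))
  if (length(bad)) {
    stop("row ", bad[1], ": load must be 1, 2, or 3 (got ", x$load[bad[1]], ")",
         call. = FALSE)
  }
  bad <- which(!is.finite(x$delay_s) | x$delay_s <= 0)
  if (length(bad)) {
    stop("row ", bad[1], ": delay_s must be a positive number", call. = FALSE)
  }
  for (col in c("target_deg", "report_deg")) {
    bad <- which(!is.finite(x[[col]]))
    if (length(bad)) stop("row ", bad[1], ": ", col, " is not finite",
                          call. = FALSE)
    x[[col]] <- wrap_deg(x[[col]])
  }
  n_nt <- rowSums(!is.na(x[c("nontarget1_deg", "nontarget2_deg")]))
  bad <- which(n_nt != x$load - 1)
  if (length(bad)) {
    stop("row ", bad[1], ": load ", x$load[bad[1]], " requires ",
         x$load[bad[1]] - 1, " non-target(s), found ", n_nt[bad[1]],
         call. = FALSE)
  }
  for (col in c("nontarget1_deg", "nontarget2_deg")) {
    ok <- !is.na(x[[col]])
    x[[col]][ok] <- wrap_deg(x[[col]][ok])
  }
  class(x) <- c("wm_trials", class(x))
  x
}

#' Read or write a trial table CSV
#'
#' The CSV header matches the columns documented in [trials]. Writing then
#' reading reproduces the table (round-trip identity).
#'
#' @param path file path.
#' @return `read_trials()`: a validated `wm_trials` tibble.
#' @export
read_trials <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_trials(x)
}

#' @rdname read_trials
#' @param trials a trial table ([as_trials()]).
#' @export
write_trials <- function(trials, path) {
  trials <- as_trials(trials)
  readr::write_csv(as.data.frame(trials), path, progress = FALSE)
  invisible(path)
}

#' Validation report for a trial table
#'
#' Reporting-only companion to [as_trials()]: counts per load-by-delay
#' condition, angle-range violations, and duplicated trials. A valid table
#' yields an empty violation tibble.
#'
#' @param trials a data frame of trials (not necessarily validated).
#' @return a list with `counts` (tibble of trials per load x delay),
#'   `violations` (tibble: row, problem), and `n_duplicates`.
#' @export
validate_trials <- function(trials) {
  stopifnot(is.data.frame(trials))
  x <- tibble::as_tibble(trials)
  probs <- list()
  note <- function(rows, what) {
    if (length(rows)) tibble::tibble(row = rows, problem = what)
  }
  if (all(c("load") %in% names(x))) {
    probs <- c(probs, list(note(which(!x$load %in% c(1, 2, 3)),
                                "load outside 1..3")))
  }
  for (col in c("target_deg", "report_deg", "nontarget1_deg", "nontarget2_deg")) {
    if (col %in% names(x)) {
      v <- x[[col]]
      bad <- which(!is.na(v) & (v < 0 | v >= 360))
      probs <- c(probs, list(note(bad, paste0(col, " outside [0, 360)"))))
    }
  }
  if (all(c("nontarget1_deg", "nontarget2_deg", "load") %in% names(x))) {
    n_nt <- rowSums(!is.na(x[c("nontarget1_deg", "nontarget2_deg")]))
    probs <- c(probs, list(note(which(n_nt != x$load - 1),
                                "non-target count != load - 1")))
  }
  violations <- dplyr::bind_rows(purrr::compact(probs))
  if (nrow(violations)) violations <- dplyr::arrange(violations, .data$row)
  counts <- if (all(c("load", "delay_s") %in% names(x))) {
    dplyr::count(x, .data$load, .data$delay_s, name = "n_trials")
  } else {
    tibble::tibble(load = numeric(), delay_s = numeric(), n_trials = integer())
  }
  dup_cols <- intersect(trial_cols, names(x))
  list(counts = counts,
       violations = violations,
       n_duplicates = sum(duplicated(x[dup_cols])))
}

#' Per-trial signed error
#'
#' Adds an `error_deg` column (signed circular deviation of report from
#' target, clockwise positive).
#'
#' @param trials a trial table.
#' @return the table with `error_deg` appended.
#' @export
add_error <- function(trials) {
  trials <- as_trials(trials)
  trials$error_deg <- circ_error(trials$report_deg, trials$target_deg)
  trials
}
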