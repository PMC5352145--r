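## Per-fly survival event tables: the raw observation unit of the pipeline.
## One row per fly: line, sex, replicate tube, observation time (hours) and
## whether the fly died at that time or was censored (e.g. at a 14-day
## assay horizon). Treatment distinguishes pathogen-challenged flies from
## water-treated controls.

EVENT_COLUMNS <- c("line_id", "sex", "replicate_id", "time_h", "status", "treatment")

#' Construct a validated event table
#'
#' @param df data frame with columns `line_id`, `sex` (`"M"`/`"F"`),
#'   `replicate_id`, `time_h` (hours, non-negative), `status`
#'   (`"dead"`/`"censored"`) and optionally `treatment`
#'   (`"pathogen"`/`"control"`, default `"pathogen"`).
#' @param scoring_grid_hours optional scoring interval; when given, all times
#'   must be positive multiples of it and offending rows are rejected.
#' @return an `event_table` (a data frame).
#' @export
event_table <- function(df, scoring_grid_hours = NULL) {
  if (is.null(df$treatment)) df$treatment <- "pathogen"
  miss <- setdiff(EVENT_COLUMNS, names(df))
  if (length(miss) > 0)
    stop_format("event table format error: missing column(s) %s",
                paste(miss, collapse = ", "))
  df <- df[, EVENT_COLUMNS]
  df$line_id <- as.character(df$line_id)
  df$sex <- as.character(df$sex)
  df$replicate_id <- as.character(df$replicate_id)
  df$status <- as.character(df$status)
  df$treatment <- as.character(df$treatment)

  bad_sex <- which(!df$sex %in% c("M", "F"))
  if (length(bad_sex) > 0)
    stop_format("unknown sex token at row(s) %s (expected M or F)",
                paste(utils::head(bad_sex, 10), collapse = ", "))
  bad_status <- which(!df$status %in% c("dead", "censored"))
  if (length(bad_status) > 0)
    stop_format("unknown status token at row(s) %s (expected dead or censored)",
                paste(utils::head(bad_status, 10), collapse = ", "))
  bad_trt <- which(!df$treatment %in% c("pathogen", "control"))
  if (length(bad_trt) > 0)
    stop_format("unknown treatment token at row(s) %s",
                paste(utils::head(bad_trt, 10), collapse = ", "))
  if (!is.numeric(df$time_h))
    stop_format("event table validation error: time_h must be numeric")
  bad_time <- which(is.na(df$time_h) | df$time_h < 0)
  if (length(bad_time) > 0)
    stop_format("negative or missing time at row(s) %s",
                paste(utils::head(bad_time, 10), collapse = ", "))
  if (!is.null(scoring_grid_hours)) {
    off <- which(abs(df$time_h / scoring_grid_hours -
                       round(df$time_h / scoring_grid_hours)) > 1e-8)
    if (length(off) > 0)
      stop_format("time off the %g-h scoring grid at row(s) %s",
                  scoring_grid_hours, paste(utils::head(off, 20), collapse = ", "))
  }
  rownames(df) <- NULL
  structure(df, class = c("event_table", "data.frame"),
            scoring_grid_hours = scoring_grid_hours)
}

#' Read per-fly survival events from CSV
#'
#' Expects header `line_id,sex,replicate_id,time_h,status,treatment`.
#' Rows violating the declared scoring grid are rejected with their row
#' numbers. An optional early-death exclusion window can drop records
#' observed before `exclude_before_h`; the default keeps every record.
#'
#' @param path CSV file path.
#' @inheritParams event_table
#' @param exclude_before_h optional cutoff (hours); records with
#'   `time_h < exclude_before_h` are dropped and counted in the
#'   `n_excluded_early` attribute.
#' @return an `event_table`; attribute `counts` carries summary tallies.
#' @export
read_events <- function(path, scoring_grid_hours = NULL, exclude_before_h = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab <- event_table(df, scoring_grid_hours = scoring_grid_hours)
  n_early <- 0L
  if (!is.null(exclude_before_h)) {
    drop <- tab$time_h < exclude_before_h
    n_early <- sum(drop)
    tab <- tab[!drop, , drop = FALSE]
    tab <- event_table(as.data.frame(tab), scoring_grid_hours = scoring_grid_hours)
  }
  attr(tab, "n_excluded_early") <- n_early
  attr(tab, "counts") <- event_counts(tab)
  tab
}

event_counts <- function(tab) {
  c(n_records = nrow(tab),
    n_lines = length(unique(tab$line_id)),
    n_sexes = length(unique(tab$sex)),
    n_replicates = nrow(unique(tab[, c("line_id", "sex", "replicate_id")])),
    n_dead = sum(tab$status == "dead"),
    n_censored = sum(tab$status == "censored"))
}

#' Write an event table to CSV
#'
#' Fixed column order, newline-terminated, no quoting; companion writer of
#' [read_events()] (their composition is the identity).
#'
#' @param events an `event_table`.
#' @param path output CSV path.
#' @export
write_events <- function(events, path) {
  utils::write.csv(as.data.frame(events)[, EVENT_COLUMNS], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
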