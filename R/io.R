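TRACKING_SCHEMA <- "# wigwag tracking TSV v1"
TRACKING_COLS <- c("animal_id", "frame", "t_s", "x_mm", "y_mm")
TRAJECTORY_COLS <- c("agent_id", "event_index", "t_s", "x", "y", "phi_deg")

#' Write / read a tracking table as TSV
#'
#' Plain UTF-8 TSV with a schema-version comment line, a mandatory header
#' (`animal_id, frame, t_s, x_mm, y_mm`, optional `heading_deg`) and '.'
#' as the decimal separator. The round trip is lossless at full double
#' precision.
#'
#' @param x a tracking table (from [generate_tracking()] or compatible).
#' @param path file path.
#' @return `write_tracking_tsv` returns `path` invisibly;
#'   `read_tracking_tsv` returns a `tracking_table` data frame.
#' @export
write_tracking_tsv <- function(x, path) {
  stopifnot(all(TRACKING_COLS %in% names(x)))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(TRACKING_SCHEMA, con)
  utils::write.table(format(as.data.frame(x), digits = 17, trim = TRUE,
                            scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracking_tsv
#' @export
read_tracking_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  if (!identical(first, TRACKING_SCHEMA))
    stop("not a tracking TSV: missing schema line '", TRACKING_SCHEMA, "'")
  tab <- utils::read.delim(path, comment.char = "#", sep = "\t",
                           stringsAsFactors = FALSE)
  missing <- setdiff(TRACKING_COLS, names(tab))
  if (length(missing))
    stop("tracking TSV schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  if (nrow(tab) == 0L) stop("tracking TSV contains no data rows")
  for (id in unique(tab$animal_id)) {
    fr <- tab$frame[tab$animal_id == id]
    if (any(diff(fr) != 1L))
      stop("tracking TSV schema error: frames not consecutive for animal ", id)
  }
  structure(tab, class = c("tracking_table", "data.frame"))
}

#' Write / read simulated trajectories as TSV
#'
#' Long-format TSV with mandatory header
#' `agent_id, event_index, t_s, x, y, phi_deg` (one row per wigwag event
#' per agent, event 0 being the start).
#'
#' @param cohort a `planarian_cohort` (or a single trajectory).
#' @param path file path.
#' @return `write_trajectory_tsv` returns `path` invisibly;
#'   `read_trajectory_tsv` returns a long `data.frame`.
#' @export
write_trajectory_tsv <- function(cohort, path) {
  if (inherits(cohort, "planarian_trajectory")) cohort <- list(cohort)
  long <- do.call(rbind, lapply(seq_along(cohort), function(i) {
    traj <- cohort[[i]]
    data.frame(agent_id = i, event_index = traj$event, t_s = traj$t_s,
               x = traj$x, y = traj$y, phi_deg = traj$phi_deg)
  }))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(format(long, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_tsv
#' @export
read_trajectory_tsv <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  missing <- setdiff(TRAJECTORY_COLS, names(tab))
  if (length(missing))
    stop("trajectory TSV schema error: missing column(s) ",
         paste(missing, collapse = ", "))
  if (nrow(tab) == 0L) stop("trajectory TSV contains no data rows")
  tab
}

#' Split a long trajectory table back into a cohort list
#'
#' @param tab long `data.frame` as from [read_trajectory_tsv()].
#' @return list of per-agent trajectory data frames with columns
#'   `event`, `t_s`, `x`, `y`, `phi_deg`.
#' @export
split_trajectories <- function(tab) {
  lapply(split(tab, tab$agent_id), function(d) {
    data.frame(event = d$event_index, t_s = d$t_s, x = d$x, y = d$y,
               phi_deg = d$phi_deg)
  })
}

read_structured <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::fromJSON(path, simplifyVector = TRUE)
  else stop("config must be YAML (.yaml/.yml) or JSON (.json)")
}

#' Read a simulation configuration file
#'
#' YAML or JSON with top-level keys `assay`, `bf_deg`, `tau`, `gain`,
#' `gain_units`, `n_agents`, `seed`, and nested blocks
#' `wigwag: {enabled, angle_sd_deg, log_mean, log_sd}`,
#' `perturbation: {left_gain, right_gain, left_unshielded, right_unshielded}`,
#' `arena: {radius, max_events}`. Missing keys fall back to package
#' defaults; unknown keys are an error.
#'
#' @param path config file path.
#' @return a validated [sim_config()] object.
#' @export
read_sim_config <- function(path) {
  raw <- read_structured(path)
  known <- c("assay", "bf_deg", "tau", "gain", "gain_units",
             "wigwag", "perturbation", "arena", "n_agents", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  args <- raw[intersect(names(raw), c("assay", "bf_deg", "tau", "gain",
                                      "gain_units", "n_agents", "seed"))]
  w <- raw$wigwag
  if (!is.null(w)) {
    if (!is.null(w$enabled)) args$wigwag_enabled <- w$enabled
    if (!is.null(w$angle_sd_deg)) args$wigwag_angle_sd <- w$angle_sd_deg
    if (!is.null(w$log_mean)) args$wigwag_log_mean <- w$log_mean
    if (!is.null(w$log_sd)) args$wigwag_log_sd <- w$log_sd
  }
  p <- raw$perturbation
  if (!is.null(p)) args$perturbation <- do.call(perturbation_config, p)
  a <- raw$arena
  if (!is.null(a)) {
    if (!is.null(a$radius)) args$arena_radius <- a$radius
    if (!is.null(a$max_events)) args$max_events <- a$max_events
  }
  do.call(sim_config, args)
}

#' Read tracking-fixture generator parameters
#'
#' YAML or JSON with flat keys matching the arguments of
#' [tracking_params()], plus optional `n_animals`.
#'
#' @param path parameter file path.
#' @return list with elements `params` ([tracking_params()]) and
#'   `n_animals`.
#' @export
read_tracking_params <- function(path) {
  raw <- read_structured(path)
  n_animals <- raw$n_animals %||% 1L
  raw$n_animals <- NULL
  unknown <- setdiff(names(raw), names(formals(tracking_params)))
  if (length(unknown))
    stop("unknown fixture parameter(s): ", paste(unknown, collapse = ", "))
  list(params = do.call(tracking_params, raw), n_animals = n_animals)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
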