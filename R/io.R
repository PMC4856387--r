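schema_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("stereomet_schema_error",
                                             "error", "condition")))
}

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) schema_error("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    schema_error(path, ": missing column(s) ", paste(missing, collapse = ", "))
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read and write guessing-task trial logs
#'
#' The trials TSV has one row per trial with columns `subject_id`, `trial`,
#' `choice`, `baited`, `rewarded` (0/1). Sides are case-sensitive `"L"`/`"R"`.
#'
#' @param path File path.
#' @return `read_trials()`: a named list of [choice_sequence()] objects, one
#'   per subject, in file order. `write_trials()`: the path, invisibly.
#' @export
read_trials <- function(path) {
  df <- read_tsv_checked(path, c("subject_id", "trial", "choice", "baited",
                                 "rewarded"))
  for (col in c("choice", "baited")) {
    bad <- which(!(df[[col]] %in% c("L", "R")))
    if (length(bad))
      schema_error(path, " row ", bad[1], ": ", col, " value ",
                   deparse(df[[col]][bad[1]]), " is not 'L' or 'R'")
  }
  out <- list()
  for (sid in unique(df$subject_id)) {
    d <- df[df$subject_id == sid, , drop = FALSE]
    d <- d[order(d$trial), , drop = FALSE]
    if (anyDuplicated(d$trial))
      schema_error(path, ": duplicate trial index for subject ", sid)
    if (!identical(as.integer(d$trial), seq_len(nrow(d))))
      schema_error(path, ": trial indices for subject ", sid,
                   " are not contiguous from 1")
    if (!identical(as.integer(d$rewarded),
                   as.integer(d$choice == d$baited)))
      schema_error(path, ": rewarded flag inconsistent with choice/baited ",
                   "for subject ", sid)
    out[[sid]] <- choice_sequence(sid, d$choice, d$baited)
  }
  out
}

#' @rdname read_trials
#' @param seqs A [choice_sequence()] or list of them.
#' @export
write_trials <- function(seqs, path) {
  if (inherits(seqs, "choice_sequence")) seqs <- list(seqs)
  df <- do.call(rbind, lapply(seqs, as.data.frame))
  write_tsv(df, path)
}

#' Read and write radial-maze visit logs
#'
#' The visits TSV has columns `subject_id`, `session_id`, `arm_id`,
#' `entry_s`, `exit_s`; one [arm_visit_log()] is built per
#' (subject, session), validating non-overlap and time bounds.
#'
#' @param path File path.
#' @param duration_s Session duration passed to [arm_visit_log()].
#' @return `read_visits()`: a list of [arm_visit_log()] objects.
#' @export
read_visits <- function(path, duration_s = 600) {
  df <- read_tsv_checked(path, c("subject_id", "session_id", "arm_id",
                                 "entry_s", "exit_s"))
  out <- list()
  if (!nrow(df)) return(out)
  key <- paste(df$subject_id, df$session_id, sep = "\r")
  for (k in unique(key)) {
    d <- df[key == k, , drop = FALSE]
    log <- tryCatch(
      arm_visit_log(d$subject_id[1],
                    d[, c("arm_id", "entry_s", "exit_s"), drop = FALSE],
                    session_id = d$session_id[1], duration_s = duration_s),
      error = function(e) schema_error(
        path, " subject ", d$subject_id[1], " session ", d$session_id[1],
        ": ", conditionMessage(e)))
    out[[length(out) + 1L]] <- log
  }
  out
}

#' @rdname read_visits
#' @param logs An [arm_visit_log()] or list of them.
#' @export
write_visits <- function(logs, path) {
  if (inherits(logs, "arm_visit_log")) logs <- list(logs)
  df <- do.call(rbind, lapply(logs, function(l) {
    if (!nrow(l$visits))
      return(data.frame(subject_id = character(0), session_id = character(0),
                        arm_id = integer(0), entry_s = numeric(0),
                        exit_s = numeric(0)))
    data.frame(subject_id = l$subject_id, session_id = l$session_id,
               l$visits, stringsAsFactors = FALSE)
  }))
  write_tsv(df, path)
}

#' Read and write ethogram event streams
#'
#' The events TSV has columns `subject_id`, `behaviour`, `start_s`, `end_s`
#' and optional `repeat_index`.
#'
#' @param path File path.
#' @return `read_events()`: a named list of per-subject event data.frames.
#' @export
read_events <- function(path) {
  df <- read_tsv_checked(path, c("subject_id", "behaviour", "start_s",
                                 "end_s"))
  if (is.null(df$repeat_index)) df$repeat_index <- NA_integer_
  if (nrow(df)) {
    bad <- which(df$start_s >= df$end_s)
    if (length(bad))
      schema_error(path, " row ", bad[1], ": start_s >= end_s")
    tryCatch(validate_events(df), error = function(e)
      schema_error(path, ": ", conditionMessage(e)))
  }
  split(df[, c("behaviour", "start_s", "end_s", "repeat_index")],
        df$subject_id)
}

#' @rdname read_events
#' @param events A per-subject named list of event data.frames, or one
#'   data.frame already carrying `subject_id`.
#' @export
write_events <- function(events, path) {
  if (is.data.frame(events)) {
    df <- events
  } else {
    df <- do.call(rbind, lapply(names(events), function(sid)
      data.frame(subject_id = sid, events[[sid]], stringsAsFactors = FALSE)))
  }
  write_tsv(df, path)
}

#' Read an arm-role map from JSON
#'
#' The JSON maps arm ids to roles, e.g. `{"1": "positive", ...}`.
#' @param path File path.
#' @return An [arm_role_map()].
#' @export
read_roles <- function(path) {
  if (!file.exists(path)) schema_error("file not found: ", path)
  arm_role_map(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Read an observation scheme from JSON
#'
#' Recognised fields: `interval_s`, `block_starts_s`, `block_length_s`,
#' `days`; missing fields take the [observation_scheme()] defaults.
#' @param path File path.
#' @return An [observation_scheme()].
#' @export
read_scheme <- function(path) {
  if (!file.exists(path)) schema_error("file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- x[intersect(names(x), c("interval_s", "block_starts_s",
                                  "block_length_s", "days"))]
  do.call(observation_scheme, args)
}

#' Run an analysis pipeline from a configuration
#'
#' Executes the requested stages against input files and writes long-format
#' results (one row per subject/session x metric) plus a JSON manifest
#' (stages, parameters, seed, package version) sufficient to reproduce the
#' run. Stages: `"perseveration"` (needs `trials`), `"bias_scores"` (needs
#' `visits` and `roles`), `"ethogram"` (needs `events`; optional `scheme`).
#'
#' @param config List with elements `stages` (character vector), `out_dir`,
#'   `seed` (optional), file paths `trials`, `visits`, `roles`, `events`,
#'   `scheme` as required by the stages, and optional parameters `order`
#'   (Markov order) and `duration_s`.
#'
#' @return Invisibly, the combined long-format results data.frame (also
#'   written to `<out_dir>/results.tsv`, with the manifest at
#'   `<out_dir>/manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$out_dir))
  stages <- config$stages %||% character(0)
  unknown <- setdiff(stages, c("perseveration", "bias_scores", "ethogram"))
  if (length(unknown))
    stop(errorCondition(paste("unknown stage(s):",
                              paste(unknown, collapse = ", ")),
                        class = c("stereomet_config_error", "error",
                                  "condition")))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  long <- list()
  as_long <- function(df, session) {
    metrics <- setdiff(names(df), c("subject_id", "session_id"))
    do.call(rbind, lapply(metrics, function(m)
      data.frame(subject_id = df$subject_id,
                 session_id = if ("session_id" %in% names(df))
                   df$session_id else session,
                 metric = m, value = as.numeric(df[[m]]),
                 stringsAsFactors = FALSE)))
  }
  if ("perseveration" %in% stages) {
    seqs <- read_trials(config$trials)
    res <- perseveration_summary(seqs, order = config$order %||% 3)
    long[[length(long) + 1L]] <- as_long(res, "guessing")
  }
  if ("bias_scores" %in% stages) {
    roles <- read_roles(config$roles)
    logs <- read_visits(config$visits,
                        duration_s = config$duration_s %||% 600)
    res <- do.call(rbind, lapply(logs, bias_scores, roles = roles))
    long[[length(long) + 1L]] <- as_long(res, "maze")
  }
  if ("ethogram" %in% stages) {
    scheme <- if (is.null(config$scheme)) observation_scheme() else
      read_scheme(config$scheme)
    evs <- read_events(config$events)
    res <- do.call(rbind, lapply(names(evs), function(sid)
      ethogram_levels(one_zero_sample(evs[[sid]], scheme), sid)))
    long[[length(long) + 1L]] <- as_long(res, "home_cage")
  }
  results <- if (length(long)) do.call(rbind, long) else
    data.frame(subject_id = character(0), session_id = character(0),
               metric = character(0), value = numeric(0))
  write_tsv(results, file.path(config$out_dir, "results.tsv"))
  manifest <- list(
    package = "stereomet",
    version = as.character(utils::packageVersion("stereomet")),
    stages = stages, seed = config$seed,
    parameters = config[setdiff(names(config), c("stages", "out_dir"))],
    n_result_rows = nrow(results))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
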