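#' Walker condition labels
#'
#' The six walker conditions cross the two paths with the three local-flow
#' conditions; the heading experiment adds a no-walker baseline.
#'
#' @param include_none Include the `"none"` baseline (heading experiment)?
#' @return Character vector of condition labels such as
#'   `"equidistant:congruent_with_walker"`.
#' @export
walker_conditions <- function(include_none = FALSE) {
  conds <- as.vector(outer(c("equidistant", "approaching"),
                           c("congruent_with_walker",
                             "incongruent_with_walker",
                             "congruent_with_flow"),
                           paste, sep = ":"))
  if (include_none) c("none", conds) else conds
}

split_condition <- function(cond) {
  parts <- strsplit(cond, ":", fixed = TRUE)
  data.frame(path_kind = vapply(parts, `[`, "", 1L),
             flow_condition = vapply(parts, function(p)
               if (length(p) > 1L) p[2L] else "none", ""))
}

#' Heading-experiment trial schedule
#'
#' Builds the 280-trial randomized block design: 4 blocks, each presenting
#' the 7 walker conditions in random order; within a condition its 10 trials
#' (5 heading directions x left/right) run in shuffled order, so every
#' maximal run of one walker condition has length exactly 10. For the
#' no-walker baseline the side factor is a formal duplicate: the same
#' stimulus design is presented in either case.
#'
#' @param seed Integer seed; the schedule is a deterministic function of it.
#' @param headings Heading directions (degrees).
#' @return A data.frame of trial specifications: `trial`, `experiment`, `block`,
#'   `walker_condition`, `heading_angle`, `walker_direction`,
#'   `articulation`, `translation`, `stimulus_seed`.
#' @export
build_heading_schedule <- function(seed = 1L, headings = c(-10, -5, 0, 5, 10)) {
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  conds <- walker_conditions(include_none = TRUE)
  rows <- list()
  last_cond <- NULL
  for (block in 1:4) {
    order <- sample(conds)
    # keep condition runs at exactly one condition sub-block: the first
    # condition of a block must differ from the last of the previous block
    while (!is.null(last_cond) && order[1L] == last_cond)
      order <- sample(conds)
    last_cond <- order[length(order)]
    for (cond in order) {
      cells <- expand.grid(heading_angle = headings,
                           walker_direction = c("left", "right"),
                           stringsAsFactors = FALSE)
      cells <- cells[sample.int(nrow(cells)), ]
      cells$block <- block
      cells$walker_condition <- cond
      rows[[length(rows) + 1L]] <- cells
    }
  }
  out <- do.call(rbind, rows)
  out$experiment <- "heading"
  out$articulation <- "forward"
  out$translation <- "normal"
  out$trial <- seq_len(nrow(out))
  out$stimulus_seed <- sample.int(.Machine$integer.max - 1L, nrow(out))
  rownames(out) <- NULL
  out[, c("trial", "experiment", "block", "walker_condition",
          "heading_angle", "walker_direction", "articulation",
          "translation", "stimulus_seed")]
}

#' Facing / articulation experiment trial schedule
#'
#' Builds the 192-trial design shared by the facing and articulation
#' experiments: 4 blocks x 6 walker conditions in random order x 8 trials
#' (forward/backward articulation x normal/moonwalk translation x
#' left/right), shuffled within the condition, so runs of one walker
#' condition have length exactly 8. Observer motion is straight ahead.
#'
#' @param experiment `"facing"` or `"articulation"`.
#' @param seed Integer seed.
#' @return A data.frame with the same columns as
#'   [build_heading_schedule()] (heading_angle is 0 throughout).
#' @export
build_choice_schedule <- function(experiment = c("facing", "articulation"),
                                  seed = 1L) {
  experiment <- match.arg(experiment)
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  rows <- list()
  last_cond <- NULL
  for (block in 1:4) {
    order <- sample(walker_conditions())
    while (!is.null(last_cond) && order[1L] == last_cond)
      order <- sample(walker_conditions())
    last_cond <- order[length(order)]
    for (cond in order) {
      cells <- expand.grid(articulation = c("forward", "backward"),
                           translation = c("normal", "moonwalk"),
                           walker_direction = c("left", "right"),
                           stringsAsFactors = FALSE)
      cells <- cells[sample.int(nrow(cells)), ]
      cells$block <- block
      cells$walker_condition <- cond
      rows[[length(rows) + 1L]] <- cells
    }
  }
  out <- do.call(rbind, rows)
  out$experiment <- experiment
  out$heading_angle <- 0
  out$trial <- seq_len(nrow(out))
  out$stimulus_seed <- sample.int(.Machine$integer.max - 1L, nrow(out))
  rownames(out) <- NULL
  out[, c("trial", "experiment", "block", "walker_condition",
          "heading_angle", "walker_direction", "articulation",
          "translation", "stimulus_seed")]
}

#' Build the stimulus configuration for one trial
#'
#' @param trial One row of a schedule data.frame.
#' @param camera A [camera_model()].
#' @param speed Observer speed (m/s).
#' @param ... Passed on to [stimulus_config()] (e.g. `density`).
#' @return A [stimulus_config()].
#' @export
trial_stimulus_config <- function(trial, camera = camera_model(),
                                  speed = 1.5, ...) {
  cond <- split_condition(trial$walker_condition)
  path <- if (cond$flow_condition == "none") NULL else
    walker_path(cond$path_kind, trial$walker_direction)
  stimulus_config(camera = camera,
                  observer = observer_motion(trial$heading_angle, speed),
                  path = path,
                  condition = cond$flow_condition,
                  articulation = trial$articulation,
                  translation = trial$translation,
                  seed = trial$stimulus_seed, ...)
}

schedule_columns <- c("trial", "experiment", "block", "walker_condition",
                      "heading_angle", "walker_direction", "articulation",
                      "translation", "stimulus_seed")

#' Write a session log (schedule plus responses)
#'
#' Joins a schedule with response records by trial id and writes one
#' tab-separated row per trial. [read_session_log()] round-trips the format.
#'
#' @param schedule A schedule data.frame.
#' @param responses A data.frame with columns `trial`, `response` and
#'   `responder`. Heading responses are screen x positions (m); facing
#'   responses `"left"`/`"right"`; articulation responses
#'   `"forward"`/`"backward"`.
#' @param file Output path.
#' @export
write_session_log <- function(schedule, responses, file) {
  stopifnot(all(schedule_columns %in% names(schedule)))
  if (!all(c("trial", "response", "responder") %in% names(responses)))
    stop("responses need columns: trial, response, responder")
  if (!all(responses$trial %in% schedule$trial))
    stop("responses refer to unknown trials")
  log <- merge(responses, schedule, by = "trial")
  log <- log[order(log$responder, log$trial),
             c(schedule_columns, "responder", "response")]
  utils::write.table(log, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read and validate a session log
#'
#' @param file Path written by [write_session_log()].
#' @param experiment Optional expected experiment; a mixed- or
#'   wrong-experiment log raises an error.
#' @return A data.frame of trials with responses.
#' @export
read_session_log <- function(file, experiment = NULL) {
  log <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c(schedule_columns, "responder", "response")
  missing <- setdiff(need, names(log))
  if (length(missing))
    stop("log is missing columns: ", paste(missing, collapse = ", "))
  exps <- unique(log$experiment)
  if (length(exps) != 1L)
    stop("log mixes experiments: ", paste(exps, collapse = ", "))
  if (!is.null(experiment) && exps != experiment)
    stop(sprintf("log is a '%s' experiment, expected '%s'", exps, experiment))
  if (exps == "heading") {
    log$response <- as.numeric(log$response)
    if (anyNA(log$response)) stop("non-numeric heading responses")
  } else {
    valid <- if (exps == "facing") c("left", "right")
             else c("forward", "backward")
    if (!all(log$response %in% valid))
      stop("invalid responses for a ", exps, " log")
  }
  log
}
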