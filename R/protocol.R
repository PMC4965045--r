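# Block-design experiment protocol: run schedules and the three
# experiment designs (subject-dependent ME, subject-dependent MI, and
# subject-independent transfer).

#' Create a block-design run schedule
#'
#' A run alternates rest and task blocks, starting and ending with rest
#' (`n_task_blocks` task blocks separated by `n_task_blocks + 1` rest
#' blocks; the default mirrors the standard six-task/seven-rest run).
#' Task blocks are labelled left/right hand in a balanced order that is
#' shuffled reproducibly by `seed`.
#'
#' @param n_task_blocks even number of task blocks (0 gives a single
#'   rest block).
#' @param task_type `"ME"` (motor execution) or `"MI"` (motor imagery).
#' @param task_dur_s,rest_dur_s block durations in seconds.
#' @param run_index position of the run within its experiment (1-based).
#' @param seed integer seed controlling the left/right order.
#' @return An object of class `run_spec`: a list with a `blocks` data
#'   frame (`kind`, `class`, `duration_s`, onset/offset times) plus
#'   `task_type`, `run_index` and `seed`.
#' @examples
#' spec <- make_run_spec(6, "ME", run_index = 1, seed = 7)
#' nrow(spec$blocks)                      # 13
#' table(spec$blocks$class)
#' @export
make_run_spec <- function(n_task_blocks = 6L, task_type = c("ME", "MI"),
                          task_dur_s = 20, rest_dur_s = 20,
                          run_index = 1L, seed = 1L) {
  task_type <- match.arg(task_type)
  if (!is_count(n_task_blocks, min = 0L)) {
    stop_invalid("`n_task_blocks` must be a non-negative count")
  }
  if (n_task_blocks %% 2L != 0L) {
    stop_invalid("`n_task_blocks` must be even so left/right labels balance")
  }
  if (!is_number(task_dur_s) || !is_number(rest_dur_s) ||
      task_dur_s <= 0 || rest_dur_s <= 0) {
    stop_invalid("block durations must be positive")
  }
  if (!is_count(run_index)) stop_invalid("`run_index` must be a count >= 1")

  n_task_blocks <- as.integer(n_task_blocks)
  if (n_task_blocks == 0L) {
    blocks <- data.frame(kind = "rest", class = "none",
                         duration_s = rest_dur_s)
  } else {
    labels <- rep(c("left", "right"), each = n_task_blocks / 2L)
    labels <- with_seed(seed, sample(labels))
    kind <- rep(c("rest", "task"), n_task_blocks)[seq_len(2L * n_task_blocks)]
    kind <- c(kind, "rest")
    cls <- rep("none", length(kind))
    cls[kind == "task"] <- labels
    blocks <- data.frame(
      kind = kind, class = cls,
      duration_s = ifelse(kind == "task", task_dur_s, rest_dur_s))
  }
  blocks$onset_s <- cumsum(c(0, blocks$duration_s[-nrow(blocks)]))
  blocks$offset_s <- blocks$onset_s + blocks$duration_s

  structure(list(blocks = blocks,
                 task_type = task_type,
                 run_index = as.integer(run_index),
                 seed = as.integer(seed)),
            class = "run_spec")
}

#' @export
print.run_spec <- function(x, ...) {
  cat(sprintf("<run_spec> run %d (%s): %d block(s), %g s total\n",
              x$run_index, x$task_type, nrow(x$blocks),
              sum(x$blocks$duration_s)))
  invisible(x)
}

run_duration <- function(spec) sum(spec$blocks$duration_s)

#' Serialize / restore a run schedule
#'
#' @param spec a `run_spec`.
#' @param json a JSON string produced by `run_spec_to_json`.
#' @return `run_spec_to_json` returns a JSON string; `run_spec_from_json`
#'   the reconstructed `run_spec`.
#' @export
run_spec_to_json <- function(spec) {
  jsonlite::toJSON(unclass(spec), digits = NA, auto_unbox = TRUE)
}

#' @rdname run_spec_to_json
#' @export
run_spec_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  obj$blocks <- as.data.frame(obj$blocks)
  obj$run_index <- as.integer(obj$run_index)
  obj$seed <- as.integer(obj$seed)
  structure(obj, class = "run_spec")
}

#' Experiment designs 1-3
#'
#' Returns the per-run task type, training/testing role and feedback
#' setting for the three experiment paradigms:
#' \describe{
#'   \item{1}{ME ME ME MI MI; runs 1-2 train the subject-dependent
#'     classifier, runs 3-5 are feedback test runs.}
#'   \item{2}{MI MI MI MI ME; run 1 trains, runs 2-5 are feedback test
#'     runs with between-run adaptation.}
#'   \item{3}{ME MI MI MI ME; the classifier is supplied externally
#'     (subject-independent) and feedback is on in every run; runs 2-5
#'     are scored.}
#' }
#'
#' @param experiment_id 1, 2 or 3.
#' @return An object of class `experiment_plan`: a list with `id` and a
#'   `runs` data frame (`run`, `task_type`, `role`, `feedback`).
#' @export
experiment_plan <- function(experiment_id) {
  if (!is_count(experiment_id) || !(experiment_id %in% 1:3)) {
    stop_invalid("`experiment_id` must be 1, 2 or 3")
  }
  experiment_id <- as.integer(experiment_id)
  runs <- switch(experiment_id,
    data.frame(run = 1:5,
               task_type = c("ME", "ME", "ME", "MI", "MI"),
               role = c("train", "train", "test", "test", "test"),
               feedback = c(FALSE, FALSE, TRUE, TRUE, TRUE)),
    data.frame(run = 1:5,
               task_type = c("MI", "MI", "MI", "MI", "ME"),
               role = c("train", "test", "test", "test", "test"),
               feedback = c(FALSE, TRUE, TRUE, TRUE, TRUE)),
    data.frame(run = 1:5,
               task_type = c("ME", "MI", "MI", "MI", "ME"),
               role = c("external", "test", "test", "test", "test"),
               feedback = c(TRUE, TRUE, TRUE, TRUE, TRUE)))
  structure(list(id = experiment_id, runs = runs), class = "experiment_plan")
}

#' @export
print.experiment_plan <- function(x, ...) {
  cat(sprintf("<experiment_plan> Experiment %d\n", x$id))
  print(x$runs)
  invisible(x)
}

#' @rdname run_spec_to_json
#' @param plan an `experiment_plan`.
#' @export
experiment_plan_to_json <- function(plan) {
  jsonlite::toJSON(unclass(plan), digits = NA, auto_unbox = TRUE)
}
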