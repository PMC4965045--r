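# Plain-text readers/writers (CSV + JSON sidecar) and the validated
# run configuration.

#' Write / read a run as CSV with a JSON sidecar
#'
#' `write_run` stores the sampled series as CSV (columns `time_s`,
#' `block`, `label`, then `chNN_hbo` and `chNN_hbr` in channel order,
#' full double precision) and the metadata -- sampling rate, layout
#' geometry and hash, generator parameters, seed, task type and block
#' schedule -- as `<path>.json`.  `read_run` reverses this losslessly to
#' within float text precision, rebuilding the layout from the sidecar
#' and validating the channel count against it.
#'
#' @param run a `run_data`.
#' @param path CSV file path; the sidecar is written next to it.
#' @return `write_run`: `path` invisibly; `read_run`: a `run_data`.
#' @export
write_run <- function(run, path) {
  stopifnot(inherits(run, "run_data"))
  df <- as.data.frame(run)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(col) sprintf("%.15g", col))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  sidecar <- list(
    fs = run$fs,
    task_type = run$task_type,
    seed = run$seed,
    run_index = run$run_index,
    layout = list(grid_rows = run$layout$grid_rows,
                  grid_cols = run$layout$grid_cols,
                  n_grids = run$layout$n_grids,
                  spacing_mm = run$layout$spacing_mm,
                  hash = layout_hash(run$layout),
                  n_channels = run$layout$n_channels),
    params = unclass(run$params),
    blocks = run$spec$blocks[, c("kind", "class", "duration_s")],
    active = run$active)
  writeLines(jsonlite::toJSON(sidecar, digits = NA, auto_unbox = TRUE,
                              pretty = TRUE),
             sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

#' @rdname write_run
#' @export
read_run <- function(path) {
  if (!file.exists(path)) stop_format("run file not found: ", path)
  if (!file.exists(sidecar_path(path))) {
    stop_format("missing metadata sidecar: ", sidecar_path(path))
  }
  meta <- jsonlite::fromJSON(sidecar_path(path))
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e) stop_format("malformed run CSV (", path,
                                                 "): ", conditionMessage(e)))
  if (nrow(df) == 0L) stop_format("run file is empty: ", path)
  need <- c("time_s", "block", "label")
  if (!all(need %in% names(df))) {
    stop_format("run CSV must start with columns ",
                paste(need, collapse = ", "))
  }
  nt <- meta$layout$n_channels
  hbo_cols <- sprintf("ch%02d_hbo", seq_len(nt))
  hbr_cols <- sprintf("ch%02d_hbr", seq_len(nt))
  missing <- setdiff(c(hbo_cols, hbr_cols), names(df))
  if (length(missing)) {
    stop_format("run CSV has ", sum(grepl("_hbo$", names(df))),
                " HbO channel column(s) but the sidecar declares ", nt,
                " channels (first missing: ", missing[1], ")")
  }
  layout <- build_checkerboard_layout(meta$layout$grid_rows,
                                      meta$layout$grid_cols,
                                      meta$layout$n_grids,
                                      meta$layout$spacing_mm)
  if (!identical(layout_hash(layout), meta$layout$hash)) {
    stop_format("layout hash mismatch between sidecar and rebuilt layout")
  }
  params <- do.call(hemo_params, meta$params)
  blocks <- as.data.frame(meta$blocks)
  spec <- make_run_spec(sum(blocks$kind == "task"),
                        meta$task_type,
                        task_dur_s = blocks$duration_s[match("task", blocks$kind)][1],
                        rest_dur_s = blocks$duration_s[1],
                        run_index = meta$run_index,
                        seed = meta$seed)
  # restore the exact recorded label order (the seed shuffle may differ)
  spec$blocks$class <- blocks$class
  spec$task_type <- meta$task_type
  structure(list(time_s = as.numeric(df$time_s),
                 kind = as.character(df$block),
                 label = as.character(df$label),
                 hbo = unname(as.matrix(df[hbo_cols])),
                 hbr = unname(as.matrix(df[hbr_cols])),
                 layout = layout, fs = meta$fs, task_type = meta$task_type,
                 spec = spec, params = params, seed = as.integer(meta$seed),
                 active = lapply(meta$active, as.integer),
                 run_index = as.integer(meta$run_index)),
            class = "run_data")
}

# -------- configuration ---------------------------------------------------

default_config <- function() {
  list(
    protocol = list(n_task_blocks = 6L, task_dur_s = 20, rest_dur_s = 20,
                    thermometer_levels = 20L),
    layout = list(grid_rows = 4L, grid_cols = 4L, n_grids = 2L,
                  spacing_mm = 25),
    hemo = unclass(hemo_params()),
    preproc = unclass(preproc_config()),
    selector = list(n_select = 12L),
    svm = list(c_param = 1),
    seeds = list(master = 1L)
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads a JSON configuration, fills every unset key from the defaults
#' (12 selected channels, 7.69 Hz, six 20 s task blocks with seven 20 s
#' rest blocks, 20 thermometer levels, 25 mm optode separation, unit SVM
#' penalty), rejects unknown keys, and validates values (even selector
#' size, positive durations, ...).  Passing `NULL` returns the full
#' defaults.
#'
#' @param path JSON file path, or `NULL`.
#' @return nested configuration list of class `bci_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_format("config file not found: ", path)
    user <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                     error = function(e) stop_format("config is not valid JSON: ",
                                                     conditionMessage(e)))
    bad <- setdiff(names(user), names(cfg))
    if (length(bad)) stop_format("unknown config section(s): ",
                                 paste(bad, collapse = ", "))
    for (sec in names(user)) {
      badkey <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
      if (length(badkey)) {
        stop_format("unknown key(s) in config section '", sec, "': ",
                    paste(badkey, collapse = ", "))
      }
      cfg[[sec]][names(user[[sec]])] <- user[[sec]]
    }
  }
  # validation (each failure names the key)
  v <- function(ok, key, msg) if (!ok) stop_format("config key '", key, "' ", msg)
  v(is_count(cfg$selector$n_select, 0L) && cfg$selector$n_select %% 2 == 0,
    "selector.n_select", "must be an even count (hemisphere balance)")
  v(is_number(cfg$protocol$task_dur_s) && cfg$protocol$task_dur_s > 0,
    "protocol.task_dur_s", "must be positive")
  v(is_number(cfg$protocol$rest_dur_s) && cfg$protocol$rest_dur_s > 0,
    "protocol.rest_dur_s", "must be positive")
  v(is_count(cfg$protocol$n_task_blocks, 0L) &&
      cfg$protocol$n_task_blocks %% 2 == 0,
    "protocol.n_task_blocks", "must be an even count")
  v(is_number(cfg$svm$c_param) && cfg$svm$c_param > 0,
    "svm.c_param", "must be positive")
  v(is_count(cfg$seeds$master, 0L), "seeds.master", "must be an integer")
  # full hemo validation by reconstruction
  cfg$hemo <- unclass(do.call(hemo_params, cfg$hemo))
  structure(cfg, class = "bci_config")
}
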