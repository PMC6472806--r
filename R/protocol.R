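# Timed stimulus sequencing. A protocol is an ordered list of stimuli, each
# with a duration, a start event fired once at its cumulative onset and an
# update event fired every clock tick while active. All tests run against a
# simulated clock (integer tick counter over an exact ticks-per-second rate)
# so transitions fall on exact multiples of the tick and two runs of the same
# protocol produce byte-identical logs. Every parameter read during a run is
# recorded, so the saved metadata tree provably contains everything that
# influenced the experiment.

#' Stimulus specification
#'
#' @param name stimulus name (used in logs).
#' @param duration seconds, > 0.
#' @param params flat named list of static parameters (physical units).
#' @param on_start optional `function(t, ctx)` fired once at onset.
#' @param on_update optional `function(t, t_local, ctx)` fired each tick
#'   while active; its named-list return value is logged as the stimulus's
#'   dynamic state. `ctx$estimator_sample` holds the latest estimator value.
#' @param dynamic flag marking a stimulus whose state changes between ticks.
#' @return an object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(name, duration, params = list(), on_start = NULL,
                          on_update = NULL, dynamic = !is.null(on_update)) {
  if (duration <= 0) stopf("stimulus duration must be > 0")
  structure(
    list(name = name, duration = duration, params = params,
         on_start = on_start, on_update = on_update, dynamic = dynamic),
    class = "stimulus_spec"
  )
}

#' A pause (blank screen) stimulus
#' @param duration seconds.
#' @return a `stimulus_spec`.
#' @export
pause_stimulus <- function(duration) {
  stimulus_spec("pause", duration)
}

#' Full-field flash stimulus
#' @param duration seconds.
#' @param color RGB triple, 0-255.
#' @return a `stimulus_spec`.
#' @export
flash_stimulus <- function(duration, color = c(255, 255, 255)) {
  stimulus_spec("flash", duration, params = list(color = color))
}

#' Closed-loop grating stimulus
#'
#' Each tick the grating velocity is computed from the latest estimator
#' sample (a fish velocity in mm/s) by the feedback law
#' [grating_velocity()], and logged.
#'
#' @param duration seconds.
#' @param base_velocity open-loop speed, mm/s.
#' @param spatial_frequency cycles/mm.
#' @param gain feedback gain.
#' @return a `stimulus_spec`.
#' @export
grating_stimulus <- function(duration, base_velocity = 10,
                             spatial_frequency = 0.1, gain = 1) {
  stimulus_spec(
    "grating", duration,
    params = list(base_velocity = base_velocity,
                  spatial_frequency = spatial_frequency, gain = gain),
    on_update = function(t, t_local, ctx) {
      v_fish <- ctx$estimator_sample
      if (is.null(v_fish) || is.na(v_fish)) v_fish <- 0
      list(velocity = grating_velocity(base_velocity, v_fish, gain))
    }
  )
}

#' Protocol specification
#' @param name protocol name.
#' @param stimuli non-empty list of [stimulus_spec()] objects.
#' @return an object of class `protocol_spec`.
#' @export
protocol_spec <- function(name, stimuli) {
  if (length(stimuli) == 0L) stopf("protocol needs at least one stimulus")
  stopifnot(all(vapply(stimuli, inherits, logical(1), "stimulus_spec")))
  structure(list(name = name, stimuli = stimuli), class = "protocol_spec")
}

#' Simulated clock
#'
#' Time advances as an exact integer tick counter over `fps` ticks per
#' second, so `t = k / fps` and transitions at whole-second boundaries are
#' exact in floating point.
#'
#' @param fps ticks per second.
#' @return an object of class `sim_clock`.
#' @export
sim_clock <- function(fps = 60) {
  structure(list(mode = "simulated", fps = fps, tick = 1 / fps),
            class = "sim_clock")
}

# --- parameter tree with access auditing -----------------------------------

#' Parameter tree with access recording
#'
#' Flat name -> value store; [pt_get()] records every key read so the
#' metadata audit can verify that each parameter that influenced a run is
#' present in the saved tree.
#'
#' @param values named list of parameter values.
#' @return an environment of class `param_tree`.
#' @export
param_tree <- function(values = list()) {
  e <- new.env(parent = emptyenv())
  e$values <- values
  e$accessed <- character(0)
  class(e) <- "param_tree"
  e
}

#' Read a parameter, recording the access
#' @param tree a [param_tree()].
#' @param key parameter name.
#' @param default value returned (and stored) when the key is absent.
#' @export
pt_get <- function(tree, key, default = NULL) {
  if (!key %in% names(tree$values)) {
    if (is.null(default)) stopf("parameter '%s' not set", key)
    tree$values[[key]] <- default
  }
  tree$accessed <- union(tree$accessed, key)
  tree$values[[key]]
}

#' @export
pt_set <- function(tree, key, value) {
  tree$values[[key]] <- value
  invisible(tree)
}

# --- combiners and conditionals --------------------------------------------

#' Present several stimuli simultaneously
#'
#' The composite's start and update fan out to all members in listed order;
#' each plain member's dynamic state is logged under `"<name>."`-prefixed
#' keys. Nested combiners pass their members' already-prefixed state through
#' unchanged, so combining is associative at the level of logs.
#'
#' @param stimuli non-empty list of [stimulus_spec()]s of equal duration.
#' @return a combined `stimulus_spec`.
#' @export
combine_stimuli <- function(stimuli) {
  if (length(stimuli) == 0L) stopf("cannot combine an empty stimulus list")
  if (length(stimuli) == 1L) return(stimuli[[1]])  # singleton identity
  durs <- vapply(stimuli, `[[`, numeric(1), "duration")
  if (length(unique(durs)) != 1L) {
    stopf("combined stimuli must share one duration")
  }
  params <- list()
  for (s in stimuli) {
    if (inherits(s, "combined_stimulus")) {
      params <- c(params, s$params)
    } else if (length(s$params)) {
      params <- c(params, stats::setNames(
        s$params, paste0(s$name, ".", names(s$params))))
    }
  }
  member_update <- function(s) {
    if (is.null(s$on_update)) return(NULL)
    if (inherits(s, "combined_stimulus")) return(s$on_update)
    function(t, t_local, ctx) {
      out <- s$on_update(t, t_local, ctx)
      if (length(out)) stats::setNames(out, paste0(s$name, ".", names(out)))
      else out
    }
  }
  updates <- Filter(Negate(is.null), lapply(stimuli, member_update))
  starts <- Filter(Negate(is.null), lapply(stimuli, `[[`, "on_start"))
  spec <- stimulus_spec(
    name = paste(vapply(stimuli, `[[`, character(1), "name"),
                 collapse = "+"),
    duration = durs[1], params = params,
    on_start = if (length(starts)) function(t, ctx) {
      for (f in starts) f(t, ctx)
    },
    on_update = if (length(updates)) function(t, t_local, ctx) {
      out <- list()
      for (f in updates) out <- c(out, f(t, t_local, ctx))
      out
    },
    dynamic = length(updates) > 0L
  )
  class(spec) <- c("combined_stimulus", class(spec))
  spec
}

prefix_params <- function(params, prefix) {
  if (length(params) == 0L) return(list())
  stats::setNames(params, paste0(prefix, ".", names(params)))
}

#' Behavior-dependent stimulus
#'
#' Each tick the predicate is evaluated on the latest estimator sample; the
#' active branch's update runs and the branch taken is logged. Requires an
#' estimator stream to be attached to the protocol run (checked at start).
#'
#' @param stimulus_if,stimulus_else the two branches (equal durations).
#' @param predicate `function(estimator_sample)` returning TRUE for the
#'   `stimulus_if` branch; must be pure per tick.
#' @return a conditional `stimulus_spec`.
#' @export
conditional_stimulus <- function(stimulus_if, stimulus_else, predicate) {
  if (stimulus_if$duration != stimulus_else$duration) {
    stopf("conditional branches must share one duration")
  }
  spec <- stimulus_spec(
    name = sprintf("if(%s)else(%s)", stimulus_if$name, stimulus_else$name),
    duration = stimulus_if$duration,
    params = c(prefix_params(stimulus_if$params, "if"),
               prefix_params(stimulus_else$params, "else")),
    on_update = function(t, t_local, ctx) {
      take_if <- isTRUE(predicate(ctx$estimator_sample))
      branch <- if (take_if) stimulus_if else stimulus_else
      out <- list(branch = if (take_if) "if" else "else")
      if (!is.null(branch$on_update)) {
        out <- c(out, branch$on_update(t, t_local, ctx))
      }
      out
    },
    dynamic = TRUE
  )
  spec$requires_estimator <- TRUE
  spec
}

# --- execution --------------------------------------------------------------

#' Run a protocol against a clock
#'
#' Stimuli execute in listed order. Stimulus k starts at the exact cumulative
#' onset time of the durations before it; its update fires on every tick in
#' `[onset, onset + duration)` — on a transition tick only the incoming
#' stimulus updates. A hook or update exception aborts the protocol; the
#' partial record is returned with `aborted = TRUE`.
#'
#' @param protocol a [protocol_spec()].
#' @param clock a [sim_clock()].
#' @param update_hook optional `function(t, ctx)` called every tick after the
#'   stimulus update.
#' @param estimator optional `function(t)` returning the current estimator
#'   sample (e.g. a fish velocity) at time `t`.
#' @param tree optional [param_tree()] collecting run metadata; one is
#'   created when absent.
#' @return an `experiment_record`: list with `metadata`, `stimulus_log`
#'   (data.frame), `estimator_log`, `tracking_log` (NULL here; filled by
#'   tracking pipelines) and `aborted`.
#' @export
run_protocol <- function(protocol, clock, update_hook = NULL,
                         estimator = NULL, tree = NULL) {
  stopifnot(inherits(protocol, "protocol_spec"), inherits(clock, "sim_clock"))
  needs_est <- any(vapply(protocol$stimuli, function(s) {
    isTRUE(s$requires_estimator)
  }, logical(1)))
  if (needs_est && is.null(estimator)) {
    stopf("protocol contains a conditional stimulus but no estimator stream")
  }
  if (is.null(tree)) tree <- param_tree()
  pt_set(tree, "protocol.name", protocol$name)
  pt_set(tree, "clock.mode", clock$mode)
  pt_set(tree, "clock.fps", clock$fps)
  for (i in seq_along(protocol$stimuli)) {
    s <- protocol$stimuli[[i]]
    pt_set(tree, sprintf("stimulus.%02d.name", i), s$name)
    pt_set(tree, sprintf("stimulus.%02d.duration", i), s$duration)
    for (p in names(s$params)) {
      pt_set(tree, sprintf("stimulus.%02d.%s", i, p), s$params[[p]])
    }
  }

  durs <- vapply(seq_along(protocol$stimuli), function(i) {
    pt_get(tree, sprintf("stimulus.%02d.duration", i))
  }, numeric(1))
  onsets <- c(0, cumsum(durs))
  total <- onsets[length(onsets)]
  fps <- pt_get(tree, "clock.fps")
  n_ticks <- as.integer(round(total * fps))

  stim_rows <- vector("list", n_ticks + length(durs) + 1L)
  est_rows <- vector("list", n_ticks)
  nrow_used <- 0L
  add_row <- function(row) {
    nrow_used <<- nrow_used + 1L
    stim_rows[[nrow_used]] <<- row
  }
  started <- logical(length(durs))
  aborted <- FALSE
  abort_msg <- NULL
  ctx <- new.env(parent = emptyenv())

  run_loop <- function() {
    for (k in 0:(n_ticks - 1L)) {
      t <- k / fps
      active <- findInterval(t, onsets, rightmost.closed = FALSE)
      if (active < 1L || active > length(durs)) next
      s <- protocol$stimuli[[active]]
      ctx$estimator_sample <- if (!is.null(estimator)) estimator(t) else NULL
      if (!started[active]) {
        started[active] <<- TRUE
        if (!is.null(s$on_start)) s$on_start(t, ctx)
        add_row(c(list(t = t, stimulus = s$name, event = "start"), list()))
      }
      dyn <- if (!is.null(s$on_update)) s$on_update(t, t - onsets[active], ctx)
             else NULL
      add_row(c(list(t = t, stimulus = s$name, event = "update"),
                if (length(dyn)) dyn else list()))
      if (!is.null(ctx$estimator_sample)) {
        est_rows[[k + 1L]] <<- list(t = t, value = ctx$estimator_sample)
      }
      if (!is.null(update_hook)) update_hook(t, ctx)
    }
    add_row(list(t = total, stimulus = "<protocol>", event = "end"))
  }
  tryCatch(run_loop(), error = function(e) {
    aborted <<- TRUE
    abort_msg <<- conditionMessage(e)
  })

  stimulus_log <- rows_to_df(stim_rows[seq_len(nrow_used)])
  estimator_log <- rows_to_df(Filter(Negate(is.null), est_rows))
  pt_set(tree, "software.version",
         as.character(utils::packageVersion("fishtrack")))
  structure(
    list(metadata = list(params = tree$values,
                         accessed_params = sort(tree$accessed),
                         version = as.character(
                           utils::packageVersion("fishtrack")),
                         aborted = aborted, abort_message = abort_msg),
         stimulus_log = stimulus_log,
         estimator_log = estimator_log,
         tracking_log = NULL,
         aborted = aborted),
    class = "experiment_record"
  )
}

# Bind heterogeneous log rows (named lists) into one data.frame, filling
# missing columns with NA and flattening length > 1 values to strings.
rows_to_df <- function(rows) {
  if (length(rows) == 0L) return(data.frame(t = numeric(0)))
  cols <- unique(unlist(lapply(rows, names)))
  out <- lapply(cols, function(cn) {
    vals <- lapply(rows, function(r) {
      v <- r[[cn]]
      if (is.null(v)) NA
      else if (length(v) > 1L) paste(v, collapse = ";")
      else v
    })
    unlist(vals)
  })
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE)
}

# --- persistence ------------------------------------------------------------

#' Save an experiment record
#'
#' Writes `metadata.json` plus one table per log into `path`. CSV keeps 15
#' significant digits (round trip within 1e-12 relative); HDF5 is lossless.
#'
#' @param record an `experiment_record`.
#' @param path output directory (created; must be writable).
#' @param format `"csv"` or `"hdf5"`.
#' @return invisibly, the vector of files written.
#' @export
save_record <- function(record, path, format = c("csv", "hdf5")) {
  format <- match.arg(format)
  stopifnot(inherits(record, "experiment_record"))
  ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path) || file.access(path, mode = 2) != 0) {
    stopf("output path '%s' is not writable", path)
  }
  files <- character(0)
  meta_file <- file.path(path, "metadata.json")
  jsonlite::write_json(record$metadata, meta_file, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  files <- c(files, meta_file)
  logs <- c("stimulus_log", "estimator_log", "tracking_log")
  present <- logs[vapply(logs, function(l) {
    !is.null(record[[l]]) && nrow(record[[l]]) > 0L
  }, logical(1))]
  if (format == "csv") {
    for (l in present) {
      f <- file.path(path, paste0(l, ".csv"))
      data.table::fwrite(record[[l]], f)
      files <- c(files, f)
    }
  } else {
    f <- file.path(path, "logs.h5")
    if (file.exists(f)) unlink(f)
    rhdf5::h5createFile(f)
    for (l in present) {
      df <- record[[l]]
      for (cn in names(df)) if (is.logical(df[[cn]])) {
        df[[cn]] <- as.integer(df[[cn]])
      }
      rhdf5::h5write(df, f, l)
    }
    rhdf5::h5closeAll()
    files <- c(files, f)
  }
  invisible(files)
}

#' Reload a saved experiment record
#' @param path directory written by [save_record()].
#' @param format `"csv"` or `"hdf5"`.
#' @return an `experiment_record`.
#' @export
load_record <- function(path, format = c("csv", "hdf5")) {
  format <- match.arg(format)
  meta <- jsonlite::read_json(file.path(path, "metadata.json"),
                              simplifyVector = TRUE)
  out <- list(metadata = meta, stimulus_log = NULL, estimator_log = NULL,
              tracking_log = NULL, aborted = isTRUE(meta$aborted))
  if (format == "csv") {
    for (l in c("stimulus_log", "estimator_log", "tracking_log")) {
      f <- file.path(path, paste0(l, ".csv"))
      if (file.exists(f)) out[[l]] <- as.data.frame(data.table::fread(f))
    }
  } else {
    f <- file.path(path, "logs.h5")
    if (file.exists(f)) {
      for (l in rhdf5::h5ls(f)$name) {
        df <- rhdf5::h5read(f, l)
        # rhdf5 decorates columns with a dim attribute; strip it
        for (cn in names(df)) df[[cn]] <- as.vector(df[[cn]])
        out[[l]] <- df
      }
      rhdf5::h5closeAll()
    }
  }
  structure(out, class = "experiment_record")
}
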