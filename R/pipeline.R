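#' @section Pipeline architecture:
#' Messages flow from a source module to a sink in a feed-forward chain.
#' Each message carries a frame id (strictly increasing per run), a capture
#' timestamp from a monotonic millisecond clock, an optional raster image and
#' a flat key-value data map with namespaced keys (`pose.*`, `au.*`,
#' `camera.*`, `timing.*`, `avatar.*`). Modules may overlap in time on
#' different messages; the engine realises that contract as a deterministic
#' discrete-event simulation with per-module processing durations, so runs
#' are exactly reproducible under a simulated clock.
#' @name mirrorkit-pipeline
NULL

.registry <- new.env(parent = emptyenv())

spec_error <- function(msg) {
  stop(errorCondition(msg, class = c("mirror_spec_error", "error", "condition")))
}

config_error <- function(msg) {
  stop(errorCondition(msg, class = c("mirror_config_error", "error", "condition")))
}

#' Register a pipeline module type
#'
#' A module type is a named factory. The factory receives the parameter map
#' from the pipeline spec line and returns an instance: a list with `type`,
#' a `process(msg, now)` function (sources instead provide `emit(frame_id,
#' now)`), and optionally `proc_ms` (numeric vector of simulated processing
#' durations, cycled per message). Instances may keep state in their closure.
#'
#' @param type Type tag used in pipeline spec files.
#' @param factory `function(params)` returning a module instance.
#' @param role `"source"`, `"transform"` or `"sink"`.
#' @export
register_module_type <- function(type, factory, role = "transform") {
  stopifnot(is.character(type), is.function(factory))
  assign(type, list(factory = factory, role = role), envir = .registry)
  invisible(type)
}

#' @rdname register_module_type
#' @export
registered_module_types <- function() sort(ls(.registry))

module_role <- function(type) get(type, envir = .registry)$role

#' Parse a pipeline specification
#'
#' One module per line, whitespace-separated `type key=value ...`; `#` starts
#' a comment; blank lines are ignored. Values that parse as numbers become
#' numeric, `true`/`false` become logical, anything else stays a string;
#' unknown keys are preserved verbatim for the module factory.
#'
#' @param text Spec file contents (single string or character vector of lines).
#' @return A `pipeline_spec`: ordered list of descriptors `list(type, params)`.
#' @export
parse_pipeline_spec <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  descriptors <- list()
  for (ln in seq_along(lines)) {
    line <- sub("#.*$", "", lines[ln])
    line <- trimws(line)
    if (!nzchar(line)) next
    tokens <- strsplit(line, "[[:space:]]+")[[1]]
    type <- tokens[1]
    if (!exists(type, envir = .registry)) {
      spec_error(sprintf("line %d: unknown module type '%s' (registered: %s)",
                         ln, type, paste(registered_module_types(), collapse = ", ")))
    }
    params <- list()
    for (tok in tokens[-1]) {
      kv <- strsplit(tok, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2 || !nzchar(kv[1]))
        spec_error(sprintf("line %d: malformed parameter '%s' (expected key=value)", ln, tok))
      params[[kv[1]]] <- parse_param_value(kv[2])
    }
    descriptors[[length(descriptors) + 1]] <- list(type = type, params = params, line = ln)
  }
  if (!length(descriptors)) spec_error("empty pipeline specification")
  if (module_role(descriptors[[1]]$type) != "source")
    spec_error(sprintf("first module '%s' is not a source", descriptors[[1]]$type))
  structure(descriptors, class = "pipeline_spec")
}

parse_param_value <- function(v) {
  num <- suppressWarnings(as.numeric(v))
  if (!is.na(num)) return(num)
  if (tolower(v) %in% c("true", "false")) return(tolower(v) == "true")
  v
}

#' @export
print.pipeline_spec <- function(x, ...) {
  cat("<pipeline_spec> with", length(x), "modules\n")
  for (d in x) {
    p <- if (length(d$params))
      paste(names(d$params), unlist(lapply(d$params, format)), sep = "=", collapse = " ")
    else ""
    cat(sprintf("  %-12s %s\n", d$type, p))
  }
  invisible(x)
}

build_modules <- function(spec) {
  lapply(seq_along(spec), function(i) {
    d <- spec[[i]]
    entry <- get(d$type, envir = .registry)
    mod <- entry$factory(d$params)
    mod$type <- d$type
    mod$name <- mod$name %||% if (sum(vapply(spec, function(x) x$type, "") == d$type) > 1)
      paste0(d$type, i) else d$type
    mod$role <- entry$role
    if (is.null(mod$proc_ms)) mod$proc_ms <- parse_proc_ms(d$params$proc_ms)
    mod
  })
}

parse_proc_ms <- function(p) {
  if (is.null(p)) return(0)
  if (is.character(p)) p <- as.numeric(strsplit(p, ",", fixed = TRUE)[[1]])
  if (any(is.na(p)) || any(p < 0)) spec_error("proc_ms must be non-negative numbers")
  p
}

#' Run a pipeline on synthetic messages
#'
#' Drives `n_messages` messages from the source through every module of the
#' pipeline under the injected clock and returns a run report. Source frames
#' are emitted at the source's frame interval; each downstream module starts
#' a message as soon as both the message has arrived and the module is free,
#' so modules overlap in (simulated) time. When a module is slower than its
#' upstream, the `"latest"` drop policy keeps only the most recent pending
#' message per edge (a mirror must show the freshest frame), while
#' `"queue"` processes every message.
#'
#' @param spec A `pipeline_spec` (or spec text, parsed on the fly).
#' @param n_messages Number of messages to emit.
#' @param drop Drop policy: `"latest"` (default) or `"queue"`.
#' @param clock A [sim_clock()] or [monotonic_clock()].
#' @return A `mirror_run_report`: list with `emitted`, `delivered`, `dropped`
#'   counts, `messages` (delivered messages with `delivery_time`),
#'   `durations` (per-module numeric vectors over processed messages),
#'   `modules`, `fps`, and `failed_module`/`error` if a module raised.
#' @export
run_pipeline <- function(spec, n_messages, drop = c("latest", "queue"),
                         clock = sim_clock()) {
  if (is.character(spec)) spec <- parse_pipeline_spec(spec)
  stopifnot(inherits(spec, "pipeline_spec"), n_messages >= 1)
  drop <- match.arg(drop)
  mods <- build_modules(spec)
  source_mod <- mods[[1]]
  fps <- source_mod$fps %||% 120
  interval <- 1000 / fps

  durations <- stats::setNames(
    lapply(mods, function(m) numeric(0)),
    vapply(mods, function(m) m$name, "")
  )
  failed <- NULL; err_msg <- NULL

  # stage 0: emissions
  t0 <- clock_now(clock)
  current <- vector("list", n_messages)
  for (i in seq_len(n_messages)) {
    now <- t0 + (i - 1) * interval
    clock_set(clock, now)
    msg <- source_mod$emit(i - 1L, now)
    dur <- cycle_proc(source_mod, i)
    msg$data[[paste0("timing.", source_mod$name, "_ms")]] <- dur
    durations[[source_mod$name]][i] <- dur
    current[[i]] <- list(msg = msg, t = now + dur)
  }
  emitted <- n_messages
  dropped <- 0L

  # downstream stages: event-driven per edge with the chosen drop policy
  for (j in seq_along(mods)[-1]) {
    mod <- mods[[j]]
    out <- vector("list", length(current))
    n_out <- 0L
    free_at <- -Inf
    pending <- NULL
    k <- 0L  # processed-message counter for this module

    start_one <- function(entry, start) {
      k <<- k + 1L
      # `start` is the simulated processing start; modules receive it as `now`
      msg <- tryCatch(mod$process(entry$msg, start), error = function(e) e)
      if (inherits(msg, "error")) {
        failed <<- mod$name; err_msg <<- conditionMessage(msg)
        return(NULL)
      }
      dur <- cycle_proc(mod, k)
      msg$data[[paste0("timing.", mod$name, "_ms")]] <- dur
      durations[[mod$name]][k] <<- dur
      free_at <<- start + dur
      n_out <<- n_out + 1L
      out[[n_out]] <<- list(msg = msg, t = start + dur)
      msg
    }

    for (entry in current) {
      if (!is.null(failed)) break
      a <- entry$t
      if (!is.null(pending)) {
        start <- max(pending$t, free_at)
        if (start <= a) {            # module frees up before this arrival
          start_one(pending, start)
          pending <- NULL
        }
      }
      if (!is.null(failed)) break
      if (is.null(pending) && free_at <= a) {
        start_one(entry, a)
      } else if (drop == "queue") {
        # FIFO: process in order as the module frees up
        if (!is.null(pending)) start_one(pending, max(pending$t, free_at))
        pending <- entry
      } else if (is.null(pending)) {
        pending <- entry
      } else {                       # latest-wins: overwrite the pending slot
        dropped <- dropped + 1L
        pending <- entry
      }
    }
    if (!is.null(pending) && is.null(failed)) start_one(pending, max(pending$t, free_at))
    current <- out[seq_len(n_out)]
    if (!is.null(failed)) break
  }

  messages <- lapply(current, function(e) {
    m <- e$msg
    m$delivery_time <- e$t
    m
  })
  structure(list(
    emitted = emitted,
    delivered = length(messages),
    dropped = emitted - length(messages),
    dropped_by_policy = dropped,
    messages = messages,
    durations = durations,
    modules = vapply(mods, function(m) m$name, ""),
    fps = fps,
    drop = drop,
    failed_module = failed,
    error = err_msg
  ), class = "mirror_run_report")
}

cycle_proc <- function(mod, k) {
  p <- mod$proc_ms
  p[(k - 1L) %% length(p) + 1L]
}

#' @export
print.mirror_run_report <- function(x, ...) {
  cat("<mirror_run_report>", x$emitted, "emitted,", x$delivered, "delivered,",
      x$dropped, "dropped (policy:", x$drop, ")\n")
  if (!is.null(x$failed_module))
    cat("  FAILED in module", x$failed_module, ":", x$error, "\n")
  invisible(x)
}

#' Per-module timing statistics of a run
#'
#' The duration a message spends in each module's process step, summarised as
#' mean and SD per module, plus the pipeline total (delivery time minus
#' capture time, over delivered messages). SD is 0 when only one message was
#' processed.
#'
#' @param report A `mirror_run_report` with at least one delivered message.
#' @return A `mirror_timing`: list with `per_module` (`data.frame` of module,
#'   n, mean_ms, sd_ms) and `pipeline` (n, mean_ms, sd_ms of totals).
#' @export
module_timing <- function(report) {
  stopifnot(inherits(report, "mirror_run_report"))
  if (report$delivered < 1) stop("run report contains no delivered messages")
  per <- do.call(rbind, lapply(names(report$durations), function(nm) {
    d <- report$durations[[nm]]
    data.frame(module = nm, n = length(d),
               mean_ms = if (length(d)) mean(d) else NA_real_,
               sd_ms = if (length(d) > 1) stats::sd(d) else 0)
  }))
  totals <- vapply(report$messages, function(m) m$delivery_time - m$capture_time,
                   numeric(1))
  structure(list(
    per_module = per,
    pipeline = c(n = length(totals), mean_ms = mean(totals),
                 sd_ms = if (length(totals) > 1) stats::sd(totals) else 0)
  ), class = "mirror_timing")
}

#' @export
print.mirror_timing <- function(x, ...) {
  print(x$per_module, row.names = FALSE)
  cat(sprintf("pipeline total: mean %.2f ms, sd %.2f ms over %d messages\n",
              x$pipeline[["mean_ms"]], x$pipeline[["sd_ms"]], x$pipeline[["n"]]))
  invisible(x)
}

#' Export run timing as CSV or JSON
#' @param timing A `mirror_timing` from [module_timing()].
#' @param path Output path; format inferred from the extension unless given.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(timing, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "csv") {
    utils::write.csv(timing$per_module, path, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(
      list(per_module = timing$per_module, pipeline = as.list(timing$pipeline)),
      path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}
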