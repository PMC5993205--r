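# Dependency-resolving task engine with durable persistence.
#
# Workflows are acyclic graphs of named modules. Acquisition modules touch
# the (single) microscope and are serialised behind a hardware lock;
# compute modules may run concurrently. The engine executes tasks in
# deterministic scheduling waves (a virtual-time model of concurrency: one
# wave holds at most one acquisition task plus up to `workers` compute
# tasks), persisting every status transition, so an interrupted run resumes
# without repeating completed work.
#
# The store is a single JSON state file (schema: workflows, modules, tasks,
# task_parents, runs) written atomically via rename, plus an append-only
# log. Status lifecycle: NEW -> IN_PROGRESS -> {SUCCESS, ERROR, DEFER};
# DEFER may re-enter IN_PROGRESS after acknowledgement; SUCCESS is terminal.

TASK_STATUSES <- c("NEW", "IN_PROGRESS", "SUCCESS", "ERROR", "DEFER")

#' Describe a workflow module
#'
#' @param name Unique module name within the workflow.
#' @param kind `"acquisition"` (serialised behind the hardware lock) or
#'   `"compute"` (runs concurrently up to the worker limit).
#' @param entry Name of a registered entry function (see
#'   [register_module_entry()]).
#' @param config Named list of configuration values (JSON-serialisable).
#' @export
wf_module <- function(name, kind = c("compute", "acquisition"), entry,
                      config = list()) {
  kind <- match.arg(kind)
  structure(list(name = name, kind = kind, entry = entry, config = config),
            class = "sf_module")
}

#' Assemble a workflow graph
#'
#' @param modules List of [wf_module()] with unique names.
#' @param edges Data frame with `parent`, `child` module-name columns.
#' @param entry_points Named list of character vectors; each entry point
#'   names the modules execution starts from (their descendants run too).
#' @export
wf_graph <- function(modules, edges = data.frame(parent = character(),
                                                 child = character()),
                     entry_points = list(all = vapply(modules, `[[`, "", "name"))) {
  names(modules) <- vapply(modules, `[[`, "", "name")
  if (anyDuplicated(names(modules)))
    sf_stop("sf_workflow_error", "module names must be unique")
  g <- structure(list(modules = modules,
                      edges = data.frame(parent = as.character(edges$parent),
                                         child = as.character(edges$child)),
                      entry_points = entry_points),
                 class = "sf_workflow_graph")
  validate_graph(g)
  g
}

validate_graph <- function(g) {
  nm <- names(g$modules)
  bad <- setdiff(unique(c(g$edges$parent, g$edges$child)), nm)
  if (length(bad))
    sf_stop("sf_workflow_error", "edge references missing module(s): %s",
            paste(bad, collapse = ", "))
  if (any(!vapply(g$entry_points, length, 1L)))
    sf_stop("sf_workflow_error", "entry points must be non-empty")
  bad_ep <- setdiff(unlist(g$entry_points), nm)
  if (length(bad_ep))
    sf_stop("sf_workflow_error", "entry point references missing module(s): %s",
            paste(bad_ep, collapse = ", "))
  topo_sort(g)     # errors on cycles
  invisible(g)
}

# Kahn's algorithm; reports a cycle if one exists
topo_sort <- function(g) {
  nm <- names(g$modules)
  indeg <- stats::setNames(integer(length(nm)), nm)
  for (ch in g$edges$child) indeg[ch] <- indeg[ch] + 1L
  queue <- nm[indeg == 0L]
  out <- character(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    kids <- g$edges$child[g$edges$parent == v]
    for (ch in kids) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < length(nm))
    sf_stop("sf_workflow_error", "workflow graph contains a cycle through: %s",
            paste(setdiff(nm, out), collapse = " -> "))
  out
}

#' Open (or create) a workflow store
#'
#' @param path Storage root directory; created if missing.
#' @return A store handle (environment caching the state).
#' @export
wf_store <- function(path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  st <- new.env(parent = emptyenv())
  st$path <- normalizePath(path)
  st$file <- file.path(st$path, "store.json")
  if (file.exists(st$file)) {
    st$state <- tryCatch(
      jsonlite::fromJSON(st$file, simplifyDataFrame = FALSE, simplifyVector = FALSE),
      error = function(e)
        sf_stop("sf_store_error", "unrecoverable store at %s: %s", st$file,
                conditionMessage(e)))
  } else {
    st$state <- list(workflows = list(), tasks = list(), runs = list(),
                     next_task_id = 1L, next_run_id = 1L)
    store_save(st)
  }
  class(st) <- "sf_store"
  st
}

store_save <- function(st) {
  tmp <- paste0(st$file, ".tmp")
  jsonlite::write_json(st$state, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  file.rename(tmp, st$file)
  invisible(st)
}

store_log <- function(st, msg) {
  cat(sprintf("[%s] %s\n", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg),
      file = file.path(st$path, "run.log"), append = TRUE)
}

#' Stable digest of a parameter list
#'
#' md5 of the canonical (recursively key-sorted) JSON encoding.
#' @param x A JSON-serialisable list.
#' @export
params_digest <- function(x) {
  canon <- function(v) {
    if (is.list(v) && !is.null(names(v))) {
      v <- v[order(names(v))]
      lapply(v, canon)
    } else if (is.list(v)) lapply(v, canon) else v
  }
  tf <- tempfile()
  on.exit(unlink(tf))
  jsonlite::write_json(canon(x), tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

graph_to_list <- function(g) {
  list(modules = lapply(unname(g$modules), unclass),
       edges = list(parent = as.list(g$edges$parent),
                    child = as.list(g$edges$child)),
       entry_points = g$entry_points)
}

list_to_graph <- function(l) {
  mods <- lapply(l$modules, function(m)
    wf_module(m$name, m$kind, m$entry, if (is.null(m$config)) list() else m$config))
  edges <- if (length(l$edges$parent))
    data.frame(parent = unlist(l$edges$parent), child = unlist(l$edges$child))
  else data.frame(parent = character(), child = character())
  eps <- lapply(l$entry_points, function(e) unlist(e))
  wf_graph(mods, edges, eps)
}

#' Persist a workflow graph
#'
#' The graph, module configurations and entry points are durably written;
#' re-opening the store reconstructs an equal graph. Cyclic graphs are
#' rejected with an error listing the cycle.
#'
#' @param graph An [wf_graph()].
#' @param store An [wf_store()].
#' @return The stored workflow id (character).
#' @export
wf_persist <- function(graph, store) {
  validate_graph(graph)
  gl <- graph_to_list(graph)
  digest <- params_digest(gl)
  wid <- sprintf("wf_%s", substr(digest, 1, 12))
  store$state$workflows[[wid]] <- c(gl, list(digest = digest))
  store_save(store)
  store_log(store, sprintf("persisted workflow %s (%d modules)", wid,
                           length(graph$modules)))
  wid
}

#' Load a persisted workflow graph
#' @param store An [wf_store()].
#' @param workflow_id Id returned by [wf_persist()].
#' @export
wf_load_graph <- function(store, workflow_id) {
  wl <- store$state$workflows[[workflow_id]]
  if (is.null(wl))
    sf_stop("sf_store_error", "workflow %s not found in store", workflow_id)
  list_to_graph(wl)
}

# modules included by an entry point: the named modules plus descendants
entry_closure <- function(g, entry_point) {
  if (!entry_point %in% names(g$entry_points))
    sf_stop("sf_workflow_error", "unknown entry point '%s'", entry_point)
  seeds <- g$entry_points[[entry_point]]
  seen <- character(0); queue <- seeds
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (v %in% seen) next
    seen <- c(seen, v)
    queue <- c(queue, g$edges$child[g$edges$parent == v])
  }
  intersect(topo_sort(g), seen)    # topological order
}

#' Task table of a store
#' @param store An [wf_store()].
#' @return A data frame with one row per task.
#' @export
wf_tasks <- function(store) {
  ts <- store$state$tasks
  if (!length(ts))
    return(data.frame(task_id = integer(), workflow_id = character(),
                      module = character(), slide_id = character(),
                      params_digest = character(), status = character(),
                      run_id = integer(), result_uri = character(),
                      created = character(), updated = character()))
  do.call(rbind, lapply(ts, function(t)
    data.frame(task_id = t$task_id, workflow_id = t$workflow_id,
               module = t$module, slide_id = t$slide_id,
               params_digest = t$params_digest, status = t$status,
               run_id = if (is.null(t$run_id)) NA_integer_ else t$run_id,
               result_uri = if (is.null(t$result_uri)) NA_character_ else t$result_uri,
               created = t$created, updated = t$updated)))
}

task_parents_of <- function(store, task_id) {
  t <- store$state$tasks[[as.character(task_id)]]
  if (is.null(t$parent_ids)) integer(0) else unlist(t$parent_ids)
}

set_task <- function(store, task_id, status = NULL, run_id = NULL,
                     result_uri = NULL) {
  key <- as.character(task_id)
  t <- store$state$tasks[[key]]
  if (!is.null(status)) {
    ok <- switch(t$status,
                 NEW = status %in% c("IN_PROGRESS"),
                 IN_PROGRESS = status %in% c("SUCCESS", "ERROR", "DEFER"),
                 DEFER = status %in% c("IN_PROGRESS"),
                 ERROR = status %in% c("IN_PROGRESS", "NEW"),
                 SUCCESS = FALSE)
    if (!isTRUE(ok) && status != t$status)
      sf_stop("sf_workflow_error", "illegal status transition %s -> %s for task %d",
              t$status, status, task_id)
    t$status <- status
  }
  if (!is.null(run_id)) t$run_id <- run_id
  if (!is.null(result_uri)) t$result_uri <- result_uri
  t$updated <- format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3")
  store$state$tasks[[key]] <- t
  store_save(store)
  store_log(store, sprintf("task %d (%s/%s) -> %s", t$task_id, t$module,
                           t$slide_id, t$status))
  invisible(t)
}

# create (or reuse) the task set for (workflow, entry point, slide set)
ensure_tasks <- function(store, workflow_id, graph, entry_point, slide_ids) {
  mods <- entry_closure(graph, entry_point)
  existing <- wf_tasks(store)
  made <- list()   # name -> slide -> id map for parent wiring
  for (m in mods) for (s in slide_ids) {
    hit <- existing[existing$workflow_id == workflow_id &
                    existing$module == m & existing$slide_id == s, ]
    if (nrow(hit)) { made[[m]][[s]] <- hit$task_id[1]; next }
    id <- store$state$next_task_id
    store$state$next_task_id <- id + 1L
    parents <- graph$edges$parent[graph$edges$child == m]
    parents <- intersect(parents, mods)
    pids <- unlist(lapply(parents, function(p) made[[p]][[s]]))
    store$state$tasks[[as.character(id)]] <- list(
      task_id = id, workflow_id = workflow_id, module = m, slide_id = s,
      params_digest = params_digest(list(module = graph$modules[[m]]$config,
                                         slide = s)),
      status = "NEW", parent_ids = as.list(pids),
      run_id = NULL, result_uri = NULL,
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3"),
      updated = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3"))
    made[[m]][[s]] <- id
  }
  store_save(store)
  invisible(made)
}

#' Dispatch a workflow
#'
#' Creates one task per (module, slide) reachable from the entry point and
#' executes them in dependency order: a child starts only after all its
#' parents succeed. At most one acquisition task is in progress at any
#' instant (the hardware lock); compute tasks run up to `workers` at a time
#' within a scheduling wave. A failing task marks its record `ERROR`,
#' leaves its descendants `NEW`, and lets independent branches continue.
#'
#' @param store An [wf_store()].
#' @param workflow_id Id from [wf_persist()].
#' @param entry_point Name of the entry point to start from.
#' @param slide_ids Character vector: the unit-of-work identifiers.
#' @param workers Maximum concurrent compute tasks per wave.
#' @param ctx Named list passed to every entry function (configuration,
#'   pool handles, counters...). `ctx$interrupt_after`, if set, aborts the
#'   run after that many task completions (used to exercise crash recovery).
#' @return A run log: list with `run_id`, `schedule` (data frame of task,
#'   wave, kind), and `summary` (status counts).
#' @export
wf_dispatch <- function(store, workflow_id, entry_point, slide_ids,
                        workers = 2L, ctx = list()) {
  graph <- wf_load_graph(store, workflow_id)
  ensure_tasks(store, workflow_id, graph, entry_point, slide_ids)
  run_loop(store, workflow_id, graph, entry_point, workers, ctx)
}

#' Resume an interrupted workflow
#'
#' Tasks already `SUCCESS` are not re-executed; `IN_PROGRESS` tasks owned
#' by a dead run are reset to `NEW` (ownership, not timeouts, detects
#' staleness); `ERROR` tasks are retried. Completion yields a task table
#' whose SUCCESS set equals an uninterrupted run with the same seeds.
#'
#' @inheritParams wf_dispatch
#' @export
wf_resume <- function(store, workflow_id, entry_point, slide_ids,
                      workers = 2L, ctx = list()) {
  graph <- wf_load_graph(store, workflow_id)
  ensure_tasks(store, workflow_id, graph, entry_point, slide_ids)
  tt <- wf_tasks(store)
  stale <- tt$task_id[tt$status == "IN_PROGRESS"]
  for (id in stale) {
    t <- store$state$tasks[[as.character(id)]]
    t$status <- "NEW"; t$run_id <- NULL
    store$state$tasks[[as.character(id)]] <- t
  }
  for (id in tt$task_id[tt$status == "ERROR"]) {
    t <- store$state$tasks[[as.character(id)]]
    t$status <- "NEW"
    store$state$tasks[[as.character(id)]] <- t
  }
  if (length(stale)) store_log(store, sprintf("reset %d stale task(s): %s",
                                              length(stale),
                                              paste(stale, collapse = ",")))
  store_save(store)
  run_loop(store, workflow_id, graph, entry_point, workers, ctx)
}

run_loop <- function(store, workflow_id, graph, entry_point, workers, ctx) {
  ctx$store <- store
  run_id <- store$state$next_run_id
  store$state$next_run_id <- run_id + 1L
  store$state$runs[[as.character(run_id)]] <-
    list(run_id = run_id, workflow_id = workflow_id, entry_point = entry_point,
         started = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3"))
  store_save(store)
  mods <- entry_closure(graph, entry_point)
  kind_of <- vapply(graph$modules, `[[`, "", "kind")
  schedule <- data.frame(task_id = integer(), wave = integer(),
                         kind = character(), module = character(),
                         status = character())
  wave <- 0L
  completed <- 0L
  interrupted <- FALSE
  repeat {
    tt <- wf_tasks(store)
    tt <- tt[tt$workflow_id == workflow_id & tt$module %in% mods, ]
    runnable <- tt$status == "NEW" |
      (tt$status == "DEFER" & vapply(tt$task_id, function(id)
        isTRUE(store$state$tasks[[as.character(id)]]$acknowledged), TRUE))
    ready <- tt[runnable & vapply(tt$task_id, function(id) {
      ps <- task_parents_of(store, id)
      !length(ps) || all(tt$status[match(ps, tt$task_id)] == "SUCCESS")
    }, TRUE), ]
    if (nrow(ready) == 0) break
    ready <- ready[order(ready$task_id), ]
    k <- kind_of[ready$module]
    acq <- ready$task_id[k == "acquisition"][1]        # hardware lock: <= 1
    cmp <- utils::head(ready$task_id[k == "compute"], workers)
    batch <- c(if (!is.na(acq)) acq, cmp)
    if (!length(batch)) break
    wave <- wave + 1L
    for (id in batch) set_task(store, id, "IN_PROGRESS", run_id = run_id)
    for (id in batch) {
      t <- store$state$tasks[[as.character(id)]]
      entry <- graph$modules[[t$module]]$entry
      fn <- get_module_entry(entry)
      res <- tryCatch({
        out <- fn(t, ctx)
        if (identical(out$status, "DEFER")) "DEFER" else "SUCCESS"
      }, sf_interrupt = function(e) { interrupted <<- TRUE; "INTERRUPTED" },
         error = function(e) {
        store_log(store, sprintf("task %d error: %s", id, conditionMessage(e)))
        "ERROR"
      })
      if (res == "INTERRUPTED") break       # simulated crash: task left IN_PROGRESS
      set_task(store, id, res)
      schedule <- rbind(schedule,
                        data.frame(task_id = id, wave = wave,
                                   kind = unname(kind_of[t$module]),
                                   module = t$module, status = res))
      completed <- completed + 1L
      if (!is.null(ctx$interrupt_after) && completed >= ctx$interrupt_after) {
        interrupted <- TRUE
        break
      }
    }
    if (interrupted) break
  }
  tt <- wf_tasks(store)
  tt <- tt[tt$workflow_id == workflow_id & tt$module %in% mods, ]
  summary <- table(factor(tt$status, levels = TASK_STATUSES))
  store$state$runs[[as.character(run_id)]]$finished <-
    format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3")
  store_save(store)
  store_log(store, sprintf("run %d done: %s", run_id,
                           paste(names(summary), as.integer(summary),
                                 sep = "=", collapse = " ")))
  list(run_id = run_id, schedule = schedule, summary = summary,
       interrupted = interrupted)
}

#' Acknowledge a deferred task
#'
#' Manual-loading prompts park their task in `DEFER`; acknowledgement allows
#' the next dispatch or resume to re-enter it.
#'
#' @param store An [wf_store()].
#' @param task_id Task to acknowledge.
#' @export
wf_acknowledge <- function(store, task_id) {
  t <- store$state$tasks[[as.character(task_id)]]
  if (is.null(t)) sf_stop("sf_store_error", "no such task %s", task_id)
  t$acknowledged <- TRUE
  store$state$tasks[[as.character(task_id)]] <- t
  store_save(store)
  invisible(TRUE)
}

# ---- module entry registry ------------------------------------------------

.sf_registry <- new.env(parent = emptyenv())

#' Register a module entry function
#'
#' Entry functions are looked up by name at dispatch time; they receive the
#' task record and the dispatch context and return a list with an optional
#' `status` (`"DEFER"` to park the task) and `result_uri`.
#'
#' @param name Entry name referenced by [wf_module()].
#' @param fn Function `(task, ctx) -> list`.
#' @export
register_module_entry <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = .sf_registry)
  invisible(name)
}

get_module_entry <- function(name) {
  if (!exists(name, envir = .sf_registry))
    sf_stop("sf_workflow_error", "no registered entry function '%s'", name)
  get(name, envir = .sf_registry)
}

#' Signal a simulated crash from inside an entry function
#'
#' Used by tests and by interrupt-style fixtures: the current task stays
#' `IN_PROGRESS` in the store, exactly as after a hard kill.
#' @export
sf_interrupt <- function() {
  stop(errorCondition("interrupted", class = c("sf_interrupt", "scopeflow_error")))
}
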