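#' Build a task dependency graph
#'
#' Tasks are nodes, dependency edges run prerequisite -> dependent. A task
#' may start only once all its prerequisites have finished. Statuses are
#' `waiting`, `started`, `finished` or `error`.
#'
#' @param tasks Data.frame with columns `id` (unique strings) and `command`
#'   (opaque command descriptors); or a character vector of ids.
#' @param edges Data.frame with columns `from` (prerequisite id) and `to`
#'   (dependent id); may have zero rows.
#' @return An object of class `task_graph`.
#' @export
task_graph <- function(tasks, edges = NULL) {
  if (is.character(tasks))
    tasks <- data.frame(id = tasks, command = tasks,
                        stringsAsFactors = FALSE)
  if (anyDuplicated(tasks$id)) stop("duplicate task ids")
  if (is.null(edges))
    edges <- data.frame(from = character(), to = character(),
                        stringsAsFactors = FALSE)
  unknown <- setdiff(c(edges$from, edges$to), tasks$id)
  if (length(unknown))
    stop("edge references unknown task(s): ",
         paste(unique(unknown), collapse = ", "))
  if (any(edges$from == edges$to)) stop("self-dependency not allowed")
  status <- rep("waiting", nrow(tasks))
  names(status) <- tasks$id
  structure(list(tasks = tasks, edges = edges, status = status),
            class = "task_graph")
}

#' @export
print.task_graph <- function(x, ...) {
  cat("Task graph:", nrow(x$tasks), "tasks,", nrow(x$edges), "edges\n")
  print(table(x$status))
  invisible(x)
}

#' Topological order of a task graph
#'
#' Kahn's algorithm with a deterministic tie-break: among ready tasks the
#' lexicographically smallest id runs first. Every prerequisite precedes its
#' dependents; a cycle is an error naming the tasks involved.
#'
#' @param graph A [task_graph()].
#' @return Character vector of task ids in execution order.
#' @export
topo_order <- function(graph) {
  ids <- graph$tasks$id
  indeg <- integer(length(ids))
  names(indeg) <- ids
  for (t in graph$edges$to) indeg[t] <- indeg[t] + 1L
  ready <- sort(ids[indeg == 0L])
  out <- character(0)
  while (length(ready)) {
    v <- ready[1L]
    ready <- ready[-1L]
    out <- c(out, v)
    deps <- graph$edges$to[graph$edges$from == v]
    for (d in deps) {
      indeg[d] <- indeg[d] - 1L
      if (indeg[d] == 0L) ready <- sort(c(ready, d))
    }
  }
  if (length(out) < length(ids)) {
    cyc <- setdiff(ids, out)
    stop("dependency cycle involving: ", paste(sort(cyc), collapse = ", "))
  }
  out
}

# ---------------------------------------------------------------------------
# Status file: one line per task, "id<TAB>status<TAB>command"

#' Write a task status file
#' @param graph A `task_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_status <- function(graph, path) {
  lines <- paste(graph$tasks$id, graph$status[graph$tasks$id],
                 graph$tasks$command, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a task status file
#' @param path Status file path.
#' @return Data.frame with `id`, `status`, `command`.
#' @export
read_status <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop("corrupt status file ", path, ": line ", bad[1L],
         " has fewer than 3 fields")
  df <- data.frame(id = vapply(parts, `[[`, character(1L), 1L),
                   status = vapply(parts, `[[`, character(1L), 2L),
                   command = vapply(parts, function(p)
                     paste(p[-(1:2)], collapse = "\t"), character(1L)),
                   stringsAsFactors = FALSE)
  ok <- df$status %in% c("waiting", "started", "finished", "error")
  if (!all(ok))
    stop("corrupt status file ", path, ": unknown status '",
         df$status[!ok][1L], "'")
  df
}

#' Run a task graph with resumable status tracking
#'
#' Executes tasks in dependency order through an injected executor. If the
#' status file exists, tasks recorded as `finished` are skipped (resume);
#' `started` tasks are re-run (they were interrupted). The status file is
#' rewritten after every state change, so an interrupted run resumes
#' correctly. On a task failure its dependents never start and the run stops
#' once runnable-independent work is done.
#'
#' @param graph A [task_graph()].
#' @param executor Function `(id, command) -> logical` returning `TRUE` on
#'   success. The default local executor runs `command` with [system()] and
#'   succeeds on exit status 0.
#' @param status_path Path of the status file (created if absent).
#' @param max_parallel Upper bound on tasks claimed per scheduling round.
#'   The shipped executor is sequential; the bound caps batch size so that
#'   failures stop the run promptly.
#' @param stop_on_error Stop scheduling new tasks after a failure (default).
#' @return Named character vector of final statuses.
#' @export
run_graph <- function(graph, executor = NULL, status_path,
                      max_parallel = 1L, stop_on_error = TRUE) {
  if (is.null(executor))
    executor <- function(id, command) system(command) == 0L
  order <- topo_order(graph)  # also validates acyclicity
  if (file.exists(status_path)) {
    st <- read_status(status_path)
    if (!setequal(st$id, graph$tasks$id))
      stop("corrupt status file ", status_path,
           ": task ids do not match the graph")
    done <- st$id[st$status == "finished"]
    graph$status[done] <- "finished"
    graph$status[setdiff(graph$tasks$id, done)] <- "waiting"
  }
  write_status(graph, status_path)

  prereq <- split(graph$edges$from, graph$edges$to)
  failed <- FALSE
  repeat {
    runnable <- Filter(function(id) {
      graph$status[[id]] == "waiting" &&
        all(graph$status[prereq[[id]]] == "finished")
    }, order)
    if (!length(runnable) || (failed && stop_on_error)) break
    batch <- utils::head(runnable, max_parallel)
    for (id in batch) {
      graph$status[[id]] <- "started"
      write_status(graph, status_path)
      cmd <- graph$tasks$command[graph$tasks$id == id]
      ok <- tryCatch(isTRUE(executor(id, cmd)), error = function(e) FALSE)
      graph$status[[id]] <- if (ok) "finished" else "error"
      if (!ok) failed <- TRUE
      write_status(graph, status_path)
      if (!ok && stop_on_error) break
    }
  }
  graph$status
}
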