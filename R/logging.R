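# Session step log: every processing action is recorded with its timestamp
# and full parameter set, in memory and optionally appended to a JSON-lines
# file, so a processing sequence can be audited or replayed.

.log_state <- new.env(parent = emptyenv())
.log_state$entries <- list()
.log_state$file <- NULL

#' Set (or unset) the on-disk session log
#' @param path JSON-lines file to append log entries to, or `NULL` to keep
#'   the log in memory only
#' @export
set_log_file <- function(path = NULL) {
  if (!is.null(path)) {
    ok <- tryCatch(suppressWarnings({
      con <- file(path, open = "a"); close(con); TRUE
    }), error = function(e) FALSE)
    if (!ok) stop("log destination is not writable: ", path)
  }
  .log_state$file <- path
  invisible(path)
}

#' Record one processing step
#'
#' Appends an entry (timestamp, action label, parameter record) to the
#' in-memory session log and, if configured via [set_log_file()], to the
#' on-disk JSON-lines log. The log is append-only.
#'
#' @param action short action label, e.g. `"highpass"`
#' @param params named list of the action's parameters
#' @return the entry, invisibly
#' @export
log_step <- function(action, params = list()) {
  entry <- list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z"),
                action = action, params = params)
  .log_state$entries[[length(.log_state$entries) + 1L]] <- entry
  if (!is.null(.log_state$file)) {
    line <- jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA)
    ok <- tryCatch({
      cat(line, "\n", sep = "", file = .log_state$file, append = TRUE)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop("could not append to log file: ", .log_state$file)
  }
  invisible(entry)
}

#' Retrieve the in-memory session log
#' @return list of log entries in order of recording
#' @export
get_log <- function() .log_state$entries

#' Clear the in-memory session log
#' @export
clear_log <- function() {
  .log_state$entries <- list()
  invisible(NULL)
}

#' Read a JSON-lines session log back into a list of entries
#' @param path log file path
#' @export
read_log <- function(path) {
  lines <- readLines(path)
  lapply(lines[nzchar(lines)], function(l)
    jsonlite::fromJSON(l, simplifyVector = TRUE))
}
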