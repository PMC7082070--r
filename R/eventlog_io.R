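# Event-table files: tab-separated with a fixed four-column header
#   time <TAB> action <TAB> process <TAB> parameters
# Times are written with 10 significant digits; parameter values are one
# bracketed, comma-separated column.  A batch writer adds a plain key=value
# run manifest for provenance.

fmt_time <- function(x) formatC(x, digits = 10, format = "g")

fmt_params <- function(p) {
  sprintf("[%s]", paste(vapply(p, fmt_num, character(1)), collapse = ","))
}

#' Write an event log to a TSV file
#'
#' @param log A `bcs_eventlog` (or any tibble with columns `time`, `action`,
#'   `process`, `params`).
#' @param path Destination file.
#' @return `path`, invisibly.
#' @seealso [read_event_log()], [bcs_write_run()]
#' @export
write_event_log <- function(log, path) {
  stopifnot(all(c("time", "action", "process", "params") %in% names(log)))
  lines <- c(
    "time\taction\tprocess\tparameters",
    if (nrow(log)) {
      sprintf("%s\t%s\t%s\t%s",
              vapply(log$time, fmt_time, character(1)),
              log$action, log$process,
              vapply(log$params, fmt_params, character(1)))
    }
  )
  writeLines(lines, path)
  invisible(path)
}

parse_params_field <- function(s, lineno) {
  if (!grepl("^\\[.*\\]$", s)) {
    stop(sprintf("malformed parameters field at line %d: '%s'", lineno, s),
         call. = FALSE)
  }
  body <- substr(s, 2L, nchar(s) - 1L)
  if (!nzchar(body)) return(numeric(0))
  v <- suppressWarnings(as.numeric(strsplit(body, ",", fixed = TRUE)[[1L]]))
  if (anyNA(v)) {
    stop(sprintf("non-numeric parameter value at line %d: '%s'", lineno, s),
         call. = FALSE)
  }
  v
}

#' Read an event log written by [write_event_log()]
#'
#' Validates the header, the field count of every row, numeric fields, and
#' that times are non-negative and non-decreasing; the first offending line
#' is reported by number.
#'
#' @param path Path to a TSV event table.
#' @return A tibble with columns `time`, `action`, `process`, `params`.
#' @export
read_event_log <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L || lines[[1L]] != "time\taction\tprocess\tparameters") {
    stop(sprintf("'%s' is not an event table (bad or missing header)", path),
         call. = FALSE)
  }
  body <- lines[-1L]
  body <- body[nzchar(body)]
  n <- length(body)
  time <- numeric(n)
  action <- character(n)
  process <- character(n)
  params <- vector("list", n)
  for (k in seq_len(n)) {
    lineno <- k + 1L
    fields <- strsplit(body[[k]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) != 4L) {
      stop(sprintf("malformed row at line %d: expected 4 tab-separated fields, found %d",
                   lineno, length(fields)), call. = FALSE)
    }
    tv <- suppressWarnings(as.numeric(fields[[1L]]))
    if (is.na(tv)) {
      stop(sprintf("non-numeric time at line %d: '%s'", lineno, fields[[1L]]),
           call. = FALSE)
    }
    if (tv < 0) {
      stop(sprintf("negative time at line %d", lineno), call. = FALSE)
    }
    if (k > 1L && tv < time[[k - 1L]]) {
      stop(sprintf("times out of order at line %d", lineno), call. = FALSE)
    }
    time[[k]] <- tv
    action[[k]] <- fields[[2L]]
    process[[k]] <- fields[[3L]]
    params[[k]] <- parse_params_field(fields[[4L]], lineno)
  }
  tibble::tibble(time = time, action = action, process = process, params = params)
}

# 32-bit polynomial rolling hash over the model source, for the run manifest
source_hash <- function(text) {
  h <- 5381
  for (b in utf8ToInt(paste(text, collapse = "\n"))) {
    h <- (h * 33 + b) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Write a batch of event logs with a run manifest
#'
#' Writes `<prefix>_rep<k>.tsv` for each replicate plus
#' `<prefix>_manifest.txt`, a key=value provenance file recording the model
#' source hash, seed scheme and caps.
#'
#' @param logs A `bcs_batch` from [bcs_run_batch()] (or list of event logs).
#' @param prefix Output path prefix.
#' @param model Optional `bcs_model` for the manifest's source hash.
#' @return Character vector of files written, invisibly.
#' @export
bcs_write_run <- function(logs, prefix, model = NULL) {
  files <- character(0)
  for (k in seq_along(logs)) {
    f <- sprintf("%s_rep%d.tsv", prefix, k)
    write_event_log(logs[[k]], f)
    files <- c(files, f)
  }
  seeds <- vapply(logs, function(l) attr(l, "seed") %||% NA_integer_, integer(1))
  mf <- sprintf("%s_manifest.txt", prefix)
  writeLines(c(
    sprintf("replicates=%d", length(logs)),
    sprintf("base_seed=%s", if (length(seeds)) seeds[[1L]] else NA),
    "seed_scheme=base_seed + replicate - 1",
    sprintf("model_hash=%s", if (is.null(model)) "NA" else source_hash(model$source)),
    sprintf("terminations=%s",
            paste(vapply(logs, function(l) attr(l, "termination") %||% "NA",
                         character(1)), collapse = ","))
  ), mf)
  invisible(c(files, mf))
}
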