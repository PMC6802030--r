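#' Write and read event logs as delimited text
#'
#' Event logs are serialized as tab-separated tables preceded by `#`
#' comment lines echoing the generating configuration, so a stored log can
#' be re-summarized without the original R session.
#'
#' @param log An `fgm_log` event log.
#' @param path File path.
#' @return `write_event_log()` returns `path` invisibly;
#'   `read_event_log()` returns an `fgm_log` with its configuration
#'   attributes restored.
#' @examples
#' cfg <- scenario_config("standard", n_iterations = 10, burn_in = 0)
#' set.seed(1)
#' log <- run_standard(cfg)
#' f <- tempfile(fileext = ".tsv")
#' write_event_log(log, f)
#' log2 <- read_event_log(f)
#' all.equal(log$z_after, log2$z_after)
#' @export
write_event_log <- function(log, path) {
  stopifnot(inherits(log, "fgm_log"))
  config <- attr(log, "config")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# fgmconflict event log", con)
  for (key in names(unclass(config))) {
    writeLines(sprintf("# %s = %s", key, format(config[[key]], digits = 17)),
               con)
  }
  write.table(as.data.frame(log), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_log
#' @export
read_event_log <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- regmatches(hdr, regexec("^# *([a-z_0-9]+) *= *(.*)$", hdr))
  kv <- kv[lengths(kv) == 3L]
  raw <- list()
  for (m in kv) {
    val <- m[3]
    num <- suppressWarnings(as.numeric(val))
    raw[[m[2]]] <- if (!is.na(num)) num else val
  }
  config <- validate_config(raw)
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  df$fixed <- as.logical(df$fixed)
  parties <- build_parties(config)
  make_log(df, config, parties, parties$party1$optimum)
}

#' Read a flat experiment-grid configuration file
#'
#' Parses a human-editable `key = value` file into the argument list of
#' [experiment_grid()]. Values may be comma-separated lists (expanded as
#' grid dimensions), numbers, `Inf`, or strings; lines starting with `#`
#' are comments.
#'
#' @param path Path to the configuration file.
#' @return A named list suitable for `do.call(experiment_grid, ...)`.
#' @export
read_grid_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stop("malformed line (expected `key = value`): ", ln, call. = FALSE)
    key <- trimws(parts[1])
    vals <- trimws(strsplit(parts[2], ",", fixed = TRUE)[[1]])
    nums <- suppressWarnings(as.numeric(vals))
    out[[key]] <- if (all(!is.na(nums))) nums else vals
  }
  out
}
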