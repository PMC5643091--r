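# Plain-text readers and writers for the shared schemas.
#
# Trace matrices travel as CSV with '#'-prefixed metadata lines
# (frame_rate, start_time) followed by a header row and one row per
# neuron; events as two-column CSV (event_type, time_s).

#' Write fluorescence traces to CSV
#'
#' @param traces A `fluorescence_traces` or `dff_traces` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  stopifnot(inherits(traces, c("fluorescence_traces", "dff_traces")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# frame_rate: %.10g", traces$frame_rate),
               sprintf("# start_time: %.10g", traces$start_time),
               sprintf("# kind: %s",
                       if (inherits(traces, "dff_traces")) "dff" else "raw")),
             con)
  df <- data.frame(neuron = rownames(traces$values), traces$values,
                   check.names = FALSE)
  colnames(df) <- c("neuron", sprintf("f%d", seq_len(ncol(traces$values))))
  utils::write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read fluorescence traces from CSV
#'
#' @param path File written by [write_traces()].
#' @return A `fluorescence_traces` or `dff_traces` object, per the file's
#'   `kind` metadata.
#' @export
read_traces <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- function(key, default) {
    m <- grep(sprintf("^# %s:", key), meta_lines, value = TRUE)
    if (length(m) == 0L) return(default)
    trimws(sub(sprintf("^# %s:", key), "", m[1]))
  }
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = body, check.names = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  dimnames(vals) <- list(df[[1]], NULL)
  fr <- as.numeric(meta("frame_rate", "30"))
  st <- as.numeric(meta("start_time", "0"))
  if (identical(meta("kind", "raw"), "dff")) {
    new_dff_traces(vals, fr, st)
  } else {
    fluorescence_traces(vals, fr, st)
  }
}

#' Write behavioural events to CSV
#' @param events An [event_list()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  stopifnot(inherits(events, "event_list"))
  df <- rbind(
    data.frame(event_type = "delivery", time_s = events$delivery_times),
    data.frame(event_type = "lick", time_s = events$lick_times)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read behavioural events from CSV
#' @param path File with columns `event_type` (delivery/lick), `time_s`.
#' @return An [event_list()].
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("event_type", "time_s") %in% names(df))) {
    stop_invalid("events file needs columns event_type, time_s")
  }
  event_list(sort(df$time_s[df$event_type == "delivery"]),
             sort(df$time_s[df$event_type == "lick"]))
}

# atomic write: write to a temp sibling, then rename, so a failed stage
# never leaves a partially written final output
write_atomic <- function(path, writer) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

write_csv_atomic <- function(df, path) {
  write_atomic(path, function(p) {
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
  })
}

write_json_atomic <- function(x, path) {
  write_atomic(path, function(p) {
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
}
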