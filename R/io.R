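# Plain-text interchange: beat tables as CSV, events as JSON lines or CSV,
# configurations as YAML.

#' Write / read a beat table as CSV
#'
#' One row per beat with all fiducials as sample indices and intervals in
#' milliseconds.
#'
#' @param beats Beat tibble.
#' @param path File path.
#' @return `write_beats_csv()` returns `path` invisibly; `read_beats_csv()`
#'   a tibble.
#' @export
write_beats_csv <- function(beats, path) {
  utils::write.csv(as.data.frame(beats), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_beats_csv
#' @export
read_beats_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write / read rhythm events as JSON lines
#'
#' One JSON object per line with fields `etype`, `start_beat`, `end_beat`,
#' `n_vpb`, `onset_time_s` (plus any extra columns present).
#'
#' @param events Event tibble.
#' @param path File path.
#' @return `write_events_jsonl()` returns `path` invisibly;
#'   `read_events_jsonl()` a tibble.
#' @export
write_events_jsonl <- function(events, path) {
  lines <- vapply(seq_len(nrow(events)), function(i) {
    as.character(jsonlite::toJSON(as.list(events[i, ]), auto_unbox = TRUE,
                                  digits = NA, na = "null"))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_events_jsonl
#' @export
read_events_jsonl <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) {
    return(tibble::tibble(
      etype = character(), start_beat = integer(), end_beat = integer(),
      n_vpb = integer(), onset_time_s = numeric()
    ))
  }
  rows <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    x[vapply(x, is.null, logical(1))] <- NA
    tibble::as_tibble(x)
  })
  do.call(rbind, rows)
}

#' Write / read rhythm events as CSV
#'
#' @inheritParams write_events_jsonl
#' @return `write_events_csv()` returns `path` invisibly;
#'   `read_events_csv()` a tibble.
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events_csv
#' @export
read_events_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Save / load a classifier configuration as YAML
#'
#' Persists every threshold so an analysis run is fully logged.
#'
#' @param config A [classifier_config()].
#' @param path File path.
#' @return `write_classifier_config()` returns `path` invisibly;
#'   `read_classifier_config()` a [classifier_config()].
#' @export
write_classifier_config <- function(config, path) {
  stopifnot(inherits(config, "classifier_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_classifier_config
#' @export
read_classifier_config <- function(path) {
  do.call(classifier_config, yaml::read_yaml(path))
}
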