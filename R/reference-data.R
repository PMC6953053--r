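# Bundled reference summary of published arrhythmia counts, used for
# internal-consistency checks and to parameterize count simulations.

#' Reference arrhythmia count summary
#'
#' Group-level mean and SD event counts from a two-stage murine infarction
#' telemetry experiment, bundled as plain CSV: three groups (`URI` untreated
#' reinfarction, n = 9; `SRI` stem-cell-treated reinfarction, n = 6; `MIC`
#' infarction control without reinfarction, n = 6), two interventions
#' (`first_ligation`, `second_ligation`), four event categories (`vpb`,
#' `bg_tg`, `salvo`, `vt`) and four time windows (`0-15min`, `15-45min`,
#' `45min-12h` and their union `0-12h`).
#'
#' @return Tibble with columns `etype`, `intervention`, `window`, `group`,
#'   `n`, `mean`, `sd`.
#' @export
#' @examples
#' ref <- reference_count_summary()
#' subset(ref, etype == "vt" & intervention == "second_ligation")
reference_count_summary <- function() {
  path <- system.file("extdata", "reference_count_summary.csv",
                      package = "murineECG", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Check union-window additivity of a count summary
#'
#' For every (etype, intervention, group) cell, the union-window value must
#' equal the sum of the sub-window values. Works on any table with `etype`,
#' `intervention`, `group`, `window` and a value column (`mean` or `count`).
#' Rounded published means may be off in the last printed digit; rows whose
#' printed values are exactly additive can be singled out with `tol`.
#'
#' @param summary Table to check (default: the bundled reference summary).
#' @param value Name of the value column (default `"mean"`).
#' @param union_label Label of the union window.
#' @param tol Absolute tolerance for flagging a row as additive.
#' @return Tibble with one row per cell: the union value, the sub-window
#'   sum, `abs_error` and logical `additive`.
#' @export
check_window_additivity <- function(summary = reference_count_summary(),
                                    value = "mean", union_label = "0-12h",
                                    tol = 1e-9) {
  stopifnot(is.data.frame(summary),
            all(c("etype", "intervention", "group", "window",
                  value) %in% names(summary)))
  v <- summary[[value]]
  is_union <- summary$window == union_label
  key <- paste(summary$etype, summary$intervention, summary$group,
               sep = "\r")
  uni <- summary[is_union, ]
  uni_val <- v[is_union]
  sub_sum <- vapply(key[is_union], function(k) {
    sum(v[!is_union & key == k])
  }, numeric(1))
  tibble::tibble(
    etype = uni$etype, intervention = uni$intervention, group = uni$group,
    union_value = uni_val, subwindow_sum = unname(sub_sum),
    abs_error = abs(uni_val - sub_sum),
    additive = abs(uni_val - sub_sum) <= tol
  )
}
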