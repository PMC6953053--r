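# Finite-state detection of ventricular arrhythmia patterns on a beat-label
# sequence. Four categories, scanned greedily left to right with precedence
# VT > salvo > trigeminy > bigeminy > isolated VPB; every beat is consumed
# by at most one event, so category tallies are disjoint.
#
# Definitions (murine telemetry convention):
#   VT        run of >= 4 consecutive VPBs
#   salvo     run of 2-3 consecutive VPBs
#   bigeminy  V,(N,V) repeated: >= 3 VPBs in strict V/N alternation
#   trigeminy V,(N,N,V) repeated: >= 3 VPBs in a strict V/N/N cycle

.check_labels <- function(labels) {
  if (!all(labels %in% c("sinus", "vpb"))) {
    stop('labels must be "sinus" or "vpb"')
  }
}

#' Maximal runs of consecutive VPBs
#'
#' @param labels Character vector of beat labels (`"sinus"`/`"vpb"`).
#' @return Tibble with one row per maximal run: `start`, `length`.
#' @export
detect_runs <- function(labels) {
  .check_labels(labels)
  if (length(labels) == 0L) {
    return(tibble::tibble(start = integer(), length = integer()))
  }
  r <- rle(labels == "vpb")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble::tibble(start = starts[keep], length = r$lengths[keep])
}

# length of the maximal vpb run containing each position (0 for sinus)
.run_len_at <- function(is_v) {
  r <- rle(is_v)
  rep(ifelse(r$values, r$lengths, 0L), r$lengths)
}

# extend an alternating pattern with period `per` from a single VPB at i:
# each subsequent VPB must itself be a run of length 1. Returns the index of
# the last VPB accepted.
.extend_alternation <- function(is_v, run_len, i, per, n) {
  j <- i
  repeat {
    nxt <- j + per
    if (nxt > n) break
    if (any(is_v[(j + 1L):(nxt - 1L)])) break       # intervening beats sinus
    if (!is_v[nxt] || run_len[nxt] != 1L) break     # next VPB must be single
    j <- nxt
  }
  j
}

#' Classify arrhythmia patterns in a label sequence
#'
#' Greedy left-to-right scan with precedence VT > salvo > trigeminy >
#' bigeminy > isolated VPB. Matches are maximal and consumed beats are not
#' reused; a maximal alternating stretch yields exactly one bigeminy or
#' trigeminy event. Runs truncated by the recording edges still count when
#' they meet the minimum length.
#'
#' @param labels Character vector of beat labels (`"sinus"`/`"vpb"`).
#' @param times Optional numeric vector of per-beat onset times (s); used to
#'   fill `onset_time_s`.
#' @return Tibble of events: `etype` (one of `"vpb_isolated"`, `"bigeminy"`,
#'   `"trigeminy"`, `"salvo"`, `"vt"`), `start_beat`, `end_beat` (inclusive),
#'   `n_vpb`, `onset_time_s`.
#' @export
#' @examples
#' classify_patterns(c("vpb", "sinus", "vpb", "sinus", "vpb"))
classify_patterns <- function(labels, times = NULL) {
  .check_labels(labels)
  n <- length(labels)
  if (is.null(times)) times <- rep(NA_real_, n)
  stopifnot(length(times) == n)
  is_v <- labels == "vpb"
  run_len <- if (n) .run_len_at(is_v) else integer(0)

  etype <- character(0)
  start <- end <- integer(0)
  i <- 1L
  while (i <= n) {
    if (!is_v[i]) {
      i <- i + 1L
      next
    }
    r <- run_len[i]
    if (r >= 4L) {
      etype <- c(etype, "vt"); start <- c(start, i); end <- c(end, i + r - 1L)
    } else if (r >= 2L) {
      etype <- c(etype, "salvo"); start <- c(start, i)
      end <- c(end, i + r - 1L)
    } else {
      j3 <- .extend_alternation(is_v, run_len, i, 3L, n)
      j2 <- .extend_alternation(is_v, run_len, i, 2L, n)
      if ((j3 - i) / 3L + 1L >= 3L) {          # >= 3 VPBs in V,N,N cycle
        etype <- c(etype, "trigeminy"); start <- c(start, i)
        end <- c(end, j3)
      } else if ((j2 - i) / 2L + 1L >= 3L) {   # >= 3 VPBs in V,N alternation
        etype <- c(etype, "bigeminy"); start <- c(start, i)
        end <- c(end, j2)
      } else {
        etype <- c(etype, "vpb_isolated"); start <- c(start, i)
        end <- c(end, i)
      }
    }
    i <- end[length(end)] + 1L
  }

  n_vpb <- vapply(seq_along(etype), function(k) {
    sum(is_v[start[k]:end[k]])
  }, integer(1))
  tibble::tibble(
    etype = etype, start_beat = start, end_beat = end, n_vpb = n_vpb,
    onset_time_s = times[start]
  )
}

#' Tally events by category
#'
#' Bigeminy and trigeminy are merged into one `bg_tg` category, matching the
#' usual reporting convention. Counts are event counts, not beat counts; the
#' total number of VPB-labeled beats across all events is attached as
#' attribute `"vpb_beats"`.
#'
#' @param events Event tibble from [classify_patterns()].
#' @param vpb_mode `"exclusive"` (default): the `vpb` row counts isolated
#'   VPB events only. `"inclusive"`: it counts all VPB beats, including
#'   pattern members.
#' @return Tibble with rows `vpb`, `bg_tg`, `salvo`, `vt` and a `count`
#'   column.
#' @export
count_by_type <- function(events, vpb_mode = c("exclusive", "inclusive")) {
  vpb_mode <- match.arg(vpb_mode)
  vpb_beats <- if (nrow(events)) sum(events$n_vpb) else 0L
  vpb_count <- if (vpb_mode == "exclusive") {
    sum(events$etype == "vpb_isolated")
  } else {
    vpb_beats
  }
  out <- tibble::tibble(
    etype = c("vpb", "bg_tg", "salvo", "vt"),
    count = c(
      vpb_count,
      sum(events$etype %in% c("bigeminy", "trigeminy")),
      sum(events$etype == "salvo"),
      sum(events$etype == "vt")
    )
  )
  attr(out, "vpb_beats") <- as.integer(vpb_beats)
  out
}

#' Map pattern event types onto reporting categories
#'
#' `vpb_isolated` becomes `vpb`; `bigeminy` and `trigeminy` become `bg_tg`.
#'
#' @param etype Character vector of event types.
#' @return Character vector of reporting categories.
#' @export
event_category <- function(etype) {
  out <- etype
  out[etype == "vpb_isolated"] <- "vpb"
  out[etype %in% c("bigeminy", "trigeminy")] <- "bg_tg"
  out
}
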