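# Independent oracles and fixtures used across the suite.

# integer -> label sequence of length len ("sinus"/"vpb"), for exhaustive
# sweeps over all 2^len sequences
int_to_labels <- function(x, len) {
  bits <- as.integer(intToBits(x))[seq_len(len)]
  ifelse(bits == 1L, "vpb", "sinus")
}

# Brute-force regex/backtracking implementation of the rhythm-pattern
# grammar: greedy left-to-right, precedence VT > salvo > trigeminy >
# bigeminy > isolated VPB, maximal matches, consumed beats not reused.
# Written against the grammar definition, independently of the package's
# scanner.
oracle_classify <- function(labels) {
  s <- paste(ifelse(labels == "vpb", "V", "N"), collapse = "")
  pats <- list(
    vt           = "^V{4,}",
    salvo        = "^V{2,3}(?!V)",
    trigeminy    = "^V(?:NNV){2,}(?!V)",
    bigeminy     = "^V(?:NV){2,}(?!V)",
    vpb_isolated = "^V(?!V)"
  )
  etype <- character(0); start <- integer(0); end <- integer(0)
  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    if (substr(s, i, i) != "V") {
      i <- i + 1L
      next
    }
    rest <- substr(s, i, n)
    for (nm in names(pats)) {
      m <- regexpr(pats[[nm]], rest, perl = TRUE)
      if (m != -1L) {
        len <- attr(m, "match.length")
        etype <- c(etype, nm)
        start <- c(start, i)
        end <- c(end, i + len - 1L)
        i <- i + len
        break
      }
    }
  }
  data.frame(etype = etype, start_beat = start, end_beat = end,
             stringsAsFactors = FALSE)
}

# a moderately busy arrhythmia mix used by several end-to-end tests
busy_spec <- function() {
  arrhythmia_spec(
    vpb_rate = 40,
    vt_run_lengths = 5,
    salvo_run_lengths = c(2, 3),
    n_bigeminy = 1,
    n_trigeminy = 1
  )
}
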