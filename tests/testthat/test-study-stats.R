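make_events <- function(times, etype = "vpb_isolated", animal = "a1",
                        intervention = "first_ligation") {
  tibble::tibble(
    etype = etype, start_beat = seq_along(times),
    end_beat = seq_along(times), n_vpb = 1L, onset_time_s = times,
    animal_id = animal, intervention = intervention
  )
}

test_that("window boundaries are half-open and late events are excluded", {
  ev <- make_events(c(0, 899.999, 900, 2700, 43199, 43200, 13 * 3600))
  tagged <- assign_windows(ev, intervention_time_s = 0)
  expect_identical(tagged$window,
                   c("0-15min", "0-15min", "15-45min", "45min-12h",
                     "45min-12h"))
  expect_identical(nrow(tagged), 5L)  # 12 h and 13 h onsets dropped
})

test_that("pre-intervention events are dropped with a warning", {
  ev <- make_events(c(-5, 10, 100))
  expect_warning(tagged <- assign_windows(ev, intervention_time_s = 0),
                 "before the intervention")
  expect_identical(nrow(tagged), 2L)
})

test_that("malformed window schemes are rejected", {
  expect_error(window_scheme(data.frame(
    window = c("a", "b"), start_s = c(0, 50), end_s = c(100, 150)
  )), "overlap")
  expect_error(window_scheme(data.frame(
    window = c("a", "b"), start_s = c(100, 0), end_s = c(200, 50)
  )), "ordered")
  expect_error(window_scheme(data.frame(
    window = "a", start_s = 10, end_s = 10
  )), "end_s > start_s")
})

test_that("sub-window counts always sum to the union window", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      times <- runif(50, 0, 15 * 3600)  # some beyond 12 h
      ev <- make_events(times,
                        etype = sample(c("vpb_isolated", "vt", "salvo",
                                         "bigeminy"), 50, replace = TRUE))
      tagged <- assign_windows(ev, 0)
      animals <- data.frame(animal_id = "a1", group = "URI")
      ct <- build_count_table(tagged, animals)
      chk <- check_window_additivity(ct$counts, value = "count")
      expect_true(all(chk$additive))
      expect_identical(sum(ct$counts$count[ct$counts$window == "0-12h"]),
                       sum(tagged$onset_time_s < 43200))
    }
  })
})

test_that("count tables complete the grid and flag single-animal groups", {
  ev <- make_events(c(10, 1000, 5000), animal = "a1")
  animals <- data.frame(animal_id = c("a1", "b1", "b2"),
                        group = c("URI", "MIC", "MIC"))
  ct <- build_count_table(assign_windows(ev, 0), animals)
  # zero rows exist for animals without events
  b1 <- ct$counts[ct$counts$animal_id == "b1", ]
  expect_true(all(b1$count == 0))
  s <- ct$summary
  expect_true(all(s$single_animal[s$group == "URI"]))
  expect_true(all(s$sd[s$group == "URI"] == 0))
  expect_false(any(s$single_animal[s$group == "MIC"]))
  # group means match a brute-force recount
  uri_vpb <- s[s$group == "URI" & s$etype == "vpb" & s$window == "0-12h", ]
  expect_equal(uri_vpb$mean, 3)
})

test_that("exact Mann-Whitney reproduces hand enumeration", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_identical(mw$u_statistic, 0)
  expect_equal(mw$p_value, 0.1)  # 2/20 rank assignments as extreme
  expect_identical(mw$method, "exact")
  expect_false(mw$significant)
})

test_that("identical samples give p = 1", {
  expect_equal(mann_whitney(c(2, 2, 5), c(2, 2, 5))$p_value, 1)
})

test_that("exact p matches the reference implementation on tie-free draws", {
  withr::with_seed(17, {
    for (rep in 1:50) {
      n_a <- sample(3:6, 1); n_b <- sample(3:6, 1)
      x <- sample(1:1000, n_a + n_b)  # tie-free
      a <- x[seq_len(n_a)]; b <- x[-seq_len(n_a)]
      mw <- mann_whitney(a, b)
      wt <- stats::wilcox.test(a, b, exact = TRUE, correct = FALSE)
      expect_identical(mw$method, "exact")
      expect_equal(mw$u_statistic, unname(wt$statistic))
      expect_equal(mw$p_value, wt$p.value)
    }
  })
})

test_that("U + U' equals n_a * n_b", {
  withr::with_seed(23, {
    for (rep in 1:30) {
      a <- rpois(sample(2:8, 1), 5)
      b <- rpois(sample(2:8, 1), 5)
      u1 <- mann_whitney(a, b)$u_statistic
      u2 <- mann_whitney(b, a)$u_statistic
      expect_equal(u1 + u2, length(a) * length(b))
    }
  })
})

test_that("normal approximation tracks the exact p at n = 6 + 6", {
  withr::with_seed(31, {
    for (rep in 1:50) {
      x <- sample(1:10000, 12)
      a <- x[1:6]; b <- x[7:12]
      exact <- mann_whitney(a, b)$p_value
      approx <- mann_whitney(a, b, exact_max_n = 0L)$p_value
      expect_lt(abs(exact - approx), 0.01)
    }
  })
})

test_that("compare_all covers every cell-pair and stays quiet under the null", {
  withr::with_seed(41, {
    ev <- make_events(runif(30, 0, 40000),
                      etype = sample(c("vpb_isolated", "vt"), 30, TRUE),
                      animal = "u1")
    more <- lapply(c("u2", "s1", "s2", "m1", "m2"), function(a) {
      make_events(runif(30, 0, 40000),
                  etype = sample(c("vpb_isolated", "vt"), 30, TRUE),
                  animal = a)
    })
    ev <- do.call(rbind, c(list(ev), more))
    animals <- data.frame(
      animal_id = c("u1", "u2", "s1", "s2", "m1", "m2"),
      group = c("URI", "URI", "SRI", "SRI", "MIC", "MIC")
    )
    ct <- build_count_table(assign_windows(ev, 0), animals)
    cmp <- compare_all(ct)
    expect_identical(nrow(cmp), 4L * 4L * 1L * 3L)  # etype x window x pairs
    expect_true(all(cmp$p_value >= 0 & cmp$p_value <= 1))
    expect_true(all(cmp$u_statistic >= 0 &
                      cmp$u_statistic <= cmp$n_a * cmp$n_b))
    # identical constant groups are never significant
    ct0 <- ct
    ct0$counts$count <- 3L
    cmp0 <- compare_all(ct0)
    expect_false(any(cmp0$significant))
    # Holm adjustment is monotone and never smaller than the raw p
    cmp_h <- compare_all(ct, adjust = "holm")
    expect_true(all(cmp_h$p_adjusted >= cmp_h$p_value))
  })
})

test_that("the bundled reference summary has exactly-additive rows", {
  chk <- check_window_additivity(reference_count_summary(), tol = 1e-9)
  expect_identical(nrow(chk), 24L)  # 4 etypes x 2 interventions x 3 groups
  exact_rows <- chk[chk$additive, ]
  expect_gte(nrow(exact_rows), 3L)
})
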