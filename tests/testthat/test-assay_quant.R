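make_table <- function(intensity_by, background = 100, n_cells = 40) {
  rows <- list()
  for (rep_i in seq_along(intensity_by)) {
    for (cond in names(intensity_by[[rep_i]])) {
      rows[[length(rows) + 1]] <- data.frame(
        replicate = rep_i, condition = cond, cell = seq_len(n_cells),
        intensity = intensity_by[[rep_i]][[cond]],
        background = background)
    }
  }
  do.call(rbind, rows)
}

test_that("cells at background level give zero deltas", {
  tab <- make_table(list(list(pco2_35 = 100, pco2_55 = 100)))
  s <- dye_loading_summary(tab)
  expect_equal(s$delta$delta, 0)
})

test_that("groups below the cell minimum warn but are summarised", {
  tab <- rbind(make_table(list(list(pco2_35 = 100))),
               make_table(list(list(pco2_55 = 150)), n_cells = 39))
  expect_warning(s <- dye_loading_summary(tab), "39 cells")
  expect_equal(nrow(s$delta), 1L)
  expect_equal(s$delta$delta, 50)
})

test_that("a missing control condition is an error", {
  tab <- make_table(list(list(pco2_55 = 150)))
  expect_error(dye_loading_summary(tab), "missing pco2_35")
})

test_that("background subtraction is shift-equivariant", {
  set.seed(31)
  base <- make_table(list(list(pco2_35 = rnorm(40, 120, 15),
                               pco2_55 = rnorm(40, 190, 15)),
                          list(pco2_35 = rnorm(40, 110, 15),
                               pco2_55 = rnorm(40, 160, 15))))
  shifted <- base
  shifted$intensity <- shifted$intensity + 37
  shifted$background <- shifted$background + 37
  expect_equal(dye_loading_summary(base)$delta,
               dye_loading_summary(shifted)$delta)
})

test_that("an injected +50 unit shift is recovered within median sampling error", {
  sim <- simulate_assay(c(probe = "opens_moderate_pco2"),
                        effects = rbind(opens_moderate_pco2 =
                                          c(pco2_55 = 50)),
                        seed = 77)
  tab <- sim$loading[, setdiff(names(sim$loading), "construct")]
  s <- dye_loading_summary(tab)
  expect_equal(nrow(s$delta), 5L)
  expect_lt(abs(mean(s$delta$delta) - 50), 10)
})

test_that("identical groups give a two-sided exact p of 1", {
  mw <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(mw$p_value, 1)
  expect_equal(mw$method, "exact enumeration")
})

test_that("fully separated triples give the textbook one-sided 1/20", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(mw$p_value, 1 / 20)
  expect_equal(mann_whitney(c(4, 5, 6), c(1, 2, 3),
                            alternative = "greater")$p_value, 1 / 20)
})

test_that("exact p matches full enumeration for all n1, n2 <= 6", {
  set.seed(41)
  for (n1 in 2:6) {
    for (n2 in 2:6) {
      x <- round(rnorm(n1, 0, 2), 1)
      y <- round(rnorm(n2, 0.5, 2), 1)
      for (alt in c("two.sided", "less", "greater")) {
        expect_equal(mann_whitney(x, y, alt)$p_value, mw_oracle(x, y, alt),
                     info = paste(n1, n2, alt))
      }
    }
  }
})

test_that("exact p agrees with wilcox.test in tie-free cases", {
  set.seed(43)
  for (i in 1:10) {
    x <- rnorm(5); y <- rnorm(6)
    expect_equal(mann_whitney(x, y)$p_value,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value)
  }
})

test_that("U statistics of the two orientations are complementary", {
  set.seed(47)
  x <- rnorm(5); y <- rnorm(7)
  expect_equal(mann_whitney(x, y)$statistic + mann_whitney(y, x)$statistic,
               5 * 7)
})

test_that("group_tests gates pairwise flags on the omnibus test", {
  vals <- c(1, 2, 3, 4, 5, 11, 12, 13, 14, 15, 21, 22, 23, 24, 25)
  grp <- rep(c("a", "b", "c"), each = 5)
  gt <- group_tests(vals, grp)
  expect_equal(gt$kruskal$p_value,
               stats::kruskal.test(vals, factor(grp))$p.value)
  expect_equal(nrow(gt$pairwise), 3L)
  expect_true(all(gt$pairwise$significant))

  expect_error(group_tests(1:5, rep("a", 5)), ">= 2 groups")
  expect_error(group_tests(c(1, 2, 3), c("a", "a", "b")), "< 2 values")
})

test_that("transfer calls follow the 10% of donor rule", {
  time <- seq(0, 600, by = 10)
  ramp <- list(time = time, donor = rep(1000, length(time)),
               acceptor = 0.5 * time)
  call <- call_transfer_time(ramp)
  expect_equal(call$time, 200)
  expect_equal(call$interpolated, 200)
  expect_false(call$censored)

  silent <- list(time = time, donor = rep(1000, length(time)),
                 acceptor = rep(0, length(time)))
  expect_true(call_transfer_time(silent)$censored)

  at_start <- list(time = time, donor = rep(1000, length(time)),
                   acceptor = rep(100, length(time)))
  expect_equal(call_transfer_time(at_start)$time, 0)

  dead <- list(time = time, donor = rep(0, length(time)),
               acceptor = rep(0, length(time)))
  expect_error(call_transfer_time(dead), "no donor signal")
})

test_that("a pointwise-larger acceptor never yields a later call", {
  set.seed(53)
  time <- seq(0, 600, by = 10)
  for (i in 1:20) {
    acc <- cumsum(runif(length(time), 0, 3))
    tr1 <- list(time = time, donor = rep(1000, length(time)), acceptor = acc)
    tr2 <- list(time = time, donor = rep(1000, length(time)),
                acceptor = acc + runif(length(time), 0, 30))
    c1 <- call_transfer_time(tr1)
    c2 <- call_transfer_time(tr2)
    expect_lte(c2$time, c1$time)
  }
})

test_that("box-whisker summaries follow the median-anchored rule", {
  s1 <- box_whisker_stats(5)
  expect_equal(unlist(s1[c("median", "q1", "q3", "whisker_low",
                           "whisker_high")]),
               c(median = 5, q1 = 5, q3 = 5, whisker_low = 5,
                 whisker_high = 5))

  v <- as.numeric(1:100)
  s2 <- box_whisker_stats(v)
  expect_equal(s2$median, 50.5)
  expect_equal(s2$q1, unname(quantile(v, 0.25, type = 7)))
  expect_equal(s2$q3, unname(quantile(v, 0.75, type = 7)))
  expect_gte(s2$whisker_low, s2$median - 1.5 * s2$iqr)
  expect_lte(s2$whisker_high, s2$median + 1.5 * s2$iqr)
  expect_length(s2$outliers, 0L)

  w <- c(10, 11, 12, 13, 14, 60)
  s3 <- box_whisker_stats(w)
  expect_equal(s3$outliers, 60)
  expect_equal(s3$whisker_high, 14)

  expect_error(box_whisker_stats(numeric(0)), "empty input")
})

test_that("the median anchor and the Tukey anchor can disagree", {
  # median-anchored fences are tighter than Tukey fences on skewed data
  v <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 13)
  med <- box_whisker_stats(v, anchor = "median")
  tuk <- box_whisker_stats(v, anchor = "quartile")
  expect_true(length(med$outliers) >= length(tuk$outliers))
  expect_equal(med$median, tuk$median)
})
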