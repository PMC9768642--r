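cfg_fast <- function(B = 2000, seed = 1) permutation_config(B, seed = seed)

test_that("degenerate and error cases behave as specified", {
  same <- grouped_sample(list(A = c(5, 5, 5), B = c(5, 5, 5)))
  expect_message(res <- single_step_median_test(same, cfg_fast(100)),
                 "all values identical")
  expect_true(all(res$d == 0) && all(res$p_adjusted == 1))

  expect_error(single_step_median_test(grouped_sample(list(A = 1:3))),
               "needs-two-groups", class = "sg_data_error")
  expect_error(grouped_sample(list(A = 1:3, B = numeric(0))),
               "empty", class = "sg_data_error")

  tiny <- grouped_sample(list(A = 1, B = 1))
  expect_equal(exhaustive_null(tiny)$p_adjusted, 1)
})

test_that("exhaustive oracle reproduces the worked case and guards size", {
  s <- grouped_sample(list(A = c(1, 2, 3), B = c(4, 5, 6)))
  ex <- exhaustive_null(s)
  expect_equal(ex$p_adjusted, 0.2)   # 4 of the 20 labelled assignments
  expect_equal(attr(ex, "B"), 20)
  expect_equal(ex$d, 3)

  big <- grouped_sample(list(A = rep(1, 15), B = rep(2, 15)))
  expect_error(exhaustive_null(big, max_assignments = 1e4), "size-guard",
               class = "sg_config_error")
})

test_that("Monte Carlo p agrees with the oracle on random small instances", {
  set.seed(101)
  B <- 4000
  for (rep in 1:12) {
    s <- random_small_sample()
    ex <- exhaustive_null(s)
    mc <- single_step_median_test(s, permutation_config(B, seed = rep))
    tol <- 3 * sqrt(ex$p_adjusted * (1 - ex$p_adjusted) / B)
    expect_true(all(abs(mc$p_adjusted - ex$p_adjusted) <= tol + 1 / B),
                info = sprintf("instance %d", rep))
  }
})

test_that("p-values are deterministic, label-invariant and monotone in d", {
  set.seed(7)
  g <- list(A = rnbinom(25, 3, mu = 8), B = rnbinom(30, 3, mu = 9),
            C = rnbinom(10, 3, mu = 6), D = rnbinom(18, 3, mu = 8))
  s <- grouped_sample(g)
  r1 <- single_step_median_test(s, cfg_fast(seed = 5))
  r2 <- single_step_median_test(s, cfg_fast(seed = 5))
  expect_identical(r1$p_adjusted, r2$p_adjusted)

  # renaming groups leaves every number unchanged
  s2 <- grouped_sample(setNames(g, c("W", "X", "Y", "Z")))
  r3 <- single_step_median_test(s2, cfg_fast(seed = 5))
  expect_identical(r1$p_adjusted, r3$p_adjusted)
  expect_identical(r1$d, r3$d)

  # reordering groups permutes the exact result consistently
  perm <- c(3L, 1L, 4L, 2L)
  small <- lapply(g, function(x) x[seq_len(3)])
  e1 <- exhaustive_null(grouped_sample(small))
  e2 <- exhaustive_null(grouped_sample(small[perm]))
  key <- function(r) {
    k <- apply(cbind(r$group_a, r$group_b), 1, function(x) paste(sort(x), collapse = "."))
    setNames(r$p_adjusted, k)
  }
  expect_equal(key(e2)[names(key(e1))], key(e1))

  # within one result, larger d never gets larger p; p bounded below by 1/(B+1)
  o <- order(r1$d, decreasing = TRUE)
  expect_false(is.unsorted(r1$p_adjusted[o]))
  expect_true(all(r1$p_adjusted >= 1 / (attr(r1, "B") + 1)))
})

test_that("step-down equals single-step for k = 2 and dominates it pairwise", {
  set.seed(21)
  g2 <- list(A = rnbinom(15, 3, mu = 8), B = rnbinom(12, 3, mu = 11))
  ss <- single_step_median_test(grouped_sample(g2), cfg_fast(seed = 2))
  sd <- step_down_cms_test(grouped_sample(g2), cfg_fast(seed = 2))
  expect_identical(ss$p_adjusted, sd$p_adjusted)
  expect_identical(attr(sd, "method"), "step_down_cms")

  for (seed in 1:5) {
    set.seed(300 + seed)
    g <- list(A = rnbinom(40, 3, mu = 8), B = rnbinom(40, 3, mu = 8),
              C = rnbinom(40, 3, mu = 8) + 5L, D = rnbinom(40, 3, mu = 8))
    s <- grouped_sample(g)
    ss <- single_step_median_test(s, cfg_fast(seed = seed))
    sd <- step_down_cms_test(s, cfg_fast(seed = seed))
    expect_true(all(sd$p_adjusted <= ss$p_adjusted))
    expect_true(all(ss$rejected <= sd$rejected))  # rejection superset
    # monotone non-decreasing down the d-ordering
    o <- order(sd$d, decreasing = TRUE)
    expect_false(is.unsorted(sd$p_adjusted[o]))
  }

  ident <- grouped_sample(list(A = rep(2, 4), B = rep(2, 4), C = rep(2, 4)))
  expect_true(all(suppressMessages(
    step_down_cms_test(ident, cfg_fast(100)))$p_adjusted == 1))
})

test_that("group_moments reports quantiles and shape per its conventions", {
  s <- grouped_sample(list(sym = c(1, 2, 3, 4, 5), skew = c(0, 0, 0, 10),
                           flat = rep(4, 6)))
  m <- group_moments(s)
  expect_equal(m$median[m$group == "sym"], 3)
  expect_equal(m$skewness[m$group == "sym"], 0)
  expect_gt(m$skewness[m$group == "skew"], 0)
  expect_true(is.na(m$skewness[m$group == "flat"]))   # zero variance marker
  expect_true(is.na(m$ex_kurtosis[m$group == "flat"]))
  expect_true(all(m$q1 <= m$median & m$median <= m$q3))

  # quartile convention: linear interpolation (type 7)
  x <- c(2, 7, 1, 9, 4, 4, 6)
  mm <- group_moments(grouped_sample(list(g = x)))
  expect_equal(unlist(mm[c("q1", "median", "q3")], use.names = FALSE),
               unname(quantile(x, c(.25, .5, .75), type = 7)))
})
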