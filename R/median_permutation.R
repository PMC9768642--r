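# Permutation tests for pairwise location shifts in the median among multiple
# groups, with strong familywise error control via the max-statistic, plus an
# exact enumeration oracle and distribution shape diagnostics.
#
# The test statistic is the unstudentized absolute difference of group medians.
# Under the null that all groups share one distribution, the pooled values are
# exchangeable; each permutation reassigns them to groups (preserving sizes)
# and records D_b, the maximum |median difference| over all group pairs.
# Referring every pairwise statistic to this one max-statistic distribution
# gives strong FWER control without normality or equal-n assumptions.

#' Configuration for the permutation tests
#'
#' @param n_permutations Monte Carlo permutations B (default 10000).
#' @param seed RNG seed; the same seed and input give identical p-values.
#' @param alpha familywise significance level.
#' @param method `"single_step"` or `"step_down_cms"` (conservative maximal
#'   subsets).
#' @return A `permutation_config` list.
#' @export
permutation_config <- function(n_permutations = 10000L, seed = 1L,
                               alpha = 0.05,
                               method = c("single_step", "step_down_cms")) {
  method <- match.arg(method)
  if (n_permutations < 1L) stop_config("config error: n_permutations must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop_config("config error: alpha must be in (0,1)")
  structure(list(n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), alpha = alpha, method = method),
            class = "permutation_config")
}

# all (i, j), i < j, ordered by i then j
pair_grid <- function(k) {
  p <- expand.grid(j = seq_len(k), i = seq_len(k))
  p <- p[p$i < p$j, c("i", "j")]
  p[order(p$i, p$j), , drop = FALSE]
}

group_medians <- function(groups) vapply(groups, median, numeric(1))

new_pairwise_result <- function(sample, pairs, p, method, B, seed, alpha) {
  labels <- names(sample$groups)
  med <- group_medians(sample$groups)
  out <- data.frame(
    group_a = labels[pairs$i], group_b = labels[pairs$j],
    median_a = unname(med[pairs$i]), median_b = unname(med[pairs$j]),
    d = unname(abs(med[pairs$i] - med[pairs$j])),
    p_adjusted = unname(p), rejected = unname(p <= alpha),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("pairwise_median_result", "data.frame"),
            variable = sample$variable, labels = labels, medians = med,
            sizes = sample$sizes, method = method, B = B, seed = seed,
            alpha = alpha)
}

check_two_groups <- function(sample) {
  stopifnot(inherits(sample, "grouped_sample"))
  if (length(sample$groups) < 2L) {
    stop_data("needs-two-groups error: %d group(s) supplied",
              length(sample$groups))
  }
}

#' Single-step permutation test of pairwise median differences
#'
#' All pairwise hypotheses are referred to one permutation distribution of the
#' maximum absolute median difference, giving strong familywise error control.
#' Monte Carlo adjusted p-values use the add-one convention
#' `(1 + #\{D_b >= d_ij\}) / (B + 1)`, so they lie in `[1/(B+1), 1]` and are
#' never zero. Within a result, a larger observed difference never receives a
#' larger adjusted p.
#'
#' @param sample a [grouped_sample()] with >= 2 non-empty groups.
#' @param config a [permutation_config()].
#' @return A `pairwise_median_result` data.frame (one row per unordered pair)
#'   with attributes recording medians, sizes, method, B, seed and alpha.
#' @export
single_step_median_test <- function(sample, config = permutation_config()) {
  check_two_groups(sample)
  k <- length(sample$groups)
  pairs <- pair_grid(k)
  pooled <- unlist(sample$groups, use.names = FALSE)
  B <- config$n_permutations
  med <- group_medians(sample$groups)
  d <- abs(med[pairs$i] - med[pairs$j])
  if (length(unique(pooled)) == 1L) {
    message("single_step_median_test: all values identical; p = 1 everywhere")
    p <- rep(1, nrow(pairs))
  } else {
    set.seed(config$seed)
    D <- perm_max_median_diff(pooled, as.integer(sample$sizes), B)
    p <- vapply(d, function(di) (1 + sum(D >= di)) / (B + 1), numeric(1))
  }
  res <- new_pairwise_result(sample, pairs, p, "single_step", B,
                             config$seed, config$alpha)
  assert_p_monotone(res)
  res
}

# invariant: within one single-step result, d_ij >= d_kl => p_ij <= p_kl
assert_p_monotone <- function(res) {
  o <- order(res$d, decreasing = TRUE)
  if (is.unsorted(res$p_adjusted[o])) {
    stop("internal error: adjusted p not monotone in the observed statistic")
  }
  invisible(res)
}

#' Step-down permutation test (conservative maximal subsets)
#'
#' Sequential variant of [single_step_median_test()], more powerful because
#' hypotheses already rejected no longer inflate the reference max-statistic.
#' Hypotheses are visited in decreasing order of the observed |median
#' difference|. At each step the groups that could still be jointly homogeneous
#' form a graph whose edges are the not-yet-rejected pairs; for every maximal
#' clique containing the current pair, a restricted permutation max-statistic
#' null is computed over that clique's values, and the largest (most
#' conservative) of the candidate p-values is taken. Adjusted p-values are
#' enforced monotone non-decreasing down the ordering and never exceed the
#' single-step p for the same pair under the shared permutation stream.
#' With two groups the result equals the single-step result exactly.
#'
#' @inheritParams single_step_median_test
#' @return A `pairwise_median_result` (rows in the same pair order as the
#'   single-step result).
#' @export
step_down_cms_test <- function(sample, config = permutation_config()) {
  check_two_groups(sample)
  k <- length(sample$groups)
  if (k > 12L) {
    stop_config("config error: step-down subset search supports at most 12 groups")
  }
  ss <- single_step_median_test(sample, config)
  if (k == 2L) {
    attr(ss, "method") <- "step_down_cms"
    return(ss)
  }
  B <- config$n_permutations
  pairs <- pair_grid(k)
  d <- ss$d
  ord <- order(d, -seq_along(d), decreasing = TRUE)  # ties: keep pair order
  adj <- matrix(TRUE, k, k)
  diag(adj) <- FALSE
  clique_cache <- new.env(parent = emptyenv())
  p_out <- numeric(nrow(pairs))
  p_prev <- 0
  degenerate <- length(unique(unlist(sample$groups, use.names = FALSE))) == 1L
  for (t in ord) {
    i <- pairs$i[t]; j <- pairs$j[t]
    if (degenerate) {
      p <- 1
    } else {
      cliques <- maximal_cliques_with(adj, i, j)
      p_raw <- 0
      for (cl in cliques) {
        if (length(cl) == k) {
          # full clique: identical to the single-step reference for this d
          p_c <- ss$p_adjusted[t]
        } else {
          D <- clique_null(sample, cl, B, config$seed, clique_cache)
          p_c <- (1 + sum(D >= d[t])) / (B + 1)
        }
        p_raw <- max(p_raw, p_c)
      }
      p <- min(max(p_raw, p_prev), ss$p_adjusted[t])
    }
    p_out[t] <- p
    p_prev <- p
    if (p <= config$alpha) adj[i, j] <- adj[j, i] <- FALSE
  }
  res <- new_pairwise_result(sample, pairs, p_out, "step_down_cms", B,
                             config$seed, config$alpha)
  res
}

# restricted permutation null over the groups in `cl`, cached per clique;
# seeded deterministically from the master seed and the clique bitmask
clique_null <- function(sample, cl, B, seed, cache) {
  key <- paste(cl, collapse = ".")
  if (!is.null(cache[[key]])) return(cache[[key]])
  groups <- sample$groups[cl]
  set.seed(substream_seed(seed, sum(2^(cl - 1L))))
  D <- perm_max_median_diff(unlist(groups, use.names = FALSE),
                            as.integer(lengths(groups)), B)
  cache[[key]] <- D
  D
}

# maximal cliques containing both i and j in the graph `adj`
# (edges = not-yet-rejected pairs); brute force over the joint neighbourhood
maximal_cliques_with <- function(adj, i, j) {
  if (!adj[i, j]) stop("internal error: current pair already rejected")
  cand <- setdiff(which(adj[i, ] & adj[j, ]), c(i, j))
  m <- length(cand)
  cliques <- list()
  for (mask in 0:(2^m - 1)) {
    sub <- cand[bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0L]
    s <- c(i, j, sub)
    sub_adj <- adj[s, s, drop = FALSE]
    if (all(sub_adj[upper.tri(sub_adj)])) {
      # maximal iff no outside vertex is adjacent to all of s
      outside <- setdiff(seq_len(nrow(adj)), s)
      if (!length(outside) || !any(colSums(adj[s, outside, drop = FALSE]) == length(s))) {
        cliques[[length(cliques) + 1L]] <- sort(s)
      }
    }
  }
  cliques
}

#' Exact enumeration oracle for the single-step test
#'
#' Enumerates every labelled assignment of the pooled values to groups of the
#' observed sizes and computes the exact single-step p-value
#' `#\{assignments : D >= d_ij\} / #assignments`. Independent of the Monte
#' Carlo code path; intended as a small-instance oracle.
#'
#' @param sample a [grouped_sample()]; the multinomial coefficient of the
#'   group sizes must not exceed `max_assignments`.
#' @param alpha significance level recorded in the result.
#' @param max_assignments size guard (default 1e6).
#' @return A `pairwise_median_result` with `method = "exhaustive"`.
#' @export
exhaustive_null <- function(sample, alpha = 0.05, max_assignments = 1e6) {
  check_two_groups(sample)
  sizes <- as.integer(sample$sizes)
  n <- sum(sizes)
  n_assign <- exp(lgamma(n + 1) - sum(lgamma(sizes + 1)))
  if (n_assign > max_assignments) {
    stop_config("size-guard error: %.3g assignments exceeds limit %g",
                n_assign, max_assignments)
  }
  pooled <- unlist(sample$groups, use.names = FALSE)
  k <- length(sizes)
  D <- numeric(round(n_assign))
  count <- 0L
  recurse <- function(avail, g, meds) {
    if (g == k) {
      meds[k] <- median(pooled[avail])
      count <<- count + 1L
      D[count] <<- max(abs(outer(meds, meds, "-")))
      return(invisible())
    }
    picks <- combn(avail, sizes[g], simplify = FALSE)
    for (pick in picks) {
      meds[g] <- median(pooled[pick])
      recurse(setdiff(avail, pick), g + 1L, meds)
    }
  }
  recurse(seq_len(n), 1L, numeric(k))
  stopifnot(count == length(D))
  pairs <- pair_grid(k)
  med <- group_medians(sample$groups)
  d <- abs(med[pairs$i] - med[pairs$j])
  p <- vapply(d, function(di) sum(D >= di) / count, numeric(1))
  new_pairwise_result(sample, pairs, p, "exhaustive", count, NA_integer_, alpha)
}

#' Per-group sample moments and quartiles
#'
#' Medians and quartiles use the linear-interpolation convention
#' (`stats::quantile` type 7). Shape measures are the moment estimators
#' `g1 = m3 / m2^(3/2)` and excess kurtosis `g2 = m4 / m2^2 - 3` with central
#' sample moments `mk`; they are reported only where defined (`n >= 3` for g1,
#' `n >= 4` for g2) and are `NA` for zero-variance groups.
#'
#' @param sample a [grouped_sample()].
#' @return A `data.frame` with one row per group: `group`, `n`, `min`, `q1`,
#'   `median`, `q3`, `max`, `skewness`, `ex_kurtosis`.
#' @export
group_moments <- function(sample) {
  stopifnot(inherits(sample, "grouped_sample"))
  rows <- lapply(names(sample$groups), function(g) {
    x <- sample$groups[[g]]
    n <- length(x)
    m2 <- mean((x - mean(x))^2)
    g1 <- if (n >= 3L && m2 > 0) mean((x - mean(x))^3) / m2^1.5 else NA_real_
    g2 <- if (n >= 4L && m2 > 0) mean((x - mean(x))^4) / m2^2 - 3 else NA_real_
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(group = g, n = n, min = min(x), q1 = q[1], median = q[2],
               q3 = q[3], max = max(x), skewness = g1, ex_kurtosis = g2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.pairwise_median_result <- function(x, ...) {
  cat(sprintf("pairwise median test (%s, B = %s) on %s; alpha = %g\n",
              attr(x, "method"), format(attr(x, "B"), big.mark = ","),
              attr(x, "variable"), attr(x, "alpha")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Long-format result table
#'
#' Flattens a `pairwise_median_result` into the canonical long CSV layout:
#' variable, group_a, group_b, median_a, median_b, d, p_adjusted, rejected,
#' method, B, seed.
#'
#' @param result a `pairwise_median_result`.
#' @return A plain data.frame.
#' @export
result_long <- function(result) {
  stopifnot(inherits(result, "pairwise_median_result"))
  data.frame(variable = attr(result, "variable"),
             as.data.frame(result),
             method = attr(result, "method"),
             B = attr(result, "B"),
             seed = attr(result, "seed"),
             stringsAsFactors = FALSE)
}
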