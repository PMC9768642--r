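fast_plan <- function(vars = "thorax", B = 500, seed = 1, method = "single_step") {
  analysis_plan(vars, "period",
                config = permutation_config(B, seed = seed, method = method))
}

test_that("run_timescale tests each variable once and extracts views", {
  rec <- make_records(60, period = rep(palaeozoic_periods()[1:3], each = 20),
                      thorax = rep(c(12L, 8L, 8L), each = 20),
                      pygidium = 5L)
  res <- run_timescale(rec, fast_plan(c("thorax", "proportion"), B = 1000))
  expect_named(res, c("thorax", "proportion"))
  expect_equal(nrow(res$thorax), 3L)            # all pairs of 3 bins
  seq_rows <- sequential_view(res$thorax)
  expect_equal(nrow(seq_rows), 2L)
  # sequential view is exactly the adjacent-pair subset, not a re-test
  key <- paste(res$thorax$group_a, res$thorax$group_b)
  expect_true(all(paste(seq_rows$group_a, seq_rows$group_b) %in% key))
  expect_equal(seq_rows$p_adjusted,
               res$thorax$p_adjusted[match(paste(seq_rows$group_a, seq_rows$group_b), key)])

  # two-bin toy with identical values -> p = 1
  toy <- make_records(8, period = rep(c("Cambrian", "Permian"), each = 4),
                      thorax = 9L)
  r <- suppressMessages(run_timescale(toy, fast_plan(B = 100)))
  expect_equal(r$thorax$p_adjusted, 1)

  one_bin <- make_records(5, period = "Permian")
  expect_error(run_timescale(one_bin, fast_plan()), "2 non-empty time bins",
               class = "sg_data_error")
})

test_that("jackknife flags flips when the shifted clade is removed", {
  # Shifter carries the entire Cambrian-Ordovician thorax shift; Steady is flat
  set.seed(4)
  n <- 50
  rec <- segment_data(data.frame(
    species = sprintf("s%03d", 1:(4 * n)),
    order = rep(c("Shifter", "Steady"), each = 2 * n),
    family = rep(c("ShifterFam", "SteadyFam"), each = 2 * n),
    period = rep(rep(c("Cambrian", "Ordovician"), each = n), 2),
    thorax = c(rpois(n, 14) + 5L, rpois(n, 5), rpois(n, 9), rpois(n, 9)),
    pygidium = 5L, stringsAsFactors = FALSE))
  plan <- fast_plan(B = 1000, seed = 3)
  jk <- jackknife_taxa(rec, plan, grouping = "order")
  expect_named(jk$runs, c("Shifter", "Steady"))
  full_sig <- jk$full$thorax$rejected
  expect_true(any(full_sig))
  expect_false(any(jk$runs$Shifter$thorax$rejected))
  expect_true("Shifter" %in% jk$flips$taxon)
  expect_true(all(jk$flips$direction[jk$flips$taxon == "Shifter"] == "lost"))

  expect_error(jackknife_taxa(rec, plan, taxa = "Trilobita"),
               "unknown order group", class = "sg_data_error")
})

test_that("jackknife recovers the full result when the left-out taxon carries no data", {
  # Ghost's records all lack a pygidial count, so for the pygidium variable
  # the grouped values are identical with or without Ghost.
  base <- make_records(60, order = rep(c("Phacopida", "Proetida"), 30),
                       period = rep(palaeozoic_periods()[1:3], 20),
                       thorax = 9L, pygidium = rep(c(4L, 9L, 6L), 20))
  ghost <- make_records(6, species = sprintf("gh%d", 1:6), order = "Ghost",
                        family = "GhostFam",
                        period = palaeozoic_periods()[1:3],
                        thorax = 7L, pygidium = NA)
  rec <- segment_data(rbind(as.data.frame(base), as.data.frame(ghost)))
  jk <- jackknife_taxa(rec, fast_plan("pygidium", B = 400, seed = 9),
                       grouping = "order", taxa = "Ghost")
  expect_s3_class(jk$runs$Ghost$pygidium, "pairwise_median_result")
  expect_identical(jk$runs$Ghost$pygidium$p_adjusted,
                   jk$full$pygidium$p_adjusted)
  expect_equal(nrow(jk$flips), 0L)
})

test_that("rarefied ranges are bounded, exact at full size, monotone in n_sub", {
  rec <- generate_dataset(scenario_preset("range_contraction", seed = 7))
  rr <- rarefied_range(rec, "thorax", n_iterations = 200, seed = 2)
  obs <- rr$summary$observed_range
  for (b in seq_along(rr$ranges)) {
    expect_true(all(rr$ranges[[b]] <= obs[b]))
  }
  # monotone construction of the preset survives rarefaction
  expect_true(all(diff(rr$summary$median_rarefied) < 0))

  # n_sub equal to the bin size reproduces the observed range exactly
  small <- make_records(30, period = rep(c("Cambrian", "Permian"), each = 15),
                        thorax = c(3:17, 6:20))
  rr2 <- rarefied_range(small, "thorax", n_iterations = 50, n_sub = 15, seed = 1)
  expect_true(all(unlist(rr2$ranges) == 14))
  expect_equal(rr2$summary$median_rarefied, rr2$summary$observed_range)

  expect_error(rarefied_range(small, "thorax", n_sub = 16),
               "config error", class = "sg_config_error")

  # expected rarefied range non-decreasing in n_sub
  m5 <- mean(rarefied_range(rec, "thorax", 200, n_sub = 5, seed = 3)$summary$mean_rarefied)
  m40 <- mean(rarefied_range(rec, "thorax", 200, n_sub = 40, seed = 3)$summary$mean_rarefied)
  expect_lt(m5, m40)
})

test_that("family ranges are computed per (family, bin) with a species floor", {
  rec <- make_records(5, family = c("Fa", "Fa", "Fa", "Fb", "Fb"),
                      period = "Devonian", thorax = c(6L, 8L, 11L, 9L, 9L))
  fr <- family_range_by_interval(rec, "thorax", min_species = 2)
  expect_equal(fr$per_family$range[fr$per_family$family == "Fa"], 5)
  expect_equal(fr$per_family$range[fr$per_family$family == "Fb"], 0)
  expect_equal(fr$summary$median_range, 2.5)

  mono <- make_records(12, family = rep(c("Fa", "Fb"), each = 6),
                       period = rep(c("Cambrian", "Permian"), 6), thorax = 9L)
  fr2 <- family_range_by_interval(mono, "thorax")
  expect_true(all(fr2$per_family$range == 0))
  expect_true(all(fr2$summary$median_range == 0))

  single <- make_records(3, family = c("Fa", "Fb", "Fc"), period = "Permian")
  expect_error(family_range_by_interval(single, "thorax"),
               "empty selection", class = "sg_data_error")

  cons <- generate_dataset(scenario_preset("family_conservation", seed = 7))
  fr3 <- family_range_by_interval(cons, "thorax")
  expect_true(all(diff(fr3$summary$median_range) < 0))
})

test_that("enrolment analyses subset, prune and test both arms", {
  expect_error(enrolment_analyses(make_records(10)),
               "no enrolment labels", class = "sg_data_error")

  set.seed(6)
  n <- 40
  rec <- segment_data(data.frame(
    species = sprintf("e%03d", 1:(3 * n)),
    order = "O", family = "F",
    period = rep(c("Cambrian", "Ordovician"), length.out = 3 * n),
    thorax = c(rpois(n, 12) + 3L, rpois(n, 12) + 3L, rpois(n, 3)),
    pygidium = 6L,
    enrolment = rep(c("spheroidal", "cylindrical", "discoidal"), each = n),
    stringsAsFactors = FALSE))
  en <- enrolment_analyses(rec, permutation_config(1000, seed = 2),
                           variables = "thorax")
  bt <- en$between$thorax
  expect_s3_class(bt, "pairwise_median_result")
  disc <- bt$group_a == "discoidal" | bt$group_b == "discoidal"
  expect_true(all(bt$rejected[disc]))       # the low-median strategy stands out
  expect_false(any(bt$rejected[!disc]))
  expect_named(en$within, c("cylindrical", "discoidal", "spheroidal"))

  # groups under the n floor are dropped with a warning
  rec2 <- rbind(as.data.frame(rec),
                data.frame(species = "rare1", order = "O", family = "F",
                           period = "Cambrian", series = NA, thorax = 30L,
                           pygidium = 6L, enrolment = "other"))
  w <- capture_warnings(
    en2 <- enrolment_analyses(segment_data(rec2),
                              permutation_config(200, seed = 2),
                              variables = "thorax"))
  expect_true(any(grepl("n < 5", w)))
  expect_false("other" %in% c(en2$between$thorax$group_a,
                              en2$between$thorax$group_b))
})

test_that("run_all captures per-stage errors and completes the rest", {
  rec <- generate_dataset(scenario_preset("pygidium_trend", seed = 5))
  out <- file.path(tempdir(), "runall_err")
  cfg <- run_config(variables = "thorax", timescale = "series",
                    permutation = permutation_config(200, seed = 1),
                    stages = c("timescale", "family_ranges"))
  mf <- run_all(rec, cfg, out)   # synthetic data has no series column
  expect_match(mf$stages$timescale, "^error:")
  expect_match(mf$stages$family_ranges, "^error:")
  cfg2 <- run_config(variables = "thorax", timescale = "period",
                     permutation = permutation_config(200, seed = 1),
                     stages = c("timescale", "family_ranges"))
  mf2 <- run_all(rec, cfg2, out)
  expect_identical(mf2$stages$timescale, "ok")
  expect_identical(mf2$stages$family_ranges, "ok")
  expect_true(file.exists(file.path(out, "timescale_all_pairs.csv")))
  expect_true(all(unlist(mf2$outputs) != ""))
})
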