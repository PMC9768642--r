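# Orchestration of the full analysis: per-variable tests across a timescale,
# jackknife clade-removal sensitivity, range rarefaction, within-family range
# trends and enrolment-strategy subsets.

#' Define an analysis plan
#'
#' @param variables subset of `c("thorax", "pygidium", "trunk", "proportion")`.
#' @param timescale `"period"` (coarse) or `"series"` (fine).
#' @param taxon_scope optional character vector of order names to restrict to.
#' @param config a [permutation_config()]; its `method` selects the test.
#' @return An `analysis_plan` list.
#' @export
analysis_plan <- function(variables = segment_variables(),
                          timescale = c("period", "series"),
                          taxon_scope = NULL,
                          config = permutation_config()) {
  timescale <- match.arg(timescale)
  variables <- match.arg(variables, segment_variables(), several.ok = TRUE)
  if (!length(variables)) stop_config("config error: empty variable set")
  structure(list(variables = variables, timescale = timescale,
                 taxon_scope = taxon_scope, config = config),
            class = "analysis_plan")
}

plan_filter <- function(plan) {
  if (is.null(plan$taxon_scope)) return(NULL)
  scope <- plan$taxon_scope
  function(df) !is.na(df$order) & df$order %in% scope
}

#' Run the planned tests across a timescale
#'
#' One all-pairs analysis per variable; sequential (adjacent-bin) and
#' long-term (all-pairs) views are both extracted from this single analysis
#' rather than re-tested (see [sequential_view()]). Each variable gets a
#' deterministic substream of the plan's seed so variables are independent but
#' the whole run is reproducible.
#'
#' @param records a `segment_data` data.frame.
#' @param plan an [analysis_plan()].
#' @return Named list (one `pairwise_median_result` per variable), class
#'   `timescale_results`.
#' @export
run_timescale <- function(records, plan = analysis_plan()) {
  test_fun <- switch(plan$config$method,
                     single_step = single_step_median_test,
                     step_down_cms = step_down_cms_test)
  out <- lapply(plan$variables, function(v) {
    sample <- group_segments(records, v, by = plan$timescale,
                             filter = plan_filter(plan))
    if (length(sample$groups) < 2L) {
      stop_data("empty selection: fewer than 2 non-empty time bins for %s", v)
    }
    cfg <- plan$config
    cfg$seed <- substream_seed(cfg$seed, match(v, segment_variables()))
    test_fun(sample, cfg)
  })
  names(out) <- plan$variables
  structure(out, class = "timescale_results", timescale = plan$timescale)
}

#' Adjacent-bin (sequential) view of an all-pairs result
#'
#' Subsets the rows of an all-pairs result to chronologically adjacent bins.
#' No re-testing is done: the rows are exactly a subset of the all-pairs rows.
#'
#' @param result a `pairwise_median_result` from a time-bin analysis.
#' @return The adjacent-pair rows of `result`.
#' @export
sequential_view <- function(result) {
  labels <- attr(result, "labels")
  keep <- match(result$group_b, labels) - match(result$group_a, labels) == 1L
  out <- result[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Leave-one-taxon-out jackknife of the timescale analysis
#'
#' Repeats [run_timescale()] with each taxon (order by default) removed in
#' turn and flags every comparison whose rejection status at the plan's alpha
#' flips relative to the all-taxa run. A left-out run that empties a time bin
#' (or otherwise degenerates) is recorded as such, not fatal.
#'
#' @param records a `segment_data` data.frame.
#' @param plan an [analysis_plan()].
#' @param grouping `"order"` or `"family"`.
#' @param taxa optional subset of taxa to leave out (default: all present);
#'   naming an absent taxon is an error.
#' @return A `jackknife_report`: list with `full` (all-taxa results), `runs`
#'   (per left-out taxon: `timescale_results` or an error condition) and
#'   `flips` (data.frame taxon/variable/group_a/group_b/direction).
#' @export
jackknife_taxa <- function(records, plan = analysis_plan(),
                           grouping = c("order", "family"), taxa = NULL) {
  grouping <- match.arg(grouping)
  present <- sort(unique(stats::na.omit(as.data.frame(records)[[grouping]])))
  if (length(present) < 2L) {
    stop_data("empty selection: need >= 2 distinct %s groups", grouping)
  }
  if (is.null(taxa)) {
    taxa <- present
  } else if (length(missing <- setdiff(taxa, present))) {
    stop_data("unknown %s group(s): %s", grouping,
              paste(missing, collapse = ", "))
  }
  full <- run_timescale(records, plan)
  runs <- lapply(taxa, function(tx) {
    keep <- is.na(records[[grouping]]) | records[[grouping]] != tx
    tryCatch(run_timescale(records[keep, , drop = FALSE], plan),
             error = function(e) e)
  })
  names(runs) <- taxa
  flips <- list()
  for (tx in taxa) {
    run <- runs[[tx]]
    if (inherits(run, "error")) next
    for (v in names(full)) {
      a <- full[[v]]; b <- run[[v]]
      key_a <- paste(a$group_a, a$group_b)
      key_b <- paste(b$group_a, b$group_b)
      common <- intersect(key_a, key_b)
      ra <- a$rejected[match(common, key_a)]
      rb <- b$rejected[match(common, key_b)]
      ch <- which(ra != rb)
      if (length(ch)) {
        flips[[length(flips) + 1L]] <- data.frame(
          taxon = tx, variable = v,
          group_a = a$group_a[match(common, key_a)][ch],
          group_b = a$group_b[match(common, key_a)][ch],
          direction = ifelse(ra[ch], "lost", "gained"),
          stringsAsFactors = FALSE)
      }
    }
  }
  flips <- if (length(flips)) do.call(rbind, flips) else
    data.frame(taxon = character(), variable = character(),
               group_a = character(), group_b = character(),
               direction = character(), stringsAsFactors = FALSE)
  structure(list(full = full, runs = runs, flips = flips),
            class = "jackknife_report", grouping = grouping)
}

#' Rarefied per-bin range of a segment variable
#'
#' Subsamples each time bin without replacement to a common size `n_sub`
#' (default: the smallest bin) `n_iterations` times and records the range
#' (max - min) of each subsample, removing sample-size artefacts from raw
#' range comparisons. The rarefied range can never exceed the observed range.
#'
#' @param records a `segment_data` data.frame.
#' @param variable analysis variable (default `"thorax"`).
#' @param n_iterations subsample draws per bin.
#' @param n_sub common subsample size; must not exceed the smallest bin.
#' @param seed RNG seed.
#' @param timescale `"period"` or `"series"`.
#' @return A `rarefaction_report`: `summary` data.frame (bin, n,
#'   observed_range, median/mean rarefied range, 5% and 95% quantiles) and
#'   `ranges`, the per-bin matrix-free list of all subsampled ranges.
#' @export
rarefied_range <- function(records, variable = "thorax", n_iterations = 1000L,
                           n_sub = NULL, seed = 1L,
                           timescale = c("period", "series")) {
  timescale <- match.arg(timescale)
  sample <- group_segments(records, variable, by = timescale)
  min_n <- min(sample$sizes)
  if (is.null(n_sub)) n_sub <- min_n
  if (n_sub < 1L || n_sub > min_n) {
    stop_config("config error: n_sub = %d exceeds smallest bin size %d",
                n_sub, min_n)
  }
  set.seed(substream_seed(seed, 211L))
  ranges <- lapply(sample$groups, function(x) {
    vapply(seq_len(n_iterations), function(i) {
      s <- x[sample.int(length(x), n_sub)]
      max(s) - min(s)
    }, numeric(1))
  })
  summary <- data.frame(
    bin = names(sample$groups),
    n = as.integer(sample$sizes),
    n_sub = as.integer(n_sub),
    observed_range = vapply(sample$groups, function(x) max(x) - min(x),
                            numeric(1)),
    median_rarefied = vapply(ranges, median, numeric(1)),
    mean_rarefied = vapply(ranges, mean, numeric(1)),
    q05 = vapply(ranges, quantile, numeric(1), probs = 0.05, names = FALSE),
    q95 = vapply(ranges, quantile, numeric(1), probs = 0.95, names = FALSE),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(summary = summary, ranges = ranges, variable = variable,
                 n_iterations = as.integer(n_iterations), seed = seed),
            class = "rarefaction_report")
}

#' Within-family range of a segment variable per time bin
#'
#' For every (family, bin) cell with at least `min_species` species, the range
#' (max - min) of the variable is computed; per-bin medians and means of these
#' ranges track how conserved the trait is within families through time.
#' Singleton families carry no range information and are excluded.
#'
#' @param records a `segment_data` data.frame.
#' @param variable analysis variable (default `"thorax"`).
#' @param min_species minimum species per (family, bin) cell.
#' @param timescale `"period"` or `"series"`.
#' @return A `family_range_report`: `per_family` data.frame (bin, family, n,
#'   range) and `summary` data.frame (bin, n_families, median_range,
#'   mean_range).
#' @export
family_range_by_interval <- function(records, variable = "thorax",
                                     min_species = 2L,
                                     timescale = c("period", "series")) {
  timescale <- match.arg(timescale)
  df <- derive_variables(as.data.frame(records))
  df <- df[!is.na(df[[variable]]) & !is.na(df$family) & !is.na(df[[timescale]]), ]
  if (!nrow(df)) stop_data("empty selection: no records with family and %s", variable)
  cell <- split(df[[variable]], list(bin = df[[timescale]], family = df$family),
                drop = TRUE, sep = "\r")
  cell <- cell[lengths(cell) >= min_species]
  if (!length(cell)) {
    stop_data("empty selection: no family with >= %d species in any bin",
              min_species)
  }
  keys <- do.call(rbind, strsplit(names(cell), "\r", fixed = TRUE))
  per_family <- data.frame(bin = keys[, 1], family = keys[, 2],
                           n = lengths(cell),
                           range = vapply(cell, function(x) max(x) - min(x),
                                          numeric(1)),
                           stringsAsFactors = FALSE, row.names = NULL)
  bins <- if (timescale == "period") palaeozoic_periods() else palaeozoic_series()
  bins <- c(bins[bins %in% per_family$bin],
            sort(setdiff(unique(per_family$bin), bins)))
  per_family <- per_family[order(match(per_family$bin, bins), per_family$family), ]
  rownames(per_family) <- NULL
  summary <- do.call(rbind, lapply(bins, function(b) {
    r <- per_family$range[per_family$bin == b]
    data.frame(bin = b, n_families = length(r), median_range = median(r),
               mean_range = mean(r), stringsAsFactors = FALSE)
  }))
  structure(list(per_family = per_family, summary = summary,
                 variable = variable, min_species = as.integer(min_species)),
            class = "family_range_report")
}

#' Enrolment-strategy analyses
#'
#' Two arms, both on the subset of records with a recorded enrolment label and
#' both dropping groups below `min_n` (small subsets preclude testing):
#' (a) between strategies, pooling the whole Palaeozoic, one test per
#' variable; (b) within each strategy, across time bins, one test per
#' variable. An arm with fewer than two usable groups yields a captured
#' empty-selection error rather than aborting the other arm.
#'
#' @param records a `segment_data` data.frame.
#' @param config a [permutation_config()].
#' @param variables analysis variables (default thorax and pygidial
#'   proportion).
#' @param min_n minimum records per tested group.
#' @param timescale `"period"` or `"series"`.
#' @return List with `between` (variable -> result) and `within` (strategy ->
#'   variable -> result); unusable cells hold the captured condition object.
#' @export
enrolment_analyses <- function(records, config = permutation_config(),
                               variables = c("thorax", "proportion"),
                               min_n = 5L, timescale = c("period", "series")) {
  timescale <- match.arg(timescale)
  df <- as.data.frame(records)
  if (!any(!is.na(df$enrolment))) {
    stop_data("empty selection: no enrolment labels present")
  }
  prune <- function(sample) {
    small <- sample$sizes < min_n
    if (any(small)) {
      warning(sprintf("dropping %s group(s) with n < %d: %s", sample$variable,
                      min_n, paste(names(sample$groups)[small], collapse = ", ")),
              call. = FALSE)
      sample$groups <- sample$groups[!small]
      sample$sizes <- lengths(sample$groups)
    }
    if (length(sample$groups) < 2L) {
      stop_data("empty selection: fewer than 2 usable groups after n >= %d filter",
                min_n)
    }
    sample
  }
  test_fun <- switch(config$method,
                     single_step = single_step_median_test,
                     step_down_cms = step_down_cms_test)
  between <- lapply(variables, function(v) {
    tryCatch({
      cfg <- config
      cfg$seed <- substream_seed(config$seed, paste0("between.", v))
      test_fun(prune(group_segments(df, v, by = "enrolment")), cfg)
    }, sg_data_error = function(e) e)
  })
  names(between) <- variables
  strategies <- sort(unique(stats::na.omit(df$enrolment)))
  within <- lapply(strategies, function(s) {
    res <- lapply(variables, function(v) {
      tryCatch({
        cfg <- config
        cfg$seed <- substream_seed(config$seed, paste0("within.", s, ".", v))
        sample <- group_segments(
          df, v, by = timescale,
          filter = function(d) !is.na(d$enrolment) & d$enrolment == s)
        test_fun(prune(sample), cfg)
      }, sg_data_error = function(e) e)
    })
    names(res) <- variables
    res
  })
  names(within) <- strategies
  list(between = between, within = within)
}
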