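# Data model: species-level segment-count records with taxonomic and
# stratigraphic metadata, plus derived trunk variables and grouped samples.

canonical_columns <- function() {
  c("species", "order", "family", "period", "series", "thorax", "pygidium",
    "enrolment")
}

required_columns <- function() c("species", "order", "family", "period", "thorax")

#' Construct and validate a species-level segment-count table
#'
#' Canonicalizes period labels (case-insensitive), coerces count columns and
#' enforces the record invariants: `thorax >= 0` and `pygidium >= 0` as
#' integers, a trunk exists (`thorax + pygidium >= 1` where the pygidial count
#' is known), and `period` drawn from the six Palaeozoic periods. Records with
#' a missing pygidial count are retained (usable for thorax-only analyses);
#' rows violating an invariant are rejected with row-indexed diagnostics
#' attached to the result.
#'
#' @param df data.frame with canonical columns (see [read_segment_data()] for
#'   mapping arbitrary headers). Missing optional columns (`series`,
#'   `pygidium`, `enrolment`) are filled with `NA`.
#' @return A `segment_data` data.frame. Attributes: `n_rejected` and
#'   `rejected` (data.frame of row index and reason).
#' @export
segment_data <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_req <- setdiff(required_columns(), names(df))
  if (length(missing_req)) {
    stop_config("schema error: missing required column(s): %s",
                paste(missing_req, collapse = ", "))
  }
  for (col in setdiff(canonical_columns(), names(df))) df[[col]] <- NA
  df <- df[canonical_columns()]

  # Non-integer numeric counts are file corruption, not a rejectable row.
  for (col in c("thorax", "pygidium")) {
    v <- df[[col]]
    if (is.character(v)) {
      v[!nzchar(trimws(v))] <- NA
      num <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(num))
      if (length(bad)) {
        stop_data("validation error: non-numeric %s count in row(s): %s",
                  col, paste(bad, collapse = ", "))
      }
      v <- num
    }
    nonint <- which(!is.na(v) & v != floor(v))
    if (length(nonint)) {
      stop_data("validation error: non-integer %s count in row(s): %s",
                col, paste(nonint, collapse = ", "))
    }
    df[[col]] <- as.integer(v)
  }

  periods <- palaeozoic_periods()
  canon <- periods[match(tolower(trimws(as.character(df$period))),
                         tolower(periods))]

  reason <- character(nrow(df))
  bad_period <- is.na(canon)
  reason[bad_period] <- "period not a Palaeozoic period"
  neg <- (!is.na(df$thorax) & df$thorax < 0) |
    (!is.na(df$pygidium) & df$pygidium < 0)
  reason[neg & !nzchar(reason)] <- "negative segment count"
  na_thorax <- is.na(df$thorax)
  reason[na_thorax & !nzchar(reason)] <- "missing thoracic count"
  no_trunk <- !na_thorax & !is.na(df$pygidium) & (df$thorax + df$pygidium) < 1L
  reason[no_trunk & !nzchar(reason)] <- "thorax + pygidium < 1 (no trunk)"

  keep <- !nzchar(reason)
  rejected <- data.frame(row = which(!keep), reason = reason[!keep],
                         stringsAsFactors = FALSE)
  df$period <- canon
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (col in c("species", "order", "family", "series", "enrolment")) {
    out[[col]] <- as.character(out[[col]])
    out[[col]][!is.na(out[[col]]) & !nzchar(trimws(out[[col]]))] <- NA_character_
  }
  if (nrow(rejected)) {
    message(sprintf("segment_data: accepted %d row(s), rejected %d row(s)",
                    nrow(out), nrow(rejected)))
  }
  structure(out, class = c("segment_data", "data.frame"),
            n_rejected = nrow(rejected), rejected = rejected)
}

#' Read a species-level segment-count table from CSV
#'
#' Reads an RFC-4180 CSV (UTF-8, header row), optionally remapping arbitrary
#' source headers onto the canonical names `species`, `order`, `family`,
#' `period`, `series`, `thorax`, `pygidium`, `enrolment`, then validates via
#' [segment_data()].
#'
#' @param path path to a CSV file.
#' @param schema optional named character vector mapping canonical name ->
#'   source header, e.g. `c(thorax = "Th", species = "taxon_name")`.
#' @return A validated `segment_data` data.frame.
#' @export
read_segment_data <- function(path, schema = NULL) {
  if (!file.exists(path)) stop_data("I/O error: no such file: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""),
                 fileEncoding = "UTF-8", colClasses = "character")
  if (!is.null(schema)) {
    bad <- setdiff(unname(schema), names(df))
    if (length(bad)) {
      stop_config("schema error: mapped column(s) absent from file: %s",
                  paste(bad, collapse = ", "))
    }
    for (canon in names(schema)) {
      names(df)[names(df) == schema[[canon]]] <- canon
    }
  }
  segment_data(df)
}

#' Write a segment-count table as canonical CSV
#'
#' The canonical dialect (fixed column order, unquoted numerics, `NA` as the
#' empty string) round-trips: writing the result of reading a written file
#' reproduces it byte-identically.
#'
#' @param x a `segment_data` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segment_data <- function(x, path) {
  out <- as.data.frame(x)[canonical_columns()]
  write.csv(out, path, row.names = FALSE, na = "", quote = FALSE,
            fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

#' Derive trunk segment count and pygidial proportion
#'
#' Adds `trunk = thorax + pygidium` (exact integer arithmetic) and
#' `proportion = pygidium / trunk`, the fraction of trunk segments fused into
#' the pygidium. Both are `NA` where the pygidial count is unknown. The
#' proportion lies in (0, 1] and equals 1 exactly when `thorax == 0`.
#'
#' @param x a `segment_data` data.frame.
#' @return `x` with `trunk` and `proportion` columns appended.
#' @export
derive_variables <- function(x) {
  stopifnot(is.data.frame(x))
  trunk <- x$thorax + x$pygidium
  if (any(!is.na(trunk) & trunk == 0L)) {
    stop_data("degenerate record: trunk == 0 (should have been rejected upstream)")
  }
  x$trunk <- trunk
  x$proportion <- ifelse(is.na(trunk), NA_real_, x$pygidium / trunk)
  x
}

#' Build a grouped numeric sample for testing
#'
#' Extracts one analysis variable and splits it by a grouping column. Records
#' with a missing value for either the variable or the grouping are dropped and
#' counted; empty groups are removed. Time-bin groupings are ordered
#' chronologically, taxonomic and enrolment groupings alphabetically.
#'
#' @param x a `segment_data` data.frame.
#' @param variable one of `"thorax"`, `"pygidium"`, `"trunk"`, `"proportion"`.
#' @param by grouping column: `"period"`, `"series"`, `"order"`, `"family"`
#'   or `"enrolment"`.
#' @param filter optional predicate `function(df) -> logical` applied before
#'   grouping.
#' @return A `grouped_sample`: list with `variable`, `groups` (named list of
#'   numeric vectors), `sizes`, and `dropped` (records lost to missingness).
#' @export
group_segments <- function(x, variable = "thorax",
                           by = c("period", "series", "order", "family",
                                  "enrolment"),
                           filter = NULL) {
  by <- match.arg(by)
  variable <- match.arg(variable, segment_variables())
  df <- derive_variables(as.data.frame(x))
  if (!is.null(filter)) df <- df[filter(df), , drop = FALSE]
  n0 <- nrow(df)
  ok <- !is.na(df[[variable]]) & !is.na(df[[by]])
  df <- df[ok, , drop = FALSE]
  levels <- switch(by,
    period = palaeozoic_periods(),
    series = {
      known <- palaeozoic_series()
      c(known[known %in% df$series], sort(setdiff(unique(df$series), known)))
    },
    sort(unique(df[[by]])))
  groups <- lapply(levels, function(g) as.numeric(df[[variable]][df[[by]] == g]))
  names(groups) <- levels
  groups <- groups[lengths(groups) > 0L]
  if (!length(groups)) {
    stop_data("empty selection: no records with both %s and %s", variable, by)
  }
  grouped_sample(groups, variable, dropped = n0 - nrow(df))
}

#' Construct a grouped sample directly
#' @param groups named list of non-empty numeric vectors, in analysis order.
#' @param variable label of the measured variable.
#' @param dropped number of records excluded for missingness (bookkeeping).
#' @return A `grouped_sample` object.
#' @export
grouped_sample <- function(groups, variable = "value", dropped = 0L) {
  stopifnot(is.list(groups), length(groups) >= 1L, !is.null(names(groups)))
  if (any(lengths(groups) == 0L)) stop_data("empty selection: empty group present")
  groups <- lapply(groups, as.numeric)
  structure(list(variable = variable, groups = groups,
                 sizes = lengths(groups), dropped = as.integer(dropped)),
            class = "grouped_sample")
}

#' @export
print.grouped_sample <- function(x, ...) {
  cat(sprintf("grouped_sample: %s in %d group(s) [%s]; %d record(s) dropped\n",
              x$variable, length(x$groups),
              paste(sprintf("%s n=%d", names(x$groups), x$sizes), collapse = ", "),
              x$dropped))
  invisible(x)
}
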