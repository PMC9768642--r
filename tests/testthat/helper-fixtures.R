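# In-code fixtures: no data files on disk.

# minimal valid record table; vectors are recycled
make_records <- function(n = 6,
                         species = sprintf("sp%03d", seq_len(n)),
                         order = "Phacopida",
                         family = "Phacopidae",
                         period = palaeozoic_periods(),
                         series = NA,
                         thorax = 10L,
                         pygidium = 7L,
                         enrolment = NA) {
  segment_data(data.frame(
    species = rep_len(species, n), order = rep_len(order, n),
    family = rep_len(family, n), period = rep_len(period, n),
    series = rep_len(series, n), thorax = rep_len(thorax, n),
    pygidium = rep_len(pygidium, n), enrolment = rep_len(enrolment, n),
    stringsAsFactors = FALSE))
}

write_toy_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, na = "")
  path
}

# random small grouped_sample for oracle-equivalence checks
random_small_sample <- function() {
  k <- sample(2:3, 1)
  repeat {
    sizes <- sample(1:4, k, replace = TRUE)
    if (sum(sizes) <= 9 && sum(sizes) >= k + 1) break
  }
  values <- sample(0:8, sum(sizes), replace = TRUE)
  grouped_sample(split(values, rep(seq_len(k), times = sizes)) |>
                   setNames(LETTERS[seq_len(k)]))
}
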