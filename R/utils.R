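# Shared vocabulary and small helpers.

#' Palaeozoic period bins in chronological order
#' @return Character vector of the six Palaeozoic periods, oldest first.
#' @export
palaeozoic_periods <- function() {
  c("Cambrian", "Ordovician", "Silurian", "Devonian", "Carboniferous", "Permian")
}

#' Palaeozoic series/subsystem bins in chronological order
#'
#' The finer timescale: ICS series (subsystems for the Carboniferous).
#' @return Character vector, oldest first.
#' @export
palaeozoic_series <- function() {
  c("Terreneuvian", "Cambrian Series 2", "Miaolingian", "Furongian",
    "Lower Ordovician", "Middle Ordovician", "Upper Ordovician",
    "Llandovery", "Wenlock", "Ludlow", "Pridoli",
    "Lower Devonian", "Middle Devonian", "Upper Devonian",
    "Mississippian", "Pennsylvanian",
    "Cisuralian", "Guadalupian", "Lopingian")
}

segment_variables <- function() c("thorax", "pygidium", "trunk", "proportion")

# Condition helpers: config errors exit 1 from the CLI, data errors exit 2.
stop_config <- function(msg, ...) {
  stop(structure(class = c("sg_config_error", "sg_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

stop_data <- function(msg, ...) {
  stop(structure(class = c("sg_data_error", "sg_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

# Deterministic substream seeds derived from one master seed. Kept below
# 2^31 - 1 so they are always valid R integer seeds.
substream_seed <- function(seed, id) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  if (is.character(id)) {
    id <- sum(as.integer(charToRaw(id)) * seq_along(charToRaw(id))) %% 1000003L
  }
  as.integer((abs(as.numeric(seed)) + 97 * as.numeric(id)) %% 2147483587) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a
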