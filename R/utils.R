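# Classed conditions so callers (and the pipeline driver) can distinguish
# malformed files, bad data and bad configuration.

riqtl_stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "riqtl_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

format_error <- function(fmt, ...) riqtl_stop("riqtl_format_error", fmt, ...)
data_error   <- function(fmt, ...) riqtl_stop("riqtl_data_error", fmt, ...)
config_error <- function(fmt, ...) riqtl_stop("riqtl_config_error", fmt, ...)
range_error  <- function(fmt, ...) riqtl_stop("riqtl_range_error", fmt, ...)

# round half away from zero; R's round() is banker's rounding
round_half_up <- function(x) floor(x + 0.5)

harmonic_mean <- function(x) length(x) / sum(1 / x)

`%||%` <- function(a, b) if (is.null(a)) b else a

LOD_SCALE <- 2 * log(10)  # LRS = LOD * 2 ln 10 ~= 4.60517 * LOD
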