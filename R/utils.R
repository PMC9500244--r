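#' @importFrom stats rnorm runif sd median pt predict quantile
#' @importFrom utils read.delim write.table head
NULL

# Classed error, so callers (and run_all) can dispatch on error type.
mps_abort <- function(message, class, ...) {
  stop(structure(
    class = c(class, "mpsdiag_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

mps_warn <- function(message) warning(message, call. = FALSE)

# Deterministic sub-seed stream: n integer seeds < 2^31 derived from one seed,
# drawn under an isolated RNG state so the caller's stream is untouched.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed),
                   sample.int(.Machine$integer.max - 1L, n))
}

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == floor(x) && x >= min
}

stopifnot_count <- function(x, name, min = 1L) {
  if (!is_count(x, min)) {
    mps_abort(sprintf("'%s' must be a single integer >= %d (got: %s)",
                      name, min, paste(format(x), collapse = ", ")),
              "mpsdiag_validation_error", field = name)
  }
}
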