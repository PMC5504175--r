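# internal helpers: condition classes, seeded RNG scope, norms

stop_data <- function(..., call. = FALSE) {
  stop(errorCondition(paste0(...), class = c("nuscs_data_error", "error")))
}

stop_num <- function(..., call. = FALSE) {
  stop(errorCondition(paste0(...), class = c("nuscs_numeric_error", "error")))
}

# all stochastic APIs take a mandatory seed; evaluation never leaks RNG state
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_data("seed must be a single finite number")
  withr::with_seed(as.integer(seed), code)
}

l2 <- function(v) sqrt(sum(Mod(v)^2))

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
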