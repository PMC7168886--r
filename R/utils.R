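# internal helpers shared across modules

# run `code` under a fixed seed without disturbing the caller's RNG state;
# seed = NULL means "use the current RNG stream"
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

# deterministic child seed for sub-streams (per replicate / per group);
# kept strictly below 2^31 so it is always a valid R integer seed
child_seed <- function(seed, key) {
  if (is.null(seed)) return(NULL)
  x <- (as.double(seed) * 48271 + as.double(key) * 16807 + 12345) %% 2147483629
  as.integer(x)
}

stop_if_not <- function(cond, msg, class = "poolrna_error") {
  if (!isTRUE(cond)) abort(msg, class = class)
  invisible(TRUE)
}

is_count_matrix <- function(x) {
  is.matrix(x) && is.numeric(x) && all(x >= 0) && all(x == floor(x))
}

# scalar positive / non-negative checks used by the public constructors
check_scalar <- function(x, name, lower = -Inf, strict = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > lower else x >= lower)
  stop_if_not(ok, sprintf(
    "`%s` must be a single finite number %s %s",
    name, if (strict) ">" else ">=", format(lower)
  ), class = "poolrna_parameter_error")
  invisible(x)
}
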