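# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_ec <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "phytoextract_error")))
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream; with seed = NULL the global stream is used as is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, seed >= 0)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

check_number <- function(x, name, lower = -Inf, upper = Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_ec("`%s` must be a single finite number", name, class = "value_error")
  ok <- if (strict) x > lower && x < upper else x >= lower && x <= upper
  if (!ok)
    stop_ec("`%s` = %g is outside [%g, %g]", name, x, lower, upper,
            class = "value_error")
  invisible(x)
}

celsius_to_kelvin <- function(temp_c) {
  if (any(temp_c <= -.C_TO_K))
    stop_ec("temperature below absolute zero: %g degC", min(temp_c),
            class = "value_error")
  temp_c + .C_TO_K
}
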