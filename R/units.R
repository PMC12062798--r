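# Unit helpers shared across modules. All airway pressures are cmH2O, all
# actuator pressures kPa, forces N, flows L/s, volumes L, times s.

#' Pressure unit conversion
#'
#' Conversion between kilopascal (actuator side) and centimetres of water
#' column (airway side). 1 kPa = 10.1972 cmH2O.
#'
#' @param x numeric vector of pressures.
#' @return converted numeric vector.
#' @export
kpa_to_cmh2o <- function(x) x * 10.1972

#' @rdname kpa_to_cmh2o
#' @export
cmh2o_to_kpa <- function(x) x / 10.1972

# clamp to [lo, hi], vectorised
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# scalar finiteness check used by constructors
check_num <- function(x, name, lo = -Inf, hi = Inf, strict_lo = FALSE,
                      strict_hi = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  ok_lo <- if (strict_lo) x > lo else x >= lo
  ok_hi <- if (strict_hi) x < hi else x <= hi
  if (!ok_lo || !ok_hi)
    stop(sprintf("'%s' = %g outside admissible range %s%g, %g%s", name, x,
                 if (strict_lo) "(" else "[", lo, hi,
                 if (strict_hi) ")" else "]"), call. = FALSE)
  invisible(x)
}

#' Derive a stream seed from a root seed
#'
#' Deterministic seed-splitting used by the crossover runner: every
#' (rate, repetition) stream gets its own seed derived from the root, so a
#' whole study is reproducible from one integer. The result is kept inside
#' the 32-bit integer range.
#'
#' @param root integer root seed.
#' @param ... integer stream indices (e.g. rate index, repetition).
#' @return a single integer seed.
#' @export
derive_seed <- function(root, ...) {
  ix <- c(...)
  s <- (as.double(root) * 100003 + sum(as.double(ix) * 97 ^ seq_along(ix))) %%
    2147483647
  as.integer(s)
}
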