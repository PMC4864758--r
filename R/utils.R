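# Internal helpers: condition classes, seeded RNG scoping, validation.

#' @keywords internal
"_PACKAGE"

## Classed conditions so the CLI can map error families to exit codes.
sf_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "slantfuse_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

sf_spec_error <- function(msg, ...) sf_error("slantfuse_spec_error", msg, ...)
sf_data_error <- function(msg, ...) sf_error("slantfuse_data_error", msg, ...)
sf_stat_error <- function(msg, ...) sf_error("slantfuse_stat_error", msg, ...)
sf_geom_error <- function(msg, ...) sf_error("slantfuse_geom_error", msg, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

## Run `expr` under a temporary RNG state seeded with `seed`; restore the
## caller's stream afterwards. seed = NULL uses (and advances) the caller's.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

## Deterministic per-subject substream seed (Lehmer-style mixing, modulus
## 2^31 - 1 so all intermediates stay exactly representable as doubles).
substream_seed <- function(seed, index) {
  m <- 2147483647
  h <- (abs(as.numeric(seed)) %% m)
  h <- (h * 48271) %% m
  h <- ((h + as.numeric(index)) * 48271) %% m
  as.integer(h %% .Machine$integer.max) + 1L
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_inf = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (allow_inf || is.finite(x)) && x >= lower && x <= upper
  if (!ok) {
    sf_spec_error(sprintf(
      "`%s` must be a single number in [%s, %s]%s; got %s",
      name, format(lower), format(upper),
      if (allow_inf) " (Inf allowed)" else "",
      paste(format(x), collapse = ", ")
    ))
  }
  invisible(x)
}
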