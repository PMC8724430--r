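# internal helpers shared across modules

PROBE_CLASSES <- c("endogenous", "housekeeping", "positive", "negative")

geomean <- function(x) exp(mean(log(x)))

# log2 with the 0.5 count floor used everywhere a raw count is logged
log2_floor <- function(x, floor = 0.5) log2(pmax(x, floor))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# deterministic per-component sub-seeds derived from one top-level seed
derive_seeds <- function(seed, components) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  s <- sample.int(.Machine$integer.max - 1L, length(components))
  names(s) <- components
  s
}
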