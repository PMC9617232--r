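#' @keywords internal
"_PACKAGE"

## Classed error helper: every user-facing failure carries a condition class
## so callers (and tests) can dispatch without parsing messages.
pdb_stop <- function(type, msg, call. = FALSE) {
  stop(structure(
    class = c(paste0("pdbiometry_", type), "pdbiometry_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  ))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x)

## Deterministic sub-seed derivation: one user seed fans out to every source
## of randomness (subject draws, fold assignment, classifier fits, bootstrap)
## so the whole chain is reproducible from a single integer.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (i in idx) {
    s <- (s * 48271 + as.double(i) * 9973 + 7919) %% 2147483647
  }
  as.integer(s)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

euclid <- function(a, b) sqrt(sum((a - b)^2))
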