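#' @keywords internal
"_PACKAGE"

# Abort with a caller-friendly message.
stop2 <- function(...) stop(..., call. = FALSE)

# Derive a stream of reproducible sub-seeds from one master seed.  Used so
# that independent stages (generation, CV, GA runs, reference draws) consume
# distinct, non-overlapping random streams while the whole analysis remains
# a deterministic function of a single integer.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

# Cheap stable hash of a configuration list for output provenance headers.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  v <- utf8ToInt(s)
  h <- 5381
  for (ch in v) h <- (h * 33 + ch) %% 4294967291
  sprintf("%08x", as.integer(h %% 2147483647))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
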