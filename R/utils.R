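#' @keywords internal
"_PACKAGE"

# Stop with a classed condition so callers/tests can distinguish error families.
ms_stop <- function(msg, class = "microstatr_error", ...) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

# First offending non-finite entry of a channels x samples matrix, or NULL.
first_nonfinite <- function(x, channel_names = rownames(x)) {
  bad <- which(!is.finite(x))
  if (length(bad) == 0L) return(NULL)
  i <- bad[1L]
  ch <- ((i - 1L) %% nrow(x)) + 1L
  smp <- ((i - 1L) %/% nrow(x)) + 1L
  list(channel = if (!is.null(channel_names)) channel_names[ch] else ch,
       sample = smp)
}

assert_finite_matrix <- function(x, what, channel_names = NULL) {
  off <- first_nonfinite(x, channel_names)
  if (!is.null(off)) {
    ms_stop(sprintf("%s contains a non-finite value at channel %s, sample %d",
                    what, as.character(off$channel), off$sample),
            class = "microstatr_nonfinite_error")
  }
  invisible(TRUE)
}

# Derive a stream-specific child seed from a top-level seed. Keeps every stage
# on its own deterministic stream without touching the global RNG between calls.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

# Evaluate an expression under a local RNG state (restores global state after).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
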