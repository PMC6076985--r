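#' @keywords internal
"_PACKAGE"

# Run an expression under a private RNG state: seeds the generator, restores
# whatever state the caller had. All stochastic operations in the package go
# through this so a single integer seed makes a whole pipeline reproducible.
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single non-missing integer", call. = FALSE)
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

# stop() with a class so callers (and the CLI) can map failures to exit codes
abort2 <- function(msg, class) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = NULL)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
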