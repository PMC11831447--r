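## Evaluate `expr` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

## Shared-scope check for operations taking several per-spot vectors.
check_same_scope <- function(...) {
  vecs <- list(...)
  nm <- lapply(vecs, names)
  if (any(vapply(nm, is.null, logical(1)))) {
    stop("all per-spot vectors must carry spot ids as names")
  }
  ref <- nm[[1]]
  for (i in seq_along(nm)[-1]) {
    if (!setequal(ref, nm[[i]])) {
      stop("inputs do not share the same spot scope")
    }
  }
  ref
}
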