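# Internal RNG plumbing. All user-facing randomness flows through a single
# integer seed that is expanded into named substreams, so changing the number
# of draws consumed by one stage never shifts another stage's stream.

.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Deterministic substream seed < 2^31, derived from (seed, stage label, index).
.substream <- function(seed, stage, index = 0L) {
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes))
  val <- ((as.double(seed) %% 2147483647) * 7919 + h * 131 + as.double(index)) %%
    2147483647
  as.integer(val)
}

.assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  invisible(x)
}

# Column-wise minima of a numeric matrix (no matrixStats dependency).
.colMins <- function(M) {
  do.call(pmin, lapply(seq_len(nrow(M)), function(i) M[i, ]))
}

.rowMins <- function(M) {
  do.call(pmin, lapply(seq_len(ncol(M)), function(j) M[, j]))
}
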