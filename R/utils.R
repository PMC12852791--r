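# Internal helpers shared across modules.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# wrap an angle difference to (-pi, pi]
wrap_angle <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  a[a == -pi] <- pi
  a
}

vec_norm <- function(v) sqrt(sum(v^2))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n < .Machine$double.eps) stop("cannot normalise a zero vector")
  v / n
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL draws from the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

is_point <- function(p) is.numeric(p) && length(p) == 2 && all(is.finite(p))

stopifnot_point <- function(p, what = "point") {
  if (!is_point(p)) stop(sprintf("'%s' must be a finite numeric vector of length 2", what))
}
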