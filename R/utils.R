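# Internal helpers: typed conditions and small vector geometry.

mf_stop <- function(class, msg) {
  stop(structure(
    class = c(class, "mdfinger_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n == 0) mf_stop("mf_geometry_error", "zero-length vector has no direction")
  v / n
}

## Angle at vertex b of the triple a-b-c, degrees in [0, 180].
vec_angle <- function(a, b, c) {
  u <- a - b
  v <- c - b
  cs <- sum(u * v) / (vnorm(u) * vnorm(v))
  cs <- min(1, max(-1, cs))
  acos(cs) * 180 / pi
}

## Row-wise angles at vertex B for coordinate matrices A, B, C (n x 3).
vec_angle_rows <- function(A, B, C) {
  U <- A - B
  V <- C - B
  num <- rowSums(U * V)
  den <- sqrt(rowSums(U * U)) * sqrt(rowSums(V * V))
  cs <- pmin(1, pmax(-1, num / den))
  acos(cs) * 180 / pi
}

## Deterministic rotation matrix from three uniform deviates (Arvo's method).
random_rotation <- function(u) {
  theta <- 2 * pi * u[1]
  phi <- 2 * pi * u[2]
  z <- u[3]
  V <- c(cos(phi) * sqrt(z), sin(phi) * sqrt(z), sqrt(1 - z))
  R <- matrix(c(cos(theta), sin(theta), 0,
                -sin(theta), cos(theta), 0,
                0, 0, 1), 3, 3)
  H <- diag(3) - 2 * tcrossprod(V)
  -H %*% R
}

## Pairwise distances between rows of X and rows of Y, chunked over X to keep
## the working set small on large frames.
chunked_cross_dist <- function(X, Y, fun, chunk = 500L) {
  nx <- nrow(X)
  if (nx == 0L || nrow(Y) == 0L) return(invisible(NULL))
  starts <- seq(1L, nx, by = chunk)
  for (s in starts) {
    idx <- s:min(s + chunk - 1L, nx)
    Xi <- X[idx, , drop = FALSE]
    d2 <- outer(rowSums(Xi^2), rowSums(Y^2), `+`) - 2 * tcrossprod(Xi, Y)
    d2[d2 < 0] <- 0
    fun(idx, sqrt(d2))
  }
  invisible(NULL)
}
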