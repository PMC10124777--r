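# Small numeric helpers shared across modules.

logit <- function(p) log(p / (1 - p))

invlogit <- function(x) 1 / (1 + exp(-x))

#' Gauss-Hermite nodes and weights for expectations under N(0, 1)
#'
#' Computed by the Golub-Welsch eigendecomposition of the Jacobi matrix, so
#' no external quadrature package is needed. Returned nodes `z` and weights
#' `w` satisfy E[f(Z)] ~= sum(w * f(z)) for Z ~ N(0, 1).
#'
#' @param n number of nodes (>= 1)
#' @return list with numeric vectors `z` and `w`
#' @keywords internal
gauss_hermite_normal <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(list(z = 0, w = 1))
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  off <- sqrt(i / 2)
  J[cbind(i, i + 1)] <- off
  J[cbind(i + 1, i)] <- off
  e <- eigen(J, symmetric = TRUE)
  # nodes for weight exp(-x^2); rescale to N(0,1)
  z <- sqrt(2) * e$values
  w <- e$vectors[1, ]^2
  ord <- order(z)
  list(z = z[ord], w = w[ord] / sum(w))
}

# Even-odd point-in-polygon test, vectorised over points.
point_in_polygon <- function(x, y, px, py) {
  n <- length(px)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, cross & !is.na(cross))
    j <- i
  }
  inside
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
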