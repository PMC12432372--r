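#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorizes a non-negative matrix `V` (m x n) as `W %*% H` with `W` (m x k)
#' and `H` (k x n) non-negative, minimizing either the generalized
#' Kullback-Leibler divergence (the convention of the mutational-signature
#' literature) or the Frobenius norm (the classic consensus-clustering setup),
#' by Lee-Seung multiplicative updates from a random non-negative start.
#'
#' @param V non-negative numeric matrix (m x n).
#' @param k factorization rank, `1 <= k <= min(dim(V))`.
#' @param objective `"kl"` (generalized KL divergence) or `"frobenius"`.
#' @param max_iter maximum number of update sweeps.
#' @param tol relative decrease of the objective below which iteration stops
#'   (checked every 10 sweeps).
#' @param seed optional integer seed for the random initialization; when
#'   `NULL` the current RNG stream is used.
#' @return list with `W`, `H`, `error` (final objective value), `iterations`.
#' @export
nmf_factorize <- function(V, k, objective = c("kl", "frobenius"),
                          max_iter = 500L, tol = 1e-6, seed = NULL) {
  objective <- match.arg(objective)
  V <- as.matrix(V)
  if (any(V < 0)) stop("V must be non-negative")
  m <- nrow(V); n <- ncol(V)
  if (k < 1L || k > min(m, n)) stop("k must be in [1, min(dim(V))]")
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  eps <- .Machine$double.eps
  # W is the random start; H is a deterministic function of (W, V), which
  # makes the whole factorization exactly equivariant under sample
  # (column) permutations of V.
  W <- matrix(stats::runif(m * k, min = eps, max = 1), m, k)
  H <- pmax(crossprod(W, V), eps)
  H <- H * (mean(V) / mean(W %*% H))

  obj <- function(W, H) {
    WH <- W %*% H
    if (objective == "kl") {
      pos <- V > 0
      sum(V[pos] * log(V[pos] / pmax(WH[pos], eps))) - sum(V) + sum(WH)
    } else {
      sum((V - WH)^2) / 2
    }
  }
  err <- obj(W, H)
  it <- 0L
  repeat {
    for (sweep in seq_len(min(10L, max_iter - it))) {
      if (objective == "kl") {
        WH <- pmax(W %*% H, eps)
        H <- H * (crossprod(W, V / WH) / pmax(colSums(W), eps))
        WH <- pmax(W %*% H, eps)
        W <- W * (tcrossprod(V / WH, H) /
                    matrix(pmax(rowSums(H), eps), m, k, byrow = TRUE))
      } else {
        H <- H * (crossprod(W, V) / pmax(crossprod(W) %*% H, eps))
        W <- W * (tcrossprod(V, H) / pmax(W %*% tcrossprod(H), eps))
      }
      it <- it + 1L
    }
    new_err <- obj(W, H)
    done <- it >= max_iter ||
      (err - new_err) <= tol * max(abs(err), 1)
    err <- new_err
    if (done) break
  }
  list(W = W, H = H, error = err, iterations = it)
}

# Save/restore the global RNG state so seeded factorizations do not disturb
# the caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Non-negative least squares (Lawson-Hanson active set)
#'
#' Solves `min ||A x - b||_2` subject to `x >= 0`. Used to refit mutation
#' catalogs against fixed signature profiles, where `A` is 96 x K and small.
#'
#' @param A numeric matrix (m x n).
#' @param b numeric vector of length m.
#' @param tol tolerance on the dual feasibility check.
#' @return list with `x` (solution, length n) and `residual`
#'   (`||A x - b||_2`).
#' @export
nnls_solve <- function(A, b, tol = 1e-10) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m)
  x <- numeric(n)
  passive <- logical(n)
  w <- drop(crossprod(A, b - A %*% x))
  iter <- 0L
  max_iter <- 3L * n + 30L
  while (any(!passive) && any(w[!passive] > tol * max(1, max(abs(w))))) {
    iter <- iter + 1L
    if (iter > max_iter) break
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      P <- which(passive)
      z <- numeric(n)
      z[P] <- tryCatch(
        drop(solve(crossprod(A[, P, drop = FALSE]),
                   crossprod(A[, P, drop = FALSE], b))),
        error = function(e) {
          drop(qr.coef(qr(A[, P, drop = FALSE]), b))
        })
      z[P][is.na(z[P])] <- 0
      if (all(z[P] > tol)) { x <- z; break }
      neg <- P[z[P] <= tol]
      ratio <- x[neg] / (x[neg] - z[neg])
      ratio[!is.finite(ratio)] <- 0
      alpha <- min(ratio)
      x <- x + alpha * (z - x)
      passive[x <= tol & passive] <- FALSE
      x[!passive] <- 0
      if (!any(passive)) { x <- numeric(n); break }
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  list(x = x, residual = sqrt(sum((A %*% x - b)^2)))
}
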