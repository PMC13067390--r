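#' @keywords internal
"_PACKAGE"

## Run `code` under a temporary RNG seed, restoring the caller's RNG state.
## Seeds are kept in 32-bit integer range.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        },
        add = TRUE
      )
    }
    set.seed(as.integer(seed %% 2147483647L))
  }
  force(code)
}

## Deterministic per-subject substream seed derived from a global seed.
subject_seed <- function(seed, subject_index) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(subject_index)) %% 2147483647)
}

#' Vectorize the upper triangle of a symmetric matrix
#'
#' Connectivity matrices are symmetric with a zero diagonal, so the strict
#' upper triangle (column-major order) carries all information. This is the
#' row format of the window pool used for state clustering.
#'
#' @param mat square symmetric numeric matrix.
#' @return numeric vector of length `n*(n-1)/2`.
#' @seealso [fc_unvectorize()]
#' @export
fc_vectorize <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  mat[upper.tri(mat)]
}

#' Rebuild a symmetric zero-diagonal matrix from its upper-triangle vector
#'
#' @param vec numeric vector of length `n*(n-1)/2`.
#' @param n number of nodes (ROIs).
#' @return `n x n` symmetric matrix with zero diagonal.
#' @export
fc_unvectorize <- function(vec, n) {
  stopifnot(length(vec) == n * (n - 1) / 2)
  mat <- matrix(0, n, n)
  mat[upper.tri(mat)] <- vec
  mat + t(mat)
}

## Cosine similarity between rows of X (matrix) and rows of C (matrix).
cosine_similarity <- function(X, C) {
  Xn <- X / pmax(sqrt(rowSums(X^2)), .Machine$double.eps)
  Cn <- C / pmax(sqrt(rowSums(C^2)), .Machine$double.eps)
  Xn %*% t(Cn)
}
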