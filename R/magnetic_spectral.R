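## The magnetic Laplacian: a complex Hermitian encoding of a directed graph.
## From the binary asymmetric adjacency A,
##   S      = (A + A')/2                  symmetrized connectivity
##   Theta  = 2*pi*q*(A - A')             skew-symmetric phase, q >= 0
##   H      = S (.) exp(i*Theta)          Hermitian adjacency
##   L      = I - D^{-1/2} S D^{-1/2} (.) exp(i*Theta)
## L is Hermitian positive-semidefinite with eigenvalues in [0, 2]; q = 0
## collapses it to the classical symmetric normalized Laplacian of S. The
## Chebyshev rescaling used by the convolution takes the spectral bound 2,
## so L_tilde = L - I has spectrum in [-1, 1].

#' Symmetrize a binary directed adjacency matrix
#'
#' @param A binary N x N adjacency (no self-loops).
#' @return symmetric matrix with entries in \{0, 0.5, 1\}.
#' @export
symmetrize <- function(A) {
  A <- as.matrix(A)
  (A + t(A)) / 2
}

#' Phase matrix of a directed adjacency
#'
#' `Theta(u, v) = 2 * pi * q * (A(u, v) - A(v, u))`: a one-way edge gets
#' phase +/- 2*pi*q, a reciprocal edge phase 0.
#'
#' @param A binary N x N adjacency.
#' @param q directionality parameter, `>= 0`.
#' @return skew-symmetric matrix.
#' @export
phase_matrix <- function(A, q) {
  if (q < 0) stop("q must be >= 0")
  A <- as.matrix(A)
  2 * pi * q * (A - t(A))
}

## exp(i*Theta) with sub-epsilon trigonometric residue removed, so phases
## that are exact multiples of pi/2 give exact 0 / +-1 / +-i entries (the
## complex ReLU gates on the sign of the real part, which must not flip on
## 1e-17 noise)
unit_phase <- function(Theta) {
  re <- cos(Theta)
  im <- sin(Theta)
  re[abs(re) < 4e-16] <- 0
  im[abs(im) < 4e-16] <- 0
  matrix(complex(real = re, imaginary = im), nrow(Theta), ncol(Theta))
}

#' Complex Hermitian adjacency
#'
#' `H = S (.) exp(i * Theta)`; magnitude encodes connectivity, phase encodes
#' direction. Hermitian by construction since S is symmetric and Theta is
#' skew-symmetric.
#'
#' @param S symmetrized adjacency, see [symmetrize()].
#' @param Theta phase matrix, see [phase_matrix()].
#' @return complex Hermitian matrix.
#' @export
hermitian_adjacency <- function(S, Theta) {
  stopifnot(identical(dim(S), dim(Theta)))
  S * unit_phase(Theta)
}

## dense L_tilde straight from edge pairs; the training inner loop rebuilds
## this every epoch under edge dropout, so it stays allocation-light.
lap_tilde_dense <- function(pairs, n, q) {
  A <- matrix(0, n, n)
  if (nrow(pairs)) A[pairs] <- 1
  S <- (A + t(A)) / 2
  deg <- rowSums(S)
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  -(outer(dinv, dinv) * S) * unit_phase(2 * pi * q * (A - t(A)))
}

#' Normalized magnetic Laplacian of a gene graph
#'
#' Builds the full spectral bundle for a graph at a given q: S, Theta, H,
#' the degree matrix of S, the normalized magnetic Laplacian L and its
#' shifted form `L_tilde = L - I`. Zero-degree nodes get an identity row in
#' L (the `D^{-1/2}` entry is set to 0), so isolated genes are fixed points
#' of the filter.
#'
#' @param graph a [gene_graph()], or a binary adjacency matrix.
#' @param q directionality parameter, `>= 0`.
#' @param sparse return `H`, `L`, `L_tilde` as [sparse_complex()] (for large
#'   graphs) instead of dense complex matrices.
#' @return object of class `hermitian_operator`: list with `n`, `q`, `S`,
#'   `Theta`, `deg`, `H`, `L`, `L_tilde`.
#' @export
magnetic_laplacian <- function(graph, q = 0.25, sparse = FALSE) {
  if (q < 0) stop("q must be >= 0")
  if (inherits(graph, "gene_graph")) {
    n <- n_nodes(graph)
    if (n == 0) stop("empty graph")
    pairs <- edge_index(graph)
    A <- matrix(0, n, n)
    if (nrow(pairs)) A[pairs] <- 1
  } else {
    A <- as.matrix(graph)
    stopifnot(nrow(A) == ncol(A))
    n <- nrow(A)
    if (any(diag(A) != 0)) stop("adjacency must have no self-loops")
  }
  S <- symmetrize(A)
  Theta <- phase_matrix(A, q)
  H <- hermitian_adjacency(S, Theta)
  deg <- rowSums(S)
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  Lt <- -(outer(dinv, dinv) * S) * unit_phase(Theta)  # L - I, zero diagonal
  L <- Lt + diag(n)
  op <- list(n = n, q = q, S = S, Theta = Theta, deg = deg,
             H = H, L = L, L_tilde = Lt)
  if (sparse) {
    op$H <- as_sparse_complex(H)
    op$L <- as_sparse_complex(L)
    op$L_tilde <- as_sparse_complex(Lt)
    op$S <- Matrix::Matrix(S, sparse = TRUE)
  }
  structure(op, class = "hermitian_operator")
}

#' @export
print.hermitian_operator <- function(x, ...) {
  cat(sprintf("<hermitian_operator> N = %d, q = %g\n", x$n, x$q))
  invisible(x)
}

#' Shifted Laplacian for Chebyshev filtering
#'
#' `L_tilde = L - I`, i.e. the standard Chebyshev rescaling
#' `2 L / lambda_max - I` with `lambda_max` fixed at the proven spectral
#' bound 2; the spectrum lands in `[-1, 1]`.
#'
#' @param L dense complex Hermitian Laplacian (or a `hermitian_operator`).
#' @return complex matrix `L - I`.
#' @export
shift_operator <- function(L) {
  if (inherits(L, "hermitian_operator")) return(L$L_tilde)
  L - diag(nrow(L))
}

op_matmul <- function(M, x) {
  if (inherits(M, "sparse_complex")) sc_multiply(M, x) else M %*% x
}

#' Apply a Chebyshev spectral filter
#'
#' Computes `y = sum_{k=0}^{K} theta_k T_k(L_tilde) x` with the three-term
#' recurrence `T_0 = I`, `T_1 = L_tilde`,
#' `T_k = 2 L_tilde T_{k-1} - T_{k-2}` — no eigendecomposition is needed.
#'
#' @param L_tilde shifted operator: dense complex matrix, a
#'   [sparse_complex()], or a `hermitian_operator` (its `L_tilde` is used).
#' @param x numeric or complex vector / N x F matrix.
#' @param thetas numeric or complex coefficients, length K + 1.
#' @return complex matrix of the same shape as `x`.
#' @export
cheb_filter <- function(L_tilde, x, thetas) {
  if (length(thetas) < 1) stop("need at least one coefficient (K >= 0)")
  if (inherits(L_tilde, "hermitian_operator")) L_tilde <- L_tilde$L_tilde
  x <- as.matrix(x) + 0i
  t_prev <- x                       # T_0 x
  y <- thetas[1] * t_prev
  if (length(thetas) >= 2) {
    t_cur <- op_matmul(L_tilde, x)  # T_1 x
    y <- y + thetas[2] * t_cur
    for (k in seq_len(length(thetas) - 2) + 2) {
      t_next <- 2 * op_matmul(L_tilde, t_cur) - t_prev
      y <- y + thetas[k] * t_next
      t_prev <- t_cur
      t_cur <- t_next
    }
  }
  y
}

## ---- sparse complex matrices ------------------------------------------------

#' Sparse complex matrix from triplets
#'
#' Stored as a pair of real sparse matrices (real and imaginary parts), so
#' products against dense complex matrices reduce to four real sparse-dense
#' products. Duplicate (row, col) triplets are summed.
#'
#' @param i,j integer row/column indices.
#' @param x complex values.
#' @param n matrix dimension (square).
#' @return object of class `sparse_complex`.
#' @export
sparse_complex <- function(i, j, x, n) {
  re <- Matrix::sparseMatrix(i = i, j = j, x = Re(x), dims = c(n, n))
  im <- Matrix::sparseMatrix(i = i, j = j, x = Im(x), dims = c(n, n))
  structure(list(n = n, re = re, im = im), class = "sparse_complex")
}

#' Convert a dense complex matrix to sparse triplet form
#' @param M complex matrix.
#' @return a [sparse_complex()].
#' @export
as_sparse_complex <- function(M) {
  nz <- which(M != 0, arr.ind = TRUE)
  sparse_complex(nz[, 1], nz[, 2], M[nz], nrow(M))
}

#' @export
print.sparse_complex <- function(x, ...) {
  cat(sprintf("<sparse_complex> %d x %d, <=%d stored entries\n", x$n, x$n,
              max(Matrix::nnzero(x$re), Matrix::nnzero(x$im))))
  invisible(x)
}

#' Multiply a sparse complex matrix by a dense vector or matrix
#' @param sc a [sparse_complex()].
#' @param x numeric or complex vector / matrix.
#' @return dense complex matrix.
#' @export
sc_multiply <- function(sc, x) {
  x <- as.matrix(x)
  xr <- Re(x); xi <- Im(x)
  re <- as.matrix(sc$re %*% xr - sc$im %*% xi)
  im <- as.matrix(sc$re %*% xi + sc$im %*% xr)
  re + 1i * im
}

#' Densify a sparse complex matrix
#' @param x a [sparse_complex()].
#' @param ... unused.
#' @return complex matrix.
#' @export
as.matrix.sparse_complex <- function(x, ...) {
  as.matrix(x$re) + 1i * as.matrix(x$im)
}

#' Check Hermitian symmetry of a sparse complex matrix
#'
#' O(nnz): the real part must be symmetric and the imaginary part
#' skew-symmetric.
#'
#' @param sc a [sparse_complex()].
#' @param tol absolute tolerance.
#' @return logical.
#' @export
sc_is_hermitian <- function(sc, tol = 1e-12) {
  max(abs(sc$re - Matrix::t(sc$re))) <= tol &&
    max(abs(sc$im + Matrix::t(sc$im))) <= tol
}

#' Serialize a Hermitian operator to triplet TSV + JSON sidecar
#'
#' Writes nonzero entries of `L_tilde` as (row, col, re, im) and a JSON
#' sidecar with N and q, for caching between CLI invocations.
#'
#' @param op a `hermitian_operator`.
#' @param path output TSV path; the sidecar is `<path>.json`.
#' @export
write_operator <- function(op, path) {
  M <- op$L_tilde
  if (inherits(M, "sparse_complex")) M <- as.matrix(M)
  nz <- which(M != 0, arr.ind = TRUE)
  df <- data.frame(row = nz[, 1], col = nz[, 2],
                   re = Re(M[nz]), im = Im(M[nz]))
  df <- df[order(df$row, df$col), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(n = op$n, q = op$q), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized operator's shifted Laplacian
#' @param path TSV written by [write_operator()].
#' @return a [sparse_complex()] holding `L_tilde`.
#' @export
read_operator <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  df <- read.delim(path, header = TRUE)
  sparse_complex(df$row, df$col, complex(real = df$re, imaginary = df$im),
                 n = meta$n)
}
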