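## The network: stacked magnetic Chebyshev convolutions (complex), complex
## ReLU, real unwinding [Re | Im], sequential channel and spatial attention,
## dropout, and a single fully connected scoring head with sigmoid output.
##
## Complex gradients use the convention grad(Z) = dLoss/dRe(Z) + i*dLoss/dIm(Z),
## under which backprop through Y = X %*% W gives grad_X = grad_Y %*% Conj(t(W))
## and grad_W = Conj(t(X)) %*% grad_Y, and through Y = M %*% X with Hermitian M
## gives grad_X = M %*% grad_Y.

#' Complex rectified linear unit
#'
#' Keeps an entry when its real part is non-negative and zeroes it
#' otherwise: `z * 1[Re(z) >= 0]`.
#'
#' @param z complex vector or matrix.
#' @return same shape as `z`.
#' @export
complex_relu <- function(z) z * (Re(z) >= 0)

#' Unwind a complex matrix into real columns
#'
#' `[Re(X) | Im(X)]`: the bridge from the complex convolution stack to the
#' real-valued attention modules and scoring head; width doubles.
#'
#' @param X complex N x F matrix.
#' @return real N x 2F matrix.
#' @export
unwind <- function(X) cbind(Re(X), Im(X))

glorot <- function(nr, nc, gain = 1) {
  lim <- gain * sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

#' Initialize model parameters
#'
#' Glorot-uniform initialization applied independently to the real and
#' imaginary parts of the complex convolution weights; biases start at zero.
#' In `gcn_mode` the imaginary parts are initialized to zero and (because
#' the q = 0 operator and the inputs are real) remain exactly zero
#' throughout training, reducing the model to a real GCN.
#'
#' Parameters are stored as a flat named list of real arrays: per layer l
#' and Chebyshev order k, `l<l>_W<k>_re` / `_im` (k = 0 is the self weight,
#' k = 1 the neighbor weight) and `l<l>_b_re` / `_im`; channel-attention MLP
#' `ca_W1`, `ca_b1`, `ca_W2`, `ca_b2`; spatial-attention kernel `sa_k`
#' (2 x 7: avg-pool row, max-pool row) and bias `sa_b`; head `head_w`,
#' `head_b`.
#'
#' @param config a [run_config()].
#' @param f_in input feature width.
#' @return named list of numeric arrays (class `mdignn_params`).
#' @export
init_model_params <- function(config, f_in) {
  set.seed(config$seed)
  p <- list()
  fi <- f_in
  for (l in seq_len(config$num_layers)) {
    fo <- config$num_filters
    for (k in 0:config$cheb_order) {
      p[[sprintf("l%d_W%d_re", l, k)]] <- glorot(fi, fo)
      p[[sprintf("l%d_W%d_im", l, k)]] <-
        if (config$gcn_mode) matrix(0, fi, fo) else glorot(fi, fo)
    }
    p[[sprintf("l%d_b_re", l)]] <- numeric(fo)
    p[[sprintf("l%d_b_im", l)]] <- numeric(fo)
    fi <- fo
  }
  cw <- 2L * config$num_filters
  hidden <- max(1L, cw %/% config$attention_reduction)
  p$ca_W1 <- glorot(hidden, cw)
  p$ca_b1 <- numeric(hidden)
  p$ca_W2 <- glorot(cw, hidden)
  p$ca_b2 <- numeric(cw)
  p$sa_k <- glorot(2, 7)
  p$sa_b <- 0
  p$head_w <- drop(glorot(cw, 1))
  p$head_b <- 0
  structure(p, class = "mdignn_params")
}

layer_weights <- function(params, l, K) {
  lapply(0:K, function(k) {
    params[[sprintf("l%d_W%d_re", l, k)]] +
      1i * params[[sprintf("l%d_W%d_im", l, k)]]
  })
}

#' One magnetic convolution layer
#'
#' `X_out = crelu( sum_k T_k(L_tilde) X W_k + B )`: with Chebyshev order
#' K = 1 this is exactly the self/neighbor form
#' `crelu(X W_self + L_tilde X W_neigh + B)`.
#'
#' @param X_prev complex N x F_in input (real features are cast with zero
#'   imaginary part).
#' @param L_tilde shifted operator (dense complex or [sparse_complex()]).
#' @param W list of K + 1 complex F_in x F_out weight matrices.
#' @param b complex bias vector of length F_out.
#' @return complex N x F_out matrix.
#' @export
conv_layer <- function(X_prev, L_tilde, W, b = NULL) {
  X_prev <- as.matrix(X_prev) + 0i
  t_prev <- X_prev
  Z <- t_prev %*% W[[1]]
  if (length(W) >= 2) {
    t_cur <- op_matmul(L_tilde, X_prev)
    Z <- Z + t_cur %*% W[[2]]
    for (k in seq_len(length(W) - 2) + 2) {
      t_next <- 2 * op_matmul(L_tilde, t_cur) - t_prev
      Z <- Z + t_next %*% W[[k]]
      t_prev <- t_cur
      t_cur <- t_next
    }
  }
  if (!is.null(b)) Z <- sweep(Z, 2, b, "+")
  complex_relu(Z)
}

## T_k(L~) x for k = 0..K, kept for the backward pass
cheb_basis <- function(L_tilde, X, K) {
  out <- vector("list", K + 1)
  out[[1]] <- X
  if (K >= 1) out[[2]] <- op_matmul(L_tilde, X)
  if (K >= 2) {
    for (k in 3:(K + 1)) {
      out[[k]] <- 2 * op_matmul(L_tilde, out[[k - 1]]) - out[[k - 2]]
    }
  }
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Channel attention
#'
#' Global average pooling over nodes, a shared two-stage MLP with reduction,
#' and a sigmoid give one weight per feature channel; channels are rescaled
#' by their weight.
#'
#' @param X real N x C matrix.
#' @param W1,b1,W2,b2 MLP weights (`C -> C/r -> C`).
#' @return list with `Mc` (length-C weights in (0,1)) and `X_out`.
#' @export
channel_attention <- function(X, W1, b1, W2, b2) {
  if (ncol(X) < nrow(W1)) stop("more MLP hidden units than channels; lower the reduction ratio")
  pool <- colMeans(X)
  pre <- drop(W1 %*% pool) + b1
  h <- pmax(pre, 0)
  s <- drop(W2 %*% h) + b2
  Mc <- sigmoid(s)
  list(Mc = Mc, X_out = sweep(X, 2, Mc, "*"), pool = pool, pre = pre,
       h = h)
}

pad_shift <- function(x, d) {
  # y[i] = x[i + d], zero-padded
  n <- length(x)
  y <- numeric(n)
  src <- seq_len(n) + d
  ok <- src >= 1 & src <= n
  y[ok] <- x[src[ok]]
  y
}

#' Spatial attention
#'
#' Per node, average- and max-pooling across channels give an N x 2 map; a
#' width-7 one-dimensional convolution along the node axis (canonical gene
#' order, zero padding 3) plus sigmoid gives one weight per node; rows are
#' rescaled by their weight.
#'
#' @param X real N x C matrix (N >= 1).
#' @param kernel 2 x 7 convolution kernel (avg-pool row, max-pool row).
#' @param bias scalar.
#' @return list with `Ms` (length-N weights in (0,1)) and `X_out`.
#' @export
spatial_attention <- function(X, kernel, bias = 0) {
  if (nrow(X) < 1) stop("need at least one node")
  stopifnot(identical(dim(kernel), c(2L, 7L)))
  a <- rowMeans(X)
  jmax <- max.col(X, ties.method = "first")
  m <- X[cbind(seq_len(nrow(X)), jmax)]
  scores <- rep(bias, nrow(X))
  for (d in -3:3) {
    scores <- scores + kernel[1, d + 4] * pad_shift(a, d) +
      kernel[2, d + 4] * pad_shift(m, d)
  }
  Ms <- sigmoid(scores)
  list(Ms = Ms, X_out = X * Ms, a = a, m = m, jmax = jmax, scores = scores)
}

#' Full forward pass
#'
#' Convolution stack (complex) -> unwind -> channel attention -> spatial
#' attention -> dropout (training only) -> linear head -> sigmoid, yielding
#' one driver probability per gene. Attention modules are skipped when the
#' corresponding config flags are off (ablations), in which case the
#' unwound representation feeds the head directly.
#'
#' @param params an [init_model_params()] list.
#' @param X real N x F feature matrix (standardized).
#' @param L_tilde shifted magnetic Laplacian.
#' @param config a [run_config()].
#' @param train apply dropout (uses the current RNG stream).
#' @return list with `prob` (length N), `logits`, and `cache` for the
#'   backward pass.
#' @export
mdignn_forward <- function(params, X, L_tilde, config, train = FALSE) {
  K <- config$cheb_order
  Xc <- as.matrix(X) + 0i
  acts <- list()   # per layer: basis (list of T_k x), mask
  for (l in seq_len(config$num_layers)) {
    basis <- cheb_basis(L_tilde, Xc, K)
    W <- layer_weights(params, l, K)
    Z <- basis[[1]] %*% W[[1]]
    for (k in seq_len(K)) Z <- Z + basis[[k + 1]] %*% W[[k + 1]]
    Z <- sweep(Z, 2, params[[sprintf("l%d_b_re", l)]] +
                 1i * params[[sprintf("l%d_b_im", l)]], "+")
    mask <- Re(Z) >= 0
    acts[[l]] <- list(basis = basis, mask = mask)
    Xc <- Z * mask
    if (any(!is.finite(Re(Xc))) || any(!is.finite(Im(Xc)))) {
      stop(sprintf("non-finite activation in convolution layer %d", l))
    }
  }
  U <- unwind(Xc)
  ca <- NULL
  if (config$use_channel_attention) {
    ca <- channel_attention(U, params$ca_W1, params$ca_b1,
                            params$ca_W2, params$ca_b2)
    U1 <- ca$X_out
  } else U1 <- U
  sa <- NULL
  if (config$use_spatial_attention) {
    sa <- spatial_attention(U1, params$sa_k, params$sa_b)
    U2 <- sa$X_out
  } else U2 <- U1
  if (train && config$dropout > 0) {
    keep <- matrix(rbinom(length(U2), 1, 1 - config$dropout),
                   nrow(U2), ncol(U2)) / (1 - config$dropout)
    U3 <- U2 * keep
  } else {
    keep <- NULL
    U3 <- U2
  }
  logits <- as.vector(U3 %*% params$head_w) + params$head_b
  if (any(!is.finite(logits))) stop("non-finite activation in scoring head")
  prob <- sigmoid(logits)
  list(prob = prob, logits = logits,
       cache = list(acts = acts, Xc = Xc, U = U, ca = ca, U1 = U1, sa = sa,
                    U2 = U2, keep = keep, U3 = U3))
}

#' Backward pass
#'
#' Given the gradient of the loss with respect to the logits, returns
#' gradients for every parameter (same names and shapes as the parameter
#' list). `X` and `L_tilde` must match the forward call.
#'
#' @param params parameter list.
#' @param cache `cache` from [mdignn_forward()].
#' @param grad_logits length-N numeric gradient.
#' @param config the [run_config()] used in the forward pass.
#' @param L_tilde the operator used in the forward pass.
#' @return named list of gradients.
#' @keywords internal
mdignn_backward <- function(params, cache, grad_logits, config, L_tilde) {
  g <- list()
  U3 <- cache$U3
  g$head_w <- drop(crossprod(U3, grad_logits))
  g$head_b <- sum(grad_logits)
  GU <- outer(grad_logits, params$head_w)
  if (!is.null(cache$keep)) GU <- GU * cache$keep
  if (config$use_spatial_attention) {
    sa <- cache$sa
    U1 <- cache$U1
    G_then <- GU * sa$Ms          # path through X * Ms
    grad_Ms <- rowSums(GU * U1)
    grad_scores <- grad_Ms * sa$Ms * (1 - sa$Ms)
    gk <- matrix(0, 2, 7)
    grad_a <- numeric(length(grad_scores))
    grad_m <- numeric(length(grad_scores))
    for (d in -3:3) {
      gk[1, d + 4] <- sum(grad_scores * pad_shift(sa$a, d))
      gk[2, d + 4] <- sum(grad_scores * pad_shift(sa$m, d))
      grad_a <- grad_a + params$sa_k[1, d + 4] * pad_shift(grad_scores, -d)
      grad_m <- grad_m + params$sa_k[2, d + 4] * pad_shift(grad_scores, -d)
    }
    g$sa_k <- gk
    g$sa_b <- sum(grad_scores)
    GU <- G_then + grad_a / ncol(U1)
    GU[cbind(seq_len(nrow(U1)), sa$jmax)] <-
      GU[cbind(seq_len(nrow(U1)), sa$jmax)] + grad_m
  }
  if (config$use_channel_attention) {
    ca <- cache$ca
    U <- cache$U
    G_then <- sweep(GU, 2, ca$Mc, "*")
    grad_Mc <- colSums(GU * U)
    grad_s <- grad_Mc * ca$Mc * (1 - ca$Mc)
    g$ca_W2 <- outer(grad_s, ca$h)
    g$ca_b2 <- grad_s
    grad_h <- drop(crossprod(params$ca_W2, grad_s))
    grad_pre <- grad_h * (ca$pre > 0)
    g$ca_W1 <- outer(grad_pre, ca$pool)
    g$ca_b1 <- grad_pre
    grad_pool <- drop(crossprod(params$ca_W1, grad_pre))
    GU <- G_then + matrix(grad_pool / nrow(U), nrow(U), ncol(U), byrow = TRUE)
  }
  # unwind: U = [Re(X_L) | Im(X_L)]
  Fh <- ncol(GU) / 2
  GX <- GU[, seq_len(Fh), drop = FALSE] +
    1i * GU[, Fh + seq_len(Fh), drop = FALSE]
  K <- config$cheb_order
  for (l in rev(seq_len(config$num_layers))) {
    act <- cache$acts[[l]]
    GZ <- GX * act$mask
    g[[sprintf("l%d_b_re", l)]] <- Re(colSums(GZ))
    g[[sprintf("l%d_b_im", l)]] <- Im(colSums(GZ))
    W <- layer_weights(params, l, K)
    GXprev <- 0
    for (k in 0:K) {
      tk <- act$basis[[k + 1]]
      gW <- crossprod(Conj(tk), GZ)
      g[[sprintf("l%d_W%d_re", l, k)]] <- Re(gW)
      g[[sprintf("l%d_W%d_im", l, k)]] <- Im(gW)
      Gt <- GZ %*% Conj(t(W[[k + 1]]))
      # adjoint of T_k(L~): the operator is Hermitian, so apply T_k again
      if (k == 0) {
        GXprev <- GXprev + Gt
      } else if (k == 1) {
        GXprev <- GXprev + op_matmul(L_tilde, Gt)
      } else {
        tb <- cheb_basis(L_tilde, Gt, k)
        GXprev <- GXprev + tb[[k + 1]]
      }
    }
    GX <- GXprev
  }
  g
}

## Adam with (coupled) L2 weight decay, elementwise over the flat list of
## real parameter arrays.
adam_init <- function(params) {
  list(t = 0,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

adam_step <- function(params, grads, state, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gr <- grads[[nm]]
    if (is.null(gr)) next
    if (weight_decay > 0) gr <- gr + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
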