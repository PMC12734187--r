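# shared fixtures and independent oracles

# tiny directed graph fixture
toy_graph <- function() {
  gene_graph(data.frame(
    from = c("A", "B", "C", "C"),
    to   = c("B", "C", "A", "D"),
    tags = "TOY"))
}

# random directed adjacency without self-loops
random_adjacency <- function(n, p = 0.2) {
  A <- matrix(rbinom(n * n, 1, p), n, n)
  diag(A) <- 0
  A
}

random_gene_graph <- function(n, p = 0.1) {
  A <- random_adjacency(n, p)
  idx <- which(A == 1, arr.ind = TRUE)
  genes <- sprintf("G%03d", seq_len(n))
  gene_graph(data.frame(from = genes[idx[, 1]], to = genes[idx[, 2]]),
             nodes = genes)
}

# small random labeled dataset with optional planted mean shift on features
toy_dataset <- function(n = 60, f = 6, n_pos = round(n / 5),
                        n_neg = round(2 * n / 5), shift = 0,
                        seed = 7, edge_p = 0.08) {
  set.seed(seed)
  g <- random_gene_graph(n, edge_p)
  pos <- sample(g$nodes, n_pos)
  neg <- sample(setdiff(g$nodes, pos), n_neg)
  X <- matrix(rnorm(n * f), n, f, dimnames = list(g$nodes, sprintf("f%d", 1:f)))
  X[g$nodes %in% pos, ] <- X[g$nodes %in% pos, ] + shift
  fm <- standardize_features(feature_matrix(X))
  list(graph = g, features = fm, labels = label_set(pos, neg, g),
       pos = pos, neg = neg)
}

# independent real-arithmetic GCN: mirrors the architecture with plain real
# matrices; valid reference when q = 0 and all imaginary parts are zero
real_gcn_reference <- function(params, X, L_tilde_real, config) {
  relu <- function(x) pmax(x, 0)
  sig <- function(x) 1 / (1 + exp(-x))
  H <- X
  for (l in seq_len(config$num_layers)) {
    basis <- list(H)
    if (config$cheb_order >= 1) basis[[2]] <- L_tilde_real %*% H
    if (config$cheb_order >= 2) {
      for (k in 3:(config$cheb_order + 1)) {
        basis[[k]] <- 2 * L_tilde_real %*% basis[[k - 1]] - basis[[k - 2]]
      }
    }
    Z <- 0
    for (k in 0:config$cheb_order) {
      Z <- Z + basis[[k + 1]] %*% params[[sprintf("l%d_W%d_re", l, k)]]
    }
    Z <- sweep(Z, 2, params[[sprintf("l%d_b_re", l)]], "+")
    H <- relu(Z)
  }
  U <- cbind(H, 0 * H)  # unwound imaginary half is identically zero
  if (config$use_channel_attention) {
    pool <- colMeans(U)
    hmlp <- relu(drop(params$ca_W1 %*% pool) + params$ca_b1)
    Mc <- sig(drop(params$ca_W2 %*% hmlp) + params$ca_b2)
    U <- sweep(U, 2, Mc, "*")
  }
  if (config$use_spatial_attention) {
    a <- rowMeans(U)
    m <- apply(U, 1, max)
    n <- nrow(U)
    sc <- rep(params$sa_b, n)
    for (i in seq_len(n)) for (d in -3:3) {
      j <- i + d
      if (j >= 1 && j <= n) {
        sc[i] <- sc[i] + params$sa_k[1, d + 4] * a[j] + params$sa_k[2, d + 4] * m[j]
      }
    }
    U <- U * sig(sc)
  }
  sig(drop(U %*% params$head_w) + params$head_b)
}

# brute-force metric oracles
auroc_pairs <- function(y, p) {
  pos <- p[y == 1]; neg <- p[y == 0]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

aupr_thresholds <- function(y, p) {
  ths <- sort(unique(p), decreasing = TRUE)
  prev_r <- 0; area <- 0
  for (t in ths) {
    tp <- sum(p >= t & y == 1)
    fp <- sum(p >= t & y == 0)
    r <- tp / sum(y == 1)
    area <- area + (r - prev_r) * tp / (tp + fp)
    prev_r <- r
  }
  area
}

mcc_direct <- function(tp, tn, fp, fn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) 0 else (tp * tn - fp * fn) / den
}

# dense spectral oracle for Chebyshev filtering
cheb_spectral_oracle <- function(L_tilde, x, thetas) {
  eg <- eigen(L_tilde)
  cheb_scalar <- function(lam, K) {
    t <- numeric(K + 1); t[1] <- 1
    if (K >= 1) t[2] <- lam
    if (K >= 2) for (k in 3:(K + 1)) t[k] <- 2 * lam * t[k - 1] - t[k - 2]
    t
  }
  K <- length(thetas) - 1
  filt <- vapply(Re(eg$values), function(l) sum(thetas * cheb_scalar(l, K)),
                 numeric(1))
  eg$vectors %*% diag(filt, length(filt)) %*% Conj(t(eg$vectors)) %*%
    (as.matrix(x) + 0i)
}
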