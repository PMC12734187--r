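## Topological feature enhancement: biased random walks over the
## symmetrized graph, embedded with skip-gram negative sampling (node2vec),
## concatenated onto the biological + SYS blocks. Walks use the undirected
## view so regulatory sink nodes are still sampled; direction is handled by
## the spectral operator, not here.

#' Random-walk / skip-gram configuration
#'
#' Defaults: 16 embedding dimensions, walk length 80, context window 5, 10
#' walks per node, unbiased second-order parameters `p = q_walk = 1`, 5
#' skip-gram epochs. `q_walk` is node2vec's in-out parameter and is distinct
#' from the Laplacian's phase parameter q.
#'
#' @param dimensions embedding width.
#' @param walk_length maximum steps per walk.
#' @param context_size skip-gram window.
#' @param walks_per_node walks started from every node.
#' @param p node2vec return parameter.
#' @param q_walk node2vec in-out parameter.
#' @param sg_epochs skip-gram training epochs.
#' @param negative negative samples per positive pair.
#' @param seed integer seed (walks and embedding).
#' @return a `walk_config` list.
#' @export
walk_config <- function(dimensions = 16, walk_length = 80, context_size = 5,
                        walks_per_node = 10, p = 1, q_walk = 1,
                        sg_epochs = 5, negative = 5, seed = 1) {
  stopifnot(dimensions >= 1, walk_length >= 1, context_size >= 1,
            walks_per_node >= 1, p > 0, q_walk > 0, sg_epochs >= 1,
            negative >= 1)
  structure(list(dimensions = as.integer(dimensions),
                 walk_length = as.integer(walk_length),
                 context_size = as.integer(context_size),
                 walks_per_node = as.integer(walks_per_node),
                 p = p, q_walk = q_walk, sg_epochs = as.integer(sg_epochs),
                 negative = as.integer(negative), seed = as.integer(seed)),
            class = "walk_config")
}

## undirected adjacency in CSR-ish form (ptr/nbr), neighbors sorted
undirected_adjacency <- function(graph) {
  n <- n_nodes(graph)
  pairs <- edge_index(graph)
  und <- unique(rbind(pairs, pairs[, c(2, 1), drop = FALSE]))
  und <- und[order(und[, 1], und[, 2]), , drop = FALSE]
  deg <- tabulate(und[, 1], n)
  list(n = n, ptr = c(0L, cumsum(deg)), nbr = und[, 2], deg = deg)
}

#' Simulate random walks over a gene graph
#'
#' Starts `walks_per_node` walks from every node on the symmetrized
#' (undirected view) graph. A walk reaching an isolated node stops there, so
#' isolated nodes yield length-1 walks. With `p = q_walk = 1` the walk is a
#' plain first-order random walk (fast vectorized path); otherwise the
#' node2vec second-order bias is applied.
#'
#' @param graph a [gene_graph()].
#' @param config a [walk_config()].
#' @return integer matrix, one walk per row, node indices with `NA` padding
#'   beyond dead ends.
#' @export
simulate_walks <- function(graph, config = walk_config()) {
  adj <- undirected_adjacency(graph)
  n <- adj$n
  if (n == 0) stop("empty graph")
  set.seed(config$seed)
  starts <- rep(seq_len(n), config$walks_per_node)
  W <- matrix(NA_integer_, length(starts), config$walk_length)
  W[, 1] <- starts
  if (config$walk_length == 1) return(W)
  if (config$p == 1 && config$q_walk == 1) {
    cur <- starts
    prev_ok <- adj$deg[cur] > 0
    for (step in seq_len(config$walk_length - 1) + 1) {
      idx <- which(prev_ok)
      if (!length(idx)) break
      cc <- cur[idx]
      pick <- adj$ptr[cc] + 1L + as.integer(floor(runif(length(idx)) * adj$deg[cc]))
      nxt <- adj$nbr[pick]
      W[idx, step] <- nxt
      cur[idx] <- nxt
      prev_ok[idx] <- adj$deg[nxt] > 0
    }
  } else {
    neighbors <- function(v) {
      if (adj$deg[v] == 0) integer() else adj$nbr[(adj$ptr[v] + 1L):adj$ptr[v + 1L]]
    }
    for (w in seq_len(nrow(W))) {
      cur <- W[w, 1]
      prev <- NA_integer_
      for (step in seq_len(config$walk_length - 1) + 1) {
        nb <- neighbors(cur)
        if (!length(nb)) break
        if (is.na(prev)) {
          nxt <- nb[sample.int(length(nb), 1)]
        } else {
          pn <- neighbors(prev)
          wgt <- ifelse(nb == prev, 1 / config$p,
                        ifelse(nb %in% pn, 1, 1 / config$q_walk))
          nxt <- nb[sample.int(length(nb), 1, prob = wgt)]
        }
        W[w, step] <- nxt
        prev <- cur
        cur <- nxt
      }
    }
  }
  W
}

#' Embed a walk corpus with skip-gram negative sampling
#'
#' @param corpus walk matrix from [simulate_walks()].
#' @param config a [walk_config()].
#' @param n_nodes number of nodes (defaults to the largest id in the
#'   corpus).
#' @return numeric `n_nodes` x `dimensions` embedding matrix.
#' @export
embed_walks <- function(corpus, config = walk_config(),
                        n_nodes = max(corpus, na.rm = TRUE)) {
  if (config$dimensions <= 0) stop("embedding dimension must be positive")
  if (all(is.na(corpus))) stop("empty walk corpus")
  walks <- corpus
  walks[is.na(walks)] <- 0L
  storage.mode(walks) <- "integer"
  sgns_embed(walks, as.integer(n_nodes), config$dimensions,
             config$context_size, config$sg_epochs, config$negative,
             lr0 = 0.025, seed = config$seed)
}

#' Node2vec topological embeddings for a graph
#'
#' Convenience wrapper: [simulate_walks()] then [embed_walks()], rows in the
#' graph's canonical node order.
#'
#' @param graph a [gene_graph()].
#' @param config a [walk_config()].
#' @return matrix with `rownames = graph$nodes`.
#' @export
node2vec_embedding <- function(graph, config = walk_config()) {
  emb <- embed_walks(simulate_walks(graph, config), config,
                     n_nodes = n_nodes(graph))
  rownames(emb) <- graph$nodes
  colnames(emb) <- sprintf("topo_%02d", seq_len(ncol(emb)))
  emb
}

#' Concatenate topological embeddings onto a feature matrix
#'
#' Appends the embedding as a `topological` block (58 + 16 = 74 columns for
#' the full feature set); the existing blocks are untouched. With
#' `enabled = FALSE` (ablation) the input is returned unchanged.
#'
#' @param bio_sys a [feature_matrix()] (biological + SYS blocks).
#' @param topo embedding matrix with gene rownames in the same order.
#' @param enabled include the topological block?
#' @return a [feature_matrix()].
#' @export
concat_features <- function(bio_sys, topo, enabled = TRUE) {
  if (!enabled) return(bio_sys)
  if (!identical(rownames(bio_sys$values), rownames(topo))) {
    stop("gene order mismatch between feature matrix and embedding")
  }
  vals <- cbind(bio_sys$values, topo)
  blocks <- bio_sys$blocks
  blocks$topological <- ncol(bio_sys$values) + seq_len(ncol(topo))
  feature_matrix(vals, blocks = blocks)
}

#' End-to-end featurizer
#'
#' Biological block from the cohort, optional SYS block, optional node2vec
#' topological block, then transductive z-scoring of every column. Row order
#' is the graph's canonical node order; genes without omics data are
#' zero-filled before standardization.
#'
#' @param graph a [gene_graph()].
#' @param cohort an [omics_cohort()].
#' @param sys SYS table (matrix with gene rownames) or `NULL`.
#' @param wconfig a [walk_config()].
#' @param use_sys,use_enhancement ablation switches.
#' @param standardize z-score columns (recommended for training).
#' @return a [feature_matrix()] aligned to `graph$nodes`.
#' @export
featurize <- function(graph, cohort, sys = NULL, wconfig = walk_config(),
                      use_sys = TRUE, use_enhancement = TRUE,
                      standardize = TRUE) {
  fm <- build_biological_block(cohort, genes = graph$nodes)
  if (use_sys) {
    if (is.null(sys)) stop("use_sys = TRUE but no SYS table supplied")
    fm <- attach_sys_block(fm, sys, enabled = TRUE)
  }
  if (use_enhancement) {
    fm <- concat_features(fm, node2vec_embedding(graph, wconfig))
  }
  if (standardize) fm <- standardize_features(fm) else fm
}
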