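#' @useDynLib mdignn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbinom rbeta plogis qlogis sd quantile
#' @importFrom utils read.delim write.table head
NULL

## ---- gene symbol normalization ---------------------------------------------

#' Default gene-symbol normalizer
#'
#' Gene identifiers are treated as opaque symbols: whitespace is stripped and
#' the symbol is upper-cased so that the same gene read from two sources maps
#' to one node. Pass a different function as `normalizer` to the readers to
#' plug in an identifier-mapping service.
#'
#' @param x character vector of gene symbols.
#' @return normalized character vector.
#' @export
normalize_symbol <- function(x) toupper(trimws(as.character(x)))

## ---- GeneGraph --------------------------------------------------------------

#' Directed gene graph
#'
#' A directed gene network: an ordered node roster (canonical order is
#' lexicographic) plus a deduplicated directed edge set with per-edge weight
#' in (0, 1] and provenance tags. Self-loops are removed at construction;
#' duplicate (source, target) pairs are collapsed, keeping the maximum weight
#' and the union of tags.
#'
#' @param edges data.frame with character columns `from`, `to` and optional
#'   `weight` (default 1) and `tags` (character, `;`-separated source names).
#' @param nodes optional character vector of node symbols; the roster is the
#'   sorted union of `nodes` and all edge endpoints, so isolated nodes can be
#'   kept.
#' @param normalizer symbol normalization hook, see [normalize_symbol()].
#' @return object of class `gene_graph` with elements `nodes` (sorted unique
#'   character) and `edges` (data.frame `from`, `to`, `weight`, `tags`).
#' @export
gene_graph <- function(edges = NULL, nodes = NULL, normalizer = normalize_symbol) {
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), tags = character(),
                        stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(edges), all(c("from", "to") %in% names(edges)))
  edges$from <- normalizer(edges$from)
  edges$to <- normalizer(edges$to)
  if (is.null(edges$weight)) edges$weight <- rep(1, nrow(edges))
  if (is.null(edges$tags)) edges$tags <- rep("", nrow(edges))
  edges <- edges[edges$from != edges$to, , drop = FALSE]  # no self-loops
  if (nrow(edges)) {
    key <- paste(edges$from, edges$to, sep = "\r")
    if (anyDuplicated(key)) {
      w <- tapply(edges$weight, key, max)
      tg <- tapply(edges$tags, key, function(t) {
        paste(sort(unique(unlist(strsplit(t[nzchar(t)], ";", fixed = TRUE)))),
              collapse = ";")
      })
      ft <- do.call(rbind, strsplit(names(w), "\r", fixed = TRUE))
      edges <- data.frame(from = ft[, 1], to = ft[, 2],
                          weight = as.numeric(w), tags = as.character(tg),
                          stringsAsFactors = FALSE)
    } else {
      edges$tags <- vapply(strsplit(edges$tags, ";", fixed = TRUE),
                           function(t) paste(sort(unique(t[nzchar(t)])), collapse = ";"),
                           character(1))
    }
  }
  nodes <- sort(unique(c(if (!is.null(nodes)) normalizer(nodes) else character(),
                         edges$from, edges$to)))
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, directed = TRUE),
            class = "gene_graph")
}

#' @export
print.gene_graph <- function(x, ...) {
  tags <- graph_tags(x)
  cat(sprintf("<gene_graph> %d nodes, %d directed edges",
              length(x$nodes), nrow(x$edges)))
  if (length(tags)) cat(sprintf(" [tags: %s]", paste(tags, collapse = ", ")))
  cat("\n")
  invisible(x)
}

#' Number of nodes of a gene graph
#' @param graph a [gene_graph()].
#' @return integer.
#' @export
n_nodes <- function(graph) length(graph$nodes)

#' Edge endpoints as node indices
#'
#' @param graph a [gene_graph()].
#' @return integer matrix with columns `from`, `to`, indices into
#'   `graph$nodes`.
#' @export
edge_index <- function(graph) {
  cbind(from = match(graph$edges$from, graph$nodes),
        to = match(graph$edges$to, graph$nodes))
}

#' Tags present in a graph's edge set
#' @param graph a [gene_graph()].
#' @return sorted character vector of source tags.
#' @export
graph_tags <- function(graph) {
  sort(unique(unlist(strsplit(graph$edges$tags[nzchar(graph$edges$tags)],
                              ";", fixed = TRUE))))
}

## ---- readers / writers ------------------------------------------------------

#' Read a directed edge list
#'
#' Reads a tab-separated edge list (source, target, then optional columns).
#' When a score column is given together with `min_score`, only rows with
#' score strictly greater than `min_score` are kept (the strict inequality
#' matches confidence filters such as "> 0.5" or "> 0.85"). Self-loops are
#' dropped. Rows with missing endpoints or a non-numeric score raise an error
#' naming the offending line.
#'
#' @param path TSV file; no header unless `header = TRUE`.
#' @param score_column column name (requires header) or index holding a
#'   numeric confidence score, or `NULL` for unweighted input.
#' @param min_score keep rows with score > `min_score`; `NULL` keeps all.
#' @param tag provenance tag recorded on every edge.
#' @param header whether the file has a header row.
#' @param normalizer symbol normalization hook.
#' @return a [gene_graph()] fragment.
#' @export
read_edge_list <- function(path, score_column = NULL, min_score = NULL,
                           tag = "", header = FALSE,
                           normalizer = normalize_symbol) {
  if (file.size(path) == 0) {
    warning(sprintf("empty edge list: %s", path))
    return(gene_graph())
  }
  raw <- read.delim(path, header = header, colClasses = "character",
                    blank.lines.skip = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0) {
    warning(sprintf("empty edge list: %s", path))
    return(gene_graph())
  }
  if (ncol(raw) < 2) stop(sprintf("%s: need at least 2 columns", path))
  blank <- !nzchar(trimws(raw[[1]])) & !nzchar(trimws(raw[[2]]))
  raw <- raw[!blank, , drop = FALSE]
  lineno <- seq_len(nrow(raw)) + as.integer(header)
  bad <- !nzchar(trimws(raw[[1]])) | !nzchar(trimws(raw[[2]]))
  if (any(bad)) {
    stop(sprintf("%s: malformed row at line %d (missing endpoint)",
                 path, lineno[which(bad)[1]]))
  }
  weight <- rep(1, nrow(raw))
  if (!is.null(score_column)) {
    col <- if (is.character(score_column)) raw[[score_column]] else raw[[score_column]]
    if (is.null(col)) stop(sprintf("%s: no score column '%s'", path, score_column))
    score <- suppressWarnings(as.numeric(col))
    nn <- is.na(score) & nzchar(trimws(col))
    if (any(nn)) {
      stop(sprintf("%s: non-numeric score at line %d", path, lineno[which(nn)[1]]))
    }
    keep <- !is.na(score) & (if (is.null(min_score)) TRUE else score > min_score)
    raw <- raw[keep, , drop = FALSE]
    weight <- pmin(score[keep], 1)
    weight[weight <= 0] <- 1  # scores act as filters; weights stay in (0, 1]
  }
  if (nrow(raw) == 0) return(gene_graph())
  gene_graph(data.frame(from = raw[[1]], to = raw[[2]], weight = weight,
                        tags = tag, stringsAsFactors = FALSE),
             normalizer = normalizer)
}

#' Write a graph's edge list
#'
#' Inverse of [read_edge_list()]: writes `from`, `to`, `weight`, `tags` as
#' headerless TSV in canonical (from, to) order, so write-then-read
#' round-trips the edge set.
#'
#' @param graph a [gene_graph()].
#' @param path output file.
#' @export
write_edge_list <- function(graph, path) {
  write.table(graph$edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Labeled gene sets
#'
#' Reads positive and negative gene lists (one symbol per line), drops genes
#' absent from the graph (logging a count), and errors if any gene appears in
#' both files.
#'
#' @param pos_path,neg_path plain-text files, one gene symbol per line.
#' @param graph a [gene_graph()] defining the node universe.
#' @param normalizer symbol normalization hook.
#' @return object of class `label_set`: list with character vectors
#'   `positives`, `negatives`, `unknown` partitioning `graph$nodes`.
#' @export
read_labels <- function(pos_path, neg_path, graph,
                        normalizer = normalize_symbol) {
  rd <- function(p) unique(normalizer(readLines(p, warn = FALSE))) |>
    (\(x) x[nzchar(x)])()
  pos <- rd(pos_path)
  neg <- rd(neg_path)
  label_set(pos, neg, graph)
}

#' Construct a label set from gene vectors
#'
#' @param positives,negatives character vectors of gene symbols.
#' @param graph the [gene_graph()] whose nodes are being labeled.
#' @return a `label_set`, see [read_labels()].
#' @export
label_set <- function(positives, negatives, graph) {
  positives <- unique(as.character(positives))
  negatives <- unique(as.character(negatives))
  both <- intersect(positives, negatives)
  if (length(both)) {
    stop(sprintf("gene(s) labeled both positive and negative: %s",
                 paste(sort(both), collapse = ", ")))
  }
  dropped <- sum(!positives %in% graph$nodes) + sum(!negatives %in% graph$nodes)
  if (dropped > 0) {
    message(sprintf("label_set: dropped %d labeled gene(s) absent from graph",
                    dropped))
  }
  positives <- intersect(graph$nodes, positives)
  negatives <- intersect(graph$nodes, negatives)
  structure(list(positives = sort(positives), negatives = sort(negatives),
                 unknown = sort(setdiff(graph$nodes, c(positives, negatives)))),
            class = "label_set")
}

#' @export
print.label_set <- function(x, ...) {
  cat(sprintf("<label_set> %d positive, %d negative, %d unknown\n",
              length(x$positives), length(x$negatives), length(x$unknown)))
  invisible(x)
}

#' Label status for a vector of genes
#' @param labels a `label_set`.
#' @param genes character vector.
#' @return character vector in {"positive", "negative", "unknown"}.
#' @export
label_status <- function(labels, genes) {
  ifelse(genes %in% labels$positives, "positive",
         ifelse(genes %in% labels$negatives, "negative", "unknown"))
}

#' Write a prediction table
#'
#' Writes gene, probability, label_status and rank as TSV, ordered by
#' probability descending with alphabetical tie-break, so output is
#' deterministic.
#'
#' @param predictions data.frame as returned by [rank_candidates()].
#' @param path output file.
#' @export
write_predictions <- function(predictions, path) {
  cols <- c("gene", "probability", "label_status", "rank")
  stopifnot(all(cols %in% names(predictions)))
  out <- predictions[order(-predictions$probability, predictions$gene),
                     cols, drop = FALSE]
  out$rank <- seq_len(nrow(out))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- RunConfig --------------------------------------------------------------

#' Model and training configuration
#'
#' Defaults follow the published architecture search result: 64 filters,
#' Chebyshev order K = 1, 2 convolution layers, dropout 0.5, learning rate
#' 1e-3, weight decay 5e-3, full-batch Adam with at most 3000 epochs and an
#' early-stopping patience of 100 epochs. `q` is the directionality phase
#' parameter of the magnetic Laplacian (q = 0 recovers the classical
#' undirected normalized Laplacian; 0.25 maps a one-way edge to a pure
#' imaginary entry).
#'
#' @param q phase parameter, `>= 0`.
#' @param num_filters hidden width of each convolution layer.
#' @param cheb_order Chebyshev polynomial order K (the filter uses K+1 terms).
#' @param num_layers number of magnetic convolution layers.
#' @param dropout dropout rate on the attention output, in `[0, 1)`.
#' @param edge_dropout per-epoch directed-edge dropout rate, in `[0, 1)`.
#' @param lr,weight_decay Adam learning rate and L2 weight decay.
#' @param max_epochs,patience training length and early-stopping patience.
#' @param seed integer seed controlling initialization, splits and dropout.
#' @param use_channel_attention,use_spatial_attention ablation switches for
#'   the attention modules.
#' @param gcn_mode when `TRUE`, forces `q = 0` so the pipeline reduces to an
#'   ordinary real-valued GCN on the symmetrized graph.
#' @param use_sys,use_enhancement feature-block ablation switches consumed by
#'   the featurizer.
#' @param sources optional character vector of network source tags to retain
#'   (network ablations); `NULL` keeps all.
#' @param attention_reduction channel-attention MLP reduction ratio r.
#' @return a `run_config` list.
#' @export
run_config <- function(q = 0.25, num_filters = 64, cheb_order = 1,
                       num_layers = 2, dropout = 0.5, edge_dropout = 0.1,
                       lr = 1e-3, weight_decay = 5e-3, max_epochs = 3000,
                       patience = 100, seed = 1,
                       use_channel_attention = TRUE,
                       use_spatial_attention = TRUE,
                       gcn_mode = FALSE, use_sys = TRUE,
                       use_enhancement = TRUE, sources = NULL,
                       attention_reduction = 8) {
  stopifnot(q >= 0, num_filters >= 1, cheb_order >= 0, num_layers >= 1,
            dropout >= 0, dropout < 1, edge_dropout >= 0, edge_dropout < 1,
            lr > 0, weight_decay >= 0, max_epochs >= 1, patience >= 1,
            attention_reduction >= 1)
  cfg <- list(q = q, num_filters = as.integer(num_filters),
              cheb_order = as.integer(cheb_order),
              num_layers = as.integer(num_layers), dropout = dropout,
              edge_dropout = edge_dropout, lr = lr,
              weight_decay = weight_decay,
              max_epochs = as.integer(max_epochs),
              patience = as.integer(patience), seed = as.integer(seed),
              use_channel_attention = isTRUE(use_channel_attention),
              use_spatial_attention = isTRUE(use_spatial_attention),
              gcn_mode = isTRUE(gcn_mode), use_sys = isTRUE(use_sys),
              use_enhancement = isTRUE(use_enhancement), sources = sources,
              attention_reduction = as.integer(attention_reduction))
  if (cfg$gcn_mode) cfg$q <- 0
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of [run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(run_config, vals)
}

## ---- FeatureMatrix ----------------------------------------------------------

#' Node feature matrix with named column blocks
#'
#' @param values numeric N x F matrix with gene symbols as rownames (order
#'   must match the graph's canonical node order when used with a graph).
#' @param blocks named list of integer column index vectors (e.g.
#'   `biological`, `sys`, `topological`); widths must sum to `ncol(values)`.
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, blocks = list(biological = seq_len(ncol(values)))) {
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  if (anyNA(values)) stop("feature matrix contains missing values")
  stopifnot(sum(lengths(blocks)) == ncol(values))
  structure(list(values = values, blocks = blocks), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d genes x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s: %d", names(x$blocks), lengths(x$blocks)),
                    collapse = ", ")))
  invisible(x)
}

#' Z-score feature columns
#'
#' Standardizes every column over all graph nodes (transductive; labels are
#' never consulted). Constant columns become zero.
#'
#' @param fm a [feature_matrix()].
#' @return a standardized `feature_matrix`.
#' @export
standardize_features <- function(fm) {
  v <- fm$values
  mu <- colMeans(v)
  sdv <- apply(v, 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  fm$values <- sweep(sweep(v, 2, mu, "-"), 2, sdv, "/")
  fm
}

#' Write a feature matrix as TSV
#'
#' First column `gene`, then one column per feature; block membership is
#' recorded in a `# block:` comment header line per block.
#'
#' @param fm a [feature_matrix()].
#' @param path output file.
#' @export
write_features <- function(fm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (b in names(fm$blocks)) {
    writeLines(sprintf("# block: %s\t%s", b,
                       paste(colnames(fm$values)[fm$blocks[[b]]], collapse = "\t")),
               con)
  }
  df <- data.frame(gene = rownames(fm$values), fm$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
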