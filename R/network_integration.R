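## Multi-source network integration: directed regulatory sources plus
## undirected PPI sources merged into one directed gene graph. Confidence
## scores act only as ingestion filters; the spectral operator downstream is
## built from the binary adjacency.

#' Describe one network source
#'
#' @param name source tag recorded on every retained edge (e.g. "KEGG",
#'   "STRING").
#' @param path edge-list TSV, see [read_edge_list()].
#' @param kind "directed" (regulatory) or "undirected" (PPI); undirected
#'   edges are expanded to reciprocal directed pairs at integration.
#' @param min_score confidence threshold; rows with score strictly greater
#'   are retained (e.g. 0.5 for a CPDB-like source, 0.85 for a STRING-like
#'   source). Requires `score_column`.
#' @param score_column column index or name holding the score.
#' @param allowed_levels for categorical confidence (e.g. keep only "high"
#'   and "medium"); requires `level_column`.
#' @param level_column column index holding the confidence level.
#' @param header whether the file has a header row.
#' @return a `source_spec` list.
#' @export
source_spec <- function(name, path, kind = c("directed", "undirected"),
                        min_score = NULL, score_column = NULL,
                        allowed_levels = NULL, level_column = NULL,
                        header = FALSE) {
  kind <- match.arg(kind)
  if (!is.null(min_score) && is.null(score_column)) {
    stop(sprintf("source '%s': a score threshold requires score_column", name))
  }
  if (!is.null(allowed_levels) && is.null(level_column)) {
    stop(sprintf("source '%s': categorical filtering requires level_column", name))
  }
  structure(list(name = name, path = path, kind = kind,
                 min_score = min_score, score_column = score_column,
                 allowed_levels = allowed_levels, level_column = level_column,
                 header = header),
            class = "source_spec")
}

#' Filter rows by categorical confidence level
#'
#' Keeps rows whose confidence level is among `allowed_levels` (matched
#' case-insensitively). Rows with a missing level are dropped with a warning.
#'
#' @param rows data.frame of edge-list rows.
#' @param level_column column index or name with the level.
#' @param allowed_levels character vector of retained levels.
#' @return the filtered data.frame.
#' @export
filter_categorical <- function(rows, level_column, allowed_levels) {
  if (nrow(rows) == 0) return(rows)
  lev <- rows[[level_column]]
  if (is.null(lev)) stop("level column not present")
  lev <- tolower(trimws(as.character(lev)))
  missing_lev <- is.na(lev) | !nzchar(lev)
  if (any(missing_lev)) {
    warning(sprintf("dropping %d row(s) with missing confidence level",
                    sum(missing_lev)))
  }
  keep <- !missing_lev & lev %in% tolower(allowed_levels)
  rows[keep, , drop = FALSE]
}

read_source <- function(spec, normalizer = normalize_symbol) {
  if (!is.null(spec$allowed_levels)) {
    raw <- read.delim(spec$path, header = spec$header,
                      colClasses = "character", stringsAsFactors = FALSE)
    raw <- filter_categorical(raw, spec$level_column, spec$allowed_levels)
    if (nrow(raw) == 0) return(gene_graph())
    g <- gene_graph(data.frame(from = raw[[1]], to = raw[[2]], weight = 1,
                               tags = spec$name, stringsAsFactors = FALSE),
                    normalizer = normalizer)
  } else {
    g <- read_edge_list(spec$path, score_column = spec$score_column,
                        min_score = spec$min_score, tag = spec$name,
                        header = spec$header, normalizer = normalizer)
  }
  g
}

#' Integrate multiple network sources into one directed graph
#'
#' Directed sources contribute their edges as-is; undirected (PPI) sources
#' are expanded into reciprocal directed edge pairs, which under the phase
#' encoding carry zero phase shift, exactly as a bidirectional interaction
#' should. Duplicate directed edges across sources collapse to one edge
#' whose tag set is the union of contributing sources. The node roster is
#' the union of all endpoints; integration is order-independent.
#'
#' @param sources list of [source_spec()]s (length >= 1).
#' @param normalizer symbol normalization hook.
#' @return a merged [gene_graph()].
#' @export
integrate_sources <- function(sources, normalizer = normalize_symbol) {
  stopifnot(length(sources) >= 1)
  frags <- lapply(sources, function(spec) {
    stopifnot(inherits(spec, "source_spec"))
    g <- read_source(spec, normalizer)
    e <- g$edges
    if (spec$kind == "undirected" && nrow(e)) {
      e <- rbind(e, data.frame(from = e$to, to = e$from, weight = e$weight,
                               tags = e$tags, stringsAsFactors = FALSE))
    }
    e
  })
  gene_graph(do.call(rbind, frags), normalizer = normalizer)
}

#' Restrict a graph to edges from selected sources
#'
#' Keeps edges whose tag set intersects `tags`; the full node roster is
#' retained so feature-matrix alignment is unaffected (network-source
#' ablations such as "only PPI" / "only KEGG").
#'
#' @param graph a [gene_graph()].
#' @param tags nonempty character vector of source tags.
#' @return a [gene_graph()] with the same nodes and the filtered edges.
#' @export
subset_sources <- function(graph, tags) {
  stopifnot(length(tags) >= 1)
  known <- graph_tags(graph)
  bad <- setdiff(tags, known)
  if (length(bad)) {
    stop(sprintf("unknown source tag(s) %s; graph has: %s",
                 paste(bad, collapse = ", "), paste(known, collapse = ", ")))
  }
  etags <- strsplit(graph$edges$tags, ";", fixed = TRUE)
  keep <- vapply(etags, function(t) any(t %in% tags), logical(1))
  g <- gene_graph(graph$edges[keep, , drop = FALSE], nodes = graph$nodes)
  g
}
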