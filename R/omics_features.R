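## Per-gene biological features from per-sample omics matrices. For every
## cancer type c with matched tumor/normal sample pairs S_c, each gene i gets
##   mutation rate   : mean over samples of its SNV+CNA indicator/frequency
##   diff methylation: (1/|S_c|) * sum_s (beta_i^t - beta_i^n)
##   diff expression : mean over pairs of log2(tumor / normal)
## so the biological block has 3 columns per cancer type. The 10 SYS columns
## (ohnolog, essentiality x2, tissue breadth, degree, hub, betweenness,
## clustering, complexes, miRNAs) come from an external curated table.

#' Matched tumor/normal omics cohort
#'
#' @param mutation named list (one entry per cancer type) of genes x samples
#'   matrices of mutation indicators (binary) or per-sample frequencies.
#' @param meth_tumor,meth_normal named lists of genes x samples methylation
#'   beta matrices; tumor and normal are matched 1:1 by column within a
#'   cancer type and betas must lie in `[0, 1]`.
#' @param expr_tumor,expr_normal named lists of genes x samples expression
#'   matrices; matched 1:1 by column and strictly positive (add a pseudocount
#'   upstream if needed).
#' @return object of class `omics_cohort` with sorted `cancer_types` and
#'   `genes` (union over channels).
#' @export
omics_cohort <- function(mutation, meth_tumor, meth_normal,
                         expr_tumor, expr_normal) {
  types <- sort(unique(c(names(mutation), names(meth_tumor), names(expr_tumor))))
  if (length(types) == 0) stop("cohort has zero cancer types")
  for (ct in types) {
    pair_check <- function(t, n, what) {
      if (is.null(t) || is.null(n)) return()
      if (!identical(dim(t), dim(n)) || !identical(colnames(t), colnames(n))) {
        stop(sprintf("%s: tumor/normal samples not 1:1 matched for '%s'", what, ct))
      }
    }
    pair_check(meth_tumor[[ct]], meth_normal[[ct]], "methylation")
    pair_check(expr_tumor[[ct]], expr_normal[[ct]], "expression")
    b <- c(meth_tumor[[ct]], meth_normal[[ct]])
    if (length(b) && (min(b) < 0 || max(b) > 1)) {
      stop(sprintf("methylation betas outside [0, 1] for '%s'", ct))
    }
    e <- c(expr_tumor[[ct]], expr_normal[[ct]])
    if (length(e) && min(e) <= 0) {
      stop(sprintf("nonpositive expression for '%s'; add a pseudocount", ct))
    }
  }
  genes <- sort(unique(unlist(lapply(
    c(mutation, meth_tumor, expr_tumor), rownames))))
  structure(list(cancer_types = types, genes = genes, mutation = mutation,
                 meth_tumor = meth_tumor, meth_normal = meth_normal,
                 expr_tumor = expr_tumor, expr_normal = expr_normal),
            class = "omics_cohort")
}

#' @export
print.omics_cohort <- function(x, ...) {
  cat(sprintf("<omics_cohort> %d genes, %d cancer types (%s)\n",
              length(x$genes), length(x$cancer_types),
              paste(x$cancer_types, collapse = ", ")))
  invisible(x)
}

gene_row <- function(mat, gene) {
  if (is.null(mat) || !gene %in% rownames(mat)) NULL else mat[gene, ]
}

#' Per-gene mutation rate in one cancer type
#'
#' Mean over samples of the mutation indicator (or per-sample frequency);
#' for binary indicators this is the fraction of mutated samples. A gene
#' absent from the cohort gets 0 with a warning (zero-fill convention).
#'
#' @param cohort an [omics_cohort()].
#' @param gene gene symbol.
#' @param cancer_type one of `cohort$cancer_types`.
#' @return numeric scalar.
#' @export
mutation_rate <- function(cohort, gene, cancer_type) {
  m <- cohort$mutation[[cancer_type]]
  if (is.null(m) || ncol(m) < 1) {
    stop(sprintf("no mutation samples for cancer type '%s'", cancer_type))
  }
  x <- gene_row(m, gene)
  if (is.null(x)) {
    warning(sprintf("gene '%s' absent from mutation data; using 0", gene))
    return(0)
  }
  mean(x)
}

#' Mean tumor-normal differential methylation
#'
#' The average over matched sample pairs of (beta_tumor - beta_normal);
#' lies in `[-1, 1]` and is antisymmetric under swapping tumor and normal.
#'
#' @inheritParams mutation_rate
#' @return numeric scalar.
#' @export
diff_methylation <- function(cohort, gene, cancer_type) {
  bt <- gene_row(cohort$meth_tumor[[cancer_type]], gene)
  bn <- gene_row(cohort$meth_normal[[cancer_type]], gene)
  if (is.null(bt) || is.null(bn)) {
    warning(sprintf("gene '%s' absent from methylation data; using 0", gene))
    return(0)
  }
  if (length(bt) != length(bn)) {
    stop(sprintf("unpaired methylation samples for gene '%s'", gene))
  }
  mean(bt - bn)
}

#' Mean tumor/normal log2 fold change of expression
#'
#' Per matched pair, log2(tumor / normal), averaged over the cancer type's
#' pairs. Values must be strictly positive.
#'
#' @inheritParams mutation_rate
#' @return numeric scalar.
#' @export
diff_expression <- function(cohort, gene, cancer_type) {
  et <- gene_row(cohort$expr_tumor[[cancer_type]], gene)
  en <- gene_row(cohort$expr_normal[[cancer_type]], gene)
  if (is.null(et) || is.null(en)) {
    warning(sprintf("gene '%s' absent from expression data; using 0", gene))
    return(0)
  }
  if (length(et) != length(en)) {
    stop(sprintf("unpaired expression samples for gene '%s'", gene))
  }
  if (min(et, en) <= 0) {
    stop(sprintf("nonpositive expression for gene '%s'; add a pseudocount upstream",
                 gene))
  }
  mean(log2(et / en))
}

#' Build the biological feature block
#'
#' One row per gene, three columns per cancer type (mutation rate,
#' differential methylation, differential expression), ordered by cancer
#' type then channel, so a cohort with C cancer types yields a 3C-wide
#' block (48 columns for 16 types). Genes in `genes` but absent from the
#' cohort are zero-filled.
#'
#' @param cohort an [omics_cohort()].
#' @param genes gene universe and row order; defaults to the cohort's genes.
#' @return a [feature_matrix()] with a single `biological` block.
#' @export
build_biological_block <- function(cohort, genes = NULL) {
  if (length(cohort$cancer_types) == 0) stop("cohort has zero cancer types")
  if (is.null(genes)) genes <- cohort$genes
  cols <- list()
  for (ct in cohort$cancer_types) {
    blk <- matrix(0, length(genes), 3,
                  dimnames = list(genes, paste0(ct, c("_mut", "_meth", "_expr"))))
    mu <- cohort$mutation[[ct]]
    if (!is.null(mu)) {
      hit <- intersect(genes, rownames(mu))
      blk[hit, 1] <- rowMeans(mu[hit, , drop = FALSE])
    }
    bt <- cohort$meth_tumor[[ct]]; bn <- cohort$meth_normal[[ct]]
    if (!is.null(bt)) {
      hit <- intersect(genes, rownames(bt))
      blk[hit, 2] <- rowMeans(bt[hit, , drop = FALSE] - bn[hit, , drop = FALSE])
    }
    et <- cohort$expr_tumor[[ct]]; en <- cohort$expr_normal[[ct]]
    if (!is.null(et)) {
      hit <- intersect(genes, rownames(et))
      blk[hit, 3] <- rowMeans(log2(et[hit, , drop = FALSE] / en[hit, , drop = FALSE]))
    }
    cols[[ct]] <- blk
  }
  vals <- do.call(cbind, cols)
  colnames(vals) <- unlist(lapply(cols, colnames))
  feature_matrix(vals, blocks = list(biological = seq_len(ncol(vals))))
}

#' The ten system-level (SYS) feature columns, in canonical order
#' @return character vector of length 10.
#' @export
sys_feature_names <- function() {
  c("ohnolog", "essentiality_pct", "essential", "n_tissues", "degree",
    "hub", "betweenness", "clustering", "n_complexes", "n_mirnas")
}

#' Append the system-level (SYS) feature block
#'
#' Adds the ten cancer-agnostic gene-property columns (gene duplication,
#' essentiality, tissue breadth, network topology, complex membership,
#' miRNA targeting) to a biological block, giving 58 columns for a 16-type
#' cohort. With `enabled = FALSE` (ablation) the input is returned
#' unchanged. Genes missing from the SYS table are zero-filled (count
#' logged); extra SYS genes are ignored.
#'
#' @param features a [feature_matrix()] (typically the biological block).
#' @param sys data.frame or matrix with gene rownames and the 10 columns of
#'   [sys_feature_names()].
#' @param enabled include the SYS block?
#' @return a [feature_matrix()] with an added `sys` block when enabled.
#' @export
attach_sys_block <- function(features, sys, enabled = TRUE) {
  if (!enabled) return(features)
  genes <- rownames(features$values)
  sys <- as.matrix(sys)
  if (!all(sys_feature_names() %in% colnames(sys))) {
    stop(sprintf("SYS table must contain columns: %s",
                 paste(sys_feature_names(), collapse = ", ")))
  }
  sys <- sys[, sys_feature_names(), drop = FALSE]
  blk <- matrix(0, length(genes), ncol(sys),
                dimnames = list(genes, colnames(sys)))
  hit <- intersect(genes, rownames(sys))
  if (length(hit) < length(genes)) {
    message(sprintf("attach_sys_block: zero-filled %d gene(s) missing from SYS table",
                    length(genes) - length(hit)))
  }
  blk[hit, ] <- sys[hit, ]
  vals <- cbind(features$values, blk)
  blocks <- features$blocks
  blocks$sys <- ncol(features$values) + seq_len(ncol(blk))
  feature_matrix(vals, blocks = blocks)
}

#' Read a precomputed SYS table
#' @param path TSV with a `gene` column plus the columns of
#'   [sys_feature_names()].
#' @param normalizer symbol normalization hook.
#' @return matrix with gene rownames.
#' @export
read_sys_table <- function(path, normalizer = normalize_symbol) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot("gene" %in% names(df))
  rn <- normalizer(df$gene)
  m <- as.matrix(df[, setdiff(names(df), "gene"), drop = FALSE])
  rownames(m) <- rn
  m
}
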