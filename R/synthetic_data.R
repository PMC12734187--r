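## Synthetic benchmark: a directed gene network with planted driver nodes
## plus matched tumor/normal omics cohorts, so the whole pipeline can be
## exercised and calibrated without external downloads. Distributions are
## chosen for correct support and controllable effect sizes (Beta for
## methylation betas, log-normal for expression, Bernoulli for mutation),
## not to mimic any real cohort's marginals.

#' Simulation specification
#'
#' The graph is an undirected preferential-attachment skeleton whose
#' driver block is densified by the multiplier `rho`; an orientation step
#' then makes a fraction of edges reciprocal (emulating a PPI block) and
#' orients the rest, with `driver_orientation` biasing driver-incident
#' edges to point away from the driver (0.5 = unbiased; 1 plants a signal
#' carried *only* by edge direction). `out_boost > 1` additionally gives
#' drivers extra outgoing edges. `delta` separates driver feature means
#' from non-driver means in latent-sd units across all omics channels and
#' SYS columns; at `delta = 0`, `rho = 1`, `out_boost = 1`,
#' `driver_orientation = 0.5` drivers are exchangeable with non-drivers.
#'
#' @param n_genes number of genes (>= 10).
#' @param n_drivers planted positives.
#' @param n_nondrivers labeled negatives.
#' @param n_cancer_types pseudo cancer types (3 feature columns each).
#' @param samples_per_type matched tumor/normal pairs per type (>= 2).
#' @param attach_m skeleton edges attached per node.
#' @param rho within-driver edge multiplier (>= 1).
#' @param out_boost driver out-degree boost (>= 1).
#' @param reciprocal_frac fraction of skeleton edges made bidirectional.
#' @param driver_orientation probability that a one-way driver/non-driver
#'   edge points away from the driver, in `[0.5, 1]`.
#' @param delta effect size in latent-sd units (>= 0).
#' @param noise_sd per-sample expression noise, log2 scale.
#' @param seed integer seed.
#' @return a `sim_spec` list.
#' @export
sim_spec <- function(n_genes = 400, n_drivers = 40, n_nondrivers = 120,
                     n_cancer_types = 4, samples_per_type = 30,
                     attach_m = 4, rho = 2, out_boost = 1,
                     reciprocal_frac = 0.3, driver_orientation = 0.5,
                     delta = 2, noise_sd = 1, seed = 1) {
  stopifnot(n_genes >= 10, n_drivers >= 1, n_nondrivers >= 1,
            n_drivers + n_nondrivers <= n_genes, n_cancer_types >= 1,
            attach_m >= 1, out_boost >= 1,
            reciprocal_frac >= 0, reciprocal_frac <= 1,
            driver_orientation >= 0.5, driver_orientation <= 1,
            delta >= 0, noise_sd > 0)
  if (rho < 1) stop("rho must be >= 1")
  structure(list(n_genes = as.integer(n_genes),
                 n_drivers = as.integer(n_drivers),
                 n_nondrivers = as.integer(n_nondrivers),
                 n_cancer_types = as.integer(n_cancer_types),
                 samples_per_type = as.integer(samples_per_type),
                 attach_m = as.integer(attach_m), rho = rho,
                 out_boost = out_boost, reciprocal_frac = reciprocal_frac,
                 driver_orientation = driver_orientation, delta = delta,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sim_spec")
}

sim_genes <- function(spec) sprintf("G%04d", seq_len(spec$n_genes))

#' Planted labels of a simulation
#'
#' Drivers and labeled non-drivers are drawn deterministically from the
#' spec's seed, so [simulate_graph()] and [simulate_cohort()] agree on the
#' ground truth.
#'
#' @param spec a [sim_spec()].
#' @return list with character vectors `drivers` and `nondrivers`.
#' @export
planted_labels <- function(spec) {
  genes <- sim_genes(spec)
  set.seed(spec$seed)
  perm <- sample(genes)
  list(drivers = sort(perm[seq_len(spec$n_drivers)]),
       nondrivers = sort(perm[spec$n_drivers + seq_len(spec$n_nondrivers)]))
}

#' Simulate a directed gene network with planted drivers
#'
#' See [sim_spec()] for the generative model. Reproducible under the spec's
#' seed.
#'
#' @param spec a [sim_spec()].
#' @return a [gene_graph()] over all `n_genes` genes.
#' @export
simulate_graph <- function(spec) {
  genes <- sim_genes(spec)
  lab <- planted_labels(spec)
  is_driver <- genes %in% lab$drivers
  set.seed(spec$seed + 101)
  n <- spec$n_genes
  m <- spec$attach_m
  ord <- sample(n)          # arrival order of nodes
  deg <- numeric(n)
  eu <- integer(0); ev <- integer(0)
  add_edge <- function(u, v) {
    eu[[length(eu) + 1]] <<- u
    ev[[length(ev) + 1]] <<- v
    deg[u] <<- deg[u] + 1
    deg[v] <<- deg[v] + 1
  }
  # seed clique over the first m+1 arrivals
  first <- ord[seq_len(m + 1)]
  for (i in seq_along(first)) for (j in seq_len(i - 1)) {
    add_edge(first[j], first[i])
  }
  for (t in (m + 2):n) {
    v <- ord[t]
    present <- ord[seq_len(t - 1)]
    w <- deg[present] + 1
    if (is_driver[v]) w <- w * ifelse(is_driver[present], spec$rho, 1)
    targets <- present[sample.int(length(present), min(m, length(present)),
                                  prob = w)]
    for (u in targets) add_edge(v, u)
  }
  # extra within-driver edges (density multiplier)
  if (spec$rho > 1 && length(lab$drivers) >= 2) {
    didx <- which(is_driver)
    n_extra <- round((spec$rho - 1) * spec$n_drivers * m / 2)
    for (i in seq_len(n_extra)) {
      uv <- didx[sample.int(length(didx), 2)]
      add_edge(uv[1], uv[2])
    }
  }
  # orientation step
  from <- integer(0); to <- integer(0)
  recip <- runif(length(eu)) < spec$reciprocal_frac
  for (i in seq_along(eu)) {
    u <- eu[i]; v <- ev[i]
    if (recip[i]) {
      from <- c(from, u, v); to <- c(to, v, u)
    } else {
      du <- is_driver[u]; dv <- is_driver[v]
      p_uv <- if (du && !dv) spec$driver_orientation
      else if (!du && dv) 1 - spec$driver_orientation
      else 0.5
      if (runif(1) < p_uv) { from <- c(from, u); to <- c(to, v) }
      else { from <- c(from, v); to <- c(to, u) }
    }
  }
  # driver out-degree boost
  if (spec$out_boost > 1) {
    extra <- round((spec$out_boost - 1) * m)
    for (d in which(is_driver)) {
      tg <- sample(setdiff(seq_len(n), d), extra)
      from <- c(from, rep(d, extra)); to <- c(to, tg)
    }
  }
  gene_graph(data.frame(from = genes[from], to = genes[to],
                        weight = 1, tags = "SIM", stringsAsFactors = FALSE),
             nodes = genes)
}

shift_logit <- function(p, shift) plogis(qlogis(p) + shift)

#' Simulate matched omics cohorts and SYS features
#'
#' Per cancer type: per-sample Bernoulli mutation indicators whose per-gene
#' rate is logit-shifted by `delta` for drivers; Beta-distributed
#' methylation betas where tumor means are logit-shifted by `delta / 2` for
#' drivers and equal to normal means otherwise; log-normal expression where
#' the driver tumor/normal log2 fold change has mean `delta / 2`. The ten
#' SYS columns are Gaussian (mean shift `delta` in sd units) or Bernoulli
#' (logit shift `delta`), signed to mirror the usual driver-gene
#' assumptions (e.g. drivers less often ohnologs, more often essential).
#' At `delta = 0` drivers and non-drivers are exchangeable.
#'
#' @param spec a [sim_spec()].
#' @param driver_set character vector of driver genes; defaults to the
#'   spec's planted drivers.
#' @return list with `cohort` (an [omics_cohort()]) and `sys` (matrix with
#'   gene rownames).
#' @export
simulate_cohort <- function(spec, driver_set = planted_labels(spec)$drivers) {
  genes <- sim_genes(spec)
  if (!all(driver_set %in% genes)) stop("driver_set contains unknown genes")
  if (spec$samples_per_type < 2) stop("need at least 2 sample pairs per type")
  d <- as.numeric(genes %in% driver_set)
  n <- spec$n_genes
  ns <- spec$samples_per_type
  set.seed(spec$seed + 202)
  mutation <- meth_t <- meth_n <- expr_t <- expr_n <- list()
  for (ct in sprintf("CT%02d", seq_len(spec$n_cancer_types))) {
    sn <- sprintf("%s_S%03d", ct, seq_len(ns))
    # mutation: per-gene latent rate, drivers logit-shifted by delta
    p_g <- shift_logit(plogis(rnorm(n, qlogis(0.1), 0.5)), spec$delta * d)
    mutation[[ct]] <- matrix(rbinom(n * ns, 1, rep(p_g, ns)), n, ns,
                             dimnames = list(genes, sn))
    # methylation: Beta(mean, concentration 30)
    mu_n <- plogis(rnorm(n, 0, 0.5))
    mu_t <- shift_logit(mu_n, spec$delta / 2 * d)
    kap <- 30
    meth_n[[ct]] <- matrix(rbeta(n * ns, rep(mu_n * kap, ns),
                                 rep((1 - mu_n) * kap, ns)), n, ns,
                           dimnames = list(genes, sn))
    meth_t[[ct]] <- matrix(rbeta(n * ns, rep(mu_t * kap, ns),
                                 rep((1 - mu_t) * kap, ns)), n, ns,
                           dimnames = list(genes, sn))
    # expression: log-normal; driver tumor/normal log2FC mean delta/2
    base <- rnorm(n, 3, 1)
    lfc_g <- rnorm(n, spec$delta / 2 * d, 0.3)
    log_n <- matrix(rnorm(n * ns, rep(base, ns), spec$noise_sd), n, ns)
    log_t <- log_n + matrix(rnorm(n * ns, rep(lfc_g, ns), spec$noise_sd), n, ns)
    expr_n[[ct]] <- matrix(2^log_n, n, ns, dimnames = list(genes, sn))
    expr_t[[ct]] <- matrix(2^log_t, n, ns, dimnames = list(genes, sn))
  }
  cohort <- omics_cohort(mutation, meth_t, meth_n, expr_t, expr_n)
  sh <- spec$delta
  sys <- cbind(
    ohnolog = rbinom(n, 1, shift_logit(0.3, -sh * d)),
    essentiality_pct = rnorm(n, 0.2 + 0.1 * sh * d, 0.1),
    essential = rbinom(n, 1, shift_logit(0.2, sh * d)),
    n_tissues = rnorm(n, 20 + 5 * sh * d, 5),
    degree = rnorm(n, 10 + 3 * sh * d, 3),
    hub = rbinom(n, 1, shift_logit(0.1, sh * d)),
    betweenness = rnorm(n, 0 + sh * d, 1),
    clustering = plogis(rnorm(n, -1 - 0.5 * sh * d, 0.5)),
    n_complexes = rnorm(n, 2 + sh * d, 1),
    n_mirnas = rnorm(n, 15 + 5 * sh * d, 5))
  rownames(sys) <- genes
  list(cohort = cohort, sys = sys)
}

#' Write a complete benchmark bundle
#'
#' Produces a CLI-consumable input set under `dir`: two directed
#' pseudo-source edge lists (the simulated edges split at random), one
#' undirected pseudo-PPI edge list with uniform(0, 1) confidence scores
#' (so integration thresholds are exercised; its surviving rows add noise
#' edges), a long-format cohort TSV, a SYS table, positive/negative label
#' files, and a JSON manifest holding the ground-truth driver set and the
#' per-source ingestion rules.
#'
#' @param spec a [sim_spec()].
#' @param dir output directory (created if needed).
#' @param ppi_frac number of pseudo-PPI rows as a fraction of the simulated
#'   edge count.
#' @param ppi_min_score threshold recorded in the manifest for the PPI
#'   source.
#' @return invisibly, the manifest list.
#' @export
make_benchmark <- function(spec, dir, ppi_frac = 0.5, ppi_min_score = 0.85) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  graph <- simulate_graph(spec)
  lab <- planted_labels(spec)
  sim <- simulate_cohort(spec, lab$drivers)
  set.seed(spec$seed + 303)
  e <- graph$edges
  grp <- sample(c("SIMREGA", "SIMREGB"), nrow(e), replace = TRUE)
  for (s in c("SIMREGA", "SIMREGB")) {
    write.table(e[grp == s, c("from", "to")],
                file.path(dir, paste0(s, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  n_ppi <- round(ppi_frac * nrow(e))
  genes <- graph$nodes
  ppi <- data.frame(a = genes[sample.int(length(genes), n_ppi, replace = TRUE)],
                    b = genes[sample.int(length(genes), n_ppi, replace = TRUE)],
                    score = round(runif(n_ppi), 4))
  ppi <- ppi[ppi$a != ppi$b, ]
  write.table(ppi, file.path(dir, "SIMPPI.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_cohort(sim$cohort, file.path(dir, "cohort.tsv"))
  write.table(data.frame(gene = rownames(sim$sys), sim$sys),
              file.path(dir, "sys.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(lab$drivers, file.path(dir, "positives.txt"))
  writeLines(lab$nondrivers, file.path(dir, "negatives.txt"))
  manifest <- list(
    n_genes = spec$n_genes, seed = spec$seed,
    drivers = lab$drivers, nondrivers = lab$nondrivers,
    sources = list(
      list(name = "SIMREGA", kind = "directed", path = "SIMREGA.tsv"),
      list(name = "SIMREGB", kind = "directed", path = "SIMREGB.tsv"),
      list(name = "SIMPPI", kind = "undirected", path = "SIMPPI.tsv",
           min_score = ppi_min_score, score_column = 3)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Load a benchmark bundle written by [make_benchmark()]
#'
#' Re-ingests the edge lists through [integrate_sources()] (applying the
#' manifest's confidence rules), the cohort, the SYS table and the labels.
#'
#' @param dir bundle directory.
#' @return list with `graph`, `cohort`, `sys`, `labels`, `manifest`.
#' @export
load_benchmark <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE, simplifyDataFrame = FALSE)
  specs <- lapply(manifest$sources, function(s) {
    source_spec(name = s$name, path = file.path(dir, s$path), kind = s$kind,
                min_score = s$min_score, score_column = s$score_column)
  })
  graph <- integrate_sources(specs)
  # keep the full simulated roster even if some genes ended up edge-free
  graph <- gene_graph(graph$edges, nodes = sprintf("G%04d", seq_len(manifest$n_genes)))
  cohort <- read_cohort(file.path(dir, "cohort.tsv"))
  sys <- read_sys_table(file.path(dir, "sys.tsv"))
  labels <- read_labels(file.path(dir, "positives.txt"),
                        file.path(dir, "negatives.txt"), graph)
  list(graph = graph, cohort = cohort, sys = sys, labels = labels,
       manifest = manifest)
}

#' Write an omics cohort as a single long-format TSV
#'
#' Columns: cancer_type, gene, sample, mutation, meth_tumor, meth_normal,
#' expr_tumor, expr_normal.
#'
#' @param cohort an [omics_cohort()].
#' @param path output file.
#' @export
write_cohort <- function(cohort, path) {
  rows <- list()
  for (ct in cohort$cancer_types) {
    mu <- cohort$mutation[[ct]]
    rows[[ct]] <- data.frame(
      cancer_type = ct,
      gene = rep(rownames(mu), ncol(mu)),
      sample = rep(colnames(mu), each = nrow(mu)),
      mutation = as.vector(mu),
      meth_tumor = as.vector(cohort$meth_tumor[[ct]]),
      meth_normal = as.vector(cohort$meth_normal[[ct]]),
      expr_tumor = as.vector(cohort$expr_tumor[[ct]]),
      expr_normal = as.vector(cohort$expr_normal[[ct]]),
      stringsAsFactors = FALSE)
  }
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a long-format cohort TSV
#' @param path file written by [write_cohort()].
#' @return an [omics_cohort()].
#' @export
read_cohort <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("cancer_type", "gene", "sample", "mutation", "meth_tumor",
            "meth_normal", "expr_tumor", "expr_normal")
  stopifnot(all(need %in% names(df)))
  mk <- function(col) {
    lapply(split(df, df$cancer_type), function(dd) {
      genes <- sort(unique(dd$gene))
      samples <- sort(unique(dd$sample))
      m <- matrix(NA_real_, length(genes), length(samples),
                  dimnames = list(genes, samples))
      m[cbind(dd$gene, dd$sample)] <- dd[[col]]
      m
    })
  }
  omics_cohort(mutation = mk("mutation"),
               meth_tumor = mk("meth_tumor"), meth_normal = mk("meth_normal"),
               expr_tumor = mk("expr_tumor"), expr_normal = mk("expr_normal"))
}
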