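# minimal cohort builder: one cancer type, explicit matrices
mini_cohort <- function(genes = c("G1", "G2"), ns = 4, types = "CT01",
                        seed = 1) {
  set.seed(seed)
  mk <- function() {
    lapply(setNames(types, types), function(.)
      matrix(runif(length(genes) * ns, 0.2, 0.8), length(genes), ns,
             dimnames = list(genes, sprintf("S%d", 1:ns))))
  }
  e <- lapply(setNames(types, types), function(.)
    matrix(runif(length(genes) * ns, 1, 10), length(genes), ns,
           dimnames = list(genes, sprintf("S%d", 1:ns))))
  omics_cohort(mutation = lapply(setNames(types, types), function(.)
    matrix(rbinom(length(genes) * ns, 1, 0.3), length(genes), ns,
           dimnames = list(genes, sprintf("S%d", 1:ns)))),
    meth_tumor = mk(), meth_normal = mk(),
    expr_tumor = e, expr_normal = e)
}

test_that("mutation rate is the mean indicator, zero-filled when absent", {
  co <- mini_cohort()
  co$mutation$CT01["G1", ] <- c(1, 0, 0, 1)
  expect_equal(mutation_rate(co, "G1", "CT01"), 0.5)
  co$mutation$CT01["G2", ] <- 0
  expect_equal(mutation_rate(co, "G2", "CT01"), 0)
  co$mutation$CT01["G1", ] <- 1
  expect_equal(mutation_rate(co, "G1", "CT01"), 1.0)
  expect_warning(r <- mutation_rate(co, "ABSENT", "CT01"), "absent")
  expect_equal(r, 0)
})

test_that("differential methylation averages paired beta differences", {
  co <- mini_cohort(ns = 2)
  co$meth_tumor$CT01["G1", ] <- c(0.8, 0.5)
  co$meth_normal$CT01["G1", ] <- c(0.6, 0.6)
  expect_equal(diff_methylation(co, "G1", "CT01"), 0.05)
  co$meth_tumor$CT01["G2", ] <- co$meth_normal$CT01["G2", ]
  expect_equal(diff_methylation(co, "G2", "CT01"), 0)
})

test_that("differential methylation is antisymmetric and order-invariant", {
  set.seed(11)
  co <- mini_cohort(ns = 6, seed = 11)
  d <- diff_methylation(co, "G1", "CT01")
  sw <- co
  sw$meth_tumor$CT01 <- co$meth_normal$CT01
  sw$meth_normal$CT01 <- co$meth_tumor$CT01
  expect_equal(diff_methylation(sw, "G1", "CT01"), -d)
  perm <- sample(6)
  pc <- co
  pc$meth_tumor$CT01 <- co$meth_tumor$CT01[, perm]
  pc$meth_normal$CT01 <- co$meth_normal$CT01[, perm]
  expect_equal(diff_methylation(pc, "G1", "CT01"), d)
})

test_that("differential expression is the mean log2 fold change", {
  co <- mini_cohort(ns = 2)
  co$expr_tumor$CT01["G1", ] <- c(4, 2)
  co$expr_normal$CT01["G1", ] <- c(2, 4)
  expect_equal(diff_expression(co, "G1", "CT01"), 0)
  co2 <- mini_cohort(ns = 1)
  co2$expr_tumor$CT01["G1", 1] <- 8
  co2$expr_normal$CT01["G1", 1] <- 1
  expect_equal(diff_expression(co2, "G1", "CT01"), 3.0)
  co2$expr_tumor$CT01["G2", 1] <- 5
  co2$expr_normal$CT01["G2", 1] <- 5
  expect_equal(diff_expression(co2, "G2", "CT01"), 0)
})

test_that("the biological block is 3 columns per cancer type", {
  types16 <- sprintf("CT%02d", 1:16)
  co <- mini_cohort(types = types16)
  blk <- build_biological_block(co)
  expect_equal(ncol(blk$values), 48)  # 16 types x 3 channels
  co4 <- mini_cohort(types = sprintf("CT%02d", 1:4))
  expect_equal(ncol(build_biological_block(co4)$values), 12)
  # deterministic column order and content across rebuilds
  expect_identical(build_biological_block(co)$values, blk$values)
})

test_that("genes missing from the cohort are zero-filled", {
  co <- mini_cohort()
  blk <- build_biological_block(co, genes = c("G1", "G2", "G3"))
  expect_equal(unname(blk$values["G3", ]), rep(0, 3))
})

test_that("the SYS block appends exactly ten columns when enabled", {
  co <- mini_cohort(types = sprintf("CT%02d", 1:16))
  blk <- build_biological_block(co)
  sys <- matrix(rnorm(2 * 10), 2, 10,
                dimnames = list(c("G1", "G2"), sys_feature_names()))
  full <- attach_sys_block(blk, sys, enabled = TRUE)
  expect_equal(ncol(full$values), 58)
  expect_equal(names(full$blocks), c("biological", "sys"))
  off <- attach_sys_block(blk, sys, enabled = FALSE)
  expect_equal(ncol(off$values), 48)
  # extra SYS genes ignored; missing ones zero-filled with a message
  sys_extra <- rbind(sys, EXTRA = rnorm(10))
  rownames(sys_extra)[3] <- "EXTRA"
  full2 <- attach_sys_block(blk, sys_extra)
  expect_equal(nrow(full2$values), 2)
  blk3 <- build_biological_block(co, genes = c("G1", "G2", "G3"))
  expect_message(full3 <- attach_sys_block(blk3, sys), "zero-filled 1")
  expect_equal(unname(full3$values["G3", 49:58]), rep(0, 10))
})

test_that("cohorts with unpaired samples or bad support are rejected", {
  co <- mini_cohort()
  bad <- co$meth_normal$CT01[, 1:3]
  expect_error(
    omics_cohort(co$mutation, co$meth_tumor, list(CT01 = bad),
                 co$expr_tumor, co$expr_normal),
    "not 1:1 matched")
  bad_beta <- co$meth_tumor
  bad_beta$CT01[1, 1] <- 1.4
  expect_error(
    omics_cohort(co$mutation, bad_beta, co$meth_normal,
                 co$expr_tumor, co$expr_normal),
    "outside")
})

test_that("cohorts round-trip through the long-format TSV", {
  co <- mini_cohort(types = c("CT01", "CT02"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(co, f)
  co2 <- read_cohort(f)
  expect_equal(co2$cancer_types, co$cancer_types)
  expect_equal(co2$mutation$CT01, co$mutation$CT01)
  expect_equal(co2$expr_tumor$CT02, co$expr_tumor$CT02, tolerance = 1e-12)
})
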