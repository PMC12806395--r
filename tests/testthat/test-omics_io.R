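test_that("read_matrix parses gene-by-sample TSVs and collapses duplicate mutation rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  # geneA listed twice for s1 (two variants) -> boolean OR
  writeLines(c("gene\ts1\ts2",
               "geneA\t1\t0",
               "geneA\t1\t0",
               "geneB\t0\t1",
               "geneC\t0\t0"), f)
  m <- read_matrix(f, "mutation")
  expect_equal(m$values["geneA", "s1"], 1)
  expect_equal(m$values["geneA", "s2"], 0)
  expect_equal(dim(m), c(3L, 2L))
  expect_true(all(m$values %in% c(0, 1)))
})

test_that("read_matrix collapses variant-per-row mutation tables to booleans", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tgene\tvariant_class",
               "s1\tgeneA\tmissense",
               "s1\tgeneA\tnonsense",   # second variant, same cell
               "s2\tgeneB\tmissense"), f)
  m <- read_matrix(f, "mutation", maf = TRUE, genes = c("geneA", "geneB", "geneC"))
  expect_equal(m$values["geneA", "s1"], 1)
  expect_equal(m$values["geneC", "s2"], 0)
  expect_equal(sum(m$values), 2)
})

test_that("read_matrix rejects degenerate and invalid inputs", {
  f <- withr::local_tempfile(fileext = ".tsv")
  file.create(f)
  expect_error(read_matrix(f, "mutation"), "empty")
  writeLines(c("gene\ts1", "g1\t1.2"), f)
  expect_error(read_matrix(f, "methylation"), "\\[0, 1\\]")
  writeLines(c("gene\ts1\ts2", "g1\t0.2\toops"), f)
  expect_error(read_matrix(f, "methylation"), "malformed numeric cell")
  writeLines(c("gene\ts1", "g1\t3"), f)
  expect_error(read_matrix(f, "mutation"), "outside")
})

test_that("collapse_probes averages probes per gene over observed values", {
  pm <- rbind(p1 = c(s1 = 0.2, s2 = 0.6),
              p2 = c(0.4, NA),
              p3 = c(0.9, 0.8),
              p4 = c(NA, NA))
  map <- c(p1 = "G", p2 = "G", p3 = "H", p4 = "H2")
  out <- collapse_probes(pm, map)
  expect_equal(out$values["G", "s1"], 0.3)       # mean of two probes
  expect_equal(out$values["G", "s2"], 0.6)       # mean over observed only
  expect_equal(out$values["H", "s1"], 0.9)       # single probe passes through
  expect_true(is.na(out$values["H2", "s1"]))     # all probes missing
})

test_that("collapse_probes drops unmapped probes with a message and rejects ambiguous maps", {
  pm <- rbind(p1 = c(s1 = 0.2), px = c(s1 = 0.5))
  expect_message(out <- collapse_probes(pm, c(p1 = "G")), "without gene mapping")
  expect_equal(rownames(out$values), "G")
  expect_error(collapse_probes(pm, setNames(c("G", "H"), c("p1", "p1"))),
               "more than one gene")
})

test_that("collapse_probes conserves per-sample values when every gene has one probe", {
  pm <- matrix(runif(12), 4, 3, dimnames = list(paste0("p", 1:4), paste0("s", 1:3)))
  out <- collapse_probes(pm, setNames(paste0("G", 1:4), paste0("p", 1:4)))
  expect_equal(colMeans(out$values), colMeans(pm))
})

test_that("impute_knn is identity on complete matrices and idempotent", {
  set.seed(4)
  m <- gene_sample_matrix(matrix(runif(40), 8, 5,
                                 dimnames = list(paste0("g", 1:8), paste0("s", 1:5))),
                          "methylation")
  expect_equal(impute_knn(m)$values, m$values)
  m$values[2, 3] <- NA; m$values[5, 1] <- NA
  once <- impute_knn(m, k = 2)
  twice <- impute_knn(once, k = 2)
  expect_false(anyNA(once$values))
  expect_equal(twice$values, once$values)
  # non-missing cells unchanged
  obs <- !is.na(m$values)
  expect_equal(once$values[obs], m$values[obs])
})

test_that("impute_knn with k=1 copies the value of an exact duplicate sample", {
  v <- matrix(runif(8), 4, 2, dimnames = list(paste0("g", 1:4), c("s1", "s2")))
  v[, 2] <- v[, 1]
  v <- cbind(v, s3 = runif(4) + 2)  # a far-away third sample
  v["g2", "s1"] <- NA
  m <- gene_sample_matrix(pmin(v, 1), "methylation")
  truth <- m$values["g2", "s2"]
  out <- impute_knn(m, k = 1)
  expect_equal(out$values["g2", "s1"], truth)
})

test_that("impute_knn k=2 equals the brute-force nearest-neighbour mean", {
  set.seed(11)
  v <- matrix(runif(24), 6, 4, dimnames = list(paste0("g", 1:6), paste0("s", 1:4)))
  v["g3", "s2"] <- NA
  m <- gene_sample_matrix(v, "methylation")
  out <- impute_knn(m, k = 2)
  # oracle: mean squared difference over mutually observed genes, all pairs
  d <- rep(Inf, 4)
  for (b in c(1, 3, 4)) {
    sh <- !is.na(v[, 2]) & !is.na(v[, b])
    d[b] <- mean((v[sh, 2] - v[sh, b])^2)
  }
  nn <- order(d)[1:2]
  expect_equal(out$values["g3", "s2"], mean(v["g3", nn]))
})

test_that("impute_knn drops genes over the missingness threshold", {
  v <- matrix(runif(20), 5, 4, dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  v[1, 1:3] <- NA   # 75% missing
  v[2, 1] <- NA
  out <- impute_knn(gene_sample_matrix(v, "methylation"), k = 2)
  expect_false("g1" %in% rownames(out$values))
  expect_true("g2" %in% rownames(out$values))
})

test_that("min-max scaling follows the training-set parameters", {
  v <- matrix(c(2, 4, 6,
                3, 3, 3), 2, 3, byrow = TRUE,
              dimnames = list(c("gA", "gB"), c("s1", "s2", "s3")))
  m <- gene_sample_matrix(v, "cna")
  ps <- fit_scaler(m)
  expect_equal(unname(ps$min), c(2, 3))
  expect_equal(unname(ps$max), c(6, 3))
  out <- apply_scaler(m, ps)
  expect_equal(unname(out$values["gA", ]), c(0, 0.5, 1))
  expect_equal(unname(out$values["gB", ]), c(0, 0, 0))  # constant -> 0
})

test_that("scaling clips out-of-range test values and single-sample training works", {
  tr <- gene_sample_matrix(matrix(c(0, 10), 1, 2,
                                  dimnames = list("g", c("a", "b"))), "cna")
  ps <- fit_scaler(tr, c("a", "b"))
  te <- gene_sample_matrix(matrix(c(12, -3), 1, 2,
                                  dimnames = list("g", c("x", "y"))), "cna")
  out <- apply_scaler(te, ps)
  expect_equal(unname(out$values[1, ]), c(1, 0))
  ps1 <- fit_scaler(tr, "a")
  expect_equal(unname(ps1$min), unname(ps1$max))
  expect_error(apply_scaler(gene_sample_matrix(matrix(1, 1, 1,
    dimnames = list("other", "s")), "cna"), ps), "missing for feature")
})

test_that("scaled training values always land in [0, 1]", {
  set.seed(8)
  for (i in 1:5) {
    v <- matrix(rnorm(30, sd = 10), 6, 5,
                dimnames = list(paste0("g", 1:6), paste0("s", 1:5)))
    m <- gene_sample_matrix(v, "cna")
    out <- apply_scaler(m, fit_scaler(m))
    expect_true(all(out$values >= 0 & out$values <= 1))
  }
})

test_that("assemble_cohort intersects samples and validates labels", {
  co <- tiny_cohort()
  expect_equal(length(co$samples), 6)
  # extras get dropped to the shared sample set
  mut2 <- gene_sample_matrix(cbind(co$mutation$values,
                                   s99 = rbinom(4, 1, 0.5)), "mutation")
  co2 <- assemble_cohort(mut2, co$cna, co$meth, co$clinical, co$labels)
  expect_equal(co2$samples, co$samples)
  bad <- co$labels; bad[1] <- "EBV+"
  expect_error(assemble_cohort(co$mutation, co$cna, co$meth, co$clinical, bad),
               "unknown subtype")
  expect_error(assemble_cohort(co$mutation, co$cna, co$meth,
                               data.frame(sample = "zz", age = 1, sex = "male",
                                          os_time = 1, os_event = 1)),
               "no samples shared")
})

test_that("writing and re-reading cohort matrices is bit-exact", {
  sim <- simulate_cohort(sim_config(n_samples = 20, n_genes = 15,
                                    missing_rate = 0, seed = 3))
  dir <- withr::local_tempdir()
  write_cohort(sim, dir)
  mut <- read_matrix(file.path(dir, "mutation.tsv"), "mutation")
  cna <- read_matrix(file.path(dir, "cna.tsv"), "cna")
  meth <- read_matrix(file.path(dir, "methylation.tsv"), "methylation")
  expect_identical(mut$values, sim$cohort$mutation$values)
  expect_identical(cna$values, sim$cohort$cna$values)
  expect_identical(meth$values, sim$cohort$meth$values)
  clin <- read_clinical(file.path(dir, "clinical.tsv"))
  expect_equal(clin$os_time, sim$cohort$clinical$os_time)
})

test_that("cohort_features stacks modalities with prefixed names of fixed length m", {
  co <- tiny_cohort()
  A <- cohort_features(co, "A")
  expect_equal(dim(A), c(6L, 12L))
  expect_equal(sum(startsWith(colnames(A), "mut:")), 4)
  expect_identical(cohort_features(co, "GC"),
                   cbind(cohort_features(co, "G"), cohort_features(co, "C")))
  expect_error(cohort_features(co, "Z"), "unknown modality")
})
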