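test_that("alteration rates match a brute-force double loop", {
  co <- tiny_cohort(n = 6, ng = 8, seed = 2)
  labels <- setNames(rep(c("CIN", "MSI"), 3), co$samples)
  rt <- alteration_rates(co, labels)
  for (k in c("CIN", "MSI")) {
    idx <- which(labels == k)
    # explicit double loop over samples x genes
    mut <- 0; cna <- 0; meth <- 0
    for (i in idx) for (j in seq_len(8)) {
      mut <- mut + co$mutation$values[j, i]
      cna <- cna + (abs(co$cna$values[j, i]) > 1e-9)
      meth <- meth + co$meth$values[j, i]
    }
    denom <- length(idx) * 8
    expect_equal(rt$rate[rt$subtype == k & rt$modality == "mutation"], mut / denom)
    expect_equal(rt$rate[rt$subtype == k & rt$modality == "cna"], cna / denom)
    expect_equal(rt$rate[rt$subtype == k & rt$modality == "methylation"], meth / denom)
  }
  # absent subtypes report missing rates
  expect_true(all(is.na(rt$rate[rt$subtype %in% c("GS", "EBV")])))
})

test_that("degenerate rate inputs give the expected constants", {
  co <- tiny_cohort(n = 4, ng = 3, seed = 3)
  co$mutation$values[] <- 0
  co$meth$values[] <- 0.5
  labels <- setNames(c("CIN", "CIN", "GS", "GS"), co$samples)
  rt <- alteration_rates(co, labels)
  expect_true(all(rt$rate[rt$modality == "mutation" &
                            rt$subtype %in% c("CIN", "GS")] == 0))
  expect_true(all(rt$rate[rt$modality == "methylation" &
                            rt$subtype %in% c("CIN", "GS")] == 0.5))
})

test_that("pooled rates are the sample-weighted mean of subtype rates", {
  co <- tiny_cohort(n = 6, ng = 5, seed = 5)
  labels <- setNames(c("CIN", "CIN", "CIN", "CIN", "MSI", "MSI"), co$samples)
  rt <- alteration_rates(co, labels)
  for (mod in c("mutation", "cna", "methylation")) {
    sub <- rt[rt$modality == mod & rt$subtype %in% c("CIN", "MSI"), ]
    pooled <- rt$rate[rt$modality == mod & rt$subtype == "all"]
    expect_equal(pooled, sum(sub$rate * sub$n_samples) / sum(sub$n_samples),
                 tolerance = 1e-12)
  }
})

test_that("the continuous-CNA call threshold changes the nonzero indicator", {
  co <- tiny_cohort(n = 4, ng = 3, seed = 6)
  co$cna$values[] <- c(0.1, -0.5, 0, 0.31, -0.29, 2, 0, 0.4, -1, 0.05, 0, 0.6)
  labels <- setNames(rep(c("CIN", "GS"), 2), co$samples)
  discrete <- alteration_rates(co, labels)
  called <- alteration_rates(co, labels, cna_call_threshold = 0.3)
  r_disc <- discrete$rate[discrete$subtype == "all" & discrete$modality == "cna"]
  r_call <- called$rate[called$subtype == "all" & called$modality == "cna"]
  expect_equal(r_disc, mean(abs(co$cna$values) > 1e-9))
  expect_equal(r_call, mean(abs(co$cna$values) >= 0.3))
  expect_lt(r_call, r_disc)
})

test_that("Fisher p-values equal hypergeometric enumeration on a fixed table", {
  tab <- matrix(c(8, 1, 2, 9), 2, 2)
  expect_equal(fisher.test(tab)$p.value, oracle_fisher_p(tab), tolerance = 1e-12)
})

test_that("null cohorts yield no markers at the stringent threshold", {
  false_markers <- 0
  for (sd in 1:8) {
    cfg <- sim_config(n_samples = 150, n_genes = 150, n_marker_genes = 0,
                      mutation_rates = c(CIN = .05, GS = .05, MSI = .05, EBV = .05),
                      cna_rates = c(CIN = .1, GS = .1, MSI = .1, EBV = .1),
                      meth_means = c(CIN = .3, GS = .3, MSI = .3, EBV = .3),
                      subtype_proportions = c(CIN = .4, GS = .2, MSI = .2, EBV = .2),
                      missing_rate = 0, seed = 100 + sd)
    sim <- simulate_cohort(cfg)
    mt <- difference_tests(sim$cohort, sim$truth$labels, alpha = 1e-5)
    false_markers <- false_markers + nrow(mt)
  }
  expect_lte(false_markers, 1)
})

test_that("planted markers are recovered with correct directions", {
  cfg <- sim_config(n_samples = 600, n_genes = 300, missing_rate = 0, seed = 42)
  sim <- simulate_cohort(cfg)
  # full per-subtype OVR table for recovery accounting
  full <- difference_tests(sim$cohort, sim$truth$labels, alpha = 1e-5,
                           dedup = FALSE)
  truth <- sim$truth$markers
  hits <- merge(truth, full, by = c("gene", "modality", "subtype"),
                suffixes = c("_true", "_found"))
  expect_gte(nrow(hits), 0.9 * nrow(truth))
  cm <- hits$modality != "mutation"
  expect_true(all(hits$direction_true[cm] == hits$direction_found[cm]))
  # planted hypermethylated EBV markers carry the "+" convention
  ebv_genes <- truth$gene[truth$modality == "methylation" & truth$subtype == "EBV"]
  ebv <- full[full$modality == "methylation" & full$subtype == "EBV" &
                full$gene %in% ebv_genes, ]
  expect_gt(nrow(ebv), 0)
  expect_true(all(ebv$direction == "+"))
  expect_true(all(full$p_adjusted >= full$p_raw))
  # the reported (deduplicated) table has one row per gene/modality
  mt <- difference_tests(sim$cohort, sim$truth$labels, alpha = 1e-5)
  expect_false(any(duplicated(mt[, c("gene", "modality")])))
  expect_true(all(mt$p_adjusted < 1e-5))
})

test_that("difference_tests restricts to a prefixed candidate feature list", {
  cfg <- sim_config(n_samples = 300, n_genes = 100, missing_rate = 0, seed = 9)
  sim <- simulate_cohort(cfg)
  feats <- c("mut:mut_g0006", "meth:meth_g0011", "cna:cna_g0001")
  mt <- difference_tests(sim$cohort, sim$truth$labels, features = feats,
                         alpha = 1)
  expect_true(all(paste0(c(mutation = "mut:", cna = "cna:",
                           methylation = "meth:")[mt$modality], mt$gene)
                  %in% feats))
})

test_that("MANOVA integration check behaves at the null and under shift", {
  set.seed(15)
  # degenerate equality: permuted copies of the same group
  a <- matrix(rnorm(60), 20, 3)
  out <- manova_check(a, a[sample(20), ])
  expect_equal(out$p, 1)
  expect_equal(out$statistic, 1)
  # type-I error near nominal over repeated null draws
  rej <- 0; reps <- 400
  for (i in 1:reps) {
    x <- matrix(rnorm(50 * 3), 50, 3)
    y <- matrix(rnorm(50 * 3), 50, 3)
    if (manova_check(x, y)$p < 0.05) rej <- rej + 1
  }
  expect_gt(rej / reps, 0.02)
  expect_lt(rej / reps, 0.09)
  # a one-s.d. shift in one variable is detected
  hits <- 0
  for (i in 1:40) {
    x <- matrix(rnorm(100 * 3), 100, 3)
    y <- matrix(rnorm(100 * 3), 100, 3); y[, 1] <- y[, 1] + 1
    if (manova_check(x, y)$p < 0.01) hits <- hits + 1
  }
  expect_gte(hits, 38)
  expect_error(manova_check(matrix(0, 2, 3), matrix(0, 2, 3)), "more samples")
})

test_that("per-sample alteration summaries feed the integration check", {
  sim <- simulate_cohort(sim_config(n_samples = 80, n_genes = 60,
                                    missing_rate = 0, seed = 19))
  s <- sample_alteration_summary(sim$cohort)
  expect_equal(dim(s), c(80L, 3L))
  expect_true(all(s >= 0 & s[, "mean_methylation"] <= 1))
  half <- seq_len(40)
  out <- manova_check(s[half, ], s[-half, ])
  expect_true(out$p > 0 && out$p <= 1)
})
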