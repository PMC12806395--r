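# Shared fixtures and independent oracles used across the suite.

# small labelled cohort built directly (no simulator) for I/O-level tests
tiny_cohort <- function(n = 6, ng = 4, seed = 1) {
  set.seed(seed)
  samples <- paste0("s", seq_len(n))
  genes <- paste0("g", seq_len(ng))
  mut <- matrix(rbinom(ng * n, 1, 0.3), ng, n, dimnames = list(genes, samples))
  cna <- matrix(sample(c(0, 0, 1, -1, 2), ng * n, TRUE), ng, n,
                dimnames = list(genes, samples))
  meth <- matrix(runif(ng * n), ng, n, dimnames = list(genes, samples))
  clin <- data.frame(sample = samples, age = 50 + seq_len(n),
                     sex = rep(c("female", "male"), length.out = n),
                     os_time = seq_len(n) * 10, os_event = rep(c(1, 0), length.out = n))
  labels <- setNames(rep(c("CIN", "GS", "MSI", "EBV"), length.out = n), samples)
  assemble_cohort(gene_sample_matrix(mut, "mutation"),
                  gene_sample_matrix(cna, "cna"),
                  gene_sample_matrix(meth, "methylation"),
                  clin, labels)
}

# brute-force ROC area: Mann-Whitney pair counting with ties counted 1/2
oracle_auroc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# brute-force PR area: explicit sweep over distinct thresholds, step-wise
# (non-interpolated) integral sum (r_i - r_{i-1}) * precision_i
oracle_auprc <- function(y, s) {
  np <- sum(y == 1)
  thr <- sort(unique(s), decreasing = TRUE)
  r_prev <- 0; area <- 0
  for (t in thr) {
    pred <- s >= t
    tp <- sum(y == 1 & pred)
    prec <- tp / sum(pred)
    rec <- tp / np
    area <- area + (rec - r_prev) * prec
    r_prev <- rec
  }
  area
}

# Fisher two-sided p by exhaustive hypergeometric enumeration over all
# tables with the observed margins (null probability <= observed, with a
# relative tolerance as in fisher.test)
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(a)
    exp(lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(r1 + r2, c1)),
    numeric(1))
  p_obs <- probs[tab[1, 1] - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# random split tree over a subtype subset (for cascade-coherence checks)
random_tree <- function(subtypes = c("CIN", "GS", "MSI", "EBV"), seed = 1) {
  set.seed(seed)
  build <- function(set, depth) {
    if (length(set) == 1) return(NULL)
    ngrp <- if (length(set) == 2) 2L else sample(2:length(set), 1)
    assign_ <- sample(rep_len(seq_len(ngrp), length(set)))
    # ensure every group non-empty
    while (length(unique(assign_)) < ngrp)
      assign_ <- sample(rep_len(seq_len(ngrp), length(set)))
    groups <- split(set, assign_)
    names(groups) <- NULL
    children <- lapply(groups, function(g) build(g, depth + 1))
    split_node(paste0("n", depth, paste(set, collapse = "")), groups, children)
  }
  tree <- build(sample(subtypes), 1)
  validate_tree(tree, expect = subtypes)
  tree
}

# hand-built cascade with random sparse models (no fitting) over a tree
random_cascade <- function(tree, n_feat = 5, seed = 1) {
  set.seed(seed)
  feats <- paste0("f", seq_len(n_feat))
  nodes <- list()
  for (node in hcg:::tree_nodes(tree)) {
    cls <- vapply(node$groups, function(g) paste(g, collapse = "+"), "")
    B <- matrix(rnorm(n_feat * length(cls), sd = 0.8), n_feat, length(cls),
                dimnames = list(feats, cls))
    nodes[[node$name]] <- list(
      model = structure(list(classes = cls, coefficients = B,
                             intercepts = setNames(rnorm(length(cls)), cls),
                             lambda = 0.1, features = feats),
                        class = "sparse_model"),
      cv = NULL)
  }
  structure(list(tree = tree, nodes = nodes, features = feats,
                 classes = sort(tree$set)),
            class = "hcg_cascade")
}

# 2-D linearly separable 4-class toy with named features
separable_toy <- function(n_per = 30, seed = 1) {
  set.seed(seed)
  centers <- rbind(CIN = c(0, 0), GS = c(6, 0), MSI = c(0, 6), EBV = c(6, 6))
  X <- do.call(rbind, lapply(rownames(centers), function(cl)
    cbind(rnorm(n_per, centers[cl, 1], 0.4), rnorm(n_per, centers[cl, 2], 0.4))))
  colnames(X) <- c("f1", "f2")
  list(X = X, y = rep(rownames(centers), each = n_per))
}
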