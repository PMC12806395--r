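test_that("the strategy catalog has the declared shapes", {
  cat_ <- strategy_catalog()
  expect_setequal(names(cat_), c("I-MC", "II-HC", "III-HC"))
  imc <- cat_[["I-MC"]]
  expect_equal(length(hcg:::tree_nodes(imc)), 1)       # one internal node
  expect_equal(length(imc$groups), 4)                  # four singleton leaves
  expect_equal(hcg:::tree_depth(imc), 1)
  expect_equal(hcg:::tree_depth(cat_[["II-HC"]]), 2)
  iii <- cat_[["III-HC"]]
  expect_equal(hcg:::tree_depth(iii), 3)               # three-step chain
  expect_equal(length(hcg:::tree_nodes(iii)), 3)       # three internal nodes
  expect_equal(iii$groups[[1]], "EBV")                 # EBV split off first
})

test_that("invalid trees are rejected with the violated rule", {
  overlap <- split_node("bad", list(c("CIN", "GS"), c("GS", "MSI", "EBV")),
                        list(split_node("x", list("CIN", "GS")),
                             split_node("y", list("GS", "MSI", "EBV"),
                                        list(NULL, split_node("z", list("MSI", "EBV"))))))
  expect_error(validate_tree(overlap), "overlapping")
  partial <- split_node("p", list("CIN", "GS"))
  expect_error(validate_tree(partial), "must handle")
  nochild <- split_node("n", list("EBV", c("CIN", "GS", "MSI")))
  expect_error(validate_tree(nochild), "needs a child")
})

test_that("custom trees round-trip through YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("name: custom",
               "groups:",
               "  - [MSI]",
               "  - members: [CIN, GS, EBV]",
               "    split:",
               "      name: sub",
               "      groups:",
               "        - [EBV]",
               "        - members: [CIN, GS]",
               "          split:",
               "            name: leafy",
               "            groups:",
               "              - [CIN]",
               "              - [GS]"), f)
  tree <- read_tree_yaml(f)
  expect_equal(hcg:::tree_depth(tree), 3)
  expect_equal(tree$groups[[1]], "MSI")
})

test_that("composed probabilities follow the path-product rule", {
  # hand-built two-level cascade with fixed node probabilities
  tree <- split_node("root", list(c("EBV", "MSI"), c("CIN", "GS")),
                     list(split_node("a", list("EBV", "MSI")),
                          split_node("b", list("CIN", "GS"))))
  casc <- random_cascade(tree, n_feat = 3, seed = 2)
  X <- matrix(rnorm(9), 3, 3, dimnames = list(NULL, paste0("f", 1:3)))
  p <- predict_subtype_proba(casc, X)
  root_p <- predict_proba(casc$nodes[["root"]]$model, X)
  a_p <- predict_proba(casc$nodes[["a"]]$model, X)
  expect_equal(p[, "MSI"], root_p[, "EBV+MSI"] * a_p[, "MSI"], tolerance = 1e-12)
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-9)
})

test_that("composed probabilities are a proper distribution for random trees", {
  for (sd in 1:100) {
    subs <- sample(c("CIN", "GS", "MSI", "EBV"),
                   sample(2:4, 1))
    tree <- random_tree(subs, seed = sd)
    casc <- random_cascade(tree, n_feat = 4, seed = sd + 1)
    X <- matrix(rnorm(8), 2, 4, dimnames = list(NULL, paste0("f", 1:4)))
    p <- predict_subtype_proba(casc, X)
    expect_true(all(p >= 0))
    expect_lt(max(abs(rowSums(p) - 1)), 1e-9)
  }
})

test_that("group marginals reproduce the node model's group probability", {
  for (sd in 1:20) {
    tree <- random_tree(c("CIN", "GS", "MSI", "EBV"), seed = sd)
    casc <- random_cascade(tree, n_feat = 4, seed = sd + 50)
    X <- matrix(rnorm(12), 3, 4, dimnames = list(NULL, paste0("f", 1:4)))
    p <- predict_subtype_proba(casc, X)
    root <- casc$tree
    node_p <- predict_proba(casc$nodes[[root$name]]$model, X)
    for (g in root$groups) {
      lbl <- paste(g, collapse = "+")
      expect_equal(unname(rowSums(p[, g, drop = FALSE])),
                   unname(node_p[, lbl]), tolerance = 1e-12)
    }
  }
})

test_that("hard predictions break exact ties by the fixed subtype order", {
  tree <- strategy_catalog("I-MC")
  feats <- paste0("f", 1:2)
  B <- matrix(0, 2, 4, dimnames = list(feats, c("CIN", "GS", "MSI", "EBV")))
  m <- structure(list(classes = c("CIN", "GS", "MSI", "EBV"),
                      coefficients = B,
                      intercepts = setNames(rep(0, 4), colnames(B)),
                      lambda = 0, features = feats),
                 class = "sparse_model")
  casc <- structure(list(tree = tree, nodes = list("I-MC" = list(model = m, cv = NULL)),
                         features = feats, classes = sort(tree$set)),
                    class = "hcg_cascade")
  X <- matrix(rnorm(4), 2, 2, dimnames = list(NULL, feats))
  expect_equal(predict_subtype(casc, X), c("CIN", "CIN"))  # exact 4-way tie
  expect_identical(predict_subtype(casc, X), predict_subtype(casc, X))
})

test_that("fitting restricts each node to its subtype subset", {
  toy <- separable_toy(12, seed = 5)
  casc <- fit_cascade(toy$X, toy$y, "III-HC", lambda = 0.01, balance = FALSE)
  n2 <- casc$nodes[["III-HC:MSI|rest"]]$model
  expect_setequal(n2$classes, c("MSI", "CIN+GS"))
  n3 <- casc$nodes[["III-HC:GS|CIN"]]$model
  expect_setequal(n3$classes, c("GS", "CIN"))
  # a missing subtype trips the node contract
  keep <- toy$y != "GS"
  expect_error(fit_cascade(toy$X[keep, ], toy$y[keep], "III-HC",
                           lambda = 0.01, balance = FALSE),
               "no training samples")
})

test_that("an I-MC cascade reduces to its single multinomial model", {
  toy <- separable_toy(15, seed = 6)
  casc <- fit_cascade(toy$X, toy$y, "I-MC", lambda = 0.005, balance = FALSE)
  expect_equal(length(casc$nodes), 1)
  p <- predict_subtype_proba(casc, toy$X)
  direct <- predict_proba(casc$nodes[[1]]$model, toy$X)
  expect_equal(unname(p), unname(direct[, colnames(p)]), tolerance = 1e-12)
})

test_that("well-separated classes are fit perfectly by every strategy", {
  toy <- separable_toy(15, seed = 7)
  for (st in c("I-MC", "II-HC", "III-HC")) {
    casc <- fit_cascade(toy$X, toy$y, st, cv_folds = 3, nlambda = 8,
                        decades = 2, seed = 1, balance = TRUE)
    expect_equal(mean(predict_subtype(casc, toy$X) == toy$y), 1.0)
  }
})

test_that("cascade summary and coefficients expose per-node structure", {
  toy <- separable_toy(12, seed = 8)
  casc <- fit_cascade(toy$X, toy$y, "II-HC", lambda = 0.01, balance = FALSE)
  sm <- summary(casc)
  expect_equal(nrow(sm), 3)
  expect_true(all(sm$n_selected >= 1))
  cf <- coef(casc)
  expect_equal(length(cf), 3)
  expect_true(all(cascade_selected_features(casc) %in% c("f1", "f2")))
})
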