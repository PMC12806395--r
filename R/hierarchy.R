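# Classification strategies as split trees over the four subtype labels,
# one sparse logistic model per internal node, and composition of the
# cascade's node probabilities into coherent 4-class subtype probabilities.

group_label <- function(g) paste(g, collapse = "+")

#' Construct a split-tree node
#'
#' @param name node name.
#' @param groups ordered list of >= 2 disjoint subtype groups (character
#'   vectors); their union is the subtype set the node handles.
#' @param children list parallel to \code{groups}: a child node for
#'   non-singleton groups, \code{NULL} for singleton (leaf) groups.
#' @return a \code{split_node} list.
#' @export
split_node <- function(name, groups, children = NULL) {
  if (is.null(children)) children <- vector("list", length(groups))
  structure(list(name = name, groups = groups, children = children,
                 set = unlist(groups)),
            class = "split_node")
}

#' Validate a split tree
#'
#' Checks the strategy invariants: the root handles all four subtypes,
#' groups at each node are disjoint and union to the node's set, every
#' non-singleton group has a child handling exactly that group, and every
#' leaf is a singleton subtype.
#'
#' @param node root \code{split_node}.
#' @param expect subtype set the node must handle (root default: all four).
#' @return the node, invisibly; stops with the violated rule otherwise.
#' @export
validate_tree <- function(node, expect = SUBTYPES) {
  if (!setequal(node$set, expect))
    stop("node '", node$name, "' handles {", paste(sort(node$set), collapse = ","),
         "} but must handle {", paste(sort(expect), collapse = ","), "}")
  if (length(node$groups) < 2)
    stop("node '", node$name, "' must partition into >= 2 groups")
  all_members <- unlist(node$groups)
  if (anyDuplicated(all_members))
    stop("node '", node$name, "' has overlapping groups")
  bad <- setdiff(all_members, SUBTYPES)
  if (length(bad))
    stop("node '", node$name, "' has unknown subtype(s): ", paste(bad, collapse = ","))
  for (i in seq_along(node$groups)) {
    g <- node$groups[[i]]
    child <- node$children[[i]]
    if (length(g) == 1) {
      if (!is.null(child)) stop("singleton group ", g, " must be a leaf")
    } else {
      if (is.null(child))
        stop("node '", node$name, "' group {", paste(g, collapse = ","),
             "} needs a child split")
      validate_tree(child, g)
    }
  }
  invisible(node)
}

tree_nodes <- function(node) {
  out <- list(node)
  for (ch in node$children) if (!is.null(ch)) out <- c(out, tree_nodes(ch))
  out
}

tree_depth <- function(node) {
  kids <- Filter(Negate(is.null), node$children)
  if (!length(kids)) 1L else 1L + max(vapply(kids, tree_depth, 1L))
}

#' The three candidate classification strategies
#'
#' \describe{
#'   \item{I-MC}{one-step multi-class: a single node split into the four
#'     singleton subtypes.}
#'   \item{II-HC}{two-step hierarchical: \{EBV, MSI\} vs \{CIN, GS\} at the
#'     root (grouping the hypermutated/hypermethylated subtypes first),
#'     then two binary splits.}
#'   \item{III-HC}{three-step hierarchical chain mirroring the classical
#'     decision order: EBV vs rest, then MSI vs \{CIN, GS\}, then GS vs
#'     CIN.}
#' }
#'
#' @param name one of \code{"I-MC"}, \code{"II-HC"}, \code{"III-HC"}; omit
#'   for the full named list.
#' @return a validated \code{split_node} (or named list of all three).
#' @export
strategy_catalog <- function(name = NULL) {
  cat_ <- list(
    "I-MC" = split_node("I-MC", list("CIN", "GS", "MSI", "EBV")),
    "II-HC" = split_node("II-HC:root",
                         list(c("EBV", "MSI"), c("CIN", "GS")),
                         list(split_node("II-HC:EBV|MSI", list("EBV", "MSI")),
                              split_node("II-HC:CIN|GS", list("CIN", "GS")))),
    "III-HC" = split_node("III-HC:EBV|rest",
                          list("EBV", c("MSI", "CIN", "GS")),
                          list(NULL,
                               split_node("III-HC:MSI|rest",
                                          list("MSI", c("CIN", "GS")),
                                          list(NULL,
                                               split_node("III-HC:GS|CIN",
                                                          list("GS", "CIN")))))))
  for (tr in cat_) validate_tree(tr)
  if (is.null(name)) return(cat_)
  if (!name %in% names(cat_)) stop("unknown strategy: ", name)
  cat_[[name]]
}

#' Load a custom split tree from a YAML file
#'
#' The YAML mirrors the tree: a node is a map with \code{name} and
#' \code{groups}, each group either a list of subtype strings (a leaf when
#' singleton) or a map with \code{members} and a nested \code{split}.
#'
#' @param path YAML file path.
#' @return a validated \code{split_node}.
#' @export
read_tree_yaml <- function(path) {
  build <- function(spec) {
    groups <- list(); children <- list()
    for (g in spec$groups) {
      if (is.list(g) && !is.null(g$members)) {
        groups <- c(groups, list(unlist(g$members)))
        children <- c(children, list(if (is.null(g$split)) NULL else build(g$split)))
      } else {
        groups <- c(groups, list(unlist(g)))
        children <- c(children, list(NULL))
      }
    }
    split_node(spec$name, groups, children)
  }
  tree <- build(yaml::read_yaml(path))
  validate_tree(tree)
  tree
}

#' @export
#' @method print split_node
print.split_node <- function(x, indent = 0, ...) {
  pad <- strrep("  ", indent)
  cat(pad, x$name, ": [",
      paste(vapply(x$groups, group_label, ""), collapse = " | "), "]\n", sep = "")
  for (ch in x$children) if (!is.null(ch)) print(ch, indent + 1)
  invisible(x)
}

#' Fit a hierarchical cascade of sparse logistic models
#'
#' The central fitting function. The training set is SMOTE-balanced once
#' across the four subtypes (when \code{balance = TRUE}); for every
#' internal node of the strategy tree the relevant (balanced) subset is
#' relabelled by node group and the node model is fitted at an L1 penalty
#' selected by stratified cross-validation. Penalty selection runs on the
#' node's original (unbalanced) samples with each training fold balanced
#' inside the fold, so synthetic samples never inform the validation score.
#'
#' @param X numeric sample-by-feature training matrix (min-max-scaled
#'   alteration features; original samples, not oversampled).
#' @param y subtype label per row (must cover every subtype the tree needs).
#' @param tree a \code{split_node} strategy (name or object;
#'   default \code{"II-HC"}).
#' @param cv_folds,nlambda,decades,seed cross-validation settings passed to
#'   \code{\link{cv_select_lambda}}.
#' @param lambda optional fixed penalty (skips cross-validation).
#' @param balance SMOTE-balance the training set before the final node
#'   fits, and training folds during penalty selection (default TRUE).
#' @param smote_k SMOTE neighbour count.
#' @return an object of class \code{hcg_cascade} with one fitted
#'   \code{sparse_model} (plus its \code{cv_result}) per internal node.
#' @export
fit_cascade <- function(X, y, tree = "II-HC", cv_folds = 5, nlambda = 50,
                        decades = 4, seed = 1L, lambda = NULL,
                        balance = TRUE, smote_k = 5) {
  if (is.character(tree)) tree <- strategy_catalog(tree)
  validate_tree(tree, expect = tree$set)
  X <- as.matrix(X)
  y <- as.character(y)
  if (balance) {
    bal <- smote_balance(X, y, k = smote_k, seed = seed + 500L)
    Xb <- bal$features; yb <- bal$labels
  } else {
    Xb <- X; yb <- y
  }
  to_groups <- function(node, labs) {
    grp <- rep(NA_character_, length(labs))
    for (g in node$groups) grp[labs %in% g] <- group_label(g)
    grp
  }
  nodes <- list()
  for (node in tree_nodes(tree)) {
    keep <- y %in% node$set
    grp <- to_groups(node, y[keep])
    missing_grp <- setdiff(vapply(node$groups, group_label, ""), unique(grp))
    if (length(missing_grp))
      stop("node '", node$name, "': no training samples for group(s) ",
           paste(missing_grp, collapse = ", "))
    cv <- NULL
    lam <- lambda
    if (is.null(lam)) {
      cv <- cv_select_lambda(X[keep, , drop = FALSE], grp, folds = cv_folds,
                             nlambda = nlambda, decades = decades,
                             seed = seed, balance = balance,
                             smote_k = smote_k)
      lam <- cv$lambda
    }
    keep_b <- yb %in% node$set
    model <- fit_lasso_logistic(Xb[keep_b, , drop = FALSE],
                                to_groups(node, yb[keep_b]), lam)
    nodes[[node$name]] <- list(model = model, cv = cv)
  }
  structure(list(tree = tree, nodes = nodes, features = colnames(X),
                 classes = sort(tree$set)),
            class = "hcg_cascade")
}

compose_proba <- function(cascade, node, X, acc, out) {
  nm <- cascade$nodes[[node$name]]$model
  p <- predict_proba(nm, X)
  for (i in seq_along(node$groups)) {
    g <- node$groups[[i]]
    pg <- acc * p[, group_label(g)]
    if (length(g) == 1) out[, g] <- pg
    else out <- compose_proba(cascade, node$children[[i]], X, pg, out)
  }
  out
}

#' Composed subtype probabilities from a cascade
#'
#' The probability of a subtype is the product, along the root-to-leaf
#' path, of each node model's probability of the group containing the
#' subtype; the composed values form a proper distribution over the leaves.
#'
#' @param cascade a fitted \code{hcg_cascade}.
#' @param X sample-by-feature matrix aligned with the training features.
#' @return probability matrix with one column per subtype.
#' @export
predict_subtype_proba <- function(cascade, X) {
  X <- as.matrix(X)
  if (!is.null(colnames(X)) && !identical(colnames(X), cascade$features)) {
    if (!all(cascade$features %in% colnames(X)))
      stop("feature names of X do not match the cascade")
    X <- X[, cascade$features, drop = FALSE]
  }
  out <- matrix(NA_real_, nrow(X), length(cascade$classes),
                dimnames = list(rownames(X), cascade$classes))
  compose_proba(cascade, cascade$tree, X, rep(1, nrow(X)), out)
}

#' Hard subtype predictions from a cascade
#'
#' Argmax of the composed probabilities; exact ties break by the fixed
#' subtype order CIN < GS < MSI < EBV.
#'
#' @inheritParams predict_subtype_proba
#' @return character vector of subtype labels.
#' @export
predict_subtype <- function(cascade, X) {
  p <- predict_subtype_proba(cascade, X)
  ord <- intersect(SUBTYPES, colnames(p))
  p <- p[, ord, drop = FALSE]
  ord[max.col(p, "first")]
}

#' @export
#' @method predict hcg_cascade
predict.hcg_cascade <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (type == "prob") predict_subtype_proba(object, newdata)
  else predict_subtype(object, newdata)
}

#' @export
#' @method print hcg_cascade
print.hcg_cascade <- function(x, ...) {
  cat("<hcg_cascade> strategy tree:\n")
  print(x$tree)
  for (nm in names(x$nodes)) {
    nd <- x$nodes[[nm]]
    cat(sprintf("  %s: lambda=%.4g, %d/%d features selected\n", nm,
                nd$model$lambda, length(selected_features(nd$model)),
                length(nd$model$features)))
  }
  invisible(x)
}

#' @export
#' @method summary hcg_cascade
summary.hcg_cascade <- function(object, ...) {
  rows <- lapply(names(object$nodes), function(nm) {
    nd <- object$nodes[[nm]]
    data.frame(node = nm,
               classes = paste(nd$model$classes, collapse = " | "),
               lambda = nd$model$lambda,
               cv_auroc = if (is.null(nd$cv)) NA_real_ else max(nd$cv$score),
               n_selected = length(selected_features(nd$model)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("summary.hcg_cascade", "data.frame")
  out
}

#' @export
#' @method coef hcg_cascade
coef.hcg_cascade <- function(object, ...) {
  lapply(object$nodes, function(nd) {
    B <- nd$model$coefficients
    B[rowSums(abs(B) > 1e-8) > 0, , drop = FALSE]
  })
}

#' Union of features selected by any node of a cascade
#'
#' @param cascade a fitted \code{hcg_cascade}.
#' @param tol zero tolerance per \code{\link{selected_features}}.
#' @return character vector of feature names.
#' @export
cascade_selected_features <- function(cascade, tol = 1e-8) {
  sort(unique(unlist(lapply(cascade$nodes,
                            function(nd) selected_features(nd$model, tol)))))
}
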