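# SMOTE oversampling: synthetic minority samples interpolated between
# same-class nearest neighbours, applied to the training set so each subtype
# reaches the majority count before node models are fitted.

#' SMOTE class balancing
#'
#' Upsamples every minority class to the target count by interpolating
#' synthetic samples: each synthetic row is \code{x + u * (x_nn - x)} with
#' \code{u ~ Uniform(0, 1)} and \code{x_nn} one of the \code{k} nearest
#' same-class neighbours of \code{x} by Euclidean distance. Original rows
#' are carried through unchanged. Deterministic given the seed.
#'
#' @param features numeric sample-by-feature matrix (no missing values).
#' @param labels class label per row.
#' @param k neighbour count (default 5); reduced with a message when a class
#'   has fewer than \code{k + 1} members.
#' @param target per-class target count; default the majority-class count.
#' @param seed integer seed.
#' @return an object of class \code{balanced_set}: list with \code{features}
#'   (stacked matrix), \code{labels}, and \code{provenance}
#'   (\code{"original"} or \code{"synthetic"} per row).
#' @export
smote_balance <- function(features, labels, k = 5, target = NULL, seed = 1L) {
  features <- as.matrix(features)
  if (anyNA(features)) stop("features must not contain missing values")
  labels <- as.character(labels)
  if (nrow(features) != length(labels)) stop("features/labels length mismatch")
  counts <- table(labels)
  if (is.null(target)) target <- max(counts)
  ones <- names(counts)[counts == 1 & counts < target]
  if (length(ones))
    stop("cannot oversample class(es) with a single sample: ",
         paste(ones, collapse = ", "))
  with_seed(seed, {
    syn_feats <- list(); syn_labs <- character()
    for (cl in names(counts)) {
      need <- target - counts[[cl]]
      if (need <= 0) next
      idx <- which(labels == cl)
      x <- features[idx, , drop = FALSE]
      kk <- min(k, length(idx) - 1)
      if (kk < k)
        message("class ", cl, ": k reduced to ", kk, " (class size ", length(idx), ")")
      d <- as.matrix(dist(x))
      diag(d) <- Inf
      nn <- apply(d, 1, function(row) order(row)[seq_len(kk)], simplify = FALSE)
      if (is.matrix(nn)) nn <- asplit(nn, 2)
      base_i <- rep_len(seq_along(idx), need)
      pick <- vapply(base_i, function(i) nn[[i]][sample.int(kk, 1)], 1L)
      u <- runif(need)
      new <- x[base_i, , drop = FALSE] +
        u * (x[pick, , drop = FALSE] - x[base_i, , drop = FALSE])
      rownames(new) <- sprintf("syn_%s_%03d", cl, seq_len(need))
      syn_feats[[cl]] <- new
      syn_labs <- c(syn_labs, rep(cl, need))
    }
    syn <- if (length(syn_feats)) do.call(rbind, syn_feats) else
      features[0, , drop = FALSE]
    structure(list(features = rbind(features, syn),
                   labels = c(labels, syn_labs),
                   provenance = c(rep("original", nrow(features)),
                                  rep("synthetic", nrow(syn)))),
              class = "balanced_set")
  })
}

#' @export
#' @method print balanced_set
print.balanced_set <- function(x, ...) {
  tb <- table(x$labels)
  cat(sprintf("<balanced_set> %d rows (%d synthetic) | %s\n",
              nrow(x$features), sum(x$provenance == "synthetic"),
              paste(sprintf("%s=%d", names(tb), tb), collapse = " ")))
  invisible(x)
}
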