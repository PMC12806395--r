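# Subtype alteration-rate statistics, one-vs-rest difference tests for
# subtype-specific DNA alteration markers, and the MANOVA dataset
# integration check.

strip_prefix <- function(x) sub("^(mut|cna|meth):", "", x)
feature_modality <- function(x) c(mut = "mutation", cna = "cna",
                                  meth = "methylation")[sub(":.*$", "", x)]

#' Per-subtype alteration rates
#'
#' For each subtype k with sample set S_k (n_k samples): the mutation rate
#' is the mean of the boolean mutation cells over S_k x genes; the CNA rate
#' is the fraction of cells with a nonzero value (\code{|value| > epsilon},
#' or \code{|value| >= call_threshold} first when the input is a continuous
#' log-ratio); the methylation rate is the mean beta value.
#'
#' @param cohort an \code{omics_cohort} (methylation must be complete).
#' @param labels subtype per sample (default the cohort labels).
#' @param cna_epsilon zero tolerance for discrete CNA calls (default 1e-9).
#' @param cna_call_threshold optional absolute threshold applied first to
#'   continuous CNA values (e.g. 0.3 for log-ratios).
#' @return an object of class \code{rate_table}: data.frame with one row
#'   per subtype x modality plus pooled rows (subtype \code{"all"}).
#' @export
alteration_rates <- function(cohort, labels = cohort$labels,
                             cna_epsilon = 1e-9, cna_call_threshold = NULL) {
  if (is.null(labels)) stop("labels required")
  labels <- as.character(labels[cohort$samples])
  if (anyNA(labels)) stop("labels must cover every cohort sample")
  cna_v <- abs(cohort$cna$values)
  thr <- if (is.null(cna_call_threshold)) cna_epsilon else cna_call_threshold
  cna_ind <- if (is.null(cna_call_threshold)) cna_v > thr else cna_v >= thr
  mats <- list(mutation = cohort$mutation$values,
               cna = cna_ind + 0,
               methylation = cohort$meth$values)
  subs <- c(SUBTYPES, "all")
  rows <- list()
  for (mod in names(mats)) for (k in subs) {
    in_k <- if (k == "all") rep(TRUE, length(labels)) else labels == k
    rate <- if (!any(in_k)) NA_real_ else mean(mats[[mod]][, in_k])
    rows[[paste(mod, k)]] <- data.frame(subtype = k, modality = mod,
                                        n_samples = sum(in_k),
                                        n_genes = nrow(mats[[mod]]),
                                        rate = rate, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  class(out) <- c("rate_table", "data.frame")
  out
}

#' One-vs-rest difference tests for subtype-specific markers
#'
#' For every candidate feature and every subtype (one-vs-rest): mutation
#' features use the two-sided Fisher exact test on the 2x2 table
#' (altered/not x in-subtype/rest); CNA and methylation features use the
#' two-sided Welch two-sample t-test. P-values are adjusted (BH by default)
#' across all tests within each modality; rows with adjusted p below
#' \code{alpha} are kept, the direction is the sign of (in-subtype mean -
#' rest mean), and results are deduplicated to the single most significant
#' row per (gene, modality).
#'
#' @param cohort an \code{omics_cohort}.
#' @param labels subtype per sample (default cohort labels).
#' @param features optional candidate feature names, prefixed
#'   \code{mut:}/\code{cna:}/\code{meth:} as produced by
#'   \code{\link{cohort_features}} (typically the cascade-selected
#'   features); default all features.
#' @param alpha adjusted-p threshold (default 1e-5).
#' @param adjust adjustment method (\code{"BH"} default).
#' @param dedup keep only the most significant row per (gene, modality)
#'   (default TRUE, the reported-marker convention); set FALSE to obtain
#'   the full per-subtype OVR table.
#' @param cna_epsilon,cna_call_threshold nonzero-call rule for the Fisher
#'   table is not used for CNA (CNA is tested by t-test on values); kept
#'   for interface symmetry with \code{\link{alteration_rates}}.
#' @return an object of class \code{marker_table}: data.frame (gene,
#'   modality, subtype, direction, raw p, adjusted p, effect), sorted by
#'   adjusted p. The number of skipped zero-variance tests is attached as
#'   attribute \code{n_skipped}.
#' @export
difference_tests <- function(cohort, labels = cohort$labels, features = NULL,
                             alpha = 1e-5, adjust = "BH", dedup = TRUE,
                             cna_epsilon = 1e-9, cna_call_threshold = NULL) {
  if (is.null(labels)) stop("labels required")
  labels <- as.character(labels[cohort$samples])
  small <- names(which(table(labels) < 2))
  if (length(small)) stop("subtype(s) with < 2 samples: ",
                          paste(small, collapse = ", "))
  mats <- list(mutation = cohort$mutation$values,
               cna = cohort$cna$values,
               methylation = cohort$meth$values)
  pref <- c(mutation = "mut:", cna = "cna:", methylation = "meth:")
  present <- intersect(SUBTYPES, unique(labels))
  n_skipped <- 0L
  all_rows <- list()
  for (mod in names(mats)) {
    m <- mats[[mod]]
    genes <- rownames(m)
    if (!is.null(features)) {
      want <- strip_prefix(features[startsWith(features, pref[[mod]])])
      genes <- intersect(genes, want)
    }
    if (!length(genes)) next
    rows <- list()
    for (g in genes) {
      v <- m[g, ]
      for (k in present) {
        in_k <- labels == k
        if (mod == "mutation") {
          tab <- matrix(c(sum(v[in_k] == 1), sum(v[!in_k] == 1),
                          sum(v[in_k] == 0), sum(v[!in_k] == 0)), 2, 2)
          if (sum(tab[1, ]) == 0 || sum(tab[2, ]) == 0) { # all altered or none
            n_skipped <- n_skipped + 1L
            next
          }
          p <- fisher.test(tab, alternative = "two.sided")$p.value
          eff <- mean(v[in_k]) - mean(v[!in_k])
        } else {
          if (sd(v[in_k]) == 0 && sd(v[!in_k]) == 0) {
            n_skipped <- n_skipped + 1L
            next
          }
          tt <- tryCatch(t.test(v[in_k], v[!in_k], var.equal = FALSE),
                         error = function(e) NULL)
          if (is.null(tt)) { n_skipped <- n_skipped + 1L; next }
          p <- tt$p.value
          eff <- mean(v[in_k]) - mean(v[!in_k])
        }
        rows[[paste(g, k)]] <- data.frame(
          gene = g, modality = mod, subtype = k,
          direction = if (eff >= 0) "+" else "-",
          p_raw = p, effect = eff, stringsAsFactors = FALSE)
      }
    }
    if (!length(rows)) next
    tab <- do.call(rbind, c(rows, make.row.names = FALSE))
    tab$p_adjusted <- p.adjust(tab$p_raw, method = adjust)
    all_rows[[mod]] <- tab
  }
  out <- if (length(all_rows)) do.call(rbind, c(all_rows, make.row.names = FALSE))
         else data.frame(gene = character(), modality = character(),
                         subtype = character(), direction = character(),
                         p_raw = numeric(), effect = numeric(),
                         p_adjusted = numeric(), stringsAsFactors = FALSE)
  out <- out[!is.na(out$p_adjusted) & out$p_adjusted < alpha, , drop = FALSE]
  # deduplicate: keep the most significant row per (gene, modality)
  if (nrow(out)) {
    out <- out[order(out$p_adjusted, out$p_raw,
                     match(out$subtype, SUBTYPES)), , drop = FALSE]
    if (dedup)
      out <- out[!duplicated(out[, c("gene", "modality")]), , drop = FALSE]
    out <- out[order(out$p_adjusted), , drop = FALSE]
    rownames(out) <- NULL
  }
  out <- out[, c("gene", "modality", "subtype", "direction", "p_raw",
                 "p_adjusted", "effect")]
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("marker_table", "data.frame")
  out
}

#' One-way MANOVA integration check between two sample groups
#'
#' Tests whether two groups of samples differ in their joint mean over a
#' common set of summary variables (Wilks' lambda). Used to check that a
#' candidate dataset can be pooled with a reference dataset.
#'
#' @param features_a,features_b numeric sample-by-variable matrices with
#'   the same variables.
#' @return list with \code{statistic} (Wilks' lambda), \code{approx_f},
#'   \code{df}, \code{p}.
#' @export
manova_check <- function(features_a, features_b) {
  a <- as.matrix(features_a); b <- as.matrix(features_b)
  if (ncol(a) != ncol(b)) stop("variable sets must match")
  nv <- ncol(a)
  if (nrow(a) <= nv || nrow(b) <= nv)
    stop("each group needs more samples than variables")
  y <- rbind(a, b)
  grp <- factor(rep(c("a", "b"), c(nrow(a), nrow(b))))
  if (all(colMeans(a) == colMeans(b))) {
    # degenerate equality of group means: no between-group dispersion
    return(list(statistic = 1, approx_f = 0,
                df = c(nv, nrow(y) - 1 - nv), p = 1))
  }
  fit <- manova(y ~ grp)
  sm <- tryCatch(summary(fit, test = "Wilks"),
                 error = function(e)
                   stop("singular within-group covariance; reduce variables"))
  st <- sm$stats
  list(statistic = unname(st["grp", "Wilks"]),
       approx_f = unname(st["grp", "approx F"]),
       df = unname(c(st["grp", "num Df"], st["grp", "den Df"])),
       p = unname(st["grp", "Pr(>F)"]))
}

#' Per-sample alteration summary variables
#'
#' The three per-sample summaries used by the MANOVA integration check:
#' mean mutation indicator, fraction of nonzero CNA cells, and mean
#' methylation beta.
#'
#' @param cohort an \code{omics_cohort}.
#' @param cna_epsilon,cna_call_threshold nonzero-call rule as in
#'   \code{\link{alteration_rates}}.
#' @return numeric matrix, samples x 3 variables.
#' @export
sample_alteration_summary <- function(cohort, cna_epsilon = 1e-9,
                                      cna_call_threshold = NULL) {
  cna_v <- abs(cohort$cna$values)
  cna_ind <- if (is.null(cna_call_threshold)) cna_v > cna_epsilon
             else cna_v >= cna_call_threshold
  cbind(mutation_rate = colMeans(cohort$mutation$values),
        cna_fraction = colMeans(cna_ind),
        mean_methylation = colMeans(cohort$meth$values))
}
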