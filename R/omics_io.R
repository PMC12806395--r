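#' @importFrom stats predict coef quantile rbinom rbeta rexp runif rnorm sd
#'   setNames pchisq fisher.test t.test p.adjust manova as.formula relevel
#'   complete.cases
#' @importFrom utils read.delim write.table head
NULL

SUBTYPES <- c("CIN", "GS", "MSI", "EBV")
MODALITIES <- c("mutation", "cna", "methylation")

#' Construct a gene-by-sample alteration matrix
#'
#' The basic container for one DNA-alteration modality: a numeric matrix with
#' genes as rows and samples as columns, tagged with its modality. Missing
#' values are stored as \code{NA}. Mutation matrices must be boolean (0/1)
#' and complete; methylation values must be beta values in \[0, 1\].
#'
#' @param values numeric matrix, genes as rows (rownames = gene identifiers),
#'   samples as columns (colnames = sample identifiers).
#' @param modality one of \code{"mutation"}, \code{"cna"}, \code{"methylation"}.
#' @return an object of class \code{gene_sample_matrix}.
#' @export
gene_sample_matrix <- function(values, modality = c("mutation", "cna", "methylation")) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("gene_sample_matrix requires gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers")
  obs <- values[!is.na(values)]
  if (modality == "mutation") {
    if (anyNA(values)) stop("mutation matrix must not contain missing values")
    if (!all(obs %in% c(0, 1)))
      stop("mutation values must be 0/1 after boolean collapse")
  }
  if (modality == "methylation" && length(obs) && (min(obs) < 0 || max(obs) > 1))
    stop("methylation beta values must lie in [0, 1]")
  structure(list(values = values, modality = modality),
            class = "gene_sample_matrix")
}

#' @export
#' @method print gene_sample_matrix
print.gene_sample_matrix <- function(x, ...) {
  cat(sprintf("<gene_sample_matrix> %s: %d genes x %d samples (%d missing cells)\n",
              x$modality, nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' @export
#' @method dim gene_sample_matrix
dim.gene_sample_matrix <- function(x) dim(x$values)

#' Read a gene-by-sample matrix from a delimited text file
#'
#' Reads the tab-separated gene-by-sample export dialect (first column gene
#' symbol, header row of sample identifiers). Mutation input may instead be a
#' variant-per-row table with columns \code{sample}, \code{gene} (and
#' optionally further columns); such records are collapsed to a boolean
#' matrix in which a cell is 1 iff the gene carries at least one variant in
#' that sample.
#'
#' @param path path to the file.
#' @param modality modality tag of the matrix.
#' @param sep field separator (default tab).
#' @param transposed if \code{TRUE}, the file stores samples as rows and
#'   genes as columns.
#' @param maf if \code{TRUE}, treat the file as a variant-per-row mutation
#'   table and collapse it.
#' @param genes for \code{maf} input: optional full gene universe; genes
#'   without any variant get all-zero rows.
#' @return a \code{\link{gene_sample_matrix}}.
#' @export
read_matrix <- function(path, modality = c("mutation", "cna", "methylation"),
                        sep = "\t", transposed = FALSE, maf = FALSE,
                        genes = NULL) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0) stop("parse error: empty file: ", path)
  if (maf) {
    if (modality != "mutation") stop("variant-per-row input is only valid for mutation data")
    tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
    if (nrow(tab) == 0) stop("parse error: no variant records in ", path)
    need <- c("sample", "gene")
    if (!all(need %in% names(tab)))
      stop("variant table must have columns 'sample' and 'gene'")
    gs <- if (is.null(genes)) sort(unique(tab$gene)) else genes
    ss <- sort(unique(tab$sample))
    m <- matrix(0, length(gs), length(ss), dimnames = list(gs, ss))
    hit <- unique(tab[, c("gene", "sample")])
    hit <- hit[hit$gene %in% gs, , drop = FALSE]
    m[cbind(match(hit$gene, gs), match(hit$sample, ss))] <- 1
    return(gene_sample_matrix(m, modality))
  }
  raw <- read.delim(path, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (nrow(raw) == 0 || ncol(raw) < 2) stop("parse error: no data cells in ", path)
  rn <- as.character(raw[[1]])
  raw <- raw[-1]
  bad <- which(!vapply(raw, function(col) is.numeric(col) || all(is.na(col)), TRUE))
  for (j in bad) {
    suppressWarnings(num <- as.numeric(raw[[j]]))
    broken <- which(!is.na(raw[[j]]) & raw[[j]] != "" & is.na(num))
    if (length(broken))
      stop(sprintf("parse error: malformed numeric cell at row '%s', column '%s'",
                   rn[broken[1]], colnames(raw)[j]))
    raw[[j]] <- num
  }
  m <- as.matrix(raw)
  rownames(m) <- rn
  storage.mode(m) <- "double"
  if (transposed) m <- t(m)
  if (modality == "mutation") {
    if (anyDuplicated(rownames(m))) {
      # per-variant rows for the same gene collapse by logical OR
      m <- rowsum(m, rownames(m), reorder = FALSE)
      m <- (m > 0) + 0
    }
    if (!all(m[!is.na(m)] %in% c(0, 1)))
      stop("validation error: mutation values outside {0,1} after collapse")
  } else if (anyDuplicated(rownames(m))) {
    stop("duplicate gene rows in ", modality, " matrix")
  }
  gene_sample_matrix(m, modality)
}

#' Write a gene-by-sample matrix in the TSV dialect read_matrix() reads
#'
#' @param x a \code{gene_sample_matrix}.
#' @param path output path.
#' @export
write_matrix <- function(x, path) {
  # full double precision so a write/read round trip is bit-exact
  txt <- apply(x$values, 2, function(col) sprintf("%.17g", col))
  txt[is.na(x$values)] <- "NA"
  df <- data.frame(gene = rownames(x$values), txt, check.names = FALSE)
  colnames(df) <- c("gene", colnames(x$values))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse probe-level methylation to gene level
#'
#' Each gene's value is the arithmetic mean over its probes, computed over
#' non-missing probe values per sample; a gene cell is missing iff all of
#' its probes are missing in that sample. Probes absent from the map are
#' dropped (the count is reported via \code{message}).
#'
#' @param probe_matrix numeric probe-by-sample matrix (probe rownames).
#' @param probe_map data.frame with columns \code{probe}, \code{gene}, or a
#'   named character vector (names = probes, values = genes).
#' @return a methylation \code{\link{gene_sample_matrix}}.
#' @export
collapse_probes <- function(probe_matrix, probe_map) {
  if (inherits(probe_matrix, "gene_sample_matrix")) probe_matrix <- probe_matrix$values
  probe_matrix <- as.matrix(probe_matrix)
  if (is.data.frame(probe_map)) {
    map <- setNames(as.character(probe_map$gene), as.character(probe_map$probe))
  } else map <- probe_map
  if (anyDuplicated(names(map))) stop("a probe maps to more than one gene")
  known <- rownames(probe_matrix) %in% names(map)
  if (any(!known))
    message(sum(!known), " probe(s) without gene mapping dropped")
  pm <- probe_matrix[known, , drop = FALSE]
  if (nrow(pm) == 0) stop("no probes left after applying the probe map")
  gene <- map[rownames(pm)]
  obs <- !is.na(pm)
  pm0 <- pm; pm0[!obs] <- 0
  sums <- rowsum(pm0, gene, reorder = TRUE)
  cnts <- rowsum(obs + 0, gene, reorder = TRUE)
  out <- sums / cnts         # 0/0 -> NaN where all probes missing
  out[cnts == 0] <- NA
  gene_sample_matrix(out, "methylation")
}

#' K-nearest-neighbour imputation of missing methylation values
#'
#' Genes missing in more than \code{max_missing_fraction} of samples are
#' removed. Each remaining missing cell is replaced by the mean value of the
#' gene in the \code{k} nearest samples that observe it. Sample-to-sample
#' distance is the mean squared difference over the genes observed in both
#' samples (a per-feature-normalised Euclidean distance, so distances are
#' comparable across missingness patterns).
#'
#' @param matrix a \code{gene_sample_matrix} (methylation).
#' @param k neighbour count (default 10).
#' @param max_missing_fraction genes with a larger missing fraction are
#'   dropped (default 0.5).
#' @return a complete \code{gene_sample_matrix}; observed cells unchanged.
#' @export
impute_knn <- function(matrix, k = 10, max_missing_fraction = 0.5) {
  v <- matrix$values
  frac <- rowMeans(is.na(v))
  if (any(frac > max_missing_fraction)) {
    v <- v[frac <= max_missing_fraction, , drop = FALSE]
    if (nrow(v) == 0) stop("all genes exceed the missingness threshold")
  }
  if (!anyNA(v)) return(gene_sample_matrix(v, matrix$modality))
  ns <- ncol(v)
  obs <- !is.na(v)
  # pairwise mean squared difference over mutually observed genes, computed
  # by cross-products: sum_shared (xa-xb)^2 = xa2'Ob + Oa'xb2 - 2 xa'xb
  x <- v; x[!obs] <- 0
  o <- obs + 0
  x2 <- x * x
  shared <- crossprod(o)
  ss <- crossprod(x2, o)
  d <- (ss + t(ss) - 2 * crossprod(x)) / shared
  d[shared == 0] <- Inf
  out <- v
  short <- FALSE
  for (s in seq_len(ns)) {
    miss <- which(!obs[, s])
    if (!length(miss)) next
    ord <- order(d[, s])
    ord <- ord[ord != s & is.finite(d[ord, s])]
    for (g in miss) {
      donors <- ord[obs[g, ord]]
      if (!length(donors)) stop("no donor sample observes gene ", rownames(v)[g])
      if (length(donors) < k) short <- TRUE
      use <- head(donors, k)
      out[g, s] <- mean(v[g, use])
    }
  }
  if (short) message("fewer than k donor samples available for some cells; used all available")
  gene_sample_matrix(out, matrix$modality)
}

#' Fit per-feature min-max scaling parameters on a training sample set
#'
#' @param matrix a \code{gene_sample_matrix} (no missing values).
#' @param train_samples character vector of training sample identifiers
#'   (default: all samples).
#' @return an object of class \code{scaler_params}: per-gene \code{min} and
#'   \code{max} learned on the training samples only.
#' @export
fit_scaler <- function(matrix, train_samples = colnames(matrix$values)) {
  if (!length(train_samples)) stop("train_samples must be non-empty")
  miss <- setdiff(train_samples, colnames(matrix$values))
  if (length(miss)) stop("unknown training samples: ", paste(miss, collapse = ", "))
  v <- matrix$values[, train_samples, drop = FALSE]
  structure(list(min = apply(v, 1, min), max = apply(v, 1, max),
                 genes = rownames(v)),
            class = "scaler_params")
}

#' Apply min-max scaling
#'
#' Computes \code{(x - min) / (max - min)} per feature with parameters
#' learned on the training set. Constant features (max = min) map to 0;
#' values of non-training samples falling outside the training range are
#' clipped to \[0, 1\].
#'
#' @param matrix a \code{gene_sample_matrix}.
#' @param params a \code{scaler_params} covering every gene of \code{matrix}.
#' @return a scaled \code{gene_sample_matrix} with values in \[0, 1\].
#' @export
apply_scaler <- function(matrix, params) {
  v <- matrix$values
  idx <- match(rownames(v), params$genes)
  if (anyNA(idx))
    stop("scaler params missing for feature(s): ",
         paste(head(rownames(v)[is.na(idx)], 5), collapse = ", "))
  mn <- params$min[idx]; mx <- params$max[idx]
  rng <- mx - mn
  out <- (v - mn) / ifelse(rng == 0, 1, rng)
  out[rng == 0, ] <- 0
  out <- pmin(pmax(out, 0), 1)
  gene_sample_matrix(out, matrix$modality)
}

#' Read the clinical annotation table
#'
#' TSV with columns \code{sample}, \code{age}, \code{sex}, \code{os_months},
#' \code{os_event} (and optionally \code{dataset}).
#'
#' @param path path to the TSV file.
#' @return a validated clinical \code{data.frame}.
#' @export
read_clinical <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  names(tab)[names(tab) == "os_months"] <- "os_time"
  validate_clinical(tab)
}

validate_clinical <- function(tab) {
  need <- c("sample", "age", "sex", "os_time", "os_event")
  if (!all(need %in% names(tab)))
    stop("clinical table must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(tab$sample)) stop("duplicate sample identifiers in clinical table")
  if (any(!is.na(tab$age) & tab$age < 0)) stop("negative age")
  if (any(!is.na(tab$os_time) & tab$os_time <= 0)) stop("os_time must be > 0 where present")
  if (!all(tab$sex[!is.na(tab$sex)] %in% c("female", "male")))
    stop("sex must be 'female' or 'male'")
  if (!all(tab$os_event[!is.na(tab$os_event)] %in% c(0, 1)))
    stop("os_event must be 0/1")
  tab
}

#' Assemble an aligned multi-modal cohort
#'
#' Restricts the three alteration matrices, the clinical table and optional
#' subtype labels to their common samples, in one canonical (sorted) order,
#' and validates the container invariants.
#'
#' @param mut,cna,meth \code{gene_sample_matrix} objects of the respective
#'   modalities.
#' @param clinical clinical \code{data.frame} (see \code{\link{read_clinical}}).
#' @param labels optional named character vector mapping sample to subtype
#'   (one of CIN, GS, MSI, EBV).
#' @return an object of class \code{omics_cohort}.
#' @export
assemble_cohort <- function(mut, cna, meth, clinical, labels = NULL) {
  stopifnot(inherits(mut, "gene_sample_matrix"),
            inherits(cna, "gene_sample_matrix"),
            inherits(meth, "gene_sample_matrix"))
  if (mut$modality != "mutation" || cna$modality != "cna" ||
      meth$modality != "methylation")
    stop("matrices passed with the wrong modality tags")
  clinical <- validate_clinical(clinical)
  common <- Reduce(intersect, list(colnames(mut$values), colnames(cna$values),
                                   colnames(meth$values), clinical$sample))
  if (!length(common)) stop("no samples shared across all inputs")
  common <- sort(common)
  if (!is.null(labels)) {
    labels <- labels[common]
    if (anyNA(labels)) stop("labels missing for sample(s): ",
                            paste(head(common[is.na(labels)], 5), collapse = ", "))
    bad <- setdiff(unique(labels), SUBTYPES)
    if (length(bad)) stop("unknown subtype label(s): ", paste(bad, collapse = ", "))
    labels <- setNames(as.character(labels), common)
  }
  sub <- function(m) gene_sample_matrix(m$values[, common, drop = FALSE], m$modality)
  structure(list(mutation = sub(mut), cna = sub(cna), meth = sub(meth),
                 clinical = clinical[match(common, clinical$sample), , drop = FALSE],
                 samples = common, labels = labels),
            class = "omics_cohort")
}

#' @export
#' @method print omics_cohort
print.omics_cohort <- function(x, ...) {
  cat(sprintf("<omics_cohort> %d samples | mutation %d genes, cna %d genes, methylation %d genes\n",
              length(x$samples), nrow(x$mutation$values), nrow(x$cna$values),
              nrow(x$meth$values)))
  if (!is.null(x$labels)) {
    tb <- table(factor(x$labels, levels = SUBTYPES))
    cat("  subtypes:", paste(sprintf("%s=%d", names(tb), tb), collapse = " "), "\n")
  }
  invisible(x)
}

#' Stack cohort modalities into one sample-by-feature design matrix
#'
#' Feature names are prefixed \code{mut:}, \code{cna:}, \code{meth:} so the
#' concatenated feature vector has a fixed length m across samples.
#'
#' @param cohort an \code{omics_cohort}.
#' @param modalities subset of \code{c("G","C","M")} (gene mutations, CNAs,
#'   methylation); \code{"A"} means all three.
#' @return numeric matrix, samples as rows, features as columns.
#' @export
cohort_features <- function(cohort, modalities = "A") {
  mods <- expand_modalities(modalities)
  parts <- list()
  if ("G" %in% mods)
    parts$G <- t(cohort$mutation$values)
  if ("C" %in% mods)
    parts$C <- t(cohort$cna$values)
  if ("M" %in% mods)
    parts$M <- t(cohort$meth$values)
  pref <- c(G = "mut:", C = "cna:", M = "meth:")
  for (nm in names(parts))
    colnames(parts[[nm]]) <- paste0(pref[[nm]], colnames(parts[[nm]]))
  do.call(cbind, parts)
}

expand_modalities <- function(modalities) {
  mods <- unlist(strsplit(modalities, ""))
  if ("A" %in% mods) mods <- c("G", "C", "M")
  bad <- setdiff(mods, c("G", "C", "M"))
  if (length(bad)) stop("unknown modality code(s): ", paste(bad, collapse = ", "))
  unique(mods)
}

#' Scale all modalities of a cohort with training-set parameters
#'
#' Fits min-max scalers per modality on the designated training samples and
#' applies them to the whole cohort (mutation matrices are already 0/1 and
#' pass through scaling unchanged in value).
#'
#' @param cohort an \code{omics_cohort}.
#' @param train_samples training sample identifiers (default: all).
#' @return list with elements \code{cohort} (scaled) and \code{scalers}
#'   (per-modality \code{scaler_params}).
#' @export
scale_cohort <- function(cohort, train_samples = cohort$samples) {
  scalers <- list(mutation = fit_scaler(cohort$mutation, train_samples),
                  cna = fit_scaler(cohort$cna, train_samples),
                  meth = fit_scaler(cohort$meth, train_samples))
  out <- cohort
  out$mutation <- gene_sample_matrix(
    apply_scaler(cohort$mutation, scalers$mutation)$values, "mutation")
  out$cna <- apply_scaler(cohort$cna, scalers$cna)
  out$meth <- apply_scaler(cohort$meth, scalers$meth)
  list(cohort = out, scalers = scalers)
}
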