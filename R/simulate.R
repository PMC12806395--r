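# Seeded multi-omics cohort simulator. Default intensities reproduce the
# alteration structure of the four gastric-cancer molecular subtypes:
# MSI-specific hypermutation, CIN-specific copy-number burden, EBV-specific
# hypermethylation, and subtype-linked survival hazards.

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores the caller's RNG state so seeded package functions do
#' not disturb the global random stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulation configuration for the synthetic gastric-cancer cohort
#'
#' Defaults encode the study conditions this simulator emulates: subtype
#' prevalences CIN 0.67 / GS 0.11 / MSI 0.15 / EBV 0.07; per-subtype
#' cell-level mutation rates 0.0123 / 0.0044 / 0.0998 / 0.0140; CNA event
#' rates 0.544 / 0.0245 / 0.097 / 0.0433; methylation beta means 0.254 /
#' 0.271 / 0.281 / 0.326; subtype hazard multipliers 1 / 1.23 / 0.64 / 0.69
#' relative to CIN. Gene counts default to 1,000 per modality (desk scale).
#'
#' @param n_samples number of patients.
#' @param subtype_proportions named prevalences over CIN, GS, MSI, EBV
#'   (must sum to 1).
#' @param n_genes genes per modality (single count or named vector over
#'   mutation/cna/methylation).
#' @param mutation_rates,cna_rates,meth_means named per-subtype intensities:
#'   Bernoulli cell mutation probability, CNA event probability, and
#'   methylation beta mean respectively.
#' @param meth_concentration beta-distribution concentration (a+b).
#' @param meth_sample_sd s.d. of a per-sample random shift applied to the
#'   methylation mean of every gene of that sample, emulating sample-level
#'   global methylation variability (tumour purity, global methylator
#'   level). Without it the per-gene subtype shifts aggregate into an
#'   unrealistically clean per-sample mean.
#' @param cna_jitter_sd Gaussian jitter s.d. added to nonzero CNA levels.
#' @param n_marker_genes planted subtype-specific marker genes per
#'   (modality, subtype) pair of \code{marker_pattern}.
#' @param marker_pattern named list giving, per modality, the subtypes that
#'   receive planted markers. The default mirrors the marker structure of
#'   the four subtypes: mutation markers for GS, the hypermutated MSI and
#'   the virally driven EBV subtype (which carries recurrent point
#'   mutations in addition to its methylator phenotype), copy-number
#'   markers for the chromosomally unstable CIN subtype, methylation
#'   markers for CIN, GS and the hypermethylated EBV subtype.
#' @param marker_mutation_rate,marker_cna_rate in-subtype alteration
#'   probability of planted mutation / CNA markers; a scalar, or a named
#'   vector over subtypes. Defaults are strongest in the modality that
#'   defines the subtype (MSI mutations, CIN copy number) and moderate
#'   elsewhere.
#' @param marker_meth_high,marker_meth_low in-subtype beta mean of planted
#'   hyper-/hypo-methylated markers (scalar or named over subtypes);
#'   the EBV default is extreme, CIN/GS defaults moderate.
#' @param baseline_hazard baseline event hazard per month (CIN, age<65,
#'   female).
#' @param hazard_multipliers named per-subtype hazard ratios vs CIN.
#' @param age_hr hazard ratio for age >= 65; \code{male_hr} for male sex.
#' @param male_hr see \code{age_hr}.
#' @param censoring_rate marginal probability that a patient is censored.
#' @param missing_rate independent missingness probability injected into the
#'   methylation matrix.
#' @param seed integer seed making the whole cohort reproducible.
#' @return a validated \code{sim_config} list.
#' @export
sim_config <- function(n_samples = 600,
                       subtype_proportions = c(CIN = 0.67, GS = 0.11,
                                               MSI = 0.15, EBV = 0.07),
                       n_genes = 1000,
                       mutation_rates = c(CIN = 0.0123, GS = 0.0044,
                                          MSI = 0.0998, EBV = 0.0140),
                       cna_rates = c(CIN = 0.544, GS = 0.0245,
                                     MSI = 0.097, EBV = 0.0433),
                       meth_means = c(CIN = 0.254, GS = 0.271,
                                      MSI = 0.281, EBV = 0.326),
                       meth_concentration = 10,
                       meth_sample_sd = 0.03,
                       cna_jitter_sd = 0.1,
                       n_marker_genes = 5,
                       marker_pattern = list(mutation = c("GS", "MSI", "EBV"),
                                             cna = "CIN",
                                             methylation = c("CIN", "GS", "EBV")),
                       marker_mutation_rate = c(GS = 0.2, MSI = 0.6, EBV = 0.4),
                       marker_cna_rate = c(CIN = 0.8),
                       marker_meth_high = c(CIN = 0.5, GS = 0.5, EBV = 0.8),
                       marker_meth_low = c(CIN = 0.08, GS = 0.08),
                       baseline_hazard = 0.02,
                       hazard_multipliers = c(CIN = 1, GS = 1.23,
                                              MSI = 0.64, EBV = 0.69),
                       age_hr = 1.5, male_hr = 1.2,
                       censoring_rate = 0.3,
                       missing_rate = 0.05,
                       seed = 1L) {
  if (length(n_genes) == 1) n_genes <- c(mutation = n_genes, cna = n_genes,
                                         methylation = n_genes)
  cfg <- list(n_samples = as.integer(n_samples),
              subtype_proportions = subtype_proportions[SUBTYPES],
              n_genes = n_genes[MODALITIES],
              mutation_rates = mutation_rates[SUBTYPES],
              cna_rates = cna_rates[SUBTYPES],
              meth_means = meth_means[SUBTYPES],
              meth_concentration = meth_concentration,
              meth_sample_sd = meth_sample_sd,
              cna_jitter_sd = cna_jitter_sd,
              n_marker_genes = as.integer(n_marker_genes),
              marker_pattern = marker_pattern,
              marker_mutation_rate = marker_mutation_rate,
              marker_cna_rate = marker_cna_rate,
              marker_meth_high = marker_meth_high,
              marker_meth_low = marker_meth_low,
              baseline_hazard = baseline_hazard,
              hazard_multipliers = hazard_multipliers[SUBTYPES],
              age_hr = age_hr, male_hr = male_hr,
              censoring_rate = censoring_rate,
              missing_rate = missing_rate,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  p <- cfg$subtype_proportions
  if (anyNA(p) || any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("subtype_proportions must be non-negative over CIN/GS/MSI/EBV and sum to 1")
  probs <- c(cfg$mutation_rates, cfg$cna_rates, cfg$marker_mutation_rate,
             cfg$marker_cna_rate, cfg$missing_rate, cfg$censoring_rate)
  if (anyNA(probs) || any(probs < 0 | probs > 1))
    stop("all probabilities must lie in [0, 1]")
  if (any(cfg$meth_means <= 0 | cfg$meth_means >= 1))
    stop("methylation means must lie in (0, 1)")
  if (anyNA(cfg$hazard_multipliers) || any(cfg$hazard_multipliers <= 0))
    stop("hazard multipliers must be positive")
  bad_pat <- setdiff(unlist(cfg$marker_pattern), SUBTYPES)
  if (length(bad_pat))
    stop("marker_pattern has unknown subtype(s): ", paste(bad_pat, collapse = ", "))
  for (mod in names(cfg$marker_pattern)) {
    k <- length(cfg$marker_pattern[[mod]]) * cfg$n_marker_genes
    if (k > cfg$n_genes[[mod]])
      stop("infeasible config: more planted marker genes than genes (", mod, ")")
  }
  if (cfg$missing_rate >= 1) stop("missing_rate must be < 1")
  invisible(cfg)
}

effect_for <- function(x, subtype) {
  if (length(x) == 1 && is.null(names(x))) return(unname(x))
  if (!subtype %in% names(x))
    stop("no marker effect configured for subtype ", subtype)
  unname(x[[subtype]])
}

marker_plan <- function(cfg) {
  empty <- data.frame(gene = character(), modality = character(),
                      subtype = character(), direction = character(),
                      stringsAsFactors = FALSE)
  if (cfg$n_marker_genes == 0) return(empty)
  out <- list()
  for (mod in intersect(MODALITIES, names(cfg$marker_pattern))) {
    short <- c(mutation = "mut", cna = "cna", methylation = "meth")[[mod]]
    next_idx <- 1L
    for (sub in cfg$marker_pattern[[mod]]) {
      idx <- next_idx:(next_idx + cfg$n_marker_genes - 1L)
      next_idx <- next_idx + cfg$n_marker_genes
      dir <- if (mod == "mutation") rep("+", length(idx))
             else if (mod == "methylation" && sub == "EBV") rep("+", length(idx))
             else rep_len(c("+", "-"), length(idx))
      out[[paste(mod, sub)]] <- data.frame(
        gene = sprintf("%s_g%04d", short, idx), modality = mod,
        subtype = sub, direction = dir, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Simulate a labelled multi-omics cohort
#'
#' Draws subtype labels from the configured prevalences, then generates the
#' three alteration matrices with subtype-dependent intensities: mutation
#' cells are Bernoulli draws, CNA cells are zero except Bernoulli-selected
#' events with signed discrete magnitudes (\eqn{\pm 1} or \eqn{\pm 2}) plus
#' Gaussian jitter, methylation cells are beta draws. Planted marker genes
#' receive boosted subtype-specific effects in their subtype's samples.
#' Survival follows \code{\link{simulate_survival}} and missing methylation
#' values are injected at \code{missing_rate}. Fully deterministic given the
#' config seed.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with elements \code{cohort} (an \code{omics_cohort}) and
#'   \code{truth} (true labels and the planted marker table).
#' @export
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  with_seed(config$seed, {
    n <- config$n_samples
    samples <- sprintf("s%04d", seq_len(n))
    labels <- sample(SUBTYPES, n, replace = TRUE,
                     prob = config$subtype_proportions)
    names(labels) <- samples
    plan <- marker_plan(config)

    ## mutation: Bernoulli cells at subtype rate, markers boosted
    ng <- config$n_genes[["mutation"]]
    genes <- sprintf("mut_g%04d", seq_len(ng))
    rate <- matrix(rep(config$mutation_rates[labels], each = ng), ng, n)
    mk <- plan[plan$modality == "mutation", , drop = FALSE]
    if (nrow(mk)) {
      gi <- match(mk$gene, genes)
      for (r in seq_len(nrow(mk)))
        rate[gi[r], labels == mk$subtype[r]] <-
          effect_for(config$marker_mutation_rate, mk$subtype[r])
    }
    mut <- matrix(rbinom(ng * n, 1, rate), ng, n,
                  dimnames = list(genes, samples))

    ## CNA: Bernoulli event indicator, signed level +-{1,2} with jitter
    ng <- config$n_genes[["cna"]]
    genes <- sprintf("cna_g%04d", seq_len(ng))
    rate <- matrix(rep(config$cna_rates[labels], each = ng), ng, n)
    sgn <- matrix(sample(c(-1, 1), ng * n, replace = TRUE), ng, n)
    mk <- plan[plan$modality == "cna", , drop = FALSE]
    if (nrow(mk)) {
      gi <- match(mk$gene, genes)
      for (r in seq_len(nrow(mk))) {
        in_s <- labels == mk$subtype[r]
        rate[gi[r], in_s] <- effect_for(config$marker_cna_rate, mk$subtype[r])
        sgn[gi[r], in_s] <- if (mk$direction[r] == "+") 1 else -1
      }
    }
    event <- matrix(rbinom(ng * n, 1, rate), ng, n)
    level <- matrix(sample(1:2, ng * n, replace = TRUE), ng, n)
    cna <- event * (sgn * level + rnorm(ng * n, 0, config$cna_jitter_sd))
    dimnames(cna) <- list(genes, samples)

    ## methylation: beta draws with subtype-dependent mean
    ng <- config$n_genes[["methylation"]]
    genes <- sprintf("meth_g%04d", seq_len(ng))
    shift <- rnorm(n, 0, config$meth_sample_sd)
    mu <- matrix(rep(config$meth_means[labels] + shift, each = ng), ng, n)
    mk <- plan[plan$modality == "methylation", , drop = FALSE]
    if (nrow(mk)) {
      gi <- match(mk$gene, genes)
      for (r in seq_len(nrow(mk)))
        mu[gi[r], labels == mk$subtype[r]] <-
          if (mk$direction[r] == "+")
            effect_for(config$marker_meth_high, mk$subtype[r])
          else effect_for(config$marker_meth_low, mk$subtype[r])
    }
    mu <- pmin(pmax(mu, 0.02), 0.98)
    nu <- config$meth_concentration
    meth <- matrix(rbeta(ng * n, mu * nu, (1 - mu) * nu), ng, n,
                   dimnames = list(genes, samples))

    clin <- simulate_survival(labels, config,
                              seed = sample.int(.Machine$integer.max, 1))
    meth_gsm <- gene_sample_matrix(meth, "methylation")
    if (config$missing_rate > 0)
      meth_gsm <- inject_missing(meth_gsm, config$missing_rate,
                                 seed = sample.int(.Machine$integer.max, 1))
    cohort <- assemble_cohort(gene_sample_matrix(mut, "mutation"),
                              gene_sample_matrix(cna, "cna"),
                              meth_gsm, clin, labels)
    list(cohort = cohort,
         truth = list(labels = labels, markers = plan, config = config))
  })
}

#' Simulate overall-survival outcomes for labelled samples
#'
#' Event times are exponential with hazard = baseline x subtype multiplier x
#' age effect (age >= 65) x sex effect (male). Censoring is independent
#' exponential with a per-sample rate chosen so each patient is censored
#' with probability \code{censoring_rate}; \code{os_event = 0} iff censored.
#'
#' @param labels named subtype per sample.
#' @param config a \code{\link{sim_config}} (the survival fields are used).
#' @param seed integer seed.
#' @return a clinical \code{data.frame} (sample, age, sex, os_time, os_event).
#' @export
simulate_survival <- function(labels, config = sim_config(), seed = 1L) {
  if (any(config$hazard_multipliers <= 0)) stop("hazard multipliers must be positive")
  with_seed(seed, {
    n <- length(labels)
    samples <- if (is.null(names(labels))) sprintf("s%04d", seq_len(n)) else names(labels)
    age <- pmin(pmax(round(rnorm(n, 65, 10)), 30), 90)
    sex <- sample(c("female", "male"), n, replace = TRUE)
    hz <- config$baseline_hazard * config$hazard_multipliers[labels] *
      ifelse(age >= 65, config$age_hr, 1) *
      ifelse(sex == "male", config$male_hr, 1)
    t_event <- rexp(n, hz)
    cr <- config$censoring_rate
    if (cr > 0) {
      t_cens <- rexp(n, hz * cr / (1 - cr))
      os_event <- as.integer(t_event <= t_cens)
      os_time <- pmin(t_event, t_cens)
    } else {
      os_event <- rep(1L, n)
      os_time <- t_event
    }
    data.frame(sample = samples, age = age, sex = sex,
               os_time = os_time, os_event = os_event,
               stringsAsFactors = FALSE)
  })
}

#' Inject independent missingness into a matrix
#'
#' Each cell is masked (\code{NA}) independently with probability
#' \code{rate}; deterministic given the seed.
#'
#' @param matrix a \code{gene_sample_matrix}.
#' @param rate missingness probability in \[0, 1).
#' @param seed integer seed.
#' @return the matrix with masked cells.
#' @export
inject_missing <- function(matrix, rate, seed = 1L) {
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)")
  if (rate == 0) return(matrix)
  with_seed(seed, {
    v <- matrix$values
    mask <- matrix(runif(length(v)) < rate, nrow(v), ncol(v))
    v[mask] <- NA
    gene_sample_matrix(v, matrix$modality)
  })
}

#' Write a simulated cohort to disk in the TSV dialects read_matrix() reads
#'
#' @param sim result of \code{\link{simulate_cohort}}.
#' @param dir output directory (created if absent).
#' @return the directory path, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  co <- sim$cohort
  write_matrix(co$mutation, file.path(dir, "mutation.tsv"))
  write_matrix(co$cna, file.path(dir, "cna.tsv"))
  write_matrix(co$meth, file.path(dir, "methylation.tsv"))
  clin <- co$clinical
  names(clin)[names(clin) == "os_time"] <- "os_months"
  write.table(clin, file.path(dir, "clinical.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- data.frame(sample = names(sim$truth$labels),
                      subtype = unname(sim$truth$labels))
  write.table(truth, file.path(dir, "labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$truth$markers, file.path(dir, "markers.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
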