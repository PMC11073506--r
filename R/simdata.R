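#' Configuration of the synthetic benchmark
#'
#' Defines the study conditions of the synthetic benchmark: a negative
#' binomial RNA-seq study with a database (batch) covariate and planted
#' differential genes, a sparse non-negative latent loading matrix whose
#' "active" latent variables load on the planted genes, and a drug
#' perturbation reference containing planted "reverser" drugs whose z-score
#' profiles negate the disease signal, with annotation tables enriched for
#' those reversers.
#'
#' @param n_genes number of genes.
#' @param n_tumor,n_control samples per condition.
#' @param n_databases number of source databases (>= 1); the first is the
#'   reference level, additional databases add per-gene log2 offsets drawn
#'   from N(0, 0.25^2).  Tumor samples all come from the first database and
#'   control samples are spread over all databases, mimicking a tumor
#'   compendium complemented by an external normal-tissue compendium.
#' @param frac_de fraction of genes with a true nonzero condition effect
#'   (in `[0, 1)`; 0 gives the global null).
#' @param lfc_scale absolute log2 fold change of planted differential genes.
#' @param nb_dispersion negative binomial dispersion (1/size).
#' @param n_lvs number of latent variables.
#' @param lv_sparsity fraction of genes with nonzero loading per latent
#'   variable.
#' @param n_active_lvs number of latent variables that load preferentially
#'   on planted differential genes (condition-associated).
#' @param n_drugs number of drugs in the perturbation reference.
#' @param n_reversers number of planted reverser drugs.
#' @param reverser_strength z-score magnitude of the planted reversal signal.
#' @param annot_enrichment odds multiplier linking reverser status to
#'   trial-membership and screen-sensitivity annotations (1 = independent).
#' @param seed master RNG seed; every generator derives its own substream
#'   from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L, n_tumor = 40L, n_control = 40L,
                       n_databases = 2L, frac_de = 0.05, lfc_scale = 2,
                       nb_dispersion = 0.1, n_lvs = 100L, lv_sparsity = 0.025,
                       n_active_lvs = 5L, n_drugs = 100L, n_reversers = 10L,
                       reverser_strength = 3, annot_enrichment = 8,
                       seed = 101L) {
  cfg <- list(n_genes = as.integer(n_genes), n_tumor = as.integer(n_tumor),
              n_control = as.integer(n_control),
              n_databases = as.integer(n_databases),
              frac_de = frac_de, lfc_scale = lfc_scale,
              nb_dispersion = nb_dispersion, n_lvs = as.integer(n_lvs),
              lv_sparsity = lv_sparsity,
              n_active_lvs = as.integer(n_active_lvs),
              n_drugs = as.integer(n_drugs),
              n_reversers = as.integer(n_reversers),
              reverser_strength = reverser_strength,
              annot_enrichment = annot_enrichment, seed = as.integer(seed))
  counts <- c("n_genes", "n_tumor", "n_control", "n_databases", "n_lvs",
              "n_drugs")
  if (any(vapply(cfg[counts], function(x) x <= 0L, logical(1))))
    stop("configuration error: all counts must be positive")
  if (cfg$frac_de < 0 || cfg$frac_de >= 1)
    stop("configuration error: 'frac_de' must lie in [0, 1)")
  if (cfg$lv_sparsity <= 0 || cfg$lv_sparsity > 1)
    stop("configuration error: 'lv_sparsity' must lie in (0, 1]")
  if (cfg$nb_dispersion <= 0)
    stop("configuration error: 'nb_dispersion' must be positive")
  if (cfg$n_reversers > cfg$n_drugs)
    stop("configuration error: 'n_reversers' must not exceed 'n_drugs'")
  if (cfg$n_reversers < 0 || cfg$n_active_lvs < 0)
    stop("configuration error: counts must be non-negative")
  if (cfg$n_active_lvs > cfg$n_lvs)
    stop("configuration error: 'n_active_lvs' must not exceed 'n_lvs'")
  if (cfg$annot_enrichment <= 0)
    stop("configuration error: 'annot_enrichment' must be positive")
  structure(cfg, class = "sim_config")
}

#' Simulate an RNA-seq expression study with planted differential genes
#'
#' Counts are drawn from a negative binomial model
#' `NB(mean = baseline * 2^(condition * beta_g + database offset),
#' dispersion)` where exactly `ceiling(frac_de * n_genes)` genes carry a
#' nonzero condition effect `beta_g = +/- lfc_scale`.  Gene lengths are drawn
#' log-uniformly between 0.5 and 10 kb.  The same seed yields bitwise
#' identical output.
#'
#' @param config a [sim_config()].
#' @return A list with elements `study` (an [expression_study()]) and
#'   `truth` (list with `de_genes`, a character vector of planted gene ids,
#'   and `de_sign`, the named sign of each planted effect).
#' @export
simulate_expression_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.substream(config$seed, 1L))
  G <- config$n_genes
  n <- config$n_tumor + config$n_control
  gene_ids <- sprintf("g%05d", seq_len(G))
  sample_ids <- sprintf("s%03d", seq_len(n))
  condition <- factor(rep(c("tumor", "control"),
                          c(config$n_tumor, config$n_control)),
                      levels = c("control", "tumor"))
  # tumors from the first database, controls spread over all of them
  db_levels <- paste0("db", seq_len(config$n_databases))
  db <- c(rep(db_levels[1L], config$n_tumor),
          db_levels[1L + (seq_len(config$n_control) - 1L) %% config$n_databases])
  db <- factor(db, levels = db_levels)

  baseline <- rlnorm(G, meanlog = log(100), sdlog = 1)
  n_de <- ceiling(config$frac_de * G)
  beta <- numeric(G)
  de_idx <- integer(0)
  if (n_de > 0) {
    de_idx <- sort(sample.int(G, n_de))
    beta[de_idx] <- config$lfc_scale * sample(c(-1, 1), n_de, replace = TRUE)
  }
  offsets <- matrix(0, G, config$n_databases)
  if (config$n_databases > 1L)
    offsets[, -1L] <- rnorm(G * (config$n_databases - 1L), 0, 0.25)

  log2mu <- log2(baseline) +
    outer(beta, as.numeric(condition == "tumor")) +
    offsets[, as.integer(db), drop = FALSE]
  counts <- matrix(rnbinom(G * n, mu = 2^log2mu, size = 1 / config$nb_dispersion),
                   nrow = G, dimnames = list(gene_ids, sample_ids))
  lengths_kb <- exp(runif(G, log(0.5), log(10)))

  study <- expression_study(counts, lengths_kb, condition, db)
  truth <- list(de_genes = gene_ids[de_idx],
                de_sign = setNames(sign(beta[de_idx]), gene_ids[de_idx]))
  list(study = study, truth = truth)
}

#' Simulate a sparse non-negative latent loading matrix
#'
#' Emulates the loading matrix of a sparse non-negative factorization of a
#' large expression compendium: each latent variable has exactly
#' `ceiling(lv_sparsity * n_genes)` nonzero non-negative weights.  The
#' `n_active_lvs` active latent variables draw their support preferentially
#' from the planted differential genes of a single effect sign (alternating
#' between signs across active LVs) so that projected activity separates the
#' conditions without cancellation.  With no planted genes (global null) no
#' latent variable is condition-associated and `active_lvs` is empty.
#'
#' @param config a [sim_config()].
#' @param truth the `truth` element returned by
#'   [simulate_expression_study()] under the same config.
#' @return A list with `loadings` (gene x LV matrix) and `truth` (the input
#'   truth augmented with `active_lvs`).
#' @export
simulate_latent_loadings <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.substream(config$seed, 2L))
  G <- config$n_genes
  gene_ids <- sprintf("g%05d", seq_len(G))
  lv_ids <- sprintf("LV%03d", seq_len(config$n_lvs))
  nz <- ceiling(config$lv_sparsity * G)
  Z <- matrix(0, G, config$n_lvs, dimnames = list(gene_ids, lv_ids))

  has_signal <- length(truth$de_genes) > 0 && config$n_active_lvs > 0
  active <- if (has_signal) sort(sample(lv_ids, config$n_active_lvs)) else character(0)
  de_up <- names(truth$de_sign)[truth$de_sign > 0]
  de_dn <- names(truth$de_sign)[truth$de_sign < 0]

  for (j in seq_len(config$n_lvs)) {
    lv <- lv_ids[j]
    if (lv %in% active) {
      pool <- if (match(lv, active) %% 2L == 1L) de_up else de_dn
      if (length(pool) == 0) pool <- truth$de_genes
      support <- sample(pool, min(nz, length(pool)))
      if (length(support) < nz)
        support <- c(support,
                     sample(setdiff(gene_ids, support), nz - length(support)))
    } else {
      support <- sample(gene_ids, nz)
    }
    Z[support, j] <- abs(rnorm(nz)) + 0.1
  }
  truth$active_lvs <- active
  list(loadings = Z, truth = truth)
}

.odds_to_prob <- function(p_base, odds_ratio) {
  o <- odds_ratio * p_base / (1 - p_base)
  o / (1 + o)
}

#' Simulate a perturbation reference with planted reverser drugs
#'
#' Drug profiles are standard normal noise except for the planted reversers,
#' which additionally carry `z = -reverser_strength * sign(true effect)` on
#' the planted differential genes, i.e. their profiles negate the disease
#' signal.  Drug annotations (clinical-trial membership, screen sensitivity)
#' are enriched for reversers at the configured odds; all reversers are
#' FDA-approved so that the approved-only candidate filter can recover them,
#' and reversers share a common fingerprint bit block.
#'
#' @param config a [sim_config()].
#' @param truth truth list from [simulate_expression_study()] (optionally
#'   augmented by [simulate_latent_loadings()]) under the same config.
#' @param study the matching [expression_study()]; used only to check that
#'   the gene universes agree.
#' @return A list with `reference` (a [perturbation_reference()]),
#'   `annotations` (a [drug_annotations()]) and `truth` augmented with
#'   `reverser_drugs`.
#' @export
simulate_perturbation_reference <- function(config, truth, study) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.substream(config$seed, 3L))
  gene_ids <- sprintf("g%05d", seq_len(config$n_genes))
  if (!missing(study) && !is.null(study) &&
      !identical(rownames(study$counts), gene_ids))
    stop("dimension error: study gene universe does not match the configuration")
  if (length(truth$de_genes) > 0 && !all(truth$de_genes %in% gene_ids))
    stop("dimension error: truth gene ids outside the configured universe")

  D <- config$n_drugs
  drug_ids <- sprintf("d%04d", seq_len(D))
  z <- matrix(rnorm(D * config$n_genes), D,
              dimnames = list(drug_ids, gene_ids))
  reversers <- if (config$n_reversers > 0)
    sort(sample(drug_ids, config$n_reversers)) else character(0)
  is_rev <- drug_ids %in% reversers
  if (length(truth$de_genes) > 0 && config$reverser_strength > 0)
    for (d in reversers)
      z[d, truth$de_genes] <- z[d, truth$de_genes] -
        config$reverser_strength * truth$de_sign[truth$de_genes]

  # annotations: reversers are approved; trial membership and screen
  # sensitivity follow baseline rates boosted at the configured odds
  fda <- ifelse(is_rev, TRUE, runif(D) < 0.9)
  p_trial <- ifelse(is_rev, .odds_to_prob(0.2, config$annot_enrichment), 0.2)
  in_trial <- runif(D) < p_trial
  moa_pool <- paste0("moa", 1:8)
  moa <- sample(moa_pool, D, replace = TRUE)
  targets <- lapply(seq_len(D), function(i)
    sample(gene_ids, sample(1:3, 1)))
  names(targets) <- drug_ids

  n_bits <- 128L
  fp <- matrix(runif(D * n_bits) < 0.3, D, n_bits,
               dimnames = list(drug_ids, NULL))
  motif <- runif(24L) < 0.7
  if (any(is_rev))
    fp[is_rev, 1:24] <- matrix(motif, sum(is_rev), 24L, byrow = TRUE)

  n_lines <- 8L
  line_ids <- sprintf("line%02d", seq_len(n_lines))
  p_sens <- ifelse(is_rev, .odds_to_prob(0.25, config$annot_enrichment), 0.25)
  sens_drug <- runif(D) < p_sens
  viab <- matrix(NA_real_, D, n_lines, dimnames = list(drug_ids, line_ids))
  viab[sens_drug, ] <- rnorm(sum(sens_drug) * n_lines, 0.05, 0.10)
  viab[!sens_drug, ] <- rnorm(sum(!sens_drug) * n_lines, 0.60, 0.15)
  viab[runif(D * n_lines) < 0.05] <- NA  # sparsely assayed pairs

  annotations <- drug_annotations(
    drugs = data.frame(drug_id = drug_ids, fda_approved = fda,
                       in_trial = in_trial, moa = moa,
                       stringsAsFactors = FALSE),
    targets = targets, fingerprints = fp, viability = viab,
    disease = "synthetic")
  truth$reverser_drugs <- reversers
  list(reference = perturbation_reference(z, cell_line = "SIMCL"),
       annotations = annotations, truth = truth)
}

#' Generate the complete synthetic benchmark
#'
#' Runs all three generators under the substreams of the master seed and
#' assembles the inputs of the full pipeline.
#'
#' @param config a [sim_config()].
#' @return A list with `study`, `loadings`, `reference`, `annotations` and
#'   `truth` (`de_genes`, `de_sign`, `active_lvs`, `reverser_drugs`).
#' @export
simulate_all <- function(config = sim_config()) {
  es <- simulate_expression_study(config)
  ll <- simulate_latent_loadings(config, es$truth)
  pr <- simulate_perturbation_reference(config, ll$truth, es$study)
  list(study = es$study, loadings = ll$loadings, reference = pr$reference,
       annotations = pr$annotations, truth = pr$truth)
}
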