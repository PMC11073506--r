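#' End-to-end signature-reversion pipeline on a synthetic benchmark
#'
#' Generates (or accepts) a synthetic study with planted ground truth, builds
#' the disease-associated gene signature by each requested route, runs
#' signature reversion against the perturbation reference, applies the
#' candidate filter, and evaluates the candidate sets against the
#' clinical-trial and viability annotations.
#'
#' @param config a [sim_config()]; ignored when `sim` is supplied.
#' @param sim optional pre-generated benchmark from [simulate_all()].
#' @param routes signature routes to run, a subset of
#'   `c("moderated_lm", "nb_glm", "transfer")`.
#' @param n_target signature size aimed for.
#' @param n_perm permutation/bank size of the reversion step.
#' @param n_perm_trial,n_perm_prism permutation draws of the enrichment
#'   benchmarks.
#' @param seed RNG seed of the analysis steps (reversion nulls, enrichment
#'   draws); the generator uses `config$seed`.
#' @return A list with the simulated inputs (`sim`), the differential
#'   results (`de`), and one entry per route carrying `signature`,
#'   `connectivity`, `candidates`, `trial` and `prism` verdicts.
#' @export
run_pipeline <- function(config = sim_config(), sim = NULL,
                         routes = c("moderated_lm", "nb_glm", "transfer"),
                         n_target = 100L, n_perm = 1000L,
                         n_perm_trial = 1000L, n_perm_prism = 10000L,
                         seed = 1L) {
  routes <- match.arg(routes, several.ok = TRUE)
  if (is.null(sim)) sim <- simulate_all(config)
  universe <- sim$reference$gene_ids
  logexpr <- tpm_log(sim$study)

  de <- list()
  if (any(c("moderated_lm") %in% routes))
    de$moderated_lm <- moderated_lm_de(logexpr, sim$study$condition,
                                       sim$study$database)
  if (any(c("nb_glm", "transfer") %in% routes))
    de$nb_glm <- nb_glm_de(sim$study)

  sigs <- list()
  if ("moderated_lm" %in% routes)
    sigs$moderated_lm <- build_de_signature(de$moderated_lm, universe,
                                            n_target = n_target)
  if ("nb_glm" %in% routes)
    sigs$nb_glm <- build_de_signature(de$nb_glm, universe,
                                      n_target = n_target)
  if ("transfer" %in% routes) {
    act <- suppressMessages(project_latent(
      logexpr, sim$loadings, condition = sim$study$condition,
      database = sim$study$database))
    ld <- differential_lv(act)
    sigs$transfer <- build_tl_signature(ld, sim$loadings, de$nb_glm,
                                        universe, n_target = n_target)
  }

  results <- list()
  for (route in names(sigs)) {
    sig <- sigs[[route]]
    entry <- list(signature = sig)
    if (length(c(sig$up, sig$down)) > 0) {
      ct <- run_reversion(sig, sim$reference, n_perm = n_perm, seed = seed)
      cand <- filter_candidates(ct, sim$annotations)
      entry$connectivity <- ct
      entry$candidates <- cand$drug
      if (length(cand$drug) > 0) {
        entry$trial <- trial_enrichment(cand$drug, sim$annotations,
                                        n_perm = n_perm_trial, seed = seed)
        entry$prism <- prism_enrichment(cand$drug, sim$annotations,
                                        n_perm = n_perm_prism, seed = seed)
      }
    }
    results[[route]] <- entry
  }
  list(sim = sim, de = de, routes = results)
}
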