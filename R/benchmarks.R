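# Orthogonal validation of candidate sets: viability-screen sensitivity
# calls, permutation enrichment against trial membership and screen
# sensitivity, hypergeometric drug-set enrichment over targets, and gene
# dependency summaries.

#' Viability-screen sensitivity calls
#'
#' A cell line is called sensitive to a drug when its median log2 viability
#' fold change is strictly below `threshold` (default 0.3).  Missing entries
#' are not evaluated and are excluded from the per-drug sensitive fraction.
#'
#' @param viability drug x cell-line numeric matrix (may contain `NA`).
#' @param threshold strict sensitivity cutoff.
#' @return List with `sensitive` (logical matrix with `NA` preserved) and
#'   `fraction` (per-drug fraction of evaluated lines that are sensitive).
#' @export
sensitivity_call <- function(viability, threshold = 0.3) {
  viability <- as.matrix(viability)
  if (length(viability) == 0) stop("empty viability table")
  sens <- viability < threshold
  frac <- rowMeans(sens, na.rm = TRUE)
  frac[rowSums(!is.na(sens)) == 0] <- NA_real_
  list(sensitive = sens, fraction = frac)
}

# per-drug call: strict majority of evaluated disease lines sensitive
.drug_sensitive <- function(viability, threshold = 0.3) {
  frac <- sensitivity_call(viability, threshold)$fraction
  frac > 0.5
}

.enrichment_verdict <- function(observed, null_fractions, indicator,
                                draws_indicator, n_perm) {
  p_emp <- .perm_p(observed, matrix(null_fractions, nrow = 1), tail = "upper")
  p_wil <- tryCatch(
    wilcox.test(indicator, draws_indicator, alternative = "greater",
                exact = FALSE)$p.value,
    error = function(e) NA_real_)
  structure(list(observed = observed, null_fractions = null_fractions,
                 p_empirical = p_emp, p_wilcoxon = p_wil,
                 n_perm = as.integer(n_perm)),
            class = "enrichment_verdict")
}

#' @export
print.enrichment_verdict <- function(x, ...) {
  cat(sprintf(
    "enrichment_verdict: observed %.3f vs null mean %.3f (%d perms); p_empirical = %.4g, p_wilcoxon = %.4g\n",
    x$observed, mean(x$null_fractions), x$n_perm, x$p_empirical, x$p_wilcoxon))
  invisible(x)
}

#' Clinical-trial enrichment of a candidate set
#'
#' Tests whether the candidate drugs are in clinical trials for the disease
#' more often than random same-size draws of FDA-approved drugs.  The
#' primary statistic is the empirical permutation p-value
#' `(1 + #{null fraction > observed} + V) / (n_perm + 1)`, where `V` breaks
#' ties with the null draws uniformly at random (so the p-value is exactly
#' uniform under the null and equals the plain one-sided permutation
#' p-value whenever there are no ties); a one-tailed
#' Wilcoxon rank-sum test of the per-drug trial indicators (candidates vs
#' the pooled random draws) is reported alongside for comparability.
#'
#' @param candidates character vector of candidate drug ids; must be
#'   FDA-approved drugs of the annotation table.
#' @param annotations a [drug_annotations()].
#' @param n_perm number of random draws (default 1000).
#' @param seed RNG seed.
#' @return An `enrichment_verdict`.
#' @export
trial_enrichment <- function(candidates, annotations, n_perm = 1000L,
                             seed = 1L) {
  stopifnot(inherits(annotations, "drug_annotations"))
  if (length(candidates) == 0) stop("empty candidate set")
  drugs <- annotations$drugs
  universe <- drugs$drug_id[drugs$fda_approved]
  if (!all(candidates %in% universe))
    stop("candidates must be FDA-approved drugs of the annotation table")
  set.seed(seed)
  in_trial <- setNames(drugs$in_trial, drugs$drug_id)
  obs_ind <- as.numeric(in_trial[candidates])
  k <- length(candidates)
  draws <- replicate(n_perm, sample(universe, k))
  null_frac <- colMeans(matrix(in_trial[draws], nrow = k))
  .enrichment_verdict(mean(obs_ind), null_frac, obs_ind,
                      as.numeric(in_trial[as.vector(draws)]), n_perm)
}

#' Viability-screen enrichment of a candidate set
#'
#' As [trial_enrichment()], with the per-drug success indicator replaced by
#' screen sensitivity: a drug counts as sensitive for the disease when a
#' strict majority of its evaluated disease cell lines are sensitive
#' (median log2 viability fold change < `threshold`).  Defaults to 10000
#' random draws.
#'
#' @param candidates character vector of candidate drug ids.
#' @param annotations a [drug_annotations()] carrying the viability table.
#' @param n_perm number of random draws (default 10000).
#' @param seed RNG seed.
#' @param threshold strict per-line sensitivity cutoff.
#' @return An `enrichment_verdict`.
#' @export
prism_enrichment <- function(candidates, annotations, n_perm = 10000L,
                             seed = 1L, threshold = 0.3) {
  stopifnot(inherits(annotations, "drug_annotations"))
  if (length(candidates) == 0) stop("empty candidate set")
  if (is.null(annotations$viability)) stop("annotations carry no viability table")
  drugs <- annotations$drugs
  universe <- drugs$drug_id[drugs$fda_approved]
  universe <- intersect(universe, rownames(annotations$viability))
  if (!all(candidates %in% universe))
    stop("candidates must be FDA-approved drugs with viability data")
  set.seed(seed)
  sens <- .drug_sensitive(annotations$viability, threshold)
  obs_ind <- as.numeric(sens[candidates])
  k <- length(candidates)
  draws <- replicate(n_perm, sample(universe, k))
  null_frac <- colMeans(matrix(sens[draws], nrow = k), na.rm = TRUE)
  .enrichment_verdict(mean(obs_ind, na.rm = TRUE), null_frac, obs_ind,
                      as.numeric(sens[as.vector(draws)]), n_perm)
}

#' Hypergeometric drug-set enrichment over targets
#'
#' For every target gene annotated in the FDA-approved drug universe, tests
#' whether the drugs hitting that target are over-represented among the
#' candidates (upper-tail hypergeometric), with Benjamini-Hochberg
#' adjustment across targets.
#'
#' @param candidates character vector of candidate drug ids.
#' @param annotations a [drug_annotations()] with a `targets` list.
#' @return data.frame with columns `target`, `n_universe`, `n_target_set`,
#'   `n_candidates`, `overlap`, `p`, `p_adj`.
#' @export
target_dsea <- function(candidates, annotations) {
  stopifnot(inherits(annotations, "drug_annotations"))
  drugs <- annotations$drugs
  universe <- drugs$drug_id[drugs$fda_approved]
  candidates <- intersect(candidates, universe)
  targets <- annotations$targets[names(annotations$targets) %in% universe]
  if (length(targets) == 0) stop("no target annotations available")
  all_targets <- sort(unique(unlist(targets)))
  N <- length(universe); n <- length(candidates)
  rows <- lapply(all_targets, function(tg) {
    hit <- names(targets)[vapply(targets, function(x) tg %in% x, logical(1))]
    K <- length(hit)
    k <- length(intersect(hit, candidates))
    p <- if (k == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(target = tg, n_universe = N, n_target_set = K,
               n_candidates = n, overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, "BH")
  out
}

#' Mean gene-effect (dependency) scores
#'
#' Averages CRISPR gene-effect scores over a set of cell lines for a set of
#' genes, ignoring missing entries.  Strongly negative means indicate genes
#' whose knockout costs fitness in those lines (near -1 for core-essential
#' genes).
#'
#' @param effect_matrix cell-line x gene numeric matrix of gene-effect
#'   scores.
#' @param lines cell-line ids to average over (default: all rows); missing
#'   ids are dropped with a warning.
#' @param genes gene ids to report (default: all columns); missing ids are
#'   dropped with a warning.
#' @return Named numeric vector of per-gene means.
#' @export
gene_effect_summary <- function(effect_matrix, lines = NULL, genes = NULL) {
  effect_matrix <- as.matrix(effect_matrix)
  lines <- lines %||% rownames(effect_matrix)
  genes <- genes %||% colnames(effect_matrix)
  miss_l <- setdiff(lines, rownames(effect_matrix))
  miss_g <- setdiff(genes, colnames(effect_matrix))
  if (length(miss_l) > 0)
    warning("cell line(s) not in matrix: ", paste(miss_l, collapse = ", "))
  if (length(miss_g) > 0)
    warning("gene(s) not in matrix: ", paste(miss_g, collapse = ", "))
  lines <- intersect(lines, rownames(effect_matrix))
  genes <- intersect(genes, colnames(effect_matrix))
  if (length(lines) == 0 || length(genes) == 0)
    stop("no overlap between requested lines/genes and the matrix")
  colMeans(effect_matrix[lines, genes, drop = FALSE], na.rm = TRUE)
}
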