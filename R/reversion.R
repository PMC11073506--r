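# Core scoring engine of signature reversion: bi-directional weighted
# Kolmogorov-Smirnov enrichment, NCS normalization, Tau percentiles against
# a bank of matched-size null queries, and a permutation FDR.

# running-sum extremum evaluated only at hit boundaries; equivalent to (and
# tested against) the full G-step running sum
.es_core <- function(rank_pos, w_abs, G) {
  m <- length(rank_pos)
  o <- order(rank_pos)
  r <- rank_pos[o]
  w <- w_abs[o]
  sw <- sum(w)
  phit <- if (sw > 0) cumsum(w) / sw else seq_len(m) / m
  miss <- 1 / (G - m)
  i <- seq_len(m)
  after <- phit - (r - i) * miss          # running sum just after each hit
  before <- c(0, phit[-m]) - (r - i) * miss  # just before each hit
  # candidates in path order (before_i precedes after_i); on exact ties of
  # absolute value the extremum reached earliest in the ranking wins
  cand <- as.vector(rbind(before, after))
  unname(cand[which.max(abs(cand))])
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' GSEA-style running-sum statistic of a gene set against a ranked z-score
#' profile: genes are ranked by decreasing z (ties broken by gene id); a hit
#' at rank i increments the running sum by `|z_i| / sum(|z| over the set)`
#' and a miss decrements it by `1 / (G - set size)`.  The enrichment score
#' is the signed extremum of largest absolute value; on exact ties of the
#' absolute extremum the value reached earliest in the ranking is returned.
#'
#' @param profile named numeric vector of per-gene z-scores.
#' @param gene_set character vector of gene ids; must be a non-empty proper
#'   subset of the profile genes.
#' @return Enrichment score in `[-1, 1]`.
#' @export
weighted_es <- function(profile, gene_set) {
  if (is.null(names(profile))) stop("'profile' must be named by gene id")
  gene_set <- unique(as.character(gene_set))
  if (length(gene_set) == 0) stop("empty gene set")
  if (!all(gene_set %in% names(profile)))
    stop("gene set not contained in profile genes")
  G <- length(profile)
  if (length(gene_set) >= G) stop("gene set must be a proper subset of the profile")
  ord <- order(-profile, names(profile))
  rank_pos <- match(gene_set, names(profile)[ord])
  .es_core(rank_pos, abs(profile[gene_set]), G)
}

#' Bi-directional weighted connectivity score
#'
#' Combines the enrichment scores of the up and the down query set against a
#' perturbation profile: `(es_up - es_down) / 2` when the two scores have
#' opposite signs (or either is zero), and 0 otherwise.  Strongly negative
#' values mean the perturbation reverses the query signature.
#'
#' @param es_up,es_down enrichment scores in `[-1, 1]`.
#' @return WTCS in `[-1, 1]`.
#' @export
wtcs_score <- function(es_up, es_down) {
  stopifnot(abs(es_up) <= 1, abs(es_down) <= 1)
  if (es_up == 0 || es_down == 0 || sign(es_up) != sign(es_down))
    (es_up - es_down) / 2
  else 0
}

#' Normalized connectivity scores
#'
#' Normalizes raw connectivity scores within a cell-line group by the signed
#' mean of the same-sign scores: positive scores are divided by the mean of
#' the positive scores in the group, negative scores by the absolute mean of
#' the negative scores; zeros stay zero.
#'
#' @param wtcs numeric vector of connectivity scores (one cell-line group).
#' @return Numeric vector of normalized connectivity scores.
#' @export
normalize_ncs <- function(wtcs) {
  if (length(wtcs) == 0) stop("empty score group")
  out <- wtcs
  pos <- wtcs > 0; neg <- wtcs < 0
  if (any(pos)) out[pos] <- wtcs[pos] / mean(wtcs[pos])
  if (any(neg)) out[neg] <- wtcs[neg] / abs(mean(wtcs[neg]))
  out
}

#' Tau: signed percentile against a reference bank
#'
#' For each drug, Tau is the signed percentage of reference-bank null
#' normalized connectivity scores whose magnitude falls below the observed
#' one: `tau(d) = sign(ncs_q(d)) * 100/N * #{r : |NCS_null(d, r)| <
#' |ncs_q(d)|}`.  A Tau of -100 means the observed negative connectivity is
#' more extreme than every bank score for that drug.
#'
#' @param ncs_q named numeric vector of observed normalized connectivity
#'   scores per drug.
#' @param null_ncs drug x bank-query matrix of null normalized connectivity
#'   scores, rows named by drug.
#' @return Named numeric vector of Tau values in `[-100, 100]`.
#' @export
compute_tau <- function(ncs_q, null_ncs) {
  if (is.null(dim(null_ncs)) || ncol(null_ncs) == 0) stop("empty reference bank")
  if (!all(names(ncs_q) %in% rownames(null_ncs)))
    stop("reference bank lacks null scores for some drugs")
  null_ncs <- null_ncs[names(ncs_q), , drop = FALSE]
  n <- ncol(null_ncs)
  cnt <- rowSums(abs(null_ncs) < abs(ncs_q))
  setNames(sign(ncs_q) * 100 * cnt / n, names(ncs_q))
}

# Permutation p-value of each observed statistic against its row of null
# draws, one-sided.  The observed rank is tie-broken uniformly at random
# (seeded upstream), which makes the p-value exactly uniform under the
# null; without ties this reduces to (1 + #{null beyond obs}) / (N + 1).
.perm_p <- function(obs, nulls, tail = c("lower", "upper")) {
  tail <- match.arg(tail)
  nulls <- matrix(nulls, nrow = length(obs))
  n <- ncol(nulls)
  beyond <- if (tail == "lower") rowSums(nulls < obs) else rowSums(nulls > obs)
  ties <- rowSums(nulls == obs)
  v <- vapply(ties, function(k) sample.int(k + 1L, 1L) - 1L, integer(1))
  (1 + beyond + v) / (n + 1)
}

# draw matched-size disjoint up/down null gene sets from the universe
.null_signatures <- function(gene_ids, n_up, n_down, n) {
  lapply(seq_len(n), function(i) {
    g <- sample(gene_ids, n_up + n_down)
    list(up = g[seq_len(n_up)],
         down = if (n_down > 0) g[n_up + seq_len(n_down)] else character(0))
  })
}

# per-drug ranking tables reused across many queries
.rank_reference <- function(ref) {
  z <- ref$z
  G <- ncol(z)
  gene_ids <- colnames(z)
  ranks <- matrix(0L, nrow(z), G, dimnames = dimnames(z))
  for (d in seq_len(nrow(z))) {
    ord <- order(-z[d, ], gene_ids)
    ranks[d, ord] <- seq_len(G)
  }
  list(ranks = ranks, absz = abs(z), G = G)
}

# WTCS of a batch of query signatures (lists of up/down gene-id vectors)
# against every drug of a pre-ranked reference; compiled kernel
.wtcs_batch <- function(rr, ups, downs) {
  gene_ids <- colnames(rr$ranks)
  .wtcs_batch_cpp(rr$ranks, rr$absz,
                  lapply(ups, match, gene_ids),
                  lapply(downs, match, gene_ids))
}

#' Signature reversion against a perturbation reference
#'
#' Scores every drug of the reference against the query signature with the
#' bi-directional weighted Kolmogorov-Smirnov statistic, normalizes within
#' the cell line (NCS), computes Tau against a bank of `n_null` random
#' matched-size query signatures, and attaches one-sided (reversal-tail)
#' permutation p-values with Benjamini-Hochberg FDR from `n_perm` null
#' queries.  The same null-query bank serves the Tau reference and the
#' permutation null when `n_null == n_perm` (the default), halving the
#' dominant cost.
#'
#' @param sig a [gene_signature()] query.
#' @param ref a [perturbation_reference()].
#' @param n_perm number of permutation null queries (>= 100).
#' @param n_null size of the Tau reference bank (default `n_perm`).
#' @param seed RNG seed; the result is deterministic given the seed.
#' @return A `connectivity_table` data.frame with one row per drug and
#'   columns `drug`, `es_up`, `es_down`, `wtcs`, `ncs`, `tau`, `p`, `fdr`.
#' @export
run_reversion <- function(sig, ref, n_perm = 1000L, n_null = n_perm,
                          seed = 1L) {
  stopifnot(inherits(sig, "gene_signature"),
            inherits(ref, "perturbation_reference"))
  if (n_perm < 100L) stop("'n_perm' must be at least 100")
  if (n_null < 100L) stop("'n_null' must be at least 100")
  set.seed(seed)
  genes <- ref$gene_ids
  q_genes <- c(sig$up, sig$down)
  if (length(q_genes) == 0) stop("empty query signature")
  frac <- mean(q_genes %in% genes)
  if (frac == 0) stop("no query gene present in the reference")
  if (frac < 0.5)
    warning(sprintf("only %.0f%% of query genes present in the reference",
                    100 * frac))
  up <- intersect(sig$up, genes)
  down <- intersect(sig$down, genes)

  rr <- .rank_reference(ref)
  D <- nrow(rr$ranks)
  es_up <- es_down <- numeric(D)
  for (d in seq_len(D)) {
    es_up[d] <- if (length(up) > 0)
      .es_core(rr$ranks[d, up], rr$absz[d, up], rr$G) else 0
    es_down[d] <- if (length(down) > 0)
      .es_core(rr$ranks[d, down], rr$absz[d, down], rr$G) else 0
  }
  wtcs <- mapply(wtcs_score, es_up, es_down)
  ncs <- normalize_ncs(wtcs)

  n_bank <- max(n_perm, n_null)
  nulls <- .null_signatures(genes, length(up), length(down), n_bank)
  null_wtcs <- .wtcs_batch(rr, lapply(nulls, `[[`, "up"),
                           lapply(nulls, `[[`, "down"))
  null_ncs <- apply(null_wtcs[, seq_len(n_null), drop = FALSE], 2,
                    normalize_ncs)
  null_ncs <- matrix(null_ncs, nrow = D)
  rownames(null_wtcs) <- rownames(null_ncs) <- ref$drug_ids

  tau <- compute_tau(setNames(ncs, ref$drug_ids), null_ncs)
  p <- .perm_p(wtcs, null_wtcs[, seq_len(n_perm), drop = FALSE],
               tail = "lower")
  out <- data.frame(drug = ref$drug_ids, es_up = es_up, es_down = es_down,
                    wtcs = unname(wtcs), ncs = unname(ncs),
                    tau = unname(tau), p = unname(p),
                    fdr = p.adjust(p, "BH"), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, cell_line = ref$cell_line, n_perm = as.integer(n_perm),
            n_null = as.integer(n_null), method = sig$method,
            class = c("connectivity_table", "data.frame"))
}

#' Filter drug repurposing candidates
#'
#' Applies the candidate rule: negative normalized connectivity score,
#' permutation FDR below `fdr_cut`, Tau below `tau_cut` (all strict), and
#' optionally FDA approval; candidates are returned ordered by increasing
#' (most negative first) NCS.
#'
#' @param ct a `connectivity_table` from [run_reversion()].
#' @param annotations a [drug_annotations()] (required when
#'   `fda_only = TRUE`).
#' @param tau_cut,fdr_cut strict thresholds (defaults -80 and 0.05).
#' @param fda_only restrict to FDA-approved drugs (default `TRUE`).
#' @return The filtered `connectivity_table` rows, most negative NCS first.
#' @export
filter_candidates <- function(ct, annotations = NULL, tau_cut = -80,
                              fdr_cut = 0.05, fda_only = TRUE) {
  stopifnot(inherits(ct, "connectivity_table"))
  keep <- ct$ncs < 0 & ct$fdr < fdr_cut & ct$tau < tau_cut
  if (fda_only) {
    if (is.null(annotations))
      stop("'annotations' required when fda_only = TRUE")
    approved <- annotations$drugs$drug_id[annotations$drugs$fda_approved]
    keep <- keep & ct$drug %in% approved
  }
  out <- ct[keep, , drop = FALSE]
  out[order(out$ncs), , drop = FALSE]
}
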