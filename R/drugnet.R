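# Drug-drug similarity networks (perturbation cosine, structure Tanimoto),
# top-edge graph construction, Leiden communities, and PPI centrality
# comparison of signature gene sets.

#' Cosine similarity matrix of perturbation profiles
#'
#' @param profiles drug x gene numeric matrix; rows of all zeros have
#'   undefined similarity and are flagged with `NA` and a warning.
#' @return Symmetric drug x drug matrix with unit diagonal (class attribute
#'   `metric = "cosine"`).
#' @export
cosine_matrix <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2) stop("need at least 2 drugs")
  nrm <- sqrt(rowSums(profiles^2))
  zero <- nrm == 0
  if (any(zero)) {
    warning("all-zero profile row(s): ",
            paste(rownames(profiles)[zero], collapse = ", "))
    nrm[zero] <- 1
  }
  s <- tcrossprod(profiles / nrm)
  s[zero, ] <- NA_real_; s[, zero] <- NA_real_
  s <- (s + t(s)) / 2  # enforce exact symmetry against rounding
  diag(s)[!zero] <- 1
  attr(s, "metric") <- "cosine"
  s
}

#' Tanimoto similarity matrix of fingerprint bit vectors
#'
#' `T(a, b) = |a AND b| / |a OR b|` over equal-length bit vectors.
#'
#' @param fingerprints drug x bit logical (or 0/1) matrix; all-zero
#'   fingerprints are flagged with `NA` and a warning.
#' @return Symmetric drug x drug matrix in `[0, 1]` (attribute
#'   `metric = "tanimoto"`).
#' @export
tanimoto_matrix <- function(fingerprints) {
  fp <- as.matrix(fingerprints) != 0
  if (nrow(fp) < 2) stop("need at least 2 drugs")
  storage.mode(fp) <- "numeric"
  inter <- tcrossprod(fp)
  n_bits <- rowSums(fp)
  union <- outer(n_bits, n_bits, "+") - inter
  zero <- n_bits == 0
  if (any(zero))
    warning("all-zero fingerprint(s): ",
            paste(rownames(fp)[zero], collapse = ", "))
  s <- inter / union
  s[union == 0] <- NA_real_
  s <- (s + t(s)) / 2
  diag(s)[!zero] <- 1
  attr(s, "metric") <- "tanimoto"
  s
}

#' Top-fraction drug-drug similarity network
#'
#' Retains the `ceiling(keep_fraction * n_pairs)` largest off-diagonal
#' similarity pairs (ties at the cut are all retained) as a weighted
#' undirected graph; nodes left without edges are kept as isolated
#' vertices.
#'
#' @param sim symmetric similarity matrix (from [cosine_matrix()] or
#'   [tanimoto_matrix()]).
#' @param keep_fraction fraction of unordered pairs to keep (default 0.10).
#' @param labels optional per-node labels (e.g. the signature route that
#'   identified each drug), stored as the vertex attribute `label_group`.
#' @return An `igraph` graph with edge attribute `weight`.
#' @export
top_edge_network <- function(sim, keep_fraction = 0.10, labels = NULL) {
  sim <- as.matrix(sim)
  n <- nrow(sim)
  if (n < 2) stop("need at least 2 nodes")
  ids <- rownames(sim) %||% as.character(seq_len(n))
  iu <- which(upper.tri(sim), arr.ind = TRUE)
  w <- sim[iu]
  ok <- !is.na(w)
  iu <- iu[ok, , drop = FALSE]; w <- w[ok]
  n_pairs <- length(w)
  k <- min(n_pairs, ceiling(keep_fraction * n_pairs))
  cut <- sort(w, decreasing = TRUE)[k]
  keep <- w >= cut  # ties at the cut all retained
  edges <- data.frame(from = ids[iu[keep, 1L]], to = ids[iu[keep, 2L]],
                      weight = w[keep], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  if (!is.null(labels))
    igraph::V(g)$label_group <- labels[match(igraph::V(g)$name, ids)]
  g
}

#' Leiden communities of a drug network
#'
#' Seeded Leiden partition maximizing modularity at the given resolution.
#' Community ids are contiguous integers starting at 0.
#'
#' @param net an `igraph` graph (weighted edges used if present).
#' @param resolution resolution parameter (default 1).
#' @param seed RNG seed; the partition is deterministic given the seed.
#' @return Named integer vector mapping node id to community id.
#' @export
detect_communities <- function(net, resolution = 1.0, seed = 1L) {
  stopifnot(igraph::is_igraph(net))
  if (igraph::vcount(net) == 0) stop("empty graph")
  set.seed(seed)
  cl <- igraph::cluster_leiden(net, objective_function = "modularity",
                               resolution = resolution, n_iterations = 10)
  memb <- igraph::membership(cl)
  ids <- sort(unique(memb))
  out <- match(memb, ids) - 1L
  setNames(as.integer(out), igraph::V(net)$name)
}

#' PPI network centrality
#'
#' Filters a scored protein-protein interaction edge list (raw scores on
#' the 0-1000 scale) at confidence `score/1000 > score_cut` (strict) and
#' computes degree, unnormalized Brandes betweenness, and eigenvector
#' centrality.  Eigenvector centrality is computed per connected component
#' (principal eigenvector of the component adjacency, scaled to maximum 1).
#'
#' @param edges data.frame with columns `protein_a`, `protein_b`,
#'   `combined_score` (0-1000).
#' @param score_cut strict confidence threshold on `score/1000`
#'   (default 0.7).
#' @return data.frame with columns `node`, `degree`, `betweenness`,
#'   `eigenvector`.
#' @export
ppi_centrality <- function(edges, score_cut = 0.7) {
  stopifnot(all(c("protein_a", "protein_b", "combined_score") %in% names(edges)))
  if (any(edges$combined_score < 0 | edges$combined_score > 1000))
    stop("'combined_score' must be on the raw 0-1000 scale")
  keep <- edges$combined_score / 1000 > score_cut
  edges <- edges[keep, c("protein_a", "protein_b"), drop = FALSE]
  if (nrow(edges) == 0) stop("no edge passes the confidence filter")
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  g <- igraph::simplify(g)
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, weights = NA, normalized = FALSE)
  ev <- rep(NA_real_, igraph::vcount(g))
  names(ev) <- igraph::V(g)$name
  comp <- igraph::components(g)
  for (ci in seq_len(comp$no)) {
    vs <- names(comp$membership)[comp$membership == ci]
    sub <- igraph::induced_subgraph(g, vs)
    if (length(vs) == 1L) {
      ev[vs] <- 1
    } else {
      ev[igraph::V(sub)$name] <-
        igraph::eigen_centrality(sub, weights = NA)$vector
    }
  }
  data.frame(node = names(deg), degree = as.integer(deg),
             betweenness = unname(btw), eigenvector = unname(ev[names(deg)]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Omnibus and pairwise comparison of centrality distributions
#'
#' Kruskal-Wallis test across the (disjoint) groups of centrality values;
#' when the omnibus test is significant at `alpha`, all pairwise two-tailed
#' Wilcoxon rank-sum tests are run with Benjamini-Hochberg adjustment
#' (Bonferroni-adjusted p-values are reported alongside).
#'
#' @param groups named list of numeric vectors (>= 2 groups, each with
#'   >= 2 values).
#' @param alpha omnibus significance level gating the pairwise tests.
#' @return List with `kw_stat`, `kw_p`, and `pairwise` (data.frame with
#'   columns `group1`, `group2`, `p`, `p_bh`, `p_bonferroni`, or `NULL`
#'   when the omnibus test is not significant).
#' @export
centrality_group_test <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("every group needs at least 2 values")
  values <- unlist(groups, use.names = FALSE)
  f <- factor(rep(names(groups), vapply(groups, length, integer(1))))
  kw <- kruskal.test(values, f)
  pairwise <- NULL
  if (kw$p.value < alpha) {
    cmb <- utils::combn(names(groups), 2)
    p <- apply(cmb, 2, function(pair)
      wilcox.test(groups[[pair[1]]], groups[[pair[2]]], exact = FALSE)$p.value)
    pairwise <- data.frame(group1 = cmb[1, ], group2 = cmb[2, ], p = p,
                           p_bh = p.adjust(p, "BH"),
                           p_bonferroni = p.adjust(p, "bonferroni"),
                           stringsAsFactors = FALSE)
  }
  list(kw_stat = unname(kw$statistic), kw_p = kw$p.value, pairwise = pairwise)
}
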