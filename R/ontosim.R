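# Functional enrichment (hypergeometric) and Wang-method semantic
# similarity over a small DAG ontology, with similarity-based term
# grouping.

#' Construct an ontology
#'
#' A directed acyclic graph of terms with typed child-to-parent edges
#' (`is_a`, `part_of`) and optional per-term gene annotations.
#'
#' @param edges data.frame with columns `term`, `parent`, `relation`
#'   (values `is_a` or `part_of`); may have zero rows for a forest of
#'   roots.
#' @param annotations named list mapping term id to a character vector of
#'   annotated genes.
#' @param terms optional character vector of all term ids (defaults to the
#'   ids appearing in `edges` and `annotations`).
#' @return An object of class `ontology`.
#' @export
ontology <- function(edges, annotations = list(), terms = NULL) {
  stopifnot(is.data.frame(edges))
  if (nrow(edges) > 0) {
    stopifnot(all(c("term", "parent", "relation") %in% names(edges)))
    if (!all(edges$relation %in% c("is_a", "part_of")))
      stop("edge relations must be 'is_a' or 'part_of'")
  }
  terms <- unique(c(terms, edges$term, edges$parent, names(annotations)))
  # cycle check by repeated leaf stripping (Kahn)
  remaining <- terms
  ed <- edges
  repeat {
    leaves <- setdiff(remaining, ed$parent)
    if (length(leaves) == 0) break
    remaining <- setdiff(remaining, leaves)
    ed <- ed[!ed$term %in% leaves, , drop = FALSE]
  }
  if (length(remaining) > 0)
    stop("ontology contains a cycle involving: ",
         paste(remaining, collapse = ", "))
  structure(list(edges = edges, annotations = annotations, terms = terms),
            class = "ontology")
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf("ontology: %d terms, %d edges, %d annotated terms\n",
              length(x$terms), nrow(x$edges), length(x$annotations)))
  invisible(x)
}

#' Hypergeometric enrichment of a gene set
#'
#' Upper-tail hypergeometric test of the overlap between the query set and
#' every term's annotated genes within the universe, Benjamini-Hochberg
#' adjusted across terms.
#'
#' @param query character vector of gene ids; must be contained in
#'   `universe`.
#' @param collection named list mapping term id to annotated gene set (an
#'   [ontology()]'s `annotations` or any GMT-style collection).
#' @param universe background gene ids.
#' @param direction optional label (`"up"`/`"down"`) carried into the
#'   result.
#' @return data.frame with columns `term`, `overlap`, `term_size`,
#'   `query_size`, `universe_size`, `p`, `p_adj` (and `direction` when
#'   given).
#' @export
hypergeom_enrich <- function(query, collection, universe, direction = NULL) {
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  if (!all(query %in% universe)) stop("query must be a subset of the universe")
  if (length(collection) == 0) stop("empty term collection")
  N <- length(universe); n <- length(query)
  rows <- lapply(names(collection), function(tm) {
    set <- intersect(collection[[tm]], universe)
    K <- length(set)
    k <- length(intersect(query, set))
    p <- if (k == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, overlap = k, term_size = K, query_size = n,
               universe_size = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, "BH")
  if (!is.null(direction)) out$direction <- direction
  out
}

#' Up/down gene sets from a perturbation profile
#'
#' Splits a modified z-score profile at the strict cutoffs `z > z_cut`
#' (up) and `z < -z_cut` (down).
#'
#' @param profile named numeric vector of per-gene z-scores (finite).
#' @param z_cut strict threshold (default 2).
#' @return List with character vectors `up` and `down`; both may be empty,
#'   in which case a message notes that downstream enrichment would be
#'   skipped.
#' @export
profile_gene_sets <- function(profile, z_cut = 2) {
  if (!all(is.finite(profile))) stop("profile must be finite")
  if (is.null(names(profile))) stop("profile must be named by gene id")
  up <- names(profile)[profile > z_cut]
  down <- names(profile)[profile < -z_cut]
  if (length(up) == 0 && length(down) == 0)
    message("no gene passes |z| > ", z_cut, "; enrichment would be skipped")
  list(up = up, down = down)
}

# S-values of every ancestor (including the term itself) by upward
# relaxation of w_edge * S(child); the DAG guarantees termination
.wang_svalues <- function(term, onto, w) {
  S <- setNames(1, term)
  queue <- term
  ed <- onto$edges
  while (length(queue) > 0) {
    t0 <- queue[[1L]]; queue <- queue[-1L]
    pe <- ed[ed$term == t0, , drop = FALSE]
    for (i in seq_len(nrow(pe))) {
      p <- pe$parent[i]
      val <- unname(w[pe$relation[i]] * S[t0])
      if (is.na(S[p]) || val > S[p]) {
        S[p] <- val
        queue <- c(queue, p)
      }
    }
  }
  S
}

#' Wang semantic similarity between two ontology terms
#'
#' Each term's ancestors (itself included) receive S-values propagated from
#' the term with per-edge contribution factors (`is_a` 0.8, `part_of` 0.6
#' by default): `S_A(A) = 1` and `S_A(t) = max over child edges c -> t of
#' w_edge * S_A(c)`.  The similarity is the S-value mass of the shared
#' ancestors relative to the total,
#' `sum over shared t of (S_A(t) + S_B(t)) / (SV(A) + SV(B))`.
#'
#' @param a,b term ids.
#' @param onto an [ontology()].
#' @param w_is_a,w_part_of edge contribution factors.
#' @return Similarity in `[0, 1]`; 0 when the terms share no ancestor.
#' @export
wang_similarity <- function(a, b, onto, w_is_a = 0.8, w_part_of = 0.6) {
  stopifnot(inherits(onto, "ontology"))
  if (!a %in% onto$terms) stop("unknown term: ", a)
  if (!b %in% onto$terms) stop("unknown term: ", b)
  w <- c(is_a = w_is_a, part_of = w_part_of)
  SA <- .wang_svalues(a, onto, w)
  SB <- .wang_svalues(b, onto, w)
  shared <- intersect(names(SA), names(SB))
  if (length(shared) == 0) return(0)
  unname(sum(SA[shared] + SB[shared]) / (sum(SA) + sum(SB)))
}

#' Pairwise Wang similarity matrix
#'
#' @param terms character vector of term ids.
#' @param onto an [ontology()].
#' @param w_is_a,w_part_of edge contribution factors.
#' @return Symmetric term x term similarity matrix.
#' @export
wang_similarity_matrix <- function(terms, onto, w_is_a = 0.8,
                                   w_part_of = 0.6) {
  n <- length(terms)
  s <- matrix(1, n, n, dimnames = list(terms, terms))
  if (n > 1)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      s[i, j] <- s[j, i] <-
        wang_similarity(terms[i], terms[j], onto, w_is_a, w_part_of)
    }
  s
}

#' Group terms by semantic similarity
#'
#' Hierarchical clustering (Ward linkage on `1 - similarity`) cut at
#' distance `1 - threshold`; each group is represented by its
#' largest-annotation term, ties broken lexicographically.
#'
#' @param sim symmetric term x term similarity matrix.
#' @param threshold similarity threshold defining the cut (default 0.7).
#' @param term_sizes named numeric vector of annotation sizes used to pick
#'   representatives (missing terms count as 0).
#' @return data.frame with columns `term`, `group` (contiguous from 1) and
#'   `representative`.
#' @export
group_terms <- function(sim, threshold = 0.7, term_sizes = NULL) {
  sim <- as.matrix(sim)
  if (!isTRUE(all.equal(sim, t(sim)))) stop("similarity matrix must be symmetric")
  terms <- rownames(sim) %||% as.character(seq_len(nrow(sim)))
  if (nrow(sim) == 1) {
    grp <- setNames(1L, terms)
  } else {
    hc <- hclust(as.dist(1 - sim), method = "ward.D2")
    grp <- cutree(hc, h = 1 - threshold)
    names(grp) <- terms
  }
  sizes <- setNames(rep(0, length(terms)), terms)
  if (!is.null(term_sizes))
    sizes[intersect(names(term_sizes), terms)] <-
      term_sizes[intersect(names(term_sizes), terms)]
  rep_of <- vapply(split(terms, grp), function(tt) {
    tt[order(-sizes[tt], tt)][1L]
  }, character(1))
  data.frame(term = terms, group = as.integer(grp),
             representative = unname(rep_of[as.character(grp)]),
             stringsAsFactors = FALSE)
}
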