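# Shared fixtures, generated once per test run and cached.  Sizes are kept
# small; the full-size study conditions are exercised in the acceptance
# tests.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fixture_env))
    assign(name, make(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# small planted-signal benchmark shared by most module tests
small_config <- function(seed = 42L, ...) {
  defaults <- list(n_genes = 500L, n_tumor = 12L, n_control = 12L,
                   n_drugs = 40L, n_reversers = 5L, n_lvs = 40L,
                   lv_sparsity = 0.025, n_active_lvs = 3L, frac_de = 0.08,
                   seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

small_sim <- function() fixture("small_sim", function() {
  suppressMessages(simulate_all(small_config()))
})

small_logexpr <- function() fixture("small_logexpr", function() {
  tpm_log(small_sim()$study)
})

small_nb_de <- function() fixture("small_nb_de", function() {
  suppressMessages(nb_glm_de(small_sim()$study))
})

small_lm_de <- function() fixture("small_lm_de", function() {
  s <- small_sim()
  moderated_lm_de(small_logexpr(), s$study$condition, s$study$database)
})

# independent brute-force oracle: full G-step running sum of the weighted
# KS statistic, evaluated position by position
es_bruteforce <- function(profile, gene_set) {
  ord <- order(-profile, names(profile))
  genes <- names(profile)[ord]
  z <- profile[ord]
  hit <- genes %in% gene_set
  G <- length(genes)
  m <- sum(hit)
  sw <- sum(abs(z)[hit])
  rs <- numeric(G)
  run <- 0
  for (i in seq_len(G)) {
    run <- run + if (hit[i]) abs(z[i]) / sw else -1 / (G - m)
    rs[i] <- run
  }
  rs[which.max(abs(rs))]
}

# independent oracle: betweenness by exhaustive path enumeration
betweenness_bruteforce <- function(g) {
  vs <- igraph::V(g)$name
  n <- length(vs)
  adj <- lapply(vs, function(v)
    names(igraph::neighbors(g, v)))
  names(adj) <- vs
  all_paths <- function(s, t) {
    out <- list()
    walk <- function(path) {
      last <- path[length(path)]
      if (last == t) { out[[length(out) + 1L]] <<- path; return() }
      for (nb in adj[[last]])
        if (!nb %in% path) walk(c(path, nb))
    }
    walk(s)
    out
  }
  btw <- setNames(numeric(n), vs)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    paths <- all_paths(vs[i], vs[j])
    if (length(paths) == 0) next
    lens <- vapply(paths, length, integer(1))
    sp <- paths[lens == min(lens)]
    for (v in vs) {
      if (v %in% c(vs[i], vs[j])) next
      through <- sum(vapply(sp, function(p) v %in% p, logical(1)))
      btw[v] <- btw[v] + through / length(sp)
    }
  }
  btw
}

# all set partitions of n elements (restricted-growth enumeration)
all_partitions <- function(n) {
  res <- list()
  rec <- function(labels, mx) {
    if (length(labels) == n) {
      res[[length(res) + 1L]] <<- labels
      return()
    }
    for (k in seq_len(mx + 1L)) rec(c(labels, k), max(mx, k))
  }
  rec(integer(0), 0L)
  res
}

# independent oracle: Wang S-values by explicit enumeration of all
# directed paths from the term to each ancestor
wang_bruteforce <- function(a, b, onto, w = c(is_a = 0.8, part_of = 0.6)) {
  ed <- onto$edges
  paths_up <- function(term) {
    # list of (ancestor, weight product) over all upward paths
    out <- list(c(term = term, wprod = 1))
    pe <- ed[ed$term == term, , drop = FALSE]
    for (i in seq_len(nrow(pe))) {
      sub <- paths_up(pe$parent[i])
      for (s in sub)
        out[[length(out) + 1L]] <- c(term = unname(s["term"]),
                                     wprod = w[[pe$relation[i]]] *
                                       as.numeric(s["wprod"]))
    }
    out
  }
  svals <- function(term) {
    ps <- paths_up(term)
    anc <- unique(vapply(ps, function(x) unname(x["term"]), character(1)))
    vapply(anc, function(t0) {
      max(vapply(ps[vapply(ps, function(x) x["term"] == t0, logical(1))],
                 function(x) as.numeric(x["wprod"]), numeric(1)))
    }, numeric(1))
  }
  SA <- svals(a); SB <- svals(b)
  shared <- intersect(names(SA), names(SB))
  if (length(shared) == 0) return(0)
  sum(SA[shared] + SB[shared]) / (sum(SA) + sum(SB))
}

# random small DAG ontology for property tests
random_ontology <- function(n_terms, seed) {
  set.seed(seed)
  terms <- paste0("T", seq_len(n_terms))
  rows <- list()
  for (i in seq(2, n_terms)) {
    n_par <- sample(1:min(2, i - 1), 1)
    for (p in sample(seq_len(i - 1), n_par))
      rows[[length(rows) + 1L]] <-
        data.frame(term = terms[i], parent = terms[p],
                   relation = sample(c("is_a", "part_of"), 1),
                   stringsAsFactors = FALSE)
  }
  ontology(do.call(rbind, rows), terms = terms)
}
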