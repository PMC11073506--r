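#' Project expression onto latent-variable loadings
#'
#' Transfers latent variables learned on a large compendium to a new study:
#' each gene row of the log-expression matrix is standardized (z-scored)
#' across samples and the loading matrix is inverted in the least-squares
#' sense, `B = (Z'Z + ridge I)^-1 Z' Y_std`, giving a latent-variable x
#' sample activity matrix.  With `ridge = 0` this is plain matrix
#' (pseudo)inversion; the small default ridge is numerical regularization
#' only.
#'
#' @param logexpr gene x sample log-expression matrix with gene ids as row
#'   names.
#' @param loadings gene x latent-variable non-negative loading matrix; genes
#'   are aligned to `logexpr` by id, with missing genes dropped (a message
#'   reports how many).
#' @param ridge non-negative ridge constant.
#' @param condition,database optional per-sample metadata carried along for
#'   [differential_lv()].
#' @return An object of class `latent_activity` with elements `B`
#'   (LV x sample), `condition`, `database`.
#' @export
project_latent <- function(logexpr, loadings, ridge = 1e-6,
                           condition = NULL, database = NULL) {
  stopifnot(is.matrix(logexpr), is.matrix(loadings), ridge >= 0)
  common <- intersect(rownames(logexpr), rownames(loadings))
  if (length(common) == 0)
    stop("empty gene intersection between expression and loadings")
  dropped <- nrow(loadings) - length(common)
  if (dropped > 0)
    message(sprintf("project_latent: %d loading gene(s) not in expression matrix, dropped",
                    dropped))
  Y <- logexpr[common, , drop = FALSE]
  Z <- loadings[common, , drop = FALSE]
  mu <- rowMeans(Y)
  sd_g <- apply(Y, 1, sd)
  sd_g[sd_g == 0] <- 1  # constant rows standardize to zero
  Y_std <- (Y - mu) / sd_g
  A <- crossprod(Z) + diag(ridge, ncol(Z))
  B <- solve(A, crossprod(Z, Y_std))
  rownames(B) <- colnames(loadings)
  structure(list(B = B, condition = condition, database = database),
            class = "latent_activity")
}

#' Differential latent-variable analysis
#'
#' Per-latent-variable moderated linear models of activity on condition plus
#' the database covariate (same machinery as [moderated_lm_de()]), with
#' Bonferroni adjustment.  A latent variable is called significant when its
#' adjusted p-value is below `alpha` *and* its absolute effect (difference
#' of covariate-adjusted condition means) reaches the cutoff; by default the
#' cutoff is the [three_sd_cutoff()] of the observed effects.
#'
#' @param act a `latent_activity` with condition/database metadata.
#' @param alpha adjusted p-value cutoff.
#' @param effect_cutoff absolute effect threshold; `NULL` (default) applies
#'   the 3-standard-deviation rule to the fitted effects.
#' @return A `latent_differential` data.frame with columns `lv`, `effect`,
#'   `stat`, `p`, `p_adj`, `significant`, and the applied cutoff as
#'   attribute `cutoff`.
#' @export
differential_lv <- function(act, alpha = 0.05, effect_cutoff = NULL) {
  stopifnot(inherits(act, "latent_activity"))
  if (is.null(act$condition))
    stop("latent activity carries no condition metadata")
  condition <- factor(act$condition, levels = c("control", "tumor"))
  if (min(table(condition)) < 2L)
    stop("need at least 2 samples per condition")
  design <- .de_design(condition, act$database %||% rep("db1", ncol(act$B)))
  fit <- limma::eBayes(limma::lmFit(act$B, design))
  effect <- fit$coefficients[, 2L]
  stat <- fit$t[, 2L]
  p <- fit$p.value[, 2L]
  degen <- !is.finite(stat) & abs(effect) < 1e-12
  stat[degen] <- 0; p[degen] <- 1
  p_adj <- pmin(1, p * nrow(act$B))
  cutoff <- if (is.null(effect_cutoff)) three_sd_cutoff(effect) else effect_cutoff
  out <- data.frame(lv = rownames(act$B), effect = unname(effect),
                    stat = unname(stat), p = unname(p),
                    p_adj = unname(p_adj),
                    significant = unname(p_adj < alpha & abs(effect) >= cutoff),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, cutoff = cutoff,
            class = c("latent_differential", "data.frame"))
}

#' Three-standard-deviation effect cutoff
#'
#' Derives a single absolute effect threshold from the spread of the
#' latent-variable effects: with `upper = mean + 3 sd` and
#' `lower = mean - 3 sd`, the cutoff is `(|upper| + |lower|) / 2` rounded to
#' two decimals.  For example, an upper bound of 0.27 and a lower bound of
#' -0.23 give a cutoff of 0.25.
#'
#' @param effects numeric vector of per-latent-variable effects (length
#'   >= 2).
#' @return A single non-negative threshold.
#' @export
three_sd_cutoff <- function(effects) {
  if (length(effects) < 2L) stop("need at least 2 effects")
  m <- mean(effects); s <- sd(effects)
  round((abs(m + 3 * s) + abs(m - 3 * s)) / 2, 2)
}

#' Top-weighted genes of a latent variable
#'
#' @param loadings gene x latent-variable loading matrix.
#' @param lv latent-variable id (column name).
#' @param k number of genes to return (default 10, the conventional
#'   top-gene threshold); when fewer nonzero weights exist, all of them are
#'   returned with a warning.
#' @return Character vector of gene ids ordered by decreasing weight, ties
#'   broken by gene id.
#' @export
top_weighted_genes <- function(loadings, lv, k = 10L) {
  if (!lv %in% colnames(loadings)) stop("unknown latent variable: ", lv)
  w <- loadings[, lv]
  w <- w[w > 0]
  if (k > length(w)) {
    warning(sprintf("only %d nonzero weights in %s (requested %d)",
                    length(w), lv, k))
    k <- length(w)
  }
  names(w)[order(-w, names(w))][seq_len(k)]
}

#' Build a transfer-learning gene signature
#'
#' Harvests the top-weighted genes of the significant latent variables in
#' round-robin order: latent variables are visited by decreasing absolute
#' effect and each contributes its next-highest-weight gene that is in the
#' universe and not yet selected, until `n_target` genes are collected.
#' Up/down direction is taken from the supplied differential-expression fold
#' changes (by convention the negative-binomial route); genes with zero or
#' missing fold change are skipped.
#'
#' @param ld a `latent_differential` from [differential_lv()].
#' @param loadings gene x latent-variable loading matrix.
#' @param de a `differential_result` providing the fold-change signs.
#' @param universe eligible gene ids.
#' @param n_target signature size aimed for.
#' @return A [gene_signature()] with method `"transfer_learning"`; empty
#'   when no latent variable is significant.
#' @export
build_tl_signature <- function(ld, loadings, de, universe, n_target = 100L) {
  stopifnot(inherits(ld, "latent_differential"),
            inherits(de, "differential_result"))
  sig_lvs <- ld$lv[ld$significant]
  if (length(sig_lvs) == 0)
    return(gene_signature(character(0), character(0),
                          method = "transfer_learning", universe = universe,
                          truncated = TRUE))
  ord <- order(-abs(ld$effect[ld$significant]), sig_lvs)
  sig_lvs <- sig_lvs[ord]
  lfc <- setNames(de$log2fc, de$gene)
  eligible <- function(g)
    g %in% universe & !is.na(lfc[g]) & lfc[g] != 0
  # per-LV ranked candidate queues
  queues <- lapply(sig_lvs, function(lv) {
    w <- loadings[, lv]
    w <- w[w > 0]
    g <- names(w)[order(-w, names(w))]
    g[eligible(g)]
  })
  chosen <- character(0)
  repeat {
    added <- FALSE
    for (i in seq_along(queues)) {
      q <- setdiff(queues[[i]], chosen)
      if (length(q) > 0 && length(chosen) < n_target) {
        chosen <- c(chosen, q[1L])
        added <- TRUE
      }
      if (length(chosen) >= n_target) break
    }
    if (!added || length(chosen) >= n_target) break
  }
  gene_signature(up = chosen[lfc[chosen] > 0],
                 down = chosen[lfc[chosen] < 0],
                 method = "transfer_learning", universe = universe,
                 truncated = length(chosen) < n_target)
}

#' Gene-label-switch validation of the latent transfer
#'
#' Checks that the latent projection actually transfers gene-level
#' information: for each fraction `f`, the gene ids of a random
#' `ceiling(f * G)`-subset of the expression rows are shuffled among
#' themselves, the study is re-projected and re-tested, and the number of
#' significant latent variables (adjusted p < `alpha` and absolute effect >=
#' `effect_cutoff`) is recorded over `reps` repetitions.  On informative
#' loadings the mean count decreases with the switched fraction; the
#' returned regression of mean count on fraction quantifies that trend.
#'
#' @param study an [expression_study()].
#' @param loadings gene x latent-variable loading matrix.
#' @param fractions fractions of gene labels to switch; a zero baseline
#'   (the unpermuted study) is always included.
#' @param reps repetitions per fraction (>= 2).
#' @param seed RNG seed.
#' @param alpha adjusted p-value cutoff.
#' @param effect_cutoff fixed absolute effect threshold for this validation
#'   test.
#' @param ridge ridge constant of the projection.
#' @return List with `curve` (data.frame of fraction and mean significant-LV
#'   count) and `regression` (slope, r_squared, p of the linear fit).
#' @export
label_switch_validation <- function(study, loadings,
                                    fractions = seq(0.1, 1, by = 0.1),
                                    reps = 50L, seed = 1L, alpha = 0.05,
                                    effect_cutoff = 0.05, ridge = 1e-6) {
  stopifnot(inherits(study, "expression_study"))
  if (reps < 2L) stop("'reps' must be at least 2")
  set.seed(seed)
  logexpr <- tpm_log(study)
  G <- nrow(logexpr)
  n_sig <- function(mat) {
    act <- suppressMessages(project_latent(mat, loadings, ridge = ridge,
                                           condition = study$condition,
                                           database = study$database))
    ld <- differential_lv(act, alpha = alpha, effect_cutoff = effect_cutoff)
    sum(ld$significant)
  }
  baseline <- n_sig(logexpr)
  curve <- data.frame(fraction = 0, mean_significant = baseline)
  for (f in fractions) {
    counts <- vapply(seq_len(reps), function(r) {
      idx <- sample.int(G, ceiling(f * G))
      perm <- logexpr
      rownames(perm)[idx] <- rownames(logexpr)[sample(idx)]
      n_sig(perm)
    }, numeric(1))
    curve <- rbind(curve,
                   data.frame(fraction = f, mean_significant = mean(counts)))
  }
  fit <- lm(mean_significant ~ fraction, data = curve)
  sm <- summary(fit)
  list(curve = curve,
       regression = list(slope = unname(coef(fit)[2L]),
                         r_squared = sm$r.squared,
                         p = unname(sm$coefficients[2L, 4L])))
}
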