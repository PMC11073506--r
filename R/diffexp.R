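#' Length-normalized log expression (log2 TPM)
#'
#' Converts counts to transcripts per million,
#' `TPM_gj = 1e6 * (K_gj / len_g) / sum_i (K_ij / len_i)`, and returns
#' `log2(TPM + 1)`.  Every TPM column sums to one million before the log.
#'
#' @param study an [expression_study()].
#' @return gene x sample matrix of `log2(TPM + 1)` values.
#' @export
tpm_log <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  rate <- study$counts / study$gene_lengths
  tot <- colSums(rate)
  if (any(tot == 0))
    stop("all-zero sample column(s): ",
         paste(colnames(study$counts)[tot == 0], collapse = ", "))
  tpm <- sweep(rate, 2, tot, "/") * 1e6
  log2(tpm + 1)
}

.de_design <- function(condition, database) {
  condition <- factor(condition, levels = c("control", "tumor"))
  database <- factor(database)
  if (nlevels(database) > 1L) {
    design <- model.matrix(~ condition + database)
  } else {
    design <- model.matrix(~ condition)
  }
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    bad <- colnames(design)[qrd$pivot[(qrd$rank + 1L):ncol(design)]]
    stop("rank-deficient design; confounded column(s): ",
         paste(bad, collapse = ", "))
  }
  design
}

.new_differential_result <- function(df, method, adjust) {
  rownames(df) <- NULL
  structure(df, method = method, adjust = adjust,
            class = c("differential_result", "data.frame"))
}

#' Moderated linear-model differential expression
#'
#' Fits gene-wise linear models of log expression on condition plus the
#' source-database covariate and moderates the residual variances by
#' empirical Bayes shrinkage (limma), reporting Bonferroni-adjusted
#' p-values.
#'
#' @param logexpr gene x sample matrix of log2 expression (e.g. from
#'   [tpm_log()]).
#' @param condition per-sample factor with levels `control`/`tumor`.
#' @param database per-sample database factor; silently reduced to the
#'   one-covariate model when constant.
#' @return A `differential_result` data.frame with columns `gene`, `log2fc`,
#'   `se`, `stat`, `p`, `p_adj`.
#' @export
moderated_lm_de <- function(logexpr, condition, database) {
  condition <- factor(condition, levels = c("control", "tumor"))
  if (min(table(condition)) < 2L)
    stop("need at least 2 samples per condition")
  design <- .de_design(condition, database)
  fit <- limma::lmFit(logexpr, design)
  fit <- limma::eBayes(fit)
  i <- 2L  # condition coefficient
  log2fc <- fit$coefficients[, i]
  se <- fit$stdev.unscaled[, i] * sqrt(fit$s2.post)
  stat <- fit$t[, i]
  p <- fit$p.value[, i]
  # genes with zero residual variance and zero effect are unambiguous nulls
  degen <- !is.finite(stat) & abs(log2fc) < 1e-12
  stat[degen] <- 0; p[degen] <- 1
  p_adj <- pmin(1, p * nrow(logexpr))  # Bonferroni
  .new_differential_result(
    data.frame(gene = rownames(logexpr), log2fc = unname(log2fc),
               se = unname(se), stat = unname(stat), p = unname(p),
               p_adj = unname(p_adj), stringsAsFactors = FALSE),
    method = "moderated_lm", adjust = "bonferroni")
}

#' Negative-binomial GLM differential expression
#'
#' Models the raw counts with per-gene negative binomial generalized linear
#' models (DESeq2): median-of-ratios size factors, dispersion shrinkage
#' toward a mean-dispersion trend, and Wald tests on the condition
#' coefficient with the database covariate in the design.  The reported
#' `log2fc` is shrunk under a zero-centered normal prior on the condition
#' coefficient, which is the ranking quantity of the signature step; `stat`
#' and `p` are the unshrunken Wald results with Benjamini-Hochberg
#' adjustment.
#'
#' @param study an [expression_study()]; counts must be integers.
#' @param shrink_lfc logical; apply the normal-prior shrinkage to the
#'   reported fold changes (default `TRUE`).
#' @return A `differential_result` data.frame with columns `gene`, `log2fc`,
#'   `se`, `stat`, `p`, `p_adj`, carrying the fitted size factors and
#'   dispersions as attributes.
#' @export
nb_glm_de <- function(study, shrink_lfc = TRUE) {
  stopifnot(inherits(study, "expression_study"))
  if (any(study$counts != round(study$counts)))
    stop("counts must be integers for the negative-binomial model")
  if (min(table(study$condition)) < 2L)
    stop("need at least 2 samples per condition")
  design <- if (nlevels(droplevels(study$database)) > 1L)
    ~ database + condition else ~ condition
  # validates against confounding with the same rule as the linear route
  .de_design(study$condition, study$database)
  coldata <- data.frame(condition = study$condition,
                        database = droplevels(study$database))
  dds <- DESeq2::DESeqDataSetFromMatrix(
    countData = matrix(as.integer(study$counts), nrow = nrow(study$counts),
                       dimnames = dimnames(study$counts)),
    colData = coldata, design = design)
  # no outlier replacement, Cook's filtering or independent filtering:
  # every gene is tested and reported
  dds <- DESeq2::DESeq(dds, quiet = TRUE, minReplicatesForReplace = Inf)
  res <- DESeq2::results(dds, name = "condition_tumor_vs_control",
                         independentFiltering = FALSE, cooksCutoff = FALSE)
  lfc <- res$log2FoldChange
  se <- res$lfcSE
  if (shrink_lfc) {
    shr <- suppressMessages(DESeq2::lfcShrink(
      dds, coef = "condition_tumor_vs_control", type = "normal",
      quiet = TRUE))
    lfc <- shr$log2FoldChange
    se <- shr$lfcSE
  }
  out <- .new_differential_result(
    data.frame(gene = rownames(res), log2fc = lfc, se = se,
               stat = res$stat, p = res$pvalue,
               p_adj = p.adjust(res$pvalue, "BH"), stringsAsFactors = FALSE),
    method = "nb_glm", adjust = "bh")
  attr(out, "size_factors") <- DESeq2::sizeFactors(dds)
  attr(out, "dispersions") <- setNames(DESeq2::dispersions(dds),
                                       rownames(res))
  out
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors relative to the geometric-mean
#' pseudo-reference sample; genes whose geometric mean is zero are excluded.
#' Matches the estimator used by the negative-binomial route.
#'
#' @param counts gene x sample count matrix.
#' @return numeric vector of size factors, one per sample.
#' @export
median_ratio_size_factors <- function(counts) {
  loggeo <- rowMeans(log(counts))
  use <- is.finite(loggeo)
  if (!any(use)) stop("no gene has all-positive counts")
  apply(counts, 2, function(cnt) exp(median((log(cnt) - loggeo)[use])))
}

#' Build a differential-expression gene signature
#'
#' Ranks genes significant at `alpha` (adjusted p-value) by decreasing
#' absolute log2 fold change and walks down the ranking, skipping genes not
#' assayed in the reference `universe`, until `n_target` genes are
#' collected; each skipped gene is replaced by the next-ranked one.
#' Positive fold changes go to the up set and negative to the down set.
#' When fewer than `n_min` eligible genes exist, all of them are returned
#' with the `truncated` flag set.
#'
#' @param de a `differential_result`.
#' @param universe character vector of eligible gene ids (e.g. genes assayed
#'   in the perturbation reference).
#' @param n_min,n_max admissible signature size range.
#' @param n_target number of genes aimed for (must lie in
#'   `[n_min, n_max]`).
#' @param alpha adjusted p-value cutoff.
#' @return A [gene_signature()]; empty (but not an error) when no gene is
#'   significant.
#' @export
build_de_signature <- function(de, universe, n_min = 90L, n_max = 120L,
                               n_target = 100L, alpha = 0.05) {
  stopifnot(inherits(de, "differential_result"), nrow(de) > 0,
            length(universe) > 0)
  if (n_target < n_min || n_target > n_max)
    stop("'n_target' must lie in [n_min, n_max]")
  sig <- de[!is.na(de$p_adj) & de$p_adj < alpha & !is.na(de$log2fc) &
              de$log2fc != 0, , drop = FALSE]
  # deterministic ranking: |log2fc| descending, ties by gene id
  sig <- sig[order(-abs(sig$log2fc), sig$gene), , drop = FALSE]
  eligible <- sig[sig$gene %in% universe, , drop = FALSE]
  truncated <- nrow(eligible) < n_min
  if (truncated && nrow(eligible) < nrow(sig))
    message(sprintf("signature truncated: only %d of %d significant genes in universe",
                    nrow(eligible), nrow(sig)))
  take <- head(eligible, n_target)
  gene_signature(up = take$gene[take$log2fc > 0],
                 down = take$gene[take$log2fc < 0],
                 method = attr(de, "method"), universe = universe,
                 truncated = truncated)
}
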