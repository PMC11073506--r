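test_that("TPM normalization obeys its defining identities", {
  # equal count/length rates give equal TPM
  st <- expression_study(
    matrix(c(10, 20), 2, 1, dimnames = list(c("a", "b"), "s1")),
    gene_lengths = c(1, 2), condition = "tumor", database = "db1")
  tpm <- 2^tpm_log(st) - 1
  expect_equal(unname(tpm[, 1]), c(5e5, 5e5))

  # zero count -> log value 0; columns sum to one million
  set.seed(1)
  k <- matrix(rpois(15, 20), 5, 3,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))
  k[1, 1] <- 0
  st <- expression_study(k, gene_lengths = runif(5, 0.5, 10),
                         condition = c("tumor", "tumor", "control"),
                         database = rep("db1", 3))
  le <- tpm_log(st)
  expect_equal(le[1, 1], 0)
  expect_equal(unname(colSums(2^le - 1)), rep(1e6, 3), tolerance = 1e-6)

  # invariance to per-sample depth scaling
  k2 <- k; k2[, 2] <- k2[, 2] * 7
  st2 <- expression_study(k2, st$gene_lengths, st$condition, st$database)
  expect_equal(tpm_log(st2), le)

  # all-zero sample is an error naming the sample
  k3 <- k; k3[, 2] <- 0
  st3 <- expression_study(k3, st$gene_lengths, st$condition, st$database)
  expect_error(tpm_log(st3), "s2")
})

test_that("moderated linear model handles degenerate and confounded designs", {
  cond <- rep(c("control", "tumor"), each = 4)
  db <- rep("db1", 8)
  # identical group means per gene -> zero effect, p = 1
  y <- matrix(rep(c(1, 2, 3, 4), 2), nrow = 1)
  y <- rbind(y, y + 5)
  rownames(y) <- c("g1", "g2"); colnames(y) <- paste0("s", 1:8)
  de <- moderated_lm_de(y, cond, db)
  expect_equal(de$log2fc, c(0, 0))
  expect_equal(de$p, c(1, 1))

  # database perfectly confounded with condition -> informative error
  expect_error(moderated_lm_de(y, cond, rep(c("db1", "db2"), each = 4)),
               "confounded")
})

test_that("constant database covariate reduces to the one-covariate model", {
  s <- small_sim()
  le <- small_logexpr()
  de_one <- moderated_lm_de(le, s$study$condition, rep("db1", 24))
  X <- model.matrix(~ s$study$condition)
  fit <- limma::eBayes(limma::lmFit(le, X))
  expect_equal(de_one$log2fc, unname(fit$coefficients[, 2]),
               tolerance = 1e-10)
})

test_that("moderated linear model raw p-values are calibrated under the null", {
  cfg <- small_config(seed = 77L, frac_de = 0)
  sim <- simulate_expression_study(cfg)
  de <- moderated_lm_de(tpm_log(sim$study), sim$study$condition,
                        sim$study$database)
  # 500 null genes: binomial tolerance around the nominal level
  expect_lt(abs(mean(de$p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 500))
  expect_true(all(de$p_adj >= de$p))
})

test_that("median-of-ratios size factors react to depth only", {
  k <- matrix(c(10, 30, 50, 20, 60, 100), 3, 2,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  sf <- median_ratio_size_factors(k)
  expect_equal(unname(sf[2] / sf[1]), 2)
  k_same <- cbind(k[, 1], k[, 1]); colnames(k_same) <- c("a", "b")
  expect_equal(unname(median_ratio_size_factors(k_same)), c(1, 1))
})

test_that("negative-binomial route rejects non-integer counts and recovers planted genes", {
  s <- small_sim()
  bad <- s$study
  bad$counts[1, 1] <- 1.5
  expect_error(nb_glm_de(bad), "integer")

  de <- small_nb_de()
  expect_true(all(de$p_adj >= de$p, na.rm = TRUE))
  called <- de$gene[!is.na(de$p_adj) & de$p_adj < 0.05]
  sens <- mean(s$truth$de_genes %in% called)
  fdr <- if (length(called) > 0)
    mean(!called %in% s$truth$de_genes) else 0
  expect_gte(sens, 0.8)
  expect_lte(fdr, 0.1)

  # DESeq2 size factors agree with the median-of-ratios estimator
  expect_equal(unname(attr(de, "size_factors")),
               unname(median_ratio_size_factors(s$study$counts)),
               tolerance = 1e-6)
})

test_that("Wald statistics agree with a brute-force profile refit", {
  # refit the NB GLM by plain IRLS at the fitted dispersions and size
  # factors; Wald statistics must agree closely
  s <- small_sim()
  de <- small_nb_de()
  sf <- attr(de, "size_factors")
  disp <- attr(de, "dispersions")
  X <- model.matrix(~ database + condition,
                    data.frame(condition = s$study$condition,
                               database = droplevels(s$study$database)))
  nb_irls <- function(y, X, sf, alpha) {
    off <- log(sf)
    beta <- c(log(mean(y / sf) + 0.1), rep(0, ncol(X) - 1))
    for (it in 1:100) {
      eta <- drop(X %*% beta) + off
      mu <- pmin(exp(eta), 1e12)
      w <- mu / (1 + alpha * mu)
      fit <- stats::lm.wfit(X, eta - off + (y - mu) / mu, w)
      if (max(abs(fit$coefficients - beta)) < 1e-10) {
        beta <- fit$coefficients; break
      }
      beta <- fit$coefficients
    }
    mu <- exp(drop(X %*% beta) + off)
    w <- mu / (1 + alpha * mu)
    se <- sqrt(diag(solve(crossprod(X * sqrt(w)))))
    (beta / log(2))[ncol(X)] / (se / log(2))[ncol(X)]
  }
  set.seed(4)
  genes <- sample(which(!is.na(de$stat) & abs(de$stat) > 0.1), 20)
  for (g in genes) {
    stat_oracle <- nb_irls(s$study$counts[g, ], X, sf, disp[g])
    expect_lt(abs(stat_oracle - de$stat[g]) / abs(de$stat[g]), 0.01)
  }
})

test_that("signature selection ranks by |log2fc| and respects the universe", {
  de <- structure(
    data.frame(gene = c("gA", "gB", "gC"), log2fc = c(5, -4, 1),
               se = 1, stat = 1, p = 0.001, p_adj = 0.01,
               stringsAsFactors = FALSE),
    method = "moderated_lm", adjust = "bonferroni",
    class = c("differential_result", "data.frame"))
  sig <- build_de_signature(de, c("gA", "gB", "gC"), n_min = 1, n_max = 3,
                            n_target = 3)
  expect_equal(sig$up, c("gA", "gC"))
  expect_equal(sig$down, "gB")

  # top-ranked gene outside the universe is replaced by the next one
  sig2 <- suppressMessages(build_de_signature(de, c("gB", "gC"), n_min = 1,
                                              n_max = 3, n_target = 2))
  expect_false("gA" %in% c(sig2$up, sig2$down))
  expect_equal(sig2$down, "gB")
  expect_equal(sig2$up, "gC")

  # empty significant set: explicit empty signature, not an exception
  de$p_adj <- rep(0.9, 3)
  sig3 <- build_de_signature(de, c("gA", "gB", "gC"), n_min = 1, n_max = 3,
                             n_target = 2)
  expect_length(c(sig3$up, sig3$down), 0)
  expect_true(sig3$truncated)
})

test_that("planted-simulation signatures have the expected size and determinism", {
  s <- small_sim()
  de <- small_nb_de()
  universe <- s$reference$gene_ids
  sig <- build_de_signature(de, universe, n_min = 20, n_max = 40,
                            n_target = 30)
  expect_true(length(c(sig$up, sig$down)) >= 20 &&
                length(c(sig$up, sig$down)) <= 40)
  sig_b <- build_de_signature(de, universe, n_min = 20, n_max = 40,
                              n_target = 30)
  expect_identical(sig, sig_b)
})
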