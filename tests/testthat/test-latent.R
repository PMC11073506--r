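test_that("latent projection reduces to standardized expression for identity loadings", {
  set.seed(2)
  y <- matrix(rnorm(60, 5), 6, 10,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  Z <- diag(6); dimnames(Z) <- list(rownames(y), paste0("LV", 1:6))
  act <- project_latent(y, Z, ridge = 0)
  y_std <- matrix(t(scale(t(y))), nrow(y))
  # R's scale() uses the n-1 sd, as does the projection
  expect_equal(unname(act$B), unname(y_std), tolerance = 1e-10)

  # ridge -> infinity shrinks activity to zero
  act_big <- project_latent(y, Z, ridge = 1e12)
  expect_lt(max(abs(act_big$B)), 1e-9)

  # orthonormal loadings with zero ridge equal the plain cross-product
  Q <- qr.Q(qr(matrix(rnorm(36), 6)))
  dimnames(Q) <- dimnames(Z)
  act_q <- project_latent(y, Q, ridge = 0)
  expect_equal(unname(act_q$B), unname(crossprod(Q, y_std)),
               tolerance = 1e-8)

  expect_error(project_latent(y, matrix(1, 2, 1,
                                        dimnames = list(c("x1", "x2"), "L1"))),
               "intersection")
})

test_that("differential latent-variable analysis recovers planted activity", {
  sim <- small_sim()
  act <- suppressMessages(project_latent(
    small_logexpr(), sim$loadings, condition = sim$study$condition,
    database = sim$study$database))
  ld <- differential_lv(act)
  # all planted LVs significant at Bonferroni < 0.05
  planted <- ld[ld$lv %in% sim$truth$active_lvs, ]
  expect_true(all(planted$p_adj < 0.05))
  # the significance flag is exactly the conjunction of the two rules
  expect_equal(ld$significant,
               ld$p_adj < 0.05 & abs(ld$effect) >= attr(ld, "cutoff"))

  # constant activity row: zero effect, p = 1
  act2 <- act
  act2$B[1, ] <- 3
  ld2 <- differential_lv(act2)
  expect_equal(ld2$effect[1], 0)
  expect_equal(ld2$p[1], 1)
})

test_that("null latent activity stays below the nominal error rate", {
  cfg <- small_config(seed = 15L, frac_de = 0, n_active_lvs = 0L)
  es <- simulate_expression_study(cfg)
  ll <- simulate_latent_loadings(cfg, es$truth)
  act <- suppressMessages(project_latent(
    tpm_log(es$study), ll$loadings, condition = es$study$condition,
    database = es$study$database))
  ld <- differential_lv(act)
  expect_equal(sum(ld$significant), 0)
})

test_that("three-standard-deviation cutoff follows its closed form", {
  # asymmetric bounds average: upper 0.27 and lower -0.23 give 0.25
  effects <- c(0.02 - 0.25 / (3 * sqrt(2)), 0.02 + 0.25 / (3 * sqrt(2)))
  expect_equal(mean(effects) + 3 * sd(effects), 0.27, tolerance = 1e-12)
  expect_equal(mean(effects) - 3 * sd(effects), -0.23, tolerance = 1e-12)
  expect_equal(three_sd_cutoff(effects), 0.25)

  # symmetric effects: cutoff = round(3 sd, 2)
  set.seed(5)
  x <- rnorm(100); x <- c(x, -x)
  expect_equal(three_sd_cutoff(x), round(3 * sd(x), 2))

  # degenerate: zero spread returns the common absolute value
  expect_equal(three_sd_cutoff(c(0.1, 0.1, 0.1)), 0.10)
  expect_error(three_sd_cutoff(0.3), "at least 2")
})

test_that("top-weighted gene ranking is deterministic with lexicographic ties", {
  Z <- matrix(0, 4, 2, dimnames = list(c("a", "b", "c", "d"),
                                       c("LV1", "LV2")))
  Z[, 1] <- c(3, 2, 1, 0)
  Z[, 2] <- c(2, 2, 0, 1)
  expect_equal(top_weighted_genes(Z, "LV1", k = 2), c("a", "b"))
  expect_equal(top_weighted_genes(Z, "LV2", k = 2), c("a", "b"))  # tie a=b
  expect_warning(out <- top_weighted_genes(Z, "LV1", k = 10), "nonzero")
  expect_equal(out, c("a", "b", "c"))
  expect_error(top_weighted_genes(Z, "LV9"), "unknown")
})

test_that("transfer-learning signature harvests round-robin and deduplicates", {
  Z <- matrix(0, 6, 2, dimnames = list(paste0("g", 1:6), c("LV1", "LV2")))
  Z[, 1] <- c(6, 5, 4, 3, 0, 0)
  Z[, 2] <- c(6, 0, 0, 0, 2, 1)  # g1 appears top-ranked in both LVs
  ld <- structure(
    data.frame(lv = c("LV1", "LV2"), effect = c(0.9, -0.5),
               stat = c(10, -8), p = c(1e-8, 1e-6), p_adj = c(1e-6, 1e-4),
               significant = TRUE, stringsAsFactors = FALSE),
    cutoff = 0.1, class = c("latent_differential", "data.frame"))
  de <- structure(
    data.frame(gene = paste0("g", 1:6),
               log2fc = c(2, -1, 1, -2, 1.5, -0.5), se = 1, stat = 1,
               p = 0.001, p_adj = 0.01, stringsAsFactors = FALSE),
    method = "nb_glm", adjust = "bh",
    class = c("differential_result", "data.frame"))
  sig <- build_tl_signature(ld, Z, de, universe = paste0("g", 1:6),
                            n_target = 4)
  genes <- c(sig$up, sig$down)
  expect_length(genes, 4)
  expect_equal(anyDuplicated(genes), 0)
  # round-robin: LV1 gives g1, LV2 gives g5 (g1 taken), then g2, g6
  expect_setequal(genes, c("g1", "g5", "g2", "g6"))
  expect_setequal(sig$up, c("g1", "g5"))
  expect_setequal(sig$down, c("g2", "g6"))

  # one significant LV: its top genes in order
  ld1 <- ld[1, , drop = FALSE]
  attr(ld1, "cutoff") <- 0.1
  class(ld1) <- c("latent_differential", "data.frame")
  sig1 <- build_tl_signature(ld1, Z, de, universe = paste0("g", 1:6),
                             n_target = 3)
  expect_setequal(c(sig1$up, sig1$down), c("g1", "g2", "g3"))

  # no significant LV: explicit empty signature
  ld0 <- ld; ld0$significant <- FALSE
  sig0 <- build_tl_signature(ld0, Z, de, universe = paste0("g", 1:6))
  expect_length(c(sig0$up, sig0$down), 0)
})

test_that("synthetic transfer signature reaches the target size exactly", {
  sim <- small_sim()
  act <- suppressMessages(project_latent(
    small_logexpr(), sim$loadings, condition = sim$study$condition,
    database = sim$study$database))
  ld <- differential_lv(act)
  sig <- build_tl_signature(ld, sim$loadings, small_nb_de(),
                            sim$reference$gene_ids, n_target = 12L)
  expect_length(c(sig$up, sig$down), 12L)
  # invariant to LV row order of the differential table
  ld_shuf <- ld[rev(seq_len(nrow(ld))), ]
  attr(ld_shuf, "cutoff") <- attr(ld, "cutoff")
  class(ld_shuf) <- class(ld)
  sig_b <- build_tl_signature(ld_shuf, sim$loadings, small_nb_de(),
                              sim$reference$gene_ids, n_target = 12L)
  expect_identical(sig, sig_b)
})

test_that("label switching erodes the significant latent variables", {
  sim <- small_sim()
  ls <- label_switch_validation(sim$study, sim$loadings,
                                fractions = c(0.3, 0.6, 1), reps = 4L,
                                seed = 8L)
  # zero-fraction baseline reproduces the unpermuted count
  act <- suppressMessages(project_latent(
    small_logexpr(), sim$loadings, condition = sim$study$condition,
    database = sim$study$database))
  base <- sum(differential_lv(act, effect_cutoff = 0.05)$significant)
  expect_equal(ls$curve$mean_significant[1], base)
  expect_lt(ls$regression$slope, 0)
  expect_lt(ls$curve$mean_significant[4], base)

  ls2 <- label_switch_validation(sim$study, sim$loadings,
                                 fractions = c(0.3, 0.6, 1), reps = 4L,
                                 seed = 8L)
  expect_identical(ls, ls2)
  expect_error(label_switch_validation(sim$study, sim$loadings, reps = 1L),
               "reps")
})
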