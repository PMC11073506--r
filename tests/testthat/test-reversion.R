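test_that("enrichment score matches hand-enumerable cases", {
  z <- setNames(c(3, 2, 1, -1, -2), paste0("g", 1:5))
  # single top-ranked gene: maximal enrichment
  expect_equal(weighted_es(z, "g1"), 1)
  # single bottom-ranked gene: four misses of 1/4 precede the hit
  expect_equal(weighted_es(z, "g5"), -1)
  # top two genes: explicit running sum (0.6, 1.0, then three misses)
  expect_equal(weighted_es(z, c("g1", "g2")), 1)
  expect_equal(weighted_es(z, c("g1", "g2")),
               es_bruteforce(z, c("g1", "g2")))
  # a middling set, checked against the full running sum:
  # -1/3, +1/6, -1/6, -1/2, 0 -> extremum -1/2
  expect_equal(weighted_es(z, c("g2", "g5")), -0.5)
  expect_equal(weighted_es(z, c("g2", "g5")),
               unname(es_bruteforce(z, c("g2", "g5"))))

  expect_error(weighted_es(z, character(0)), "empty")
  expect_error(weighted_es(z, names(z)), "proper subset")
  expect_error(weighted_es(unname(z), "g1"), "named")
})

test_that("enrichment score is antisymmetric under profile negation", {
  set.seed(11)
  for (i in 1:25) {
    G <- sample(10:50, 1)
    z <- setNames(rnorm(G), paste0("g", seq_len(G)))
    set <- sample(names(z), sample(2:(G - 2), 1))
    expect_equal(weighted_es(-z, set), -weighted_es(z, set),
                 tolerance = 1e-12)
  }
})

test_that("the compiled batch kernel agrees with the reference scorer", {
  sim <- small_sim()
  ref <- sim$reference
  rr <- sigrev:::.rank_reference(ref)
  set.seed(3)
  for (i in 1:15) {
    d <- sample(nrow(ref$z), 1)
    up <- sample(ref$gene_ids, 20)
    down <- sample(setdiff(ref$gene_ids, up), 15)
    batch <- sigrev:::.wtcs_batch(rr, list(up), list(down))[d, 1]
    single <- wtcs_score(weighted_es(ref$z[d, ], up),
                         weighted_es(ref$z[d, ], down))
    expect_equal(batch, single, tolerance = 1e-12)
  }
})

test_that("bi-directional combination zeroes same-sign scores", {
  expect_equal(wtcs_score(0.8, -0.6), 0.7)
  expect_equal(wtcs_score(0.5, 0.5), 0)
  expect_equal(wtcs_score(-0.9, 0.9), -0.9)
  expect_equal(wtcs_score(0, 0.4), -0.2)
  expect_error(wtcs_score(1.2, 0))
})

test_that("NCS normalization divides by the signed same-sign means", {
  expect_equal(normalize_ncs(c(0.2, 0.4)), c(2 / 3, 4 / 3))
  expect_equal(normalize_ncs(c(-0.1, -0.3)), c(-0.5, -1.5))
  expect_equal(normalize_ncs(c(0, 0, 0)), c(0, 0, 0))
  mixed <- normalize_ncs(c(0.2, -0.1, 0, 0.4, -0.3))
  expect_equal(mixed, c(2 / 3, -0.5, 0, 4 / 3, -1.5))
  expect_equal(sign(mixed), sign(c(0.2, -0.1, 0, 0.4, -0.3)))
})

test_that("Tau is the signed percentile against the bank", {
  bank <- matrix(c(0.1, 0.2, 0.3, 0.4), 1, dimnames = list("d1", NULL))
  expect_equal(unname(compute_tau(c(d1 = -0.25), bank)), -50)
  expect_equal(unname(compute_tau(c(d1 = -0.5), bank)), -100)
  expect_equal(unname(compute_tau(c(d1 = 0), bank)), 0)
  expect_equal(unname(compute_tau(c(d1 = 0.35), bank)), 75)
  expect_error(compute_tau(c(d1 = 1), bank[, 0, drop = FALSE]), "empty")
  expect_error(compute_tau(c(d9 = 1), bank), "lacks")
})

test_that("candidate filter applies strict thresholds and the sign rule", {
  ct <- structure(
    data.frame(drug = c("a", "b", "c", "d"),
               es_up = 0, es_down = 0, wtcs = c(-0.9, -0.9, 0.5, -0.8),
               ncs = c(-1.2, -1.2, 0.5, -1.1),
               tau = c(-85, -80, -99, -90),
               p = c(0.001, 0.001, 1e-6, 0.001),
               fdr = c(0.01, 0.01, 1e-6, 0.06),
               stringsAsFactors = FALSE),
    class = c("connectivity_table", "data.frame"))
  ann <- drug_annotations(data.frame(
    drug_id = c("a", "b", "c", "d"), fda_approved = c(TRUE, TRUE, TRUE, TRUE),
    in_trial = FALSE, moa = "m", stringsAsFactors = FALSE))
  kept <- filter_candidates(ct, ann)
  expect_equal(kept$drug, "a")  # b: tau == -80 (strict); c: ncs > 0; d: fdr
  ann2 <- ann; ann2$drugs$fda_approved[1] <- FALSE
  expect_equal(nrow(filter_candidates(ct, ann2)), 0)
  expect_equal(filter_candidates(ct, fda_only = FALSE)$drug, "a")
})

test_that("reversion run is deterministic and honors its contracts", {
  sim <- small_sim()
  de <- small_nb_de()
  sig <- build_de_signature(de, sim$reference$gene_ids, n_min = 20,
                            n_max = 40, n_target = 30)
  ct <- run_reversion(sig, sim$reference, n_perm = 200, seed = 5)
  ct2 <- run_reversion(sig, sim$reference, n_perm = 200, seed = 5)
  expect_identical(ct, ct2)

  expect_true(all(abs(ct$wtcs) <= 1))
  expect_true(all(abs(ct$es_up) <= 1 & abs(ct$es_down) <= 1))
  expect_true(all(abs(ct$tau) <= 100))
  expect_true(all(ct$fdr >= ct$p))
  expect_true(all(sign(ct$ncs) == sign(ct$wtcs)))
  expect_true(all(ct$wtcs[sign(ct$es_up) == sign(ct$es_down)] == 0))

  # the most negative NCS drug is a planted reverser
  expect_true(ct$drug[which.min(ct$ncs)] %in% sim$truth$reverser_drugs)

  # a query built from a drug's own extremes maximizes its WTCS
  z1 <- sim$reference$z[7, ]
  self_sig <- gene_signature(names(sort(z1, decreasing = TRUE))[1:20],
                             names(sort(z1))[1:20],
                             universe = sim$reference$gene_ids)
  ct_self <- run_reversion(self_sig, sim$reference, n_perm = 200, seed = 5)
  expect_equal(which.max(ct_self$wtcs), 7L)

  expect_error(run_reversion(sig, sim$reference, n_perm = 50), "at least 100")
  outside <- gene_signature(c("zz1", "zz2"), character(0))
  expect_error(run_reversion(outside, sim$reference, n_perm = 200),
               "no query gene")
  half_out <- gene_signature(c(sim$reference$gene_ids[1], "zz1", "zz2"),
                             character(0))
  expect_warning(run_reversion(half_out, sim$reference, n_perm = 200,
                               seed = 1),
                 "present in the reference")
})

test_that("permutation p-values hit the floor for extreme reversers", {
  sim <- small_sim()
  de <- small_nb_de()
  sig <- build_de_signature(de, sim$reference$gene_ids, n_min = 20,
                            n_max = 40, n_target = 30)
  ct <- run_reversion(sig, sim$reference, n_perm = 200, seed = 5)
  best <- which.min(ct$wtcs)
  expect_equal(ct$p[best], 1 / 201)
})
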