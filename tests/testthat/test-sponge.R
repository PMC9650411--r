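make_targets <- function(mirnas, mrnas, lncrnas, mr_edges = NULL,
                         lnc_edges = NULL) {
  t_mr <- matrix(0L, length(mirnas), length(mrnas),
                 dimnames = list(mirnas, mrnas))
  t_lnc <- matrix(0L, length(mirnas), length(lncrnas),
                  dimnames = list(mirnas, lncrnas))
  if (!is.null(mr_edges)) t_mr[mr_edges] <- 1L
  if (!is.null(lnc_edges)) t_lnc[lnc_edges] <- 1L
  target_matrix(t_mr, t_lnc)
}

test_that("sharing counts follow the target matrix", {
  mirs <- paste0("mir", 1:35)
  tm <- make_targets(mirs, c("m1", "m2"), c("l1", "l2"))
  cnt <- sharing_counts("l1", "m1", tm, mirs)
  expect_equal(c(cnt$M1, cnt$K1, cnt$L1), c(0, 0, 0))

  tm2 <- make_targets(mirs, c("m1", "m2"), c("l1", "l2"),
                      mr_edges = cbind("mir1", "m1"),
                      lnc_edges = cbind("mir1", "l1"))
  cnt2 <- sharing_counts(c("l1", "l2"), c("m1", "m2"), tm2, mirs)
  expect_equal(c(cnt2$N1, cnt2$M1, cnt2$K1, cnt2$L1), c(35, 1, 1, 1))
  expect_identical(cnt2$shared, "mir1")

  # planted module always contributes its shared miRNAs
  sim <- generate_bundle(default_simulation_spec(seed = 2))
  mod <- sim$truth$modules[[1]]
  cnt3 <- sharing_counts(mod$lncrna, mod$mrna, sim$targets,
                         rownames(sim$bundle$mirna))
  expect_gte(cnt3$L1, 3)
  expect_true(all(mod$mirna %in% cnt3$shared))

  expect_error(sharing_counts("l1", "m1", tm, character()), "universe")
})

test_that("hypergeometric sharing p matches exact enumeration", {
  counts <- function(N, M, K, L)
    structure(list(N1 = N, M1 = M, K1 = K, L1 = L),
              class = "sharing_counts")
  expect_equal(hypergeom_sharing_pvalue(counts(10, 4, 5, 0)), 1)
  expect_equal(hypergeom_sharing_pvalue(counts(10, 4, 5, 3)), 66 / 252,
               tolerance = 1e-12)
  expect_equal(hypergeom_sharing_pvalue(counts(12, 12, 3, 1)), 1)
  expect_error(hypergeom_sharing_pvalue(counts(10, 2, 2, 3)),
               "inconsistent")
  for (N in c(5, 9, 12)) for (M in 0:N) for (K in 0:N)
    for (L in 0:min(M, K))
      expect_equal(hypergeom_sharing_pvalue(counts(N, M, K, L)),
                   enum_sharing_pvalue(N, M, K, L), tolerance = 1e-12)
})

test_that("canonical correlation agrees with oracles and its identities", {
  set.seed(40)
  # scalar case reduces to |pearson|
  x <- rnorm(60); y <- 0.4 * x + rnorm(60)
  expect_equal(canonical_correlation(cbind(x), cbind(y))$cc,
               abs(cor(x, y)), tolerance = 1e-10)
  # invariance under invertible transforms of either group
  x2 <- matrix(rnorm(60 * 3), 60)
  y2 <- matrix(rnorm(60 * 2), 60)
  r <- matrix(c(2, 1, 0, -1, 3, 0.5, 0, 0, 1), 3)
  cc0 <- canonical_correlation(x2, y2)$cc
  expect_equal(canonical_correlation(x2 %*% r, y2)$cc, cc0,
               tolerance = 1e-8)
  expect_equal(canonical_correlation(x2, y2 %*% matrix(c(1, 2, -1, 1),
                                                       2))$cc,
               cc0, tolerance = 1e-8)
  # generalized-eigenproblem oracle on random instances
  for (i in 1:100) {
    a <- matrix(rnorm(100 * 5), 100)
    b <- matrix(rnorm(100 * 3), 100)
    expect_equal(canonical_correlation(a, b)$cc, eigen_cc(a, b),
                 tolerance = 1e-8)
  }
  # full linear dependence gives cc = 1
  expect_equal(canonical_correlation(x2, x2 %*% r)$cc, 1,
               tolerance = 1e-8)
  expect_error(canonical_correlation(cbind(x, 1), cbind(y)), "constant")
  expect_error(canonical_correlation(cbind(x[1:2]), cbind(y[1:2])),
               "samples")
})

test_that("dimension guard prevents trivially perfect correlation", {
  set.seed(41)
  x <- matrix(rnorm(30 * 40), 30)  # more variables than samples
  y <- matrix(rnorm(30 * 40), 30)
  res <- canonical_correlation(x, y)
  expect_lt(res$cc, 0.9999)
  expect_true(all(res$dims <= floor(30 / 3)))
})

test_that("partial canonical correlation follows the closed form", {
  expect_equal(partial_cc(0.9, 0.6, 0.5),
               (0.9 - 0.3) / sqrt(0.64 * 0.75), tolerance = 1e-12)
  # no miRNA influence: pcc equals cc, so scc = 0 exactly
  expect_identical(partial_cc(0.7, 0, 0), 0.7)
  # scalar case equals the classical first-order partial correlation
  set.seed(42)
  z <- rnorm(500)
  x <- 0.5 * z + rnorm(500)
  y <- 0.7 * z + rnorm(500)
  r_xy <- cor(x, y); r_xz <- cor(x, z); r_yz <- cor(y, z)
  classic <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  expect_equal(partial_cc(r_xy, r_yz, r_xz), classic, tolerance = 1e-10)
  expect_error(partial_cc(0.5, 1, 0.3), "undefined")
})

test_that("sensitivity cc separates sponge modules from decoys", {
  sp <- generate_bundle(one_module_spec(beta = 0.8, seed = 50))
  dc <- generate_bundle(one_module_spec(beta = 0, seed = 50))
  m1 <- sp$truth$modules[[1]]; m2 <- dc$truth$modules[[1]]
  s1 <- sensitivity_cc(sp$bundle, m1$lncrna, m1$mrna, m1$mirna)
  s2 <- sensitivity_cc(dc$bundle, m2$lncrna, m2$mrna, m2$mirna)
  expect_equal(s1$scc, s1$cc_lnc_mr - s1$pcc)  # identity, exact
  expect_equal(s2$scc, s2$cc_lnc_mr - s2$pcc)
  expect_lt(abs(s2$scc), 0.1)
  expect_gt(s1$scc, 0)
  expect_gt(s1$scc, s2$scc)
  expect_error(sensitivity_cc(sp$bundle, m1$lncrna, m1$mrna, character()),
               "empty")
})

test_that("null-model p-values behave at the center and the tail", {
  cache <- new.env(parent = emptyenv())
  p0 <- null_model_pvalue(0, m = 4, n = 8, q = 2, n_samples = 100,
                          cc_lnc_mr = 0.7, n_null = 1000, seed = 5,
                          cache = cache)
  expect_gt(as.numeric(p0), 0.05)
  p_tail <- null_model_pvalue(1, m = 4, n = 8, q = 2, n_samples = 100,
                              cc_lnc_mr = 0.7, n_null = 1000, seed = 5,
                              cache = cache)
  expect_equal(as.numeric(p_tail), 1 / 1001)
  # deterministic and cached by shape
  cache2 <- new.env(parent = emptyenv())
  p1 <- null_model_pvalue(0.05, 4, 8, 2, 100, 0.7, 1000, seed = 5,
                          cache = cache2)
  p2 <- null_model_pvalue(0.05, 4, 8, 2, 100, 0.7, 1000, seed = 5,
                          cache = cache2)
  expect_identical(p1, p2)
  expect_equal(length(ls(cache2)), 1)
  expect_error(null_model_pvalue(0, 4, 8, 2, 100, 0.7, n_null = 10),
               "n_null")
})

test_that("module screen flags planted sponges and spares decoys", {
  spec <- simulation_spec(
    n_samples = 150, n_mrna = 80, n_lncrna = 20, n_mirna = 12,
    modules = list(module_spec(6, 30, 3, 1, 0.8),
                   module_spec(6, 30, 3, 1.7, 0)),
    background_target_density = 0.001, seed = 60
  )
  sim <- generate_bundle(spec)
  labels <- sim$truth$membership
  res <- identify_sponge_modules(sim$bundle, labels, sim$targets,
                                 n_null = 1000, seed = 61)
  expect_equal(nrow(res$summary), 2)
  expect_true(res$summary$is_sponge[res$summary$module == 1])
  expect_false(res$summary$is_sponge[res$summary$module == 2])
  # scc = cc - pcc holds in every row that reached the cc stage
  done <- !is.na(res$summary$scc)
  expect_equal(res$summary$scc[done],
               res$summary$cc_lnc_mr[done] - res$summary$pcc[done])
  # BH adjustment matches the hand-rolled step-up oracle
  expect_equal(res$summary$adj_p[done],
               brute_bh(res$summary$null_p[done]), tolerance = 1e-12)

  # without target edges nothing passes the sharing test
  empty <- make_targets(rownames(sim$bundle$mirna),
                        rownames(sim$bundle$mrna),
                        rownames(sim$bundle$lncrna))
  res0 <- identify_sponge_modules(sim$bundle, labels, empty,
                                  n_null = 1000, seed = 61)
  expect_true(all(res0$summary$sharing_p == 1))
  expect_false(any(res0$summary$is_sponge))

  # modules with fewer than 3 lncRNAs are not candidates
  few <- labels
  few[sim$truth$modules[[1]]$lncrna[-(1:2)]] <- 0L
  res1 <- identify_sponge_modules(sim$bundle, few, sim$targets,
                                  n_null = 1000, seed = 61)
  expect_false(1 %in% res1$summary$module)
})

test_that("interaction extraction enumerates shared-miRNA pairs", {
  mirs <- paste0("mir", 1:3)
  tm <- make_targets(mirs, c("B", "C", "D"), c("A", "E"),
                     mr_edges = rbind(c("mir1", "B"), c("mir1", "C")),
                     lnc_edges = cbind("mir1", "A"))
  out <- extract_interactions("A", c("B", "C", "D"), "mir1", tm)
  expect_equal(out$lncrna, c("A", "A"))
  expect_equal(out$mrna, c("B", "C"))
  expect_equal(out$mirnas, c("mir1", "mir1"))

  # shared miRNA targeting only lncRNAs yields nothing
  tl <- make_targets(mirs, c("B", "C"), c("A", "E"),
                     lnc_edges = rbind(c("mir1", "A"), c("mir1", "E")))
  expect_equal(nrow(extract_interactions(c("A", "E"), c("B", "C"), "mir1",
                                         tl)), 0)

  # 3 miRNAs x (5 lncRNAs, 20 mRNAs) fully connected: 100 pairs
  lnc <- paste0("L", 1:5); mr <- paste0("M", 1:20)
  full <- make_targets(mirs, mr, lnc,
                       mr_edges = as.matrix(expand.grid(mirs, mr)),
                       lnc_edges = as.matrix(expand.grid(mirs, lnc)))
  pairs <- extract_interactions(lnc, mr, mirs, full)
  expect_equal(nrow(pairs), 100)
  expect_true(all(pairs$mirnas == "mir1;mir2;mir3"))

  deg <- lncrna_outdegree(pairs)
  expect_equal(deg$out_degree, rep(20, 5))
  expect_equal(deg$lncrna, sort(lnc))
})

test_that("out-degree ranking counts distinct partners with stable ties", {
  ints <- data.frame(lncrna = c("A", "A", "D", "A"),
                     mrna = c("B", "C", "B", "B"))
  deg <- lncrna_outdegree(ints)
  expect_equal(deg$lncrna, c("A", "D"))
  expect_equal(deg$out_degree, c(2L, 1L))
  expect_equal(nrow(lncrna_outdegree(ints[0, ])), 0)
})
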