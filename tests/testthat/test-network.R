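test_that("signed similarity maps r = 1, -1, 0 to 1, 0, 0.5", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 5)  # some positive correlation
  expr <- rbind(a = x, b = 2 * x + 3, c = -x, d = y)
  colnames(expr) <- paste0("s", 1:5)
  s <- signed_similarity(expr)
  expect_equal(s["a", "b"], 1)
  expect_equal(s["a", "c"], 0)
  # orthogonal pair constructed to have exactly zero correlation
  u <- c(1, -1, 1, -1, 0)
  v <- c(1, 1, -1, -1, 0)
  s2 <- signed_similarity(rbind(u = u, v = v,
                                w = c(0.5, 1, 2, 0, 1))[, 1:5])
  expect_equal(s2["u", "v"], 0.5)
  expect_true(isSymmetric(s))
  expect_true(all(s >= 0 & s <= 1))
  expect_error(signed_similarity(rbind(a = x, k = rep(2, 5))), "k")
})

test_that("soft thresholding is monotone in the power", {
  sim <- generate_bundle(one_module_spec(beta = 0.5, seed = 2,
                                         n_samples = 40))
  s <- signed_similarity(rbind(sim$bundle$mrna, sim$bundle$lncrna))
  a1 <- soft_adjacency(s, 4)
  a2 <- soft_adjacency(s, 9)
  expect_true(all(a2 <= a1 + 1e-12))
  expect_true(all(a1 >= 0 & a1 <= 1))
})

test_that("scale-free fit is 1 on an exact power law and signed", {
  # rows engineered so connectivity takes values 1, 2, 4, 8 with
  # frequencies proportional to 1/k: log-log points fall on one line
  k <- rep(c(1, 2, 4, 8), times = c(8, 4, 2, 1))
  n <- length(k)
  a <- sapply(seq_len(n), function(j) k / (n - 1))
  a <- t(a)  # row i sums (excluding diagonal) to k_i
  diag(a) <- 0
  a <- a / rowSums(a) * k  # exact row sums after zeroing the diagonal
  expect_equal(suppressWarnings(scale_free_fit(a, n_bins = 10)), 1,
               tolerance = 1e-6)  # lm warns on an exactly perfect fit

  # frequency increasing with k gives a negative index
  k_inc <- rep(c(1, 2, 4, 8), times = c(1, 2, 4, 8))
  n2 <- length(k_inc)
  a2 <- t(sapply(seq_len(n2), function(i) rep(k_inc[i] / (n2 - 1), n2)))
  diag(a2) <- 0
  a2 <- a2 / rowSums(a2) * k_inc
  expect_lt(suppressWarnings(scale_free_fit(a2, n_bins = 10)), 0)

  # near-uniform connectivity has a poor fit
  set.seed(4)
  expr <- matrix(rnorm(500 * 30), 500,
                 dimnames = list(sprintf("g%03d", 1:500), NULL))
  colnames(expr) <- paste0("s", 1:30)
  fit <- scale_free_fit(soft_adjacency(signed_similarity(expr), 1))
  expect_lt(abs(fit), 0.3)

  expect_error(scale_free_fit(matrix(0.5, 4, 4)), "identical")
})

test_that("soft-threshold selection returns the first saturated power", {
  sim <- generate_bundle(one_module_spec(beta = 0.8, seed = 6,
                                         n_samples = 60, n_lnc = 10,
                                         n_mr = 40))
  s <- signed_similarity(rbind(sim$bundle$mrna, sim$bundle$lncrna))
  pk <- suppressWarnings(pick_soft_threshold(s, powers = c(2, 6, 10, 14)))
  expect_true(pk$power %in% c(2, 6, 10, 14))
  hit <- which(pk$fits$r2 >= 0.8)
  if (length(hit)) {
    expect_true(pk$saturated)
    expect_equal(pk$power, pk$fits$power[hit[1]])
  } else {
    expect_false(pk$saturated)
    expect_equal(pk$power, pk$fits$power[which.max(pk$fits$r2)])
  }
  # deterministic: same similarity, same choice
  pk2 <- suppressWarnings(pick_soft_threshold(s, powers = c(2, 6, 10, 14)))
  expect_identical(pk, pk2)
})

test_that("TOM matches its definition by hand and by brute force", {
  a <- matrix(1, 3, 3)
  tom <- topological_overlap(a)
  expect_equal(tom[1, 2], 1)  # (1 + 1) / (2 + 1 - 1)

  a0 <- diag(4)
  expect_true(all(topological_overlap(a0)[upper.tri(a0)] == 0))

  set.seed(11)
  for (i in 1:100) {
    a <- matrix(runif(36), 6, 6)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    expect_equal(topological_overlap(a), brute_tom(a), tolerance = 1e-12)
  }
  # symmetry and range on a random instance
  tom <- topological_overlap(a)
  expect_true(isSymmetric(tom))
  expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
})

test_that("tree cut recovers planted blocks and ignores noise", {
  set.seed(20)
  n <- 100
  f1 <- rnorm(n); f2 <- rnorm(n)
  block <- function(f, ids) {
    m <- t(sapply(seq_along(ids), function(i) 2 * f + rnorm(n)))
    rownames(m) <- ids
    m
  }
  expr <- rbind(block(f1, sprintf("a%02d", 1:60)),
                block(f2, sprintf("b%02d", 1:60)),
                matrix(rnorm(40 * n), 40,
                       dimnames = list(sprintf("n%02d", 1:40), NULL)))
  colnames(expr) <- sprintf("s%03d", 1:n)
  tom <- topological_overlap(soft_adjacency(signed_similarity(expr), 6))
  mods <- cut_modules(tom, min_module_size = 50)
  expect_equal(length(unique(mods$labels[mods$labels > 0])), 2)
  for (prefix in c("a", "b")) {
    planted <- grep(prefix, names(mods$labels), value = TRUE)
    lab <- mods$labels[planted]
    top <- sort(table(lab[lab > 0]), decreasing = TRUE)[1]
    expect_gte(as.integer(top), 55)
  }

  # pure noise: no module of 50 emerges
  noise <- matrix(rnorm(100 * n), 100,
                  dimnames = list(sprintf("x%03d", 1:100),
                                  colnames(expr)))
  tn <- topological_overlap(soft_adjacency(signed_similarity(noise), 6))
  mn <- cut_modules(tn, min_module_size = 50)
  expect_lte(length(unique(mn$labels[mn$labels > 0])), 1)

  # min size above gene count: everything unassigned
  m0 <- cut_modules(tn, min_module_size = 200)
  expect_true(all(m0$labels == 0))
})

test_that("module eigengene summarizes, aligns and explains variance", {
  n <- 50
  samples <- paste0("s", 1:n)
  set.seed(30)
  prof <- rnorm(n)
  # identical genes: ME equals the shared standardized profile
  expr <- rbind(g1 = prof, g2 = prof, g3 = prof)
  colnames(expr) <- samples
  labels <- c(g1 = 1L, g2 = 1L, g3 = 1L)
  me <- module_eigengene(expr, labels)
  expect_equal(unname(me$eigengenes["ME1", ]),
               unname(scale(prof)[, 1]), tolerance = 1e-8)
  expect_equal(unname(me$var_explained["ME1"]), 1)

  # two perfectly anti-correlated genes: the standardized submatrix has
  # rank 1, so the first component carries all the variance; the ME is
  # still unit-variance even though the mean profile is zero
  expr2 <- rbind(g1 = prof, g2 = -prof)
  colnames(expr2) <- samples
  me2 <- module_eigengene(expr2, c(g1 = 1L, g2 = 1L))
  expect_equal(unname(me2$var_explained["ME1"]), 1)
  expect_equal(sd(me2$eigengenes["ME1", ]), 1)
  expect_equal(abs(cor(me2$eigengenes["ME1", ], prof)), 1)

  # planted single-factor module: ME recovers the latent factor
  f <- rnorm(150)
  mod <- t(sapply(1:50, function(i) f + rnorm(150, sd = 0.5)))
  dimnames(mod) <- list(sprintf("m%02d", 1:50), sprintf("t%03d", 1:150))
  me3 <- module_eigengene(mod, setNames(rep(1L, 50), rownames(mod)))
  expect_gt(abs(cor(me3$eigengenes["ME1", ], f)), 0.95)
  # sign alignment with the module mean profile
  expect_gte(cor(me3$eigengenes["ME1", ], colMeans(t(scale(t(mod))))), 0)
})

test_that("module-trait correlation gives exact r and t-based p", {
  n <- 40
  set.seed(31)
  trait <- rnorm(n)
  me <- rbind(ME1 = trait, ME2 = rnorm(n))
  colnames(me) <- paste0("s", 1:n)
  traits <- data.frame(diagnosis = trait, case = rbinom(n, 1, 0.5))
  out <- module_trait_correlation(me, traits)
  r1 <- out[out$module == "ME1" & out$trait == "diagnosis", ]
  expect_equal(r1$r, 1)
  expect_lt(r1$p, 1e-12)
  # orthogonal by construction
  resid <- residuals(lm(rnorm(n) ~ trait))
  me2 <- rbind(ME1 = resid)
  colnames(me2) <- paste0("s", 1:n)
  out2 <- module_trait_correlation(me2, data.frame(diagnosis = trait))
  expect_lt(abs(out2$r), 1e-10)
  expect_error(
    module_trait_correlation(me, data.frame(diagnosis = rep(1, n))),
    "constant")
})
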