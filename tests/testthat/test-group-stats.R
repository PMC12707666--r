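# Group inference: sign-flip permutation, Benjamini-Hochberg, paired
# contrasts and the repeated-measures ANOVA.

test_that("sign-flip permutation enumerates 2^N assignments and is exact", {
  set.seed(1)
  maps <- matrix(rnorm(11 * 6), 11, 6)
  pr <- signflip_permutation(maps)
  expect_true(pr$exhaustive)
  expect_equal(pr$n_permutations, 2048)
  # p-values are multiples of 1/2^N and never zero
  expect_true(all(pr$p > 0))
  expect_true(all(abs(pr$p * 2048 - round(pr$p * 2048)) < 1e-9))
  # degenerate all-zero maps -> p = 1 everywhere
  pr0 <- signflip_permutation(matrix(0, 5, 3))
  expect_true(all(pr0$p == 1))
  # the fast colMeans path agrees with an explicit statistic loop
  pr_slow <- signflip_permutation(maps, statistic = function(m) {
    apply(m, 2, mean)
  })
  # summation order can flip >= ties at machine precision; allow a few
  expect_lt(max(abs(pr$p - pr_slow$p)), 3 / 2048)
  # Monte-Carlo path includes the identity and is seeded
  big <- matrix(rnorm(15 * 2), 15, 2)
  prm1 <- signflip_permutation(big, exhaustive_limit = 12, seed = 3)
  prm2 <- signflip_permutation(big, exhaustive_limit = 12, seed = 3)
  expect_false(prm1$exhaustive)
  expect_identical(prm1$p, prm2$p)
  expect_true(all(prm1$p > 0))
  expect_error(signflip_permutation(matrix(1, 1, 2)), "2 subjects")
  expect_error(signflip_permutation(matrix(c(1, NA), 2, 1)), "non-finite")
})

test_that("sign-flip test type-I error is nominal on null simulations", {
  set.seed(10)
  rej <- vapply(1:1000, function(i) {
    maps <- matrix(rnorm(11), 11, 1)
    signflip_permutation(maps)$p[1] <= 0.05
  }, TRUE)
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / 1000)
  expect_gte(mean(rej), ci[1])
  expect_lte(mean(rej), ci[2])
})

test_that("Benjamini-Hochberg matches brute-force step-up and p.adjust", {
  # all p = 1 -> nothing significant; single p at m = 1 -> raw threshold
  expect_false(any(fdr_bh(rep(1, 10))$significant))
  expect_true(fdr_bh(0.04)$significant)
  expect_false(fdr_bh(0.06)$significant)
  set.seed(4)
  p <- c(runif(70), rbeta(30, 0.2, 6))
  res <- fdr_bh(p)
  # brute-force step-up enumeration
  o <- order(p); m <- length(p)
  q_bf <- numeric(m)
  for (i in seq_len(m)) {
    q_bf[o[i]] <- min(vapply(i:m, function(j) p[o[j]] * m / j, 1), 1)
  }
  expect_equal(res$q, q_bf, tolerance = 1e-12)
  expect_equal(res$q, p.adjust(p, "BH"), tolerance = 1e-12)
  # monotone in the raw p ordering
  expect_true(all(diff(res$q[o]) >= -1e-12))
  expect_error(fdr_bh(numeric(0)), "empty")
  expect_error(fdr_bh(c(0.5, 0)), "0, 1")
})

test_that("BH controls the false discovery rate on mixed simulations", {
  set.seed(11)
  fdp <- vapply(1:200, function(i) {
    p_null <- runif(150)
    p_alt <- rbeta(50, 0.1, 8)
    res <- fdr_bh(c(p_null, p_alt), q_level = 0.05)
    disc <- which(res$significant)
    if (!length(disc)) return(0)
    mean(disc <= 150)
  }, numeric(1))
  expect_lte(mean(fdp), 0.05 + 2 * sd(fdp) / sqrt(200))
})

test_that("paired contrasts reproduce the printed effect sizes", {
  # dz identities from t statistics at N = 11
  expect_equal(round(cohens_dz(-4.01, 11), 2), 1.21)
  expect_equal(round(cohens_dz(-2.46, 11), 2), 0.74)
  expect_equal(round(cohens_dz(-9.00, 11), 2), 2.71)
  set.seed(5)
  a <- rnorm(11, mean = 0.6); b <- rnorm(11)
  pc <- paired_contrast(a, b)
  tt <- t.test(a, b, paired = TRUE)
  expect_equal(pc$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(pc$p, tt$p.value, tolerance = 1e-10)
  expect_equal(pc$dz, abs(pc$t) / sqrt(11))
  # retrospective power against power.t.test as an independent oracle
  # power.t.test drops the opposite-tail term (~1e-6 here)
  pw <- power.t.test(n = 11, delta = pc$dz, sd = 1, sig.level = 0.05,
                     type = "paired")$power
  expect_equal(pc$power, pw, tolerance = 1e-5)
  # exact two-sided noncentral-t oracle, written out independently
  pw_exact <- 1 - diff(pt(c(-1, 1) * qt(0.975, 10), df = 10,
                          ncp = abs(pc$t)))
  expect_equal(pc$power, pw_exact, tolerance = 1e-10)
  # degenerate zero-variance differences are flagged
  pd <- paired_contrast(a, a)
  expect_true(pd$degenerate)
  expect_true(is.na(pd$t))
})

test_that("the three-way RM-ANOVA matches the aov() oracle", {
  set.seed(6)
  N <- 11
  d <- expand.grid(s = factor(1:N), hemi = factor(1:2),
                   layer = factor(1:3), model = factor(1:4))
  d$y <- rnorm(nrow(d)) + 0.4 * as.numeric(d$model) +
    0.2 * as.numeric(d$layer) * (d$hemi == 1)
  res <- rm_anova_3way(d$y, d$s, d$hemi, d$layer, d$model)
  # a 4-level factor with N = 11 gives df = (3, 30)
  expect_equal(res$df1[res$effect == "C"], 3)
  expect_equal(res$df2[res$effect == "C"], 30)
  fit <- summary(aov(y ~ hemi * layer * model +
                       Error(s / (hemi * layer * model)), data = d))
  F_aov <- vapply(fit[-1], function(x) x[[1]][1, "F value"], numeric(1))
  expect_equal(res$F, unname(F_aov), tolerance = 1e-8)
  # eta_p^2 identity
  expect_equal(res$pes, partial_eta_squared(res$F, res$df1, res$df2),
               tolerance = 1e-12)
  expect_equal(round(partial_eta_squared(15.59, 3, 30), 3), 0.609)
  # all-equal data -> all F = 0
  res0 <- rm_anova_3way(rep(2, nrow(d)), d$s, d$hemi, d$layer, d$model)
  expect_true(all(res0$F == 0))
  expect_error(rm_anova_3way(d$y[-1], d$s[-1], d$hemi[-1], d$layer[-1],
                             d$model[-1]), "balanced")
})
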