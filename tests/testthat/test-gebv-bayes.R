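# The Bayesian alphabet Gibbs samplers.

test_that("no signal gives zero effects and mu near the phenotype mean", {
  set.seed(61)
  geno <- hwe_genotypes(40, 60)
  y <- setNames(rep(2.5, 40), rownames(geno))
  y <- y + rnorm(40, 0, 1e-6) # keep var(y) defined but essentially constant
  fit <- gebv(y, geno, "BRR", h2 = 0.3,
              chain = chain_control(2000, 500, 5))
  expect_lt(max(abs(coef(fit))), 1e-3)
  expect_equal(fit$mu, 2.5, tolerance = 1e-3)
})

test_that("conjugate BRR matches the closed-form ridge solution", {
  set.seed(62)
  n <- 30; p <- 100
  geno <- hwe_genotypes(n, p)
  b <- rnorm(p, 0, 0.08)
  y <- setNames(drop(geno %*% b) + rnorm(n, 0, 0.8), rownames(geno))
  h2 <- 0.5
  fit <- gebv(y, geno, "BRR", h2 = h2, fix_variances = TRUE,
              chain = chain_control(20000, 5000, 5))
  # closed form at the same fixed variances
  pf <- colMeans(geno) / 2
  Mc <- sweep(geno, 2, 2 * pf)
  s2m <- h2 * var(unname(y)) / (2 * sum(pf * (1 - pf)))
  s2e <- (1 - h2) * var(unname(y))
  lam <- s2e / s2m
  LHS <- rbind(cbind(n, t(rep(1, n)) %*% Mc),
               cbind(crossprod(Mc, rep(1, n)), crossprod(Mc) + lam * diag(p)))
  sol <- solve(LHS, c(sum(y), crossprod(Mc, unname(y))))
  rms <- sqrt(mean((coef(fit) - sol[-1])^2))
  expect_lt(rms, 0.02)
})

test_that("BayesA and BRR agree on polygenic data and recover sigma2_e", {
  set.seed(63)
  n <- 500; p <- 1000
  geno <- hwe_genotypes(n, p)
  h2 <- 0.4
  model <- scale_to_heritability(rnorm(p), geno, h2 = h2)
  tbv <- compute_tbv(geno, model)
  y <- setNames(simulate_phenotype(tbv, h2), rownames(geno))
  ch <- chain_control(2500, 500, 5)
  fa <- gebv(y, geno, "BayesA", h2 = h2, chain = ch)
  fr <- gebv(y, geno, "BRR", h2 = h2, chain = ch)
  expect_gt(cor(fa$gebv, fr$gebv), 0.95)
  # posterior-mean residual variance within 3 posterior SDs of the truth
  s2e <- fr$s2e_samples
  expect_lt(abs(mean(s2e) - (1 - h2)), 3 * sd(s2e) + 0.02)
  # both track the true breeding values
  expect_gt(cor(fa$gebv, tbv), 0.5)
})

test_that("BayesB concentrates on causal markers under a sparse architecture", {
  set.seed(64)
  n <- 300; p <- 400
  geno <- hwe_genotypes(n, p)
  causal <- sample(p, 10)
  eff <- numeric(p); eff[causal] <- rnorm(10, 0, 0.5)
  tbv <- drop(scale(geno %*% eff, scale = sqrt(var(geno %*% eff) / 0.4)))
  y <- setNames(tbv + rnorm(n, 0, sqrt(0.6)), rownames(geno))
  fit <- gebv(y, geno, "BayesB", h2 = 0.4, pi0 = 0.95,
              chain = chain_control(1500, 300, 3))
  expect_gt(mean(fit$pip[causal]), mean(fit$pip[-causal]))
  expect_gt(cor(fit$gebv, tbv), 0.5)
  expect_error(gebv(y, geno, "BayesB", h2 = 0.4,
                    chain = chain_control(100, 200)), "burn-in")
})

test_that("Bayesian LASSO fits and marker-effect prediction is consistent", {
  set.seed(65)
  n <- 200; p <- 300
  geno <- hwe_genotypes(n, p)
  model <- scale_to_heritability(rnorm(p), geno, h2 = 0.4)
  tbv <- compute_tbv(geno, model)
  yall <- simulate_phenotype(tbv, 0.4)
  ref <- 1:150
  y <- setNames(yall[ref], rownames(geno)[ref])
  fit <- gebv(y, geno, "BL", h2 = 0.4, chain = chain_control(1500, 300, 3))
  expect_gt(cor(fit$gebv, tbv), 0.3)
  expect_gt(fit$lambda2, 0)
  # predict on the fitted genotypes reproduces the stored GEBV exactly
  pr <- predict(fit, geno)
  expect_equal(pr, fit$gebv, tolerance = 1e-12)
  # single-term prediction: one marker, effect 1, centering frequency p
  toy <- structure(list(method = "BRR", effects = 1.0, p = 0.3,
                        gebv = NULL), class = "gebv")
  g1 <- matrix(c(0, 1, 2), 3, 1, dimnames = list(c("x", "y", "z"), NULL))
  expect_equal(unname(predict(toy, g1)), c(0, 1, 2) - 0.6)
  # all-zero effects give all-zero GEBV
  toy$effects <- 0
  expect_equal(unname(predict(toy, g1)), c(0, 0, 0))
  expect_error(predict(fit, geno[, 1:10]), "panel mismatch")
})
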