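# GBLUP and single-step GBLUP: closed forms, algebraic equivalences,
# permutation invariance.

test_that("GBLUP with identity G reduces to the unrelated closed form", {
  set.seed(51)
  n <- 20; nref <- 14
  geno <- hwe_genotypes(n, 50)
  y <- setNames(rnorm(nref), rownames(geno)[1:nref])
  fit <- gebv(y, geno, "GBLUP", h2 = 0.4, G = diag(n), blend = 0)
  expect_equal(unname(fit$gebv[1:nref]),
               0.4 * (unname(y) - fit$mu), tolerance = 1e-8)
  expect_equal(unname(fit$gebv[(nref + 1):n]), rep(0, n - nref),
               tolerance = 1e-10)
})

test_that("GBLUP equals RR-BLUP with matched variances", {
  set.seed(52)
  n <- 50; p <- 200; nref <- 35
  geno <- hwe_genotypes(n, p)
  b <- rnorm(p, 0, 0.05)
  y_all <- drop(geno %*% b) + rnorm(n, 0, 0.7)
  y <- setNames(y_all[1:nref], rownames(geno)[1:nref])
  h2 <- 0.45
  fit <- gebv(y, geno, "GBLUP", h2 = h2, blend = 0)
  # independent ridge-regression oracle: joint MME over (mu, marker effects)
  # with lambda_m = sigma_e^2 / sigma_m^2 and sigma_m^2 = sigma_a^2 / (2*sum pq)
  pf <- colMeans(geno) / 2
  denom <- 2 * sum(pf * (1 - pf))
  Mc <- sweep(geno, 2, 2 * pf)
  Mr <- Mc[1:nref, , drop = FALSE]
  lambda_m <- (1 - h2) / h2 * denom
  LHS <- rbind(cbind(nref, t(rep(1, nref)) %*% Mr),
               cbind(crossprod(Mr, rep(1, nref)),
                     crossprod(Mr) + lambda_m * diag(p)))
  rhs <- c(sum(y), crossprod(Mr, unname(y)))
  sol <- solve(LHS, rhs)
  gebv_rr <- drop(Mc %*% sol[-1])
  expect_lt(max(abs(unname(fit$gebv) - gebv_rr)), 1e-6)
  expect_lt(abs(fit$mu - sol[1]), 1e-6)
  # marker-effect backsolve agrees too
  expect_lt(max(abs(coef(fit) - sol[-1])), 1e-6)
})

test_that("permuting individuals permutes GEBV identically", {
  set.seed(53)
  geno <- hwe_genotypes(30, 80)
  y <- setNames(rnorm(20), rownames(geno)[1:20])
  f1 <- gebv(y, geno, "GBLUP", h2 = 0.3)
  perm <- sample(nrow(geno))
  f2 <- gebv(y, geno[perm, ], "GBLUP", h2 = 0.3)
  expect_equal(f2$gebv[names(f1$gebv)], f1$gebv, tolerance = 1e-9)
})

test_that("ssGBLUP collapses to pedigree BLUP when G carries no information", {
  set.seed(54)
  ped <- random_pedigree(8, 52)
  n <- nrow(ped)
  geno <- hwe_genotypes(n, 120, ids = as.character(ped$id))
  y <- setNames(rnorm(40), as.character(sample(ped$id, 40)))
  pfit <- pedigree_blup(y, ped, h2 = 0.35)

  # all animals genotyped, G forced equal to A
  A <- pedigree_A(ped)
  sfit <- gebv(y, geno, "ssGBLUP", h2 = 0.35, pedigree = ped,
               G = unname(A), blend = 0, tune = FALSE)
  expect_lt(max(abs(sfit$gebv - pfit$ebv)), 1e-6)

  # blending weight 1: the genotyped-block correction vanishes
  sfit2 <- gebv(y, geno, "ssGBLUP", h2 = 0.35, pedigree = ped, blend = 1)
  expect_lt(max(abs(sfit2$gebv - pfit$ebv)), 1e-6)
})

test_that("information flows through A to ungenotyped relatives", {
  set.seed(55)
  # ungenotyped dam (id 2) of genotyped progeny receives a nonzero GEBV
  ped <- data.frame(id = 1:6, sire = c(0, 0, 1, 1, 1, 1),
                    dam = c(0, 0, 2, 2, 2, 2),
                    sex = c("M", "F", rep("M", 4)))
  geno <- hwe_genotypes(5, 100, ids = as.character(c(1, 3:6)))
  y <- setNames(rnorm(4, mean = 1), as.character(3:6))
  fit <- gebv(y, geno, "ssGBLUP", h2 = 0.4, pedigree = ped)
  expect_true(abs(fit$gebv[["2"]]) > 1e-8)
  expect_error(gebv(y, hwe_genotypes(2, 10, ids = c("77", "3")), "ssGBLUP",
                    h2 = 0.4, pedigree = ped), "missing from the pedigree")
})
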