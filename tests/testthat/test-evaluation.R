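# Reference/validation design, accuracy, ANOVA and Duncan's test.

test_that("reference/validation split honors sizes, windows and composition", {
  set.seed(81)
  sim <- simulate_breeding(micro_config(), trait_config(0.34, "low"))
  sp <- split_reference_validation(sim, ref_size = 150, val_size = 100)
  expect_length(sp$ref, 150L)
  expect_length(sp$val, 100L)
  expect_length(intersect(sp$ref, sp$val), 0L)
  ped <- sim$pop$ped
  expect_true(all(ped$gen[match(as.numeric(sp$ref), ped$id)] %in% 2:7))
  expect_true(all(ped$gen[match(as.numeric(sp$val), ped$id)] %in% 8:10))
  sp2 <- split_reference_validation(sim, 120, 60,
                                    sex_composition = c(M = 40, F = 80))
  sx <- ped$sex[match(as.numeric(sp2$ref), ped$id)]
  expect_equal(sum(sx == "M"), 40L)
  expect_error(split_reference_validation(sim, 310, 60,
                                          sex_composition = c(M = 300, F = 10)),
               "only")
  expect_error(split_reference_validation(sim, 10000, 60), "pool")
})

test_that("accuracy is the Pearson correlation with guarded degenerate cases", {
  expect_equal(compute_accuracy(1:5, 1:5), 1)
  expect_equal(compute_accuracy(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(compute_accuracy(c(1, 2, 3), c(1, 2, 4)), 0.98198,
               tolerance = 1e-5)
  expect_error(compute_accuracy(1:3, rep(1, 3)), "variance")
  expect_error(compute_accuracy(1:2, 1:2), "at least 3")
})

test_that("experiment designs have the study's record counts", {
  d <- main_design()
  expect_equal(nrow(d), 216L)    # (4 + 3 + 5) levels x 6 methods x 3 reps
  s <- sex_design()
  expect_equal(nrow(s), 108L)    # 6 x 6 x 3
  # empty design passes through run_factorial untouched
  empty <- d[0, ]
  expect_equal(nrow(run_factorial(empty, function(...) 0.5)), 0L)
  # runner is called once per record
  filled <- run_factorial(d, function(f, l, m, r) 0.5)
  expect_true(all(filled$accuracy == 0.5))
})

test_that("sequential ANOVA reproduces classical identities", {
  set.seed(82)
  # one factor, two balanced groups: F equals the squared pooled t statistic
  g <- rep(c("a", "b"), each = 12)
  y <- rnorm(24) + (g == "b") * 0.8
  rec <- data.frame(grp = g, accuracy = y)
  tab <- anova_glm(rec, factors = "grp")
  tt <- t.test(y ~ g, var.equal = TRUE)$statistic
  expect_equal(tab$F[1], unname(tt)^2, tolerance = 1e-10)
  # SS are non-negative and sum to the corrected total exactly
  d <- design_records(run_factorial(main_design(),
                                    function(...) runif(1, 0.3, 0.7)))
  tab2 <- anova_glm(d, factors = c("marker_density", "n_qtl", "ref_size",
                                   "method"))
  expect_true(all(tab2$SS >= 0))
  k <- nrow(tab2)
  expect_equal(sum(tab2$SS[1:(k - 1)]), tab2$SS[k], tolerance = 1e-10)
  expect_error(anova_glm(rec[rec$grp == "a", ], factors = "grp"), "levels")
})

test_that("Duncan's test separates exactly at the protected critical range", {
  mse <- 0.02; n <- 6; dfe <- 20
  crit2 <- qtukey(0.95, 2, dfe) * sqrt(mse / n) # span-2 range, approx 2.95 q
  m <- c(a = 0.5, b = 0.5 + crit2 * 1.01)
  out <- duncan_mrt(m, n, mse, dfe)
  expect_false(any(out$group[1] == out$group[2]))
  m2 <- c(a = 0.5, b = 0.5 + crit2 * 0.99)
  out2 <- duncan_mrt(m2, n, mse, dfe)
  expect_equal(out2$group[1], out2$group[2])
  # identical means share one letter
  out3 <- duncan_mrt(c(x = 0.4, y = 0.4, z = 0.4), n, mse, dfe)
  expect_true(all(out3$group == "a"))
  expect_error(duncan_mrt(c(a = 1), n, mse, dfe), "2 levels")
})

test_that("letter groupings are order-consistent on random instances", {
  set.seed(83)
  for (rep in 1:20) {
    k <- sample(3:7, 1)
    m <- setNames(runif(k), letters[1:k])
    out <- duncan_mrt(m, n = sample(3:8, 1), ms_error = runif(1, 0.005, 0.05),
                      df_error = sample(10:40, 1))
    # each letter marks one contiguous run of the ordered means
    for (L in unique(unlist(strsplit(out$group, "")))) {
      hit <- grepl(L, out$group)
      expect_true(all(diff(which(hit)) == 1))
    }
    # every level carries at least one letter
    expect_true(all(nchar(out$group) >= 1))
  }
})

test_that("one-factor-at-a-time records expand against per-trait baselines", {
  d <- design_records(main_design(), trait = "FD")
  expect_equal(nrow(d), 216L)
  expect_equal(sort(unique(d$marker_density)), sort(c("15K", "30K", "45K",
                                                      "60K")))
  # rows varying other factors sit at the FD baseline
  sub <- d[d$ref_size == "500", ]
  expect_true(all(sub$marker_density == "60K" & sub$n_qtl == "150"))
  dl <- design_records(main_design(), trait = "LBW")
  expect_true(all(dl$marker_density[dl$ref_size == "500"] == "45K"))
})
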