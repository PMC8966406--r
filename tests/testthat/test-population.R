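# The three-phase population process.

test_that("historical phase hits the configured sizes and terminal sex split", {
  set.seed(71)
  map <- tiny_map(40, 5)
  cfg <- sim_config(chrom_lengths = c(100, 80), n_markers = 40, n_qtl = 5,
                    hist_gens1 = 5, hist_size1 = 40,
                    hist_gens2 = 5, hist_size2 = 60,
                    hist_males2 = 20, hist_females2 = 40)
  pop <- run_historical(cfg, map)
  expect_equal(nrow(pop$ped), 60L)
  expect_equal(sum(pop$ped$sex == "M"), 20L)
  expect_equal(unique(pop$ped$gen), 10L)
  # zero generations returns the founders unchanged
  cfg0 <- sim_config(chrom_lengths = c(100, 80), n_markers = 40, n_qtl = 5,
                     hist_gens1 = 0, hist_size1 = 40, hist_gens2 = 0,
                     hist_size2 = 40, hist_males2 = 20, hist_females2 = 20)
  pop0 <- run_historical(cfg0, map)
  expect_equal(nrow(pop0$ped), 40L)
  expect_equal(unique(pop0$ped$gen), 0L)
})

test_that("expansion produces full litters and caps preserve the sex ratio", {
  set.seed(72)
  map <- tiny_map(30, 4)
  cfg <- sim_config(chrom_lengths = c(100, 80), n_markers = 30, n_qtl = 4,
                    hist_gens1 = 2, hist_size1 = 30, hist_gens2 = 0,
                    hist_size2 = 30, hist_males2 = 15, hist_females2 = 15,
                    exp_males = 4, exp_females = 10, exp_gens = 1,
                    exp_litter = 5, exp_cap = 100)
  hist <- run_historical(cfg, map)
  expd <- run_expansion(hist, cfg, map)
  expect_equal(nrow(expd$ped), 50L) # 10 dams x 5 offspring, below the cap
  # offspring sex ratio is Bernoulli(1/2): binomial test non-rejecting
  expect_gt(binom.test(sum(expd$ped$sex == "M"), 50, 0.5)$p.value, 0.001)
  # with a binding cap the realised sex ratio is preserved proportionally
  cfg2 <- sim_config(chrom_lengths = c(100, 80), n_markers = 30, n_qtl = 4,
                     hist_gens1 = 2, hist_size1 = 30, hist_gens2 = 0,
                     hist_size2 = 30, hist_males2 = 15, hist_females2 = 15,
                     exp_males = 4, exp_females = 10, exp_gens = 1,
                     exp_litter = 5, exp_cap = 30)
  expd2 <- run_expansion(hist, cfg2, map)
  expect_equal(nrow(expd2$ped), 30L)
  # zero expansion generations: founders returned unchanged
  cfg3 <- sim_config(chrom_lengths = c(100, 80), n_markers = 30, n_qtl = 4,
                     hist_gens1 = 2, hist_size1 = 30, hist_gens2 = 0,
                     hist_size2 = 30, hist_males2 = 15, hist_females2 = 15,
                     exp_males = 4, exp_females = 10, exp_gens = 0)
  expect_equal(nrow(run_expansion(hist, cfg3, map)$ped), 14L)
})

test_that("recent generations are Mendelian-consistent with sane demography", {
  set.seed(73)
  cfg <- micro_config(rec_gens = 4)
  sim <- simulate_breeding(cfg, trait_config(0.34, "low"))
  ped <- sim$pop$ped
  haps <- sim$pop$haps
  # generation sizes: every dam produces 1 or 2 offspring
  for (g in 1:4) {
    n_off <- sum(ped$gen == g)
    expect_gte(n_off, 40)       # >= 1 per dam
    expect_lte(n_off, 80)       # <= 2 per dam
    expect_true(all(c("M", "F") %in% ped$sex[ped$gen == g]))
  }
  # pedigree is acyclic with parents preceding offspring and sexes correct
  expect_silent(gselsim:::check_pedigree(ped))
  # exhaustive Mendelian spot-check on 25 offspring
  off <- sample(which(ped$gen > 0), 25)
  for (k in off) {
    s <- ped$sire[k]; d <- ped$dam[k]
    pat <- haps[, 2 * k - 1]; mat <- haps[, 2 * k]
    s_ok <- pat == haps[, 2 * s - 1] | pat == haps[, 2 * s]
    d_ok <- mat == haps[, 2 * d - 1] | mat == haps[, 2 * d]
    # allow recurrent mutation: at most a handful of loci may disagree
    expect_lt(sum(!s_ok) + sum(!d_ok), 3)
  }
})

test_that("sire turnover respects the replacement rate", {
  set.seed(74)
  cfg <- micro_config(rec_gens = 5) # 8 sires, replacement 0.8 -> keep 2
  sim <- simulate_breeding(cfg, trait_config(0.34, "low"))
  ped <- sim$pop$ped
  for (g in 2:5) {
    prev <- unique(ped$sire[ped$gen == g - 1])
    cur <- unique(ped$sire[ped$gen == g])
    expect_lte(length(intersect(prev, cur)), 2L)
  }
})

test_that("downward selection reduces the genetic mean", {
  set.seed(75)
  declines <- replicate(10, {
    sim <- simulate_breeding(micro_config(rec_gens = 6),
                             trait_config(0.34, "low"))
    ped <- sim$pop$ped
    mean(ped$tbv[ped$gen == 6]) < mean(ped$tbv[ped$gen == 1])
  })
  expect_gte(sum(declines), 9L)
})

test_that("random replacement disables EBV computation and still runs", {
  set.seed(76)
  cfg <- micro_config(rec_gens = 2, selection = "random")
  sim <- simulate_breeding(cfg, trait_config(0.11, "high"))
  expect_true(all(is.na(sim$pop$ped$ebv)))
  expect_equal(max(sim$pop$ped$gen), 2L)
})

test_that("marker-panel finalization filters by MAF and errors when infeasible", {
  set.seed(77)
  map <- tiny_map(100, 12)
  cfg <- sim_config(chrom_lengths = c(100, 80), n_markers = 100, n_qtl = 12,
                    hist_gens1 = 10, hist_size1 = 50, hist_gens2 = 0,
                    hist_size2 = 50, hist_males2 = 25, hist_females2 = 25)
  pop <- run_historical(cfg, map)
  pan <- finalize_marker_panel(pop, map, n_markers = 50, n_qtl = 8,
                               maf_min = 0.05)
  expect_equal(sum(pan$map$role == "marker"), 50L)
  expect_equal(sum(pan$map$role == "qtl"), 8L)
  expect_equal(nrow(pan$pop$haps), 58L)
  f <- rowMeans(pan$pop$haps[pan$map$role == "marker", ])
  expect_true(all(pmin(f, 1 - f) >= 0.05))
  expect_error(finalize_marker_panel(pop, map, 50, 8, maf_min = 0.5),
               "below 0.5")
  expect_error(finalize_marker_panel(pop, map, 100, 8), "qualify")
  mono <- pop; mono$haps[] <- 0L
  expect_error(finalize_marker_panel(mono, map, 10, 2), "monomorphic")
})
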