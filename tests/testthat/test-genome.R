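# Genome map construction and the meiosis engine.

test_that("genome map satisfies its structural invariants", {
  set.seed(11)
  lens <- c(120, 90, 60)
  map <- build_genome_map(lens, n_markers = 400, n_qtl = 30)
  expect_equal(nrow(map), 430L)
  expect_equal(sum(map$role == "marker"), 400L)
  expect_equal(sum(map$role == "qtl"), 30L)
  expect_equal(sum(attr(map, "chrom_lengths")), sum(lens))
  for (c in 1:3) {
    pos <- map$pos_cM[map$chrom == c]
    expect_true(all(diff(pos) > 0))
    expect_true(all(pos >= 0 & pos < lens[c]))
  }
  # empty case
  empty <- build_genome_map(100, 0, 0)
  expect_equal(nrow(empty), 0L)
  # errors
  expect_error(build_genome_map(c(100, -5), 10, 1), "positive")
  expect_error(build_genome_map(100, -1, 0), "non-negative")
})

test_that("loci fall on chromosomes with probability proportional to length", {
  set.seed(12)
  # two equal chromosomes: per-replicate marker count on chr 1 is
  # Binomial(n, 1/2); the summed squared z-scores are chi-square(reps)
  n <- 2000L; reps <- 100L
  z2 <- replicate(reps, {
    m <- build_genome_map(c(75, 75), n, 0)
    c1 <- sum(m$chrom == 1L)
    (c1 - n / 2)^2 / (n / 4)
  })
  stat <- sum(z2)
  expect_gt(stat, qchisq(5e-4, reps))
  expect_lt(stat, qchisq(1 - 5e-4, reps))
})

test_that("crossover counts match the renewal-process expectation", {
  set.seed(13)
  # shape 1 reduces to Poisson: mean count on a 1-Morgan chromosome is 1
  xo <- gselsim:::cpp_sample_xover_positions(20000L, 1.0, 1.0)
  counts <- lengths(xo)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 1), 3 * se)
  # stationarity at shape 5: expected count still equals length in Morgans
  xo5 <- gselsim:::cpp_sample_xover_positions(20000L, 2.0, 5.0)
  c5 <- lengths(xo5)
  expect_lt(abs(mean(c5) - 2) , 3 * sd(c5) / sqrt(length(c5)))
})

test_that("interference shrinks the spacing coefficient of variation", {
  set.seed(14)
  cv <- function(shape) {
    xo <- gselsim:::cpp_sample_xover_positions(4000L, 10.0, shape)
    sp <- unlist(lapply(xo, diff))
    sd(sp) / mean(sp)
  }
  expect_lt(cv(5), cv(1))
})

test_that("gametes respect parental alleles and homozygote invariance", {
  set.seed(15)
  map <- tiny_map(60, 10)
  L <- nrow(map)
  hom <- rbinom(L, 1, 0.5)
  expect_identical(sample_gamete(hom, hom, map, interference = 5), hom)
  pat <- rbinom(L, 1, 0.5); mat <- rbinom(L, 1, 0.5)
  for (i in 1:20) {
    g <- sample_gamete(pat, mat, map, interference = 5)
    expect_true(all(g == pat | g == mat))
    expect_true(all(g %in% 0:1))
  }
  expect_error(sample_gamete(pat, mat, map, interference = 0), "interference")
})

test_that("recurrent mutation has exact boundaries and binomial counts", {
  set.seed(16)
  h <- rbinom(5000, 1, 0.5)
  expect_identical(apply_mutation(h, 0), h)
  expect_identical(apply_mutation(h, 1), 1L - h)
  expect_error(apply_mutation(h, 1.5), "rate")
  # flip count over many gametes matches the binomial oracle:
  # mean = G * L * rate, var ~ same (small rate)
  rate <- 1e-3; G <- 200L; L <- 5000L
  flips <- sum(replicate(G, sum(apply_mutation(integer(L), rate))))
  mean_o <- G * L * rate
  sd_o <- sqrt(G * L * rate * (1 - rate))
  expect_lt(abs(flips - mean_o), 3 * sd_o)
})
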