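# Shared in-code fixtures: tiny genomes, pedigrees and genotype sets.

tiny_map <- function(n_markers = 30, n_qtl = 5, lengths = c(100, 80)) {
  build_genome_map(lengths, n_markers, n_qtl)
}

# random pedigree with `founders` unrelated animals and `n_off` offspring of
# random earlier parents (parents always precede offspring)
random_pedigree <- function(founders = 6, n_off = 24) {
  n <- founders + n_off
  sex <- c(rep(c("M", "F"), length.out = founders),
           sample(c("M", "F"), n_off, replace = TRUE))
  sire <- dam <- integer(n)
  for (i in (founders + 1):n) {
    males <- which(sex[1:(i - 1)] == "M")
    females <- which(sex[1:(i - 1)] == "F")
    sire[i] <- if (length(males) == 1L) males else sample(males, 1)
    dam[i] <- if (length(females) == 1L) females else sample(females, 1)
  }
  data.frame(id = 1:n, sire = sire, dam = dam, sex = sex)
}

# HWE genotype matrix with uniform allele frequencies
hwe_genotypes <- function(n, m, ids = paste0("id", seq_len(n))) {
  p <- runif(m, 0.1, 0.9)
  g <- sapply(p, function(pp) rbinom(n, 2, pp))
  rownames(g) <- ids
  g
}

# micro end-to-end configuration used by the pipeline and population tests
micro_config <- function(...) {
  sim_profile("desk",
              n_markers = 300, n_qtl = 20, candidate_factor = 1.5,
              hist_gens1 = 30, hist_size1 = 80,
              hist_gens2 = 10, hist_size2 = 120,
              hist_males2 = 40, hist_females2 = 80,
              exp_males = 20, exp_females = 60, exp_gens = 2, exp_cap = 400,
              rec_males = 8, rec_females = 40, ...)
}
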