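# The three-phase population process: a long historical phase building
# linkage disequilibrium by drift and recurrent mutation, a rapid expansion,
# and recent generations run as a production system with pedigree-BLUP
# selection and age-based culling.

#' Simulation configuration
#'
#' All parameters of the three-phase population process and genome. Defaults
#' reproduce the full-scale study configuration: 29 autosomes totalling
#' 2,922 cM; a historical phase of 5,000 generations at N = 1,000 followed by
#' 500 generations growing to 3,000 (400 males / 2,600 females); expansion
#' from 400 males and 2,600 females over 10 generations with 5 offspring per
#' dam; and 10 recent generations from 40 sires and 400 dams with 1-2 progeny
#' per dam, 50% male progeny, EBV selection, replacement rates of 80%
#' (sires) / 30% (dams) and age culling.
#'
#' @param chrom_lengths Chromosome lengths in cM.
#' @param n_markers,n_qtl Target marker and QTL panel sizes after MAF
#'   filtering.
#' @param candidate_factor Candidate loci simulated per retained locus.
#' @param maf_min Minor-allele-frequency threshold for markers.
#' @param mutation_rate Recurrent per-locus flip probability per meiosis.
#' @param interference Gamma shape of the crossover renewal process.
#' @param hist_gens1,hist_size1 Length and constant size of historical
#'   phase 1.
#' @param hist_gens2,hist_size2,hist_males2,hist_females2 Length, terminal
#'   size and terminal sex split of historical phase 2 (sizes interpolate
#'   linearly).
#' @param exp_males,exp_females,exp_gens,exp_litter,exp_cap Expansion
#'   founders, generations, offspring per dam, and the population cap
#'   enforced by random sex-ratio-preserving culling.
#' @param rec_males,rec_females,rec_gens Recent-phase founders and length.
#' @param male_prop Probability a recent-phase offspring is male.
#' @param rep_sires,rep_dams Replacement rates per generation.
#' @param max_age Maximum number of breeding seasons before age culling.
#' @param selection `"ebv"` (pedigree-BLUP truncation selection) or
#'   `"random"` (replacements drawn at random; drift only).
#' @param var_p Phenotypic variance.
#' @return A validated list of class `sim_config`.
#' @seealso [sim_profile()] for the bundled full-scale and desk-scale
#'   configurations.
#' @export
sim_config <- function(chrom_lengths = goat_chrom_lengths(),
                       n_markers = 45000, n_qtl = 100,
                       candidate_factor = 2, maf_min = 0.05,
                       mutation_rate = 9.4e-6, interference = 5,
                       hist_gens1 = 5000, hist_size1 = 1000,
                       hist_gens2 = 500, hist_size2 = 3000,
                       hist_males2 = 400, hist_females2 = 2600,
                       exp_males = 400, exp_females = 2600,
                       exp_gens = 10, exp_litter = 5, exp_cap = 15000,
                       rec_males = 40, rec_females = 400, rec_gens = 10,
                       male_prop = 0.5, rep_sires = 0.8, rep_dams = 0.3,
                       max_age = 5, selection = "ebv", var_p = 1) {
  cfg <- as.list(environment())
  props <- c(cfg$male_prop, cfg$rep_sires, cfg$rep_dams, cfg$maf_min,
             cfg$mutation_rate)
  if (any(props < 0 | props > 1)) stop("all proportions must lie in [0, 1]")
  counts <- c(cfg$n_markers, cfg$n_qtl, cfg$hist_gens1, cfg$hist_size1,
              cfg$hist_gens2, cfg$hist_size2, cfg$exp_gens, cfg$rec_gens)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (cfg$hist_males2 + cfg$hist_females2 != cfg$hist_size2)
    stop("terminal historical sex split must sum to the terminal size")
  if (cfg$exp_cap < cfg$exp_males + cfg$exp_females)
    stop("expansion cap below the founder count")
  if (cfg$interference <= 0) stop("interference must be > 0")
  if (!cfg$selection %in% c("ebv", "random"))
    stop("selection must be 'ebv' or 'random'")
  structure(cfg, class = "sim_config")
}

#' Bundled simulation profiles
#'
#' `"full"` is the full-scale study configuration (hours of runtime at
#' 45 K markers). `"desk"` is a reduced configuration for interactive use and
#' testing: 250 + 50 historical generations at N = 200 growing to 400, a
#' capped expansion, 10 recent generations from 25 sires and 250 dams, and
#' 3,000 markers with 50 QTLs on a 5 x 100 cM genome. The genome is shrunk
#' along with the population so that the ratio of marker spacing to the
#' extent of linkage disequilibrium (about 1/(4Nc)) stays in the regime of
#' the full-scale study; keeping the full 2,922 cM genome at N = 200 would
#' leave adjacent markers effectively unlinked to the QTLs and turn genomic
#' prediction into pure family capture.
#'
#' @param profile `"full"` or `"desk"`.
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_profile <- function(profile = c("desk", "full"), ...) {
  profile <- match.arg(profile)
  base <- if (profile == "full") list() else
    list(chrom_lengths = rep(100, 5), n_markers = 3000, n_qtl = 50,
         hist_gens1 = 250, hist_size1 = 200,
         hist_gens2 = 50, hist_size2 = 400,
         hist_males2 = 100, hist_females2 = 300,
         exp_males = 40, exp_females = 260, exp_gens = 5, exp_cap = 1500,
         rec_males = 25, rec_females = 250)
  dots <- list(...)
  base[names(dots)] <- dots
  do.call(sim_config, base)
}

# --- population container -------------------------------------------------

# A population is a pedigree data.frame plus an L x 2n haplotype matrix;
# individual k (row k of ped) owns haplotype columns 2k-1 (paternal) and
# 2k (maternal).
new_gs_pop <- function(ped, haps) {
  stopifnot(ncol(haps) == 2L * nrow(ped))
  structure(list(ped = ped, haps = haps), class = "gs_pop")
}

#' @export
print.gs_pop <- function(x, ...) {
  cat(sprintf("Population: %d individuals (%d M / %d F), generations %d-%d, %d loci\n",
              nrow(x$ped), sum(x$ped$sex == "M"), sum(x$ped$sex == "F"),
              min(x$ped$gen), max(x$ped$gen), nrow(x$haps)))
  invisible(x)
}

#' Founder population with allele frequency 1/2
#'
#' Creates unrelated founders whose haplotype alleles are i.i.d.
#' Bernoulli(1/2) at every locus; the historical phase then shapes the
#' frequency spectrum by mutation-drift.
#'
#' @param n_males,n_females Founder counts.
#' @param map A `genome_map`.
#' @return A `gs_pop`.
#' @export
founder_population <- function(n_males, n_females, map) {
  n <- n_males + n_females
  L <- nrow(map)
  haps <- matrix(sample(0:1, L * 2L * n, replace = TRUE), nrow = L)
  ped <- data.frame(id = seq_len(n), sire = 0L, dam = 0L,
                    sex = c(rep("M", n_males), rep("F", n_females)),
                    gen = 0L)
  new_gs_pop(ped, haps)
}

# internal: one generation of random union of gametes. Returns a new gs_pop
# holding only the offspring. sire/dam picked uniformly with replacement.
random_mating_generation <- function(pop, n_off, n_off_males, map, cfg,
                                     gen) {
  males <- which(pop$ped$sex == "M")
  females <- which(pop$ped$sex == "F")
  if (length(males) == 0L || length(females) == 0L)
    stop("a generation has no males or no females")
  sire <- sample(males, n_off, replace = TRUE)
  dam <- sample(females, n_off, replace = TRUE)
  colA <- integer(2L * n_off); colB <- integer(2L * n_off)
  colA[c(TRUE, FALSE)] <- 2L * sire - 1L; colB[c(TRUE, FALSE)] <- 2L * sire
  colA[c(FALSE, TRUE)] <- 2L * dam - 1L;  colB[c(FALSE, TRUE)] <- 2L * dam
  haps <- drop_gametes(pop$haps, colA, colB, map, cfg$interference,
                       cfg$mutation_rate)
  sex <- sample(c(rep("M", n_off_males), rep("F", n_off - n_off_males)))
  ped <- data.frame(id = seq_len(n_off), sire = 0L, dam = 0L, sex = sex,
                    gen = gen)
  new_gs_pop(ped, haps)
}

#' Historical phase: mutation-drift over discrete generations
#'
#' Phase 1 keeps a constant population size; phase 2 interpolates the size
#' (and the male fraction) linearly to the configured terminal size and sex
#' split. Mating is the random union of gametes from a random male and a
#' random female with no selection.
#'
#' @param config A [sim_config()].
#' @param map A `genome_map` (usually the candidate map, before MAF
#'   filtering).
#' @return The final historical generation as a `gs_pop`.
#' @export
run_historical <- function(config, map) {
  m1 <- round(config$hist_size1 / 2)
  pop <- founder_population(m1, config$hist_size1 - m1, map)
  g1 <- config$hist_gens1; g2 <- config$hist_gens2
  if (g1 + g2 == 0L) return(pop)
  sizes <- c(rep(config$hist_size1, g1),
             if (g2 > 0) round(seq(config$hist_size1, config$hist_size2,
                                   length.out = g2 + 1))[-1])
  frac1 <- m1 / config$hist_size1
  frac2 <- config$hist_males2 / config$hist_size2
  fracs <- c(rep(frac1, g1),
             if (g2 > 0) seq(frac1, frac2, length.out = g2 + 1)[-1])
  for (g in seq_along(sizes)) {
    nm <- round(sizes[g] * fracs[g])
    if (g == length(sizes)) nm <- config$hist_males2 # exact terminal split
    pop <- random_mating_generation(pop, sizes[g], nm, map, config, g)
  }
  pop
}

#' Expansion phase: unselected growth under a population cap
#'
#' Founders are sampled at random from the supplied population; each
#' generation every dam produces the configured litter by random mating. If a
#' generation would exceed `exp_cap`, offspring are randomly culled to the
#' cap preserving the realised sex ratio.
#'
#' @param pop Source population (final historical generation).
#' @inheritParams run_historical
#' @return The final expanded generation as a `gs_pop`.
#' @export
run_expansion <- function(pop, config, map) {
  pop <- sample_founders(pop, config$exp_males, config$exp_females)
  if (config$exp_gens == 0L) return(pop)
  for (g in seq_len(config$exp_gens)) {
    n_dams <- sum(pop$ped$sex == "F")
    n_off <- n_dams * config$exp_litter
    sex_m <- stats::rbinom(1L, n_off, 0.5)
    nxt <- random_mating_generation(pop, n_off, sex_m, map, config,
                                    pop$ped$gen[1L] + 1L)
    if (n_off > config$exp_cap) {
      keep_m <- round(config$exp_cap * sex_m / n_off)
      keep <- c(sample(which(nxt$ped$sex == "M"), keep_m),
                sample(which(nxt$ped$sex == "F"), config$exp_cap - keep_m))
      nxt <- subset_pop(nxt, sort(keep))
    }
    pop <- nxt
  }
  pop
}

# internal: random founder draw of exact sex counts (ids renumbered)
sample_founders <- function(pop, n_males, n_females) {
  males <- which(pop$ped$sex == "M")
  females <- which(pop$ped$sex == "F")
  if (length(males) < n_males || length(females) < n_females)
    stop("not enough candidates of each sex to draw founders")
  keep <- c(sample(males, n_males), sample(females, n_females))
  subset_pop(pop, keep)
}

# internal: keep the given ped rows, renumbering ids 1..n and detaching
# parent links that leave the subset
subset_pop <- function(pop, rows) {
  ped <- pop$ped[rows, , drop = FALSE]
  ped$id <- seq_along(rows)
  ped$sire <- 0L; ped$dam <- 0L
  hap_cols <- as.vector(rbind(2L * rows - 1L, 2L * rows))
  new_gs_pop(ped, pop$haps[, hap_cols, drop = FALSE])
}

#' Allele-count genotypes
#'
#' @param pop A `gs_pop`.
#' @param map The matching `genome_map`.
#' @param rows Pedigree rows (default all).
#' @param role `"marker"`, `"qtl"` or `"all"`.
#' @return Integer matrix (individuals x loci) with entries 0/1/2; rownames
#'   are ids, colnames locus labels.
#' @export
genotypes <- function(pop, map, rows = NULL, role = "marker") {
  if (is.null(rows)) rows <- seq_len(nrow(pop$ped))
  loci <- if (role == "all") seq_len(nrow(map)) else which(map$role == role)
  g <- pop$haps[loci, 2L * rows - 1L, drop = FALSE] +
       pop$haps[loci, 2L * rows, drop = FALSE]
  g <- t(g)
  dimnames(g) <- list(pop$ped$id[rows],
                      paste0(ifelse(map$role[loci] == "qtl", "Q", "M"),
                             map$index[loci]))
  g
}

#' Finalize the marker panel by MAF filtering and subsampling
#'
#' From a candidate map, retains exactly `n_markers` segregating markers with
#' minor allele frequency at least `maf_min` and exactly `n_qtl` segregating
#' QTLs, chosen by random subsampling among the qualifying loci, and
#' re-indexes the population haplotypes accordingly.
#'
#' @param pop Population carrying the candidate loci (typically the final
#'   historical generation).
#' @param map Candidate `genome_map`.
#' @param n_markers,n_qtl Target counts.
#' @param maf_min MAF threshold for markers (must be < 0.5).
#' @return List with the reduced `pop` and re-indexed `map`.
#' @export
finalize_marker_panel <- function(pop, map, n_markers, n_qtl,
                                  maf_min = 0.05) {
  if (maf_min >= 0.5) stop("maf_min must be below 0.5")
  f <- rowMeans(pop$haps)
  maf <- pmin(f, 1 - f)
  if (all(maf == 0)) stop("all candidate loci are monomorphic")
  ok_m <- which(map$role == "marker" & maf >= maf_min & maf > 0)
  ok_q <- which(map$role == "qtl" & maf > 0)
  if (length(ok_m) < n_markers)
    stop(sprintf("only %d markers qualify (%d requested)",
                 length(ok_m), n_markers))
  if (length(ok_q) < n_qtl)
    stop(sprintf("only %d segregating QTLs (%d requested)",
                 length(ok_q), n_qtl))
  keep <- sort(c(sample(ok_m, n_markers), sample(ok_q, n_qtl)))
  map2 <- map[keep, , drop = FALSE]
  map2$index <- seq_len(nrow(map2))
  attr(map2, "chrom_lengths") <- attr(map, "chrom_lengths")
  class(map2) <- class(map)
  pop$haps <- pop$haps[keep, , drop = FALSE]
  list(pop = pop, map = map2)
}

#' Recent generations: a production system under EBV selection
#'
#' Samples the recent founders, scales the trait to its target heritability
#' on that base generation, then simulates `rec_gens` discrete breeding
#' seasons. Each season every active dam produces 1 or 2 progeny (equal
#' probability) by a random active sire; progeny are phenotyped at birth;
#' pedigree BLUP is run on all records to date; the configured fractions of
#' sires and dams are replaced by the top-ranked young animals in the trait's
#' selection direction, and parents beyond `max_age` breeding seasons are
#' culled.
#'
#' @param pop Source population (final expanded generation).
#' @param config A [sim_config()].
#' @param map The finalized `genome_map`.
#' @param trait A [trait_config()].
#' @param raw_effects Optional pre-drawn signed QTL effects (defaults to
#'   [sample_qtl_effects()] with shape 0.40).
#' @return A list of class `gs_recent`: `pop` (all recent animals, with
#'   pedigree columns `tbv`, `phen`, `ebv`, `alive`), `trait` (the scaled
#'   `trait_model`) and `map`.
#' @export
run_recent <- function(pop, config, map, trait, raw_effects = NULL) {
  qtl_rows <- which(map$role == "qtl")
  if (is.null(raw_effects)) raw_effects <- sample_qtl_effects(length(qtl_rows))
  pop <- sample_founders(pop, config$rec_males, config$rec_females)
  n0 <- nrow(pop$ped)
  pop$ped$gen <- 0L

  model <- scale_to_heritability(raw_effects,
                                 genotypes(pop, map, role = "qtl"),
                                 trait$h2, trait$var_p)
  ped <- pop$ped
  ped$tbv <- compute_tbv(genotypes(pop, map, role = "qtl"), model)
  ped$phen <- simulate_phenotype(ped$tbv, trait$h2, trait$var_p)
  ped$ebv <- NA_real_
  haps <- pop$haps

  sires <- which(ped$sex == "M")    # active breeding sets (ped rows)
  dams <- which(ped$sex == "F")
  age <- rep(1L, n0)                # breeding seasons served

  n_rep_s <- floor(config$rep_sires * config$rec_males)
  n_rep_d <- floor(config$rep_dams * config$rec_females)
  decr <- trait$direction == "high"

  for (g in seq_len(config$rec_gens)) {
    litter <- 1L + stats::rbinom(length(dams), 1L, 0.5)
    dam_of <- rep(dams, litter)
    sire_of <- rep(sample(sires, length(dams), replace = TRUE), litter)
    n_off <- length(dam_of)
    colA <- integer(2L * n_off); colB <- integer(2L * n_off)
    colA[c(TRUE, FALSE)] <- 2L * sire_of - 1L
    colB[c(TRUE, FALSE)] <- 2L * sire_of
    colA[c(FALSE, TRUE)] <- 2L * dam_of - 1L
    colB[c(FALSE, TRUE)] <- 2L * dam_of
    off_haps <- drop_gametes(haps, colA, colB, map, config$interference,
                             config$mutation_rate)
    off_rows <- nrow(ped) + seq_len(n_off)
    off_qtl <- t(off_haps[qtl_rows, c(TRUE, FALSE), drop = FALSE] +
                 off_haps[qtl_rows, c(FALSE, TRUE), drop = FALSE])
    tbv <- compute_tbv(off_qtl, model)
    off_ped <- data.frame(
      id = off_rows, sire = ped$id[sire_of], dam = ped$id[dam_of],
      sex = ifelse(stats::runif(n_off) < config$male_prop, "M", "F"),
      gen = g, tbv = tbv,
      phen = simulate_phenotype(tbv, trait$h2, trait$var_p),
      ebv = NA_real_)
    ped <- rbind(ped, off_ped)
    haps <- cbind(haps, off_haps)
    age <- c(age, rep(0L, n_off))

    if (config$selection == "ebv") {
      fit <- pedigree_blup(stats::setNames(ped$phen, ped$id), ped, trait$h2)
      ped$ebv <- as.numeric(fit$ebv)
    }
    sires <- replace_parents(ped, age, sires, off_rows, "M", n_rep_s,
                             config$rec_males, config$max_age, decr,
                             config$selection)
    dams <- replace_parents(ped, age, dams, off_rows, "F", n_rep_d,
                            config$rec_females, config$max_age, decr,
                            config$selection)
    age[c(sires, dams)] <- age[c(sires, dams)] + 1L
  }

  ped$alive <- seq_len(nrow(ped)) %in% c(sires, dams) | ped$gen == config$rec_gens
  structure(list(pop = new_gs_pop(ped, haps), trait = model, map = map),
            class = "gs_recent")
}

# internal: one sex's replacement step. Keeps the best (target - n_replace)
# current parents below the culling age, then fills back to `target` with
# top-ranked (or random) candidates of this generation.
replace_parents <- function(ped, age, current, off_rows, sex, n_replace,
                            target, max_age, decreasing, selection) {
  rank_of <- function(rows) {
    if (selection == "random") return(sample(rows))
    rows[order(ped$ebv[rows], decreasing = decreasing)]
  }
  survivors <- current[age[current] < max_age]
  survivors <- rank_of(survivors)
  n_keep <- max(target - n_replace, 0L)
  kept <- survivors[seq_len(min(n_keep, length(survivors)))]
  cand <- off_rows[ped$sex[off_rows] == sex]
  need <- target - length(kept)
  if (length(cand) < need)
    stop(sprintf("insufficient %s candidates for replacement", sex))
  sort(c(kept, rank_of(cand)[seq_len(need)]))
}

#' @export
print.gs_recent <- function(x, ...) {
  cat("Recent breeding population (EBV selection)\n")
  print(x$pop)
  invisible(x)
}

#' End-to-end breeding simulation for one trait
#'
#' Builds the candidate genome map, runs the historical phase, finalizes the
#' marker/QTL panel by MAF filtering, expands the population, and runs the
#' recent selected generations.
#'
#' @param config A [sim_config()].
#' @param trait A [trait_config()].
#' @return A `gs_recent` list (`pop`, `trait`, `map`).
#' @export
#' @examples
#' \donttest{
#' cfg <- sim_profile("desk", n_markers = 200, n_qtl = 10,
#'                    hist_gens1 = 30, hist_gens2 = 10)
#' sim <- simulate_breeding(cfg, trait_config(0.34, "low"))
#' }
simulate_breeding <- function(config, trait) {
  n_cm <- ceiling(config$candidate_factor * config$n_markers)
  n_cq <- max(ceiling(config$candidate_factor * config$n_qtl),
              config$n_qtl + 20L)
  map0 <- build_genome_map(config$chrom_lengths, n_cm, n_cq)
  hist <- run_historical(config, map0)
  pan <- finalize_marker_panel(hist, map0, config$n_markers, config$n_qtl,
                               config$maf_min)
  expd <- run_expansion(pan$pop, config, pan$map)
  run_recent(expd, config, pan$map, trait)
}

#' Simulate an unselected calibration cohort
#'
#' Runs a short mutation-drift historical phase to shape QTL allele
#' frequencies, scales a freshly drawn set of gamma QTL effects to the target
#' heritability on that base generation, then produces `n` unselected
#' offspring by random mating. Used to check the realized heritability and
#' phenotypic variance of a trait configuration on a large cohort.
#'
#' @param n Cohort size.
#' @param n_qtl Number of QTLs.
#' @param h2 Target heritability.
#' @param var_p Phenotypic variance.
#' @param hist_gens,hist_N Length and size of the shaping historical phase.
#' @param chrom_lengths Chromosome lengths (cM).
#' @param mutation_rate,interference Meiosis parameters.
#' @return List with `tbv`, `phen` (length-n vectors) and the scaled
#'   `trait_model`.
#' @export
simulate_unselected_cohort <- function(n, n_qtl, h2, var_p = 1,
                                       hist_gens = 100, hist_N = 200,
                                       chrom_lengths = goat_chrom_lengths(),
                                       mutation_rate = 9.4e-6,
                                       interference = 5) {
  cfg <- sim_config(chrom_lengths = chrom_lengths, n_markers = 0,
                    n_qtl = n_qtl, mutation_rate = mutation_rate,
                    interference = interference,
                    hist_gens1 = hist_gens, hist_size1 = hist_N,
                    hist_gens2 = 0, hist_size2 = hist_N,
                    hist_males2 = round(hist_N / 2),
                    hist_females2 = hist_N - round(hist_N / 2))
  map <- build_genome_map(chrom_lengths, 0, n_qtl)
  base <- run_historical(cfg, map)
  model <- scale_to_heritability(sample_qtl_effects(n_qtl),
                                 genotypes(base, map, role = "qtl"),
                                 h2, var_p)
  cohort <- random_mating_generation(base, n, round(n / 2), map, cfg,
                                     base$ped$gen[1L] + 1L)
  tbv <- compute_tbv(genotypes(cohort, map, role = "qtl"), model)
  list(tbv = tbv, phen = simulate_phenotype(tbv, h2, var_p), model = model)
}
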