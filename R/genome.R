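#' Genetic lengths of the 29 simulated autosomes
#'
#' A smoothly declining profile of 29 autosome lengths (cM) normalised so the
#' genome totals 2,922 cM, approximating the genetic map of the goat
#' (*Capra hircus*) autosomes. Used as the default chromosome configuration.
#'
#' @return Numeric vector of 29 chromosome lengths in centimorgans summing to
#'   2,922.
#' @export
#' @examples
#' sum(goat_chrom_lengths())
goat_chrom_lengths <- function() {
  len <- seq(151.5, 50, length.out = 29L)
  len * 2922 / sum(len)
}

#' Build a random genome map
#'
#' Places `n_markers` marker loci and `n_qtl` QTL loci uniformly at random
#' over a genome of one or more chromosomes: each locus falls on a chromosome
#' with probability proportional to its genetic length, at a uniform position
#' within it, and QTL status is interleaved at random among the loci.
#'
#' @param chrom_lengths Numeric vector of chromosome lengths in centimorgans
#'   (all positive).
#' @param n_markers Number of marker loci to place.
#' @param n_qtl Number of QTL loci to place.
#' @return An object of class `genome_map`: a data.frame with columns `chrom`,
#'   `pos_cM`, `role` (`"marker"` or `"qtl"`) and `index`, ordered by
#'   chromosome and position, with the chromosome lengths stored in
#'   `attr(, "chrom_lengths")`.
#' @export
#' @examples
#' map <- build_genome_map(c(100, 80), n_markers = 50, n_qtl = 5)
#' table(map$role)
build_genome_map <- function(chrom_lengths, n_markers, n_qtl) {
  if (length(chrom_lengths) < 1L || any(!is.finite(chrom_lengths)) ||
      any(chrom_lengths <= 0))
    stop("all chromosome lengths must be positive")
  if (n_markers < 0 || n_qtl < 0) stop("locus counts must be non-negative")
  n <- as.integer(n_markers + n_qtl)
  if (n == 0L) {
    map <- data.frame(chrom = integer(0), pos_cM = numeric(0),
                      role = character(0), index = integer(0))
    return(structure(map, chrom_lengths = chrom_lengths,
                     class = c("genome_map", "data.frame")))
  }
  chrom <- sample.int(length(chrom_lengths), n, replace = TRUE,
                      prob = chrom_lengths)
  pos <- stats::runif(n, 0, chrom_lengths[chrom])
  ord <- order(chrom, pos)
  chrom <- chrom[ord]; pos <- pos[ord]
  role <- rep("marker", n)
  if (n_qtl > 0) role[sample.int(n, n_qtl)] <- "qtl"
  map <- data.frame(chrom = chrom, pos_cM = pos, role = role,
                    index = seq_len(n))
  structure(map, chrom_lengths = chrom_lengths,
            class = c("genome_map", "data.frame"))
}

#' @export
print.genome_map <- function(x, ...) {
  cl <- attr(x, "chrom_lengths")
  cat(sprintf("Genome map: %d chromosomes, %.1f cM, %d markers + %d QTLs\n",
              length(cl), sum(cl), sum(x$role == "marker"),
              sum(x$role == "qtl")))
  invisible(x)
}

# internal: per-chromosome indexing in the locus order of the map
map_chrom_index <- function(map) {
  cl <- attr(map, "chrom_lengths")
  nC <- length(cl)
  cnt <- tabulate(map$chrom, nbins = nC)
  first <- cumsum(c(0L, cnt[-nC]))
  list(first = as.integer(first), count = as.integer(cnt),
       len_M = cl / 100, pos_M = map$pos_cM / 100)
}

#' Sample one gamete from a parent
#'
#' Performs a single meiosis: crossover positions on every chromosome are
#' drawn from a stationary gamma renewal process with shape equal to the
#' interference parameter and unit mean spacing in Morgans (so the expected
#' crossover count per chromosome equals its length in Morgans), and the
#' returned haplotype alternates between the two parental strands at the
#' crossover points, starting from a random strand.
#'
#' @param paternal,maternal Integer 0/1 allele vectors of the parent, one per
#'   locus of `map`.
#' @param map A [build_genome_map()] object.
#' @param interference Positive gamma shape; 1 gives a Poisson (no
#'   interference) process, larger values suppress nearby double crossovers.
#' @param mutation_rate Per-locus probability of a recurrent allele flip
#'   applied to the gamete (default 0).
#' @return Integer 0/1 vector of length `nrow(map)`.
#' @export
sample_gamete <- function(paternal, maternal, map, interference = 5,
                          mutation_rate = 0) {
  if (interference <= 0) stop("interference must be > 0")
  if (length(paternal) != nrow(map) || length(maternal) != nrow(map))
    stop("parental haplotypes must match the map locus count")
  ci <- map_chrom_index(map)
  haps <- cbind(as.integer(paternal), as.integer(maternal))
  drop(cpp_drop_gametes(haps, 1L, 2L, ci$first, ci$count, ci$pos_M, ci$len_M,
                        interference, mutation_rate))
}

#' Apply recurrent mutation to a haplotype
#'
#' Each locus flips allele (0 to 1 or 1 to 0) independently with probability
#' `rate`, the recurrent two-allele mutation model applied to markers and
#' QTLs alike.
#'
#' @param haplotype Integer 0/1 vector.
#' @param rate Per-locus per-generation flip probability in \[0, 1\].
#' @return Mutated haplotype.
#' @export
apply_mutation <- function(haplotype, rate) {
  if (!is.finite(rate) || rate < 0 || rate > 1)
    stop("mutation rate must be in [0, 1]")
  L <- length(haplotype)
  n <- stats::rbinom(1L, L, rate)
  if (n > 0) {
    idx <- sample.int(L, n)
    haplotype[idx] <- 1L - haplotype[idx]
  }
  haplotype
}

# internal: batch gamete dropping. haps is an L x H matrix (column = one
# haplotype); colA/colB give the two source haplotype columns per gamete.
drop_gametes <- function(haps, colA, colB, map, interference, mutation_rate) {
  ci <- map_chrom_index(map)
  cpp_drop_gametes(haps, as.integer(colA), as.integer(colB),
                   ci$first, ci$count, ci$pos_M, ci$len_M,
                   interference, mutation_rate)
}

#' Write a genome map in PLINK MAP format
#'
#' One line per locus: chromosome, locus id, genetic position (cM) and a
#' base-pair coordinate derived as `round(cM * 1e6)`. By default only marker
#' loci are exported (QTLs are simulation-internal).
#'
#' @param map A `genome_map`.
#' @param file Output path.
#' @param markers_only Drop QTL loci (default `TRUE`).
#' @return Invisibly, the exported data.frame.
#' @export
write_map <- function(map, file, markers_only = TRUE) {
  m <- if (markers_only) map[map$role == "marker", , drop = FALSE] else map
  out <- data.frame(chrom = m$chrom,
                    id = paste0(ifelse(m$role == "qtl", "Q", "M"), m$index),
                    cM = m$pos_cM, bp = as.integer(round(m$pos_cM * 1e6)))
  data.table::fwrite(out, file, sep = "\t", col.names = FALSE)
  invisible(out)
}
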