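# PLINK PED/MAP text exchange and the tabular CSV writers. Alleles are coded
# 1/2 in PED (1 = the ancestral 0-allele); MAP base-pair positions are
# round(cM * 1e6).

#' Write genotypes as PLINK PED/MAP text files
#'
#' @param pop A `gs_pop` (or `gs_recent`).
#' @param map The matching `genome_map`.
#' @param prefix Output path prefix; `<prefix>.ped` and `<prefix>.map` are
#'   written.
#' @param rows Pedigree rows to export (default all).
#' @param markers_only Export marker loci only (default `TRUE`; QTLs are
#'   simulation-internal).
#' @return Invisibly, the two file paths.
#' @export
write_genotypes <- function(pop, map, prefix, rows = NULL,
                            markers_only = TRUE) {
  if (inherits(pop, "gs_recent")) pop <- pop$pop
  ped <- pop$ped
  if (is.null(rows)) rows <- seq_len(nrow(ped))
  loci <- if (markers_only) which(map$role == "marker") else seq_len(nrow(map))
  pat <- pop$haps[loci, 2L * rows - 1L, drop = FALSE] + 1L
  mat <- pop$haps[loci, 2L * rows, drop = FALSE] + 1L
  allele <- matrix(0L, nrow = length(rows), ncol = 2L * length(loci))
  allele[, c(TRUE, FALSE)] <- t(pat)
  allele[, c(FALSE, TRUE)] <- t(mat)
  lead <- data.frame(fid = 1L, iid = ped$id[rows],
                     pat = ped$sire[rows], mat = ped$dam[rows],
                     sex = ifelse(ped$sex[rows] == "M", 1L, 2L),
                     phen = if ("phen" %in% names(ped))
                       round(ped$phen[rows], 6) else -9)
  data.table::fwrite(cbind(lead, as.data.frame(allele)),
                     paste0(prefix, ".ped"), sep = " ", col.names = FALSE)
  write_map(map, paste0(prefix, ".map"), markers_only = markers_only)
  invisible(c(ped = paste0(prefix, ".ped"), map = paste0(prefix, ".map")))
}

#' Read PLINK PED/MAP text files
#'
#' @param prefix Path prefix of `<prefix>.ped` / `<prefix>.map`.
#' @return List with `genotypes` (allele-count matrix, rownames = ids),
#'   `info` (id, sire, dam, sex, phenotype) and `map` (the MAP table).
#' @export
read_genotypes <- function(prefix) {
  mapf <- paste0(prefix, ".map"); pedf <- paste0(prefix, ".ped")
  map <- data.table::fread(mapf, header = FALSE,
                           col.names = c("chrom", "id", "cM", "bp"))
  pedtab <- data.table::fread(pedf, header = FALSE)
  nl <- nrow(map)
  if (ncol(pedtab) != 6L + 2L * nl)
    stop("PED column count does not match the MAP locus count")
  al <- as.matrix(pedtab[, -(1:6)])
  if (!all(al %in% c(1L, 2L))) stop("malformed PED allele codes")
  counts <- (al[, c(TRUE, FALSE), drop = FALSE] - 1L) +
            (al[, c(FALSE, TRUE), drop = FALSE] - 1L)
  rownames(counts) <- as.character(pedtab[[2L]])
  colnames(counts) <- map$id
  info <- data.frame(id = pedtab[[2L]], sire = pedtab[[3L]],
                     dam = pedtab[[4L]],
                     sex = ifelse(pedtab[[5L]] == 1L, "M", "F"),
                     phen = pedtab[[6L]])
  list(genotypes = counts, info = info, map = as.data.frame(map))
}

#' Write the pedigree and phenotype tables
#'
#' `write_pedigree()` writes id, sire, dam, sex, generation and the alive
#' flag; `write_phenotypes()` writes id, generation, sex, trait, phenotype,
#' TBV and EBV.
#'
#' @param pop A `gs_pop` or `gs_recent`.
#' @param file Output CSV path.
#' @param trait Trait label for the phenotype table.
#' @return Invisibly, the written data.frame.
#' @export
write_pedigree <- function(pop, file) {
  if (inherits(pop, "gs_recent")) pop <- pop$pop
  ped <- pop$ped
  out <- data.frame(id = ped$id, sire = ped$sire, dam = ped$dam,
                    sex = ped$sex, generation = ped$gen,
                    alive = if ("alive" %in% names(ped)) ped$alive else TRUE)
  data.table::fwrite(out, file)
  invisible(out)
}

#' @rdname write_pedigree
#' @export
write_phenotypes <- function(pop, file, trait = "trait") {
  if (inherits(pop, "gs_recent")) pop <- pop$pop
  ped <- pop$ped
  out <- data.frame(id = ped$id, generation = ped$gen, sex = ped$sex,
                    trait = trait, phenotype = ped$phen, tbv = ped$tbv,
                    ebv = ped$ebv)
  data.table::fwrite(out, file)
  invisible(out)
}

#' Write genotypes as a minimal VCF
#'
#' Diploid phased genotypes (`0|1` style) for interoperability; PED/MAP is
#' the canonical exchange format.
#'
#' @inheritParams write_genotypes
#' @param file Output path.
#' @export
write_vcf <- function(pop, map, file, rows = NULL, markers_only = TRUE) {
  if (inherits(pop, "gs_recent")) pop <- pop$pop
  if (is.null(rows)) rows <- seq_len(nrow(pop$ped))
  loci <- if (markers_only) which(map$role == "marker") else seq_len(nrow(map))
  ids <- pop$ped$id[rows]
  gt <- matrix(paste0(pop$haps[loci, 2L * rows - 1L, drop = FALSE], "|",
                      pop$haps[loci, 2L * rows, drop = FALSE]),
               nrow = length(loci))
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", paste0("ind", ids)), collapse = "\t"))
  body <- paste(map$chrom[loci], as.integer(round(map$pos_cM[loci] * 1e6)),
                paste0("M", map$index[loci]), "A", "B", ".", "PASS", ".",
                "GT", apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), file)
  invisible(file)
}

# deterministic config fingerprint (polynomial rolling hash mod 2^31 - 1)
config_hash <- function(config) {
  s <- paste(deparse(config, control = "all"), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
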