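#' Genomic relationship matrix (VanRaden)
#'
#' Centers the allele-count matrix by twice the allele frequencies and scales
#' the cross-product by `2 * sum(p * (1 - p))`:
#' `G = Mc Mc' / (2 sum p_j q_j)` with `Mc = counts - 2p`.
#'
#' @param genotypes Individuals x markers allele-count matrix (0/1/2) with
#'   rownames = ids.
#' @param freq_source Optional character vector of ids on which to compute
#'   the allele frequencies (default: all rows).
#' @return A list of class `grm`: `G` (dense symmetric matrix), `p` (allele
#'   frequencies) and `denom`.
#' @export
#' @examples
#' g <- rbind(a = c(0, 2), b = c(1, 1), c = c(2, 0))
#' build_grm(g)$G
build_grm <- function(genotypes, freq_source = NULL) {
  ids <- rownames(genotypes)
  rows <- if (is.null(freq_source)) seq_len(nrow(genotypes)) else {
    idx <- match(freq_source, ids)
    if (anyNA(idx)) stop("freq_source ids missing from the genotypes")
    idx
  }
  p <- colMeans(genotypes[rows, , drop = FALSE]) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all markers are monomorphic in the frequency source")
  Mc <- sweep(genotypes, 2L, 2 * p)
  G <- tcrossprod(Mc) / denom
  structure(list(G = G, p = p, denom = denom), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("Genomic relationship matrix: %d individuals, %d markers, mean diag %.3f\n",
              nrow(x$G), length(x$p), mean(diag(x$G))))
  invisible(x)
}
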