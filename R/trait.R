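#' Trait configuration
#'
#' Narrow-sense heritability, phenotypic variance and selection direction for
#' a single simulated trait. The two study traits are fiber diameter
#' (h2 = 0.34, selected downwards) and live body weight (h2 = 0.11, selected
#' upwards), both with phenotypic variance 1.
#'
#' @param h2 Narrow-sense heritability in (0, 1).
#' @param direction `"high"` (select large EBV) or `"low"` (select small EBV).
#' @param var_p Phenotypic variance.
#' @param name Optional trait label.
#' @return A list of class `trait_config`.
#' @export
#' @examples
#' trait_config(0.34, "low", name = "fiber diameter")
trait_config <- function(h2, direction = c("high", "low"), var_p = 1,
                         name = NULL) {
  direction <- match.arg(direction)
  if (!is.finite(h2) || h2 <= 0 || h2 >= 1) stop("h2 must lie in (0, 1)")
  if (var_p <= 0) stop("phenotypic variance must be positive")
  structure(list(h2 = h2, direction = direction, var_p = var_p, name = name),
            class = "trait_config")
}

#' Sample raw QTL allele effects
#'
#' Effect magnitudes are drawn from a Gamma distribution with the given shape
#' (scale 1) and each sign is independently positive or negative with
#' probability 1/2, so the raw effects are sign-symmetric with mean magnitude
#' equal to the shape.
#'
#' @param n_qtl Number of QTLs (at least 1).
#' @param shape Gamma shape parameter (default 0.40).
#' @return Numeric vector of signed effects.
#' @export
sample_qtl_effects <- function(n_qtl, shape = 0.40) {
  if (n_qtl < 1) stop("n_qtl must be >= 1")
  mag <- stats::rgamma(n_qtl, shape = shape, scale = 1)
  sgn <- ifelse(stats::runif(n_qtl) < 0.5, -1, 1)
  mag * sgn
}

#' Scale QTL effects to a target heritability
#'
#' Multiplies the raw signed effects by a single constant so that the
#' empirical variance of the true breeding values (TBV) over the supplied
#' base-generation individuals equals `h2 * var_p`, and sets the centering
#' offset so that the base-generation mean TBV is zero.
#'
#' @param raw_effects Signed QTL effects, e.g. from [sample_qtl_effects()].
#' @param qtl_geno Base-generation QTL allele-count matrix
#'   (individuals x QTLs, values 0/1/2).
#' @param h2 Target heritability.
#' @param var_p Phenotypic variance.
#' @return A list of class `trait_model` with elements `effects`, `offset`,
#'   `h2` and `var_p`.
#' @export
scale_to_heritability <- function(raw_effects, qtl_geno, h2, var_p = 1) {
  if (ncol(qtl_geno) != length(raw_effects))
    stop("effect/genotype dimension mismatch")
  tbv_raw <- drop(qtl_geno %*% raw_effects)
  v <- stats::var(tbv_raw)
  if (!is.finite(v) || v <= 0)
    stop("no genetic variance segregates in the base generation")
  k <- sqrt(h2 * var_p / v)
  effects <- raw_effects * k
  structure(list(effects = effects, offset = mean(tbv_raw) * k,
                 h2 = h2, var_p = var_p),
            class = "trait_model")
}

#' True breeding values from QTL genotypes
#'
#' @param qtl_geno Allele-count matrix (individuals x QTLs).
#' @param model A [scale_to_heritability()] trait model.
#' @return Numeric TBV vector (base-generation mean centred at 0).
#' @export
compute_tbv <- function(qtl_geno, model) {
  drop(qtl_geno %*% model$effects) - model$offset
}

#' Simulate phenotypes from true breeding values
#'
#' Adds an independent normal residual with variance `var_p * (1 - h2)` to
#' each TBV.
#'
#' @param tbv TBV vector.
#' @param h2 Heritability.
#' @param var_p Phenotypic variance.
#' @return Phenotype vector.
#' @export
simulate_phenotype <- function(tbv, h2, var_p = 1) {
  tbv + stats::rnorm(length(tbv), 0, sqrt(var_p * (1 - h2)))
}
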