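# Genomic breeding-value estimation: one fitting front-end over the six
# methods of the study. GBLUP and ssGBLUP are linear mixed-model solves at
# known variance ratio; the Bayesian alphabet methods are single-site Gibbs
# samplers (see src/gibbs.cpp).

#' MCMC chain settings for the Bayesian alphabet methods
#'
#' @param niter Total chain length.
#' @param burnin Discarded initial iterations.
#' @param thin Thinning interval for stored samples.
#' @return A list of class `chain_control`.
#' @export
chain_control <- function(niter = 20000, burnin = 5000, thin = 10) {
  if (niter <= 0) stop("chain length must be positive")
  if (burnin < 0 || burnin >= niter) stop("burn-in must lie in [0, niter)")
  structure(list(niter = as.integer(niter), burnin = as.integer(burnin),
                 thin = as.integer(thin)), class = "chain_control")
}

#' Fit a genomic breeding-value model
#'
#' The single fitting front-end for the six GEBV methods: `"GBLUP"` (genomic
#' relationship mixed model), `"ssGBLUP"` (single-step: pedigree and genomic
#' relationships blended into H), and the Bayesian whole-genome regressions
#' `"BayesA"`, `"BayesB"`, `"BRR"` and `"BL"` (Bayesian LASSO), all with the
#' overall mean as the only fixed effect. Phenotypes are supplied for the
#' reference animals; GEBVs are returned for every genotyped animal (every
#' pedigree member for ssGBLUP), so validation animals are simply the
#' genotyped animals without phenotypes.
#'
#' @param y Named numeric vector of reference phenotypes (names = ids, which
#'   must appear among the genotype rownames, or in the pedigree for
#'   ssGBLUP).
#' @param genotypes Allele-count matrix (individuals x markers, 0/1/2) with
#'   rownames = ids, covering reference and validation animals.
#' @param method One of `"GBLUP"`, `"ssGBLUP"`, `"BayesA"`, `"BayesB"`,
#'   `"BRR"`, `"BL"`.
#' @param h2 Trait heritability; fixes the variance ratio for the BLUP
#'   methods and calibrates the marker-variance priors for the Bayesian
#'   methods (treated as known, as the study design supplies it).
#' @param pedigree data.frame (`id`, `sire`, `dam`) for ssGBLUP; every
#'   genotyped animal must appear in it.
#' @param blend Weight moved from G toward the identity (GBLUP) or toward
#'   A22 (ssGBLUP) for numerical stability.
#' @param tune For ssGBLUP, rescale G so its mean diagonal and off-diagonal
#'   match A22 before blending.
#' @param G Optional pre-built genomic relationship matrix overriding the
#'   internal VanRaden construction (advanced use).
#' @param freq_source Ids used for allele frequencies (default: all
#'   genotyped).
#' @param pi0 BayesB prior mass at zero marker variance.
#' @param fix_variances If `TRUE` (BRR only), hold the common marker
#'   variance and the residual variance essentially fixed at their
#'   calibrated values (degenerate priors), making the sampler conjugate
#'   with a closed-form posterior mean.
#' @param df_marker Prior degrees of freedom of the scaled-inverse-chi-square
#'   marker-variance prior (BayesA/BayesB, and the common variance of BRR).
#' @param bl_shape,bl_rate Gamma hyperprior on the Bayesian LASSO `lambda^2`.
#' @param chain A [chain_control()].
#' @return An object of class `gebv` with components `gebv` (named vector),
#'   `mu`, `method`, `effects` (posterior-mean or backsolved marker effects,
#'   where defined), `p` (centering frequencies) and fit metadata, with
#'   print, summary, coef, fitted, residuals, predict and plot methods.
#' @export
#' @examples
#' set.seed(1)
#' M <- matrix(rbinom(50 * 80, 2, 0.4), 50, 80,
#'             dimnames = list(paste0("a", 1:50), NULL))
#' b <- rnorm(80, 0, 0.1)
#' y <- drop(M %*% b) + rnorm(50)
#' fit <- gebv(setNames(y[1:40], rownames(M)[1:40]), M, "GBLUP", h2 = 0.5)
#' head(predict(fit))
gebv <- function(y, genotypes, method = c("GBLUP", "ssGBLUP", "BayesA",
                                          "BayesB", "BRR", "BL"),
                 h2, pedigree = NULL, blend = 0.05, tune = TRUE, G = NULL,
                 freq_source = NULL, pi0 = 0.95, df_marker = 4.2,
                 bl_shape = 0.55, bl_rate = 0.1, fix_variances = FALSE,
                 chain = chain_control()) {
  method <- match.arg(method)
  if (length(y) == 0L || is.null(names(y))) stop("y must be a named vector")
  if (missing(h2)) stop("h2 is required (variance components are treated as known)")
  cl <- match.call()
  fit <- switch(method,
    GBLUP = fit_gblup(y, genotypes, h2, blend, G, freq_source),
    ssGBLUP = fit_ssgblup(y, genotypes, pedigree, h2, blend, tune, G,
                          freq_source),
    fit_bayes(y, genotypes, method, h2, pi0, df_marker, bl_shape, bl_rate,
              chain, freq_source, fix_variances))
  fit$method <- method
  fit$h2 <- h2
  fit$y <- y
  fit$ids_ref <- names(y)
  fit$call <- cl
  class(fit) <- "gebv"
  fit
}

fit_gblup <- function(y, genotypes, h2, blend, G, freq_source) {
  ids <- rownames(genotypes)
  ref <- match(names(y), ids)
  if (anyNA(ref)) stop("reference ids missing from the genotypes")
  if (is.null(G)) {
    grm <- build_grm(genotypes, freq_source)
    G <- grm$G; p <- grm$p; denom <- grm$denom
  } else {
    p <- colMeans(genotypes[ref, , drop = FALSE]) / 2
    denom <- 2 * sum(p * (1 - p))
  }
  n <- nrow(G)
  Gs <- (1 - blend) * G + blend * diag(n)
  lambda <- (1 - h2) / h2
  V <- Gs[ref, ref, drop = FALSE] + lambda * diag(length(ref))
  ch <- tryCatch(chol(V), error = function(e)
    stop("singular stabilized G in the reference block"))
  yv <- as.numeric(y)
  Vi1 <- backsolve(ch, forwardsolve(t(ch), rep(1, length(ref))))
  Viy <- backsolve(ch, forwardsolve(t(ch), yv))
  mu <- sum(Vi1 * yv) / sum(Vi1)
  alpha <- Viy - mu * Vi1
  u <- drop(Gs[, ref, drop = FALSE] %*% alpha)
  Mc <- sweep(genotypes[ref, , drop = FALSE], 2L, 2 * p)
  eff <- drop(crossprod(Mc, alpha)) / denom * (1 - blend)
  list(gebv = stats::setNames(u, ids), mu = mu, effects = eff, p = p,
       lambda = lambda, blend = blend)
}

fit_ssgblup <- function(y, genotypes, pedigree, h2, blend, tune, G,
                        freq_source) {
  if (is.null(pedigree)) stop("ssGBLUP requires a pedigree")
  p <- check_pedigree(pedigree)
  gid <- rownames(genotypes)
  gidx <- match(gid, as.character(p$id))
  if (anyNA(gidx)) stop("genotyped animals missing from the pedigree")
  ainv <- pedigree_Ainv(pedigree)
  A <- cpp_A_tabular(p$sire, p$dam)
  A22 <- A[gidx, gidx, drop = FALSE]
  if (is.null(G)) G <- build_grm(genotypes, freq_source)$G
  if (tune) {
    # match mean diagonal and mean off-diagonal of G to A22
    dG <- mean(diag(G)); oG <- (sum(G) - sum(diag(G))) / (length(G) - nrow(G))
    dA <- mean(diag(A22)); oA <- (sum(A22) - sum(diag(A22))) /
      (length(A22) - nrow(A22))
    beta <- if (abs(dG - oG) > 1e-12) (dA - oA) / (dG - oG) else 1
    alpha <- dA - beta * dG
    G <- alpha + beta * G
  }
  Gw <- (1 - blend) * G + blend * A22
  Gwi <- tryCatch(solve(Gw), error = function(e) stop("singular blended G"))
  A22i <- solve(A22)
  corr <- Gwi - A22i
  n <- p$n
  Hinv <- ainv$Ainv +
    Matrix::sparseMatrix(i = rep(gidx, times = length(gidx)),
                         j = rep(gidx, each = length(gidx)),
                         x = as.numeric(corr), dims = c(n, n))
  yfull <- rep(NA_real_, n)
  ridx <- match(names(y), as.character(p$id))
  if (anyNA(ridx)) stop("phenotyped ids missing from the pedigree")
  yfull[ridx] <- as.numeric(y)
  fit <- animal_model_mme(yfull, Hinv, h2)
  list(gebv = stats::setNames(fit$ebv, p$id), mu = fit$mu, effects = NULL,
       p = NULL, lambda = (1 - h2) / h2, blend = blend)
}

fit_bayes <- function(y, genotypes, method, h2, pi0, df_marker, bl_shape,
                      bl_rate, chain, freq_source, fix_variances = FALSE) {
  ids <- rownames(genotypes)
  ref <- match(names(y), ids)
  if (anyNA(ref)) stop("reference ids missing from the genotypes")
  if (length(ref) < 2L) stop("reference must contain at least 2 animals")
  rows <- if (is.null(freq_source)) ref else match(freq_source, ids)
  p <- colMeans(genotypes[rows, , drop = FALSE]) / 2
  msx <- 2 * sum(p * (1 - p))
  if (msx <= 0) stop("all markers are monomorphic")
  Zc <- sweep(genotypes[ref, , drop = FALSE], 2L, 2 * p)
  yv <- as.numeric(y)
  varp <- stats::var(yv)
  s2g <- h2 * varp
  s2m <- s2g / msx
  # expectation-matching scaled-inv-chi-square priors
  S_marker <- if (method == "BayesB") s2m / (1 - pi0) * (df_marker - 2) / df_marker
              else s2m * (df_marker - 2) / df_marker
  dfe <- 4.2
  Se <- (1 - h2) * varp * (dfe - 2) / dfe
  df_b <- df_marker; S_b <- S_marker
  if (fix_variances) {
    if (method != "BRR") stop("fix_variances is only meaningful for BRR")
    df_b <- 1e9; S_b <- s2m
    dfe <- 1e9; Se <- (1 - h2) * varp
  }
  mcode <- c(BRR = 0L, BayesA = 1L, BayesB = 2L, BL = 3L)[[method]]
  res <- cpp_bayes_gibbs(Zc, yv, mcode, chain$niter, chain$burnin,
                         chain$thin, df_marker, S_marker, df_b,
                         S_b, pi0, bl_shape, bl_rate,
                         max(bl_shape / bl_rate, 1), dfe, Se)
  Mc_all <- sweep(genotypes, 2L, 2 * p)
  u <- drop(Mc_all %*% res$b)
  list(gebv = stats::setNames(u, ids), mu = res$mu, effects = res$b, p = p,
       varb = res$varb, pip = if (method == "BayesB") res$pip else NULL,
       lambda2 = if (method == "BL") res$lambda2 else NULL,
       s2e_samples = res$s2e_samples, n_samples = res$n_samples,
       chain = chain)
}

#' @export
print.gebv <- function(x, ...) {
  cat(sprintf("Genomic breeding values (%s): %d animals (%d reference), mu = %.4f\n",
              x$method, length(x$gebv), length(x$ids_ref), x$mu))
  invisible(x)
}

#' @describeIn gebv Fit summary: counts, variance components and GEBV spread.
#' @param object,x A `gebv` fit.
#' @param ... Unused.
#' @export
summary.gebv <- function(object, ...) {
  out <- list(method = object$method, n = length(object$gebv),
              n_ref = length(object$ids_ref), mu = object$mu,
              h2 = object$h2, sd_gebv = stats::sd(object$gebv),
              n_samples = object$n_samples)
  class(out) <- "summary.gebv"
  out
}

#' @export
print.summary.gebv <- function(x, ...) {
  cat(sprintf("Method: %s\nAnimals: %d (reference %d)\n", x$method, x$n,
              x$n_ref))
  cat(sprintf("Fixed h2: %.3f   mu-hat: %.4f   sd(GEBV): %.4f\n", x$h2,
              x$mu, x$sd_gebv))
  if (!is.null(x$n_samples))
    cat(sprintf("Posterior samples kept: %d\n", x$n_samples))
  invisible(x)
}

#' @describeIn gebv Marker effects (Bayesian/GBLUP backsolved) or the GEBV
#'   vector for ssGBLUP.
#' @export
coef.gebv <- function(object, ...) {
  if (is.null(object$effects)) object$gebv else object$effects
}

#' @describeIn gebv In-sample GEBV of the reference animals.
#' @export
fitted.gebv <- function(object, ...) {
  object$gebv[object$ids_ref]
}

#' @describeIn gebv Reference residuals `y - mu - GEBV`.
#' @export
residuals.gebv <- function(object, ...) {
  object$y - object$mu - object$gebv[object$ids_ref]
}

#' Predict GEBV for new genotypes
#'
#' For marker-effect methods (Bayesian alphabet and GBLUP via backsolved
#' effects), the GEBV of an individual is its centered genotype row times the
#' marker effects, with centering at the frequencies used in the fit. For
#' ssGBLUP, predictions are looked up from the fitted pedigree (new
#' genotypes cannot be scored without refitting).
#'
#' @param object A `gebv` fit.
#' @param newdata Allele-count matrix with the fitted marker panel; if
#'   omitted, the fit's GEBVs are returned.
#' @param ... Unused.
#' @return Named GEBV vector.
#' @export
predict.gebv <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$gebv)
  if (object$method == "ssGBLUP") {
    ids <- rownames(newdata)
    if (!all(ids %in% names(object$gebv)))
      stop("ssGBLUP can only score animals present in the fitted pedigree")
    return(object$gebv[ids])
  }
  if (ncol(newdata) != length(object$effects))
    stop("marker panel mismatch between fit and newdata")
  Mc <- sweep(newdata, 2L, 2 * object$p)
  stats::setNames(drop(Mc %*% object$effects), rownames(newdata))
}

#' @describeIn gebv Plot of marker effects along the panel (marker-effect
#'   methods) or a GEBV histogram (ssGBLUP).
#' @export
plot.gebv <- function(x, ...) {
  if (!is.null(x$effects)) {
    graphics::plot(abs(x$effects), type = "h",
                   xlab = "marker", ylab = "|effect|",
                   main = paste(x$method, "marker effects"), ...)
  } else {
    graphics::hist(x$gebv, breaks = 40, xlab = "GEBV",
                   main = paste(x$method, "GEBV"), ...)
  }
  invisible(x)
}
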