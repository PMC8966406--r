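# Reference/validation design, accuracy, the one-factor-at-a-time experiment
# grid, and the fixed-effects ANOVA + Duncan multiple-range reporting.

#' Split a recent population into reference and validation sets
#'
#' The reference set is drawn at random from generations 2-7, the validation
#' set from generations 8-10, disjoint and of exactly the requested sizes.
#' An optional sex composition (named counts `c(M = , F = )`) is honoured for
#' the reference set.
#'
#' @param recent A `gs_recent` (or a `gs_pop` with `gen` and `sex` columns).
#' @param ref_size,val_size Set sizes.
#' @param sex_composition Optional named vector `c(M = , F = )` summing to
#'   `ref_size`.
#' @param ref_gens,val_gens Generation windows.
#' @return List with character vectors `ref` and `val` of animal ids.
#' @export
split_reference_validation <- function(recent, ref_size, val_size,
                                       sex_composition = NULL,
                                       ref_gens = 2:7, val_gens = 8:10) {
  ped <- if (inherits(recent, "gs_recent")) recent$pop$ped else recent$ped
  rpool <- ped[ped$gen %in% ref_gens, ]
  vpool <- ped[ped$gen %in% val_gens, ]
  ref <- if (is.null(sex_composition)) {
    if (nrow(rpool) < ref_size) stop("reference pool smaller than ref_size")
    sample(rpool$id, ref_size)
  } else {
    if (!setequal(names(sex_composition), c("M", "F")) ||
        sum(sex_composition) != ref_size)
      stop("sex_composition must be c(M=, F=) summing to ref_size")
    ids <- lapply(c("M", "F"), function(s) {
      pool <- rpool$id[rpool$sex == s]
      k <- sex_composition[[s]]
      if (length(pool) < k)
        stop(sprintf("requested %d %s but only %d available", k, s,
                     length(pool)))
      sample(pool, k)
    })
    unlist(ids)
  }
  if (nrow(vpool) < val_size) stop("validation pool smaller than val_size")
  val <- sample(vpool$id, val_size)
  list(ref = as.character(ref), val = as.character(val))
}

#' Prediction accuracy
#'
#' Pearson correlation between predicted and realized values,
#' \eqn{r = Cov(\hat P, P) / (\sigma_{\hat P} \sigma_P)}, the study's
#' accuracy measure.
#'
#' @param predicted,realized Equal-length numeric vectors (n >= 3), both
#'   non-constant.
#' @return The correlation coefficient.
#' @export
compute_accuracy <- function(predicted, realized) {
  if (length(predicted) != length(realized)) stop("length mismatch")
  if (length(predicted) < 3L) stop("need at least 3 pairs")
  if (stats::sd(predicted) == 0 || stats::sd(realized) == 0)
    stop("zero variance in predicted or realized values")
  stats::cor(predicted, realized)
}

#' One-factor-at-a-time experiment designs
#'
#' `main_design()` builds the record grid of the main study: marker density
#' (15/30/45/60 K), number of QTLs (50/100/150) and reference size
#' (500-3,000) each varied one at a time from a baseline, crossed with the
#' six methods and the replicate count: (4 + 3 + 5) x 6 x 3 = 216 records.
#' `sex_design()` builds the sex-composition study grid: 6 compositions x 6
#' methods x 3 replicates = 108 records.
#'
#' @param replicates Replicates per cell.
#' @param methods Method labels.
#' @return data.frame with one row per planned accuracy record (factor
#'   columns plus `replicate`).
#' @export
main_design <- function(replicates = 3,
                        methods = c("BayesA", "BayesB", "BL", "BRR",
                                    "GBLUP", "ssGBLUP")) {
  scen <- rbind(
    data.frame(factor = "marker_density", level = c("15K", "30K", "45K", "60K")),
    data.frame(factor = "n_qtl", level = c("50", "100", "150")),
    data.frame(factor = "ref_size", level = c("500", "1000", "1500", "2000",
                                              "3000")))
  out <- merge(merge(scen, data.frame(method = methods)),
               data.frame(replicate = seq_len(replicates)))
  out[order(out$factor, out$level, out$method, out$replicate), ]
}

#' @rdname main_design
#' @export
sex_design <- function(replicates = 3,
                       methods = c("BayesA", "BayesB", "BL", "BRR",
                                   "GBLUP", "ssGBLUP")) {
  comp <- c("100M+1400F", "200M+1300F", "400M+1100F", "800M+700F",
            "1200M+300F", "1500M")
  out <- merge(merge(data.frame(factor = "sex_composition", level = comp),
                     data.frame(method = methods)),
               data.frame(replicate = seq_len(replicates)))
  out[order(out$level, out$method, out$replicate), ]
}

#' Run an accuracy experiment over a design grid
#'
#' Calls `runner(factor, level, method, replicate)` for every row of the
#' design and collects one accuracy record per row. The runner encapsulates
#' simulation + fitting + accuracy for one cell (see the vignette for a
#' desk-scale example); `run_factorial` itself is design bookkeeping, so the
#' same grid can be filled at any simulation scale.
#'
#' @param design A design data.frame from [main_design()] / [sex_design()].
#' @param runner Function of (factor, level, method, replicate) returning a
#'   single numeric accuracy.
#' @return The design with an `accuracy` column appended (an
#'   `accuracy_records` data.frame).
#' @export
run_factorial <- function(design, runner) {
  if (nrow(design) == 0L) {
    design$accuracy <- numeric(0)
    return(design)
  }
  design$accuracy <- vapply(seq_len(nrow(design)), function(i)
    runner(design$factor[i], design$level[i], design$method[i],
           design$replicate[i]), numeric(1))
  if (any(design$accuracy < -1 | design$accuracy > 1, na.rm = TRUE))
    stop("accuracy outside [-1, 1]")
  design
}

#' Fixed-effects ANOVA of accuracy records
#'
#' Additive main-effects linear model with sequential (Type I) sums of
#' squares in the listed factor order, mirroring a GLM significance test:
#' F = MS_factor / MS_error with upper-tail P values, plus Error and
#' Corrected Total rows.
#'
#' @param records data.frame of accuracy records.
#' @param factors Character vector of factor column names, in the order the
#'   sums of squares are to be extracted.
#' @param response Response column name.
#' @return data.frame with columns Source, DF, SS, MS, F, P.
#' @export
anova_glm <- function(records, factors, response = "accuracy") {
  for (f in factors) {
    if (length(unique(records[[f]])) < 2L)
      stop(sprintf("factor '%s' needs at least 2 levels", f))
    records[[f]] <- factor(records[[f]])
  }
  fml <- stats::reformulate(factors, response = response)
  fit <- stats::lm(fml, data = records)
  if (stats::df.residual(fit) < 1L) stop("no residual degrees of freedom")
  a <- stats::anova(fit)
  k <- length(factors)
  tab <- data.frame(Source = c(factors, "Error", "Corrected Total"),
                    DF = c(a$Df, sum(a$Df)),
                    SS = c(a$`Sum Sq`, sum(a$`Sum Sq`)),
                    MS = c(a$`Mean Sq`, NA),
                    F = c(a$`F value`, NA),
                    P = c(a$`Pr(>F)`, NA))
  rownames(tab) <- NULL
  tab
}

#' Duncan's multiple range test
#'
#' Levels are sorted by mean; the critical range for a span of `p` ordered
#' means is `q(1 - alpha_p, p, df) * sqrt(MS_error / n)` with the protected
#' significance level `alpha_p = 1 - (1 - alpha)^(p - 1)` and studentized
#' range quantiles from [stats::qtukey()]. Shared letters mark statistically
#' indistinguishable runs; a non-significant span protects all spans inside
#' it.
#'
#' @param means Named vector of level means.
#' @param n Per-level replication (scalar or per-level vector; unequal
#'   counts use the harmonic mean).
#' @param ms_error Error mean square from the ANOVA.
#' @param df_error Error degrees of freedom (> 0).
#' @param alpha Nominal significance level.
#' @return data.frame with `level`, `mean` and `group` letters, sorted by
#'   decreasing mean.
#' @export
duncan_mrt <- function(means, n, ms_error, df_error, alpha = 0.05) {
  k <- length(means)
  if (k < 2L) stop("need at least 2 levels")
  if (df_error < 1) stop("error degrees of freedom must be positive")
  nh <- if (length(n) > 1L) length(n) / sum(1 / n) else n
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  crit <- vapply(2:k, function(p) {
    ap <- 1 - (1 - alpha)^(p - 1)
    stats::qtukey(1 - ap, p, df_error) * sqrt(ms_error / nh)
  }, numeric(1))
  # nonsig[i, j]: the ordered means i..j are declared homogeneous, either by
  # their own range test or by protection from a non-significant enclosing
  # span (the multiple-range rule: an interval inside a non-significant span
  # is never declared significant)
  nonsig <- diag(TRUE, k)
  for (span in if (k >= 2) k:2 else integer(0)) {
    for (i in 1:(k - span + 1)) {
      j <- i + span - 1
      own <- (m[i] - m[j]) <= crit[span - 1]
      shielded <- (i > 1 && nonsig[i - 1, j]) || (j < k && nonsig[i, j + 1])
      nonsig[i, j] <- own || shielded
    }
  }
  # letters: maximal homogeneous intervals, left to right
  groups <- character(k)
  letter <- 0L
  covered_to <- 0L
  for (i in 1:k) {
    j <- i
    while (j < k && nonsig[i, j + 1]) j <- j + 1L
    if (j > covered_to || (i == 1L && letter == 0L)) {
      letter <- letter + 1L
      groups[i:j] <- paste0(groups[i:j], letters[letter])
      covered_to <- j
    }
  }
  data.frame(level = names(m), mean = unname(m), group = groups)
}

#' Plain-text ANOVA and means reports
#'
#' Aligned text tables mirroring a GLM significance-test report (Source, DF,
#' SS, MS, F, P) and a letter-grouped means table.
#'
#' @param anova_tab Output of [anova_glm()].
#' @param file Optional path (default: print to console).
#' @return The formatted lines, invisibly.
#' @export
report_anova <- function(anova_tab, file = "") {
  fmt <- function(x, d) ifelse(is.na(x), "", formatC(x, digits = d,
                                                     format = "f"))
  lines <- c(sprintf("%-22s %4s %10s %10s %8s %10s", "Source", "DF", "SS",
                     "MS", "F", "P"),
             sprintf("%-22s %4d %10s %10s %8s %10s", anova_tab$Source,
                     anova_tab$DF, fmt(anova_tab$SS, 4),
                     fmt(anova_tab$MS, 4), fmt(anova_tab$F, 2),
                     fmt(anova_tab$P, 4)))
  if (nzchar(file)) writeLines(lines, file) else writeLines(lines)
  invisible(lines)
}

#' @rdname report_anova
#' @param duncan_tab Output of [duncan_mrt()].
#' @export
report_means <- function(duncan_tab, file = "") {
  lines <- c(sprintf("%-16s %10s %8s", "Level", "Mean", "Group"),
             sprintf("%-16s %10.4f %8s", duncan_tab$level, duncan_tab$mean,
                     duncan_tab$group))
  if (nzchar(file)) writeLines(lines, file) else writeLines(lines)
  invisible(lines)
}

#' Expand a one-factor-at-a-time design into full factor columns
#'
#' Records in the study grid vary one factor from a per-trait baseline; for
#' the GLM every record needs all factor columns filled in, with the
#' non-varied factors at their baseline levels. Default baselines are per
#' trait (FD: 60 K markers, 1,500 reference, 150 QTLs; LBW: 45 K, 3,000,
#' 100).
#'
#' @param design A [main_design()] data.frame.
#' @param trait `"FD"` or `"LBW"` (selects the baseline set), or a named
#'   list of baselines `list(marker_density=, n_qtl=, ref_size=)`.
#' @return data.frame with columns `marker_density`, `n_qtl`, `ref_size`,
#'   `method`, `replicate` (plus `accuracy` if present in `design`).
#' @export
design_records <- function(design, trait = c("FD", "LBW")) {
  base <- if (is.list(trait)) trait else {
    trait <- match.arg(trait)
    if (trait == "FD")
      list(marker_density = "60K", n_qtl = "150", ref_size = "1500")
    else
      list(marker_density = "45K", n_qtl = "100", ref_size = "3000")
  }
  out <- data.frame(marker_density = base$marker_density,
                    n_qtl = base$n_qtl, ref_size = base$ref_size,
                    method = design$method, replicate = design$replicate)
  for (f in names(base)) {
    hit <- design$factor == f
    out[[f]][hit] <- design$level[hit]
  }
  if ("accuracy" %in% names(design)) out$accuracy <- design$accuracy
  out
}
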