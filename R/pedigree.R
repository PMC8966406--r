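# Pedigree machinery: numerator relationship matrix A, its sparse inverse with
# inbreeding (ancestor-walk algorithm), and the animal-model BLUP used both for
# within-simulation selection and as the ssGBLUP backbone.

check_pedigree <- function(pedigree) {
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(pedigree)))
    stop("pedigree needs columns id, sire, dam")
  n <- nrow(pedigree)
  id <- pedigree$id
  if (anyDuplicated(id)) stop("pedigree ids must be unique")
  sire <- match(pedigree$sire, id, nomatch = 0L)
  dam <- match(pedigree$dam, id, nomatch = 0L)
  miss_s <- pedigree$sire != 0 & sire == 0L
  miss_d <- pedigree$dam != 0 & dam == 0L
  if (any(miss_s) || any(miss_d))
    stop("parents referenced but absent from the pedigree")
  if (any(sire >= seq_len(n)) || any(dam >= seq_len(n)))
    stop("parents must precede offspring in the pedigree")
  if ("sex" %in% names(pedigree)) {
    sx <- pedigree$sex
    if (any(sx[sire[sire > 0L]] == "F") || any(sx[dam[dam > 0L]] == "M"))
      stop("known sires must be male and known dams female")
  }
  list(id = id, sire = sire, dam = dam, n = n)
}

#' Numerator relationship matrix (tabular method)
#'
#' Dense pedigree relationship matrix A computed by the tabular method.
#' Parents must precede their offspring; 0 denotes an unknown parent.
#'
#' @param pedigree data.frame with columns `id`, `sire`, `dam` (and
#'   optionally `sex` for consistency checks).
#' @return Dense symmetric matrix with dimnames = ids; the diagonal is
#'   1 + the inbreeding coefficient.
#' @export
#' @examples
#' trio <- data.frame(id = 1:3, sire = c(0, 0, 1), dam = c(0, 0, 2))
#' pedigree_A(trio)
pedigree_A <- function(pedigree) {
  p <- check_pedigree(pedigree)
  A <- cpp_A_tabular(p$sire, p$dam)
  dimnames(A) <- list(p$id, p$id)
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Computes inbreeding coefficients by the ancestor-walk algorithm of
#' Meuwissen and Luo and assembles the sparse A-inverse directly from
#' Henderson's rules, without ever forming A.
#'
#' @inheritParams pedigree_A
#' @return List with `Ainv` (a `dsCMatrix`), `F` (inbreeding coefficients)
#'   and `D` (Mendelian sampling variances), all in pedigree order.
#' @export
pedigree_Ainv <- function(pedigree) {
  p <- check_pedigree(pedigree)
  res <- cpp_ainv(p$sire, p$dam)
  Ainv <- Matrix::sparseMatrix(i = res$i, j = res$j, x = res$x,
                               dims = c(p$n, p$n),
                               dimnames = list(p$id, p$id))
  list(Ainv = Matrix::forceSymmetric(Ainv), F = res$F, D = res$D)
}

# Jacobi-preconditioned conjugate gradient for sparse SPD systems.
solve_cg <- function(A, b, tol = 1e-12, maxit = 10000L) {
  x <- numeric(length(b))
  r <- b
  Minv <- 1 / Matrix::diag(A)
  z <- Minv * r
  p <- z
  rz <- sum(r * z)
  b2 <- sqrt(sum(b^2))
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r^2)) <= tol * b2) break
    z <- Minv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  x
}

# Shared mixed-model-equation solver: overall mean as the only fixed effect,
# random animal effect with relationship-inverse Kinv and variance ratio
# lambda = (1 - h2) / h2.
animal_model_mme <- function(y, Kinv, h2, solver = c("direct", "cg")) {
  solver <- match.arg(solver)
  n <- length(y)
  ph <- which(!is.na(y))
  if (length(ph) == 0L) stop("no phenotyped animals")
  if (h2 <= 0 || h2 >= 1) stop("h2 must lie in (0, 1)")
  lambda <- (1 - h2) / h2
  w <- numeric(n); w[ph] <- 1
  yf <- numeric(n); yf[ph] <- y[ph]
  ZtZ <- Matrix::Diagonal(n, w)
  LHS <- rbind(
    cbind(Matrix::Matrix(length(ph), 1, 1), Matrix::Matrix(w, 1, n)),
    cbind(Matrix::Matrix(w, n, 1), ZtZ + lambda * Kinv))
  rhs <- c(sum(yf), yf)
  sol <- if (solver == "direct") {
    as.numeric(Matrix::solve(LHS, rhs))
  } else {
    solve_cg(Matrix::forceSymmetric(LHS), rhs)
  }
  list(mu = sol[1L], ebv = sol[-1L])
}

#' Pedigree BLUP (animal model)
#'
#' Solves the animal-model mixed-model equations with the overall mean as the
#' only fixed effect and variance ratio `lambda = (1 - h2) / h2`, returning an
#' EBV for every pedigree member whether phenotyped or not.
#'
#' @inheritParams pedigree_A
#' @param y Named numeric vector of phenotypes (names = animal ids); animals
#'   absent from `y` (or `NA`) are treated as unphenotyped.
#' @param h2 Heritability used as the (known) variance ratio.
#' @param solver `"direct"` (sparse Cholesky) or `"cg"` (Jacobi-preconditioned
#'   conjugate gradient).
#' @return List with `mu` (estimated mean) and `ebv` (named vector over all
#'   pedigree ids).
#' @export
pedigree_blup <- function(y, pedigree, h2, solver = c("direct", "cg")) {
  p <- check_pedigree(pedigree)
  yfull <- rep(NA_real_, p$n)
  idx <- match(names(y), as.character(p$id))
  if (anyNA(idx)) stop("phenotyped ids missing from the pedigree")
  yfull[idx] <- as.numeric(y)
  Ainv <- pedigree_Ainv(pedigree)$Ainv
  fit <- animal_model_mme(yfull, Ainv, h2, solver)
  list(mu = fit$mu, ebv = stats::setNames(fit$ebv, p$id))
}
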