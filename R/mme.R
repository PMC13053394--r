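# Henderson mixed-model equations for the single-trait repeatability model
#   y = Xb + Za + Wpe + e,  Var(a) = H sigma2a, Var(pe) = I sigma2pe,
#   Var(e) = I sigma2e,
# solved by sparse Cholesky with fixed (input) variance components.

#' Build design matrices for the repeatability model
#'
#' X carries an intercept, contemporary-group and parity one-hot columns
#' (first level of each factor dropped), and an age-in-days linear covariate
#' nested within age-in-years class (one slope column per year class).
#' Z maps records to pedigree animals, W maps records to animals with
#' records.
#'
#' @param records data.frame with columns animal, value, cg, parity and
#'   (optionally) ageDays, ageYears; one trait at a time.
#' @param ped a [Pedigree-class]; every record's animal must be present.
#' @return list(y, X, Z, W, xCols, peIds) with sparse X, Z, W.
#' @export
buildDesign <- function(records, ped) {
  ai <- match(records$animal, animalIds(ped))
  if (anyNA(ai))
    stop("records for animals absent from pedigree: ",
         paste(head(unique(records$animal[is.na(ai)]), 5), collapse = ", "))
  nr <- nrow(records)
  onehot <- function(f, prefix) {
    f <- factor(f)
    if (nlevels(f) < 2) return(NULL)
    lv <- levels(f)[-1]
    M <- Matrix::sparseMatrix(i = which(f %in% lv),
                              j = match(f[f %in% lv], lv),
                              x = 1, dims = c(nr, length(lv)))
    colnames(M) <- paste0(prefix, lv)
    M
  }
  parts <- list(Matrix::Matrix(1, nr, 1, dimnames = list(NULL, "(Intercept)"),
                               sparse = TRUE),
                onehot(records$cg, "cg"),
                onehot(records$parity, "parity"))
  if (all(c("ageDays", "ageYears") %in% names(records))) {
    yr <- factor(records$ageYears)
    S <- Matrix::sparseMatrix(i = seq_len(nr), j = as.integer(yr),
                              x = records$ageDays, dims = c(nr, nlevels(yr)))
    colnames(S) <- paste0("ageDays.yr", levels(yr))
    parts <- c(parts, list(S))
  }
  X <- do.call(cbind, parts[!vapply(parts, is.null, logical(1))])
  Z <- Matrix::sparseMatrix(i = seq_len(nr), j = ai, x = 1,
                            dims = c(nr, nAnimals(ped)))
  colnames(Z) <- animalIds(ped)
  peIds <- sort(unique(ai))
  W <- Matrix::sparseMatrix(i = seq_len(nr), j = match(ai, peIds), x = 1,
                            dims = c(nr, length(peIds)))
  colnames(W) <- animalIds(ped)[peIds]
  list(y = records$value, X = X, Z = Z, W = W, xCols = colnames(X),
       peIds = peIds)
}

#' Solve the mixed-model equations
#'
#' Henderson's equations
#' \deqn{[X'X, X'Z, X'W; Z'X, Z'Z + K^{-1}\lambda_a, Z'W;
#'        W'X, W'Z, W'W + I\lambda_{pe}] [b; a; pe] = [X'y; Z'y; W'y]}
#' with \eqn{\lambda_a = \sigma^2_e/\sigma^2_a},
#' \eqn{\lambda_{pe} = \sigma^2_e/\sigma^2_{pe}}, solved by sparse Cholesky.
#' Rank-deficient fixed-effect columns are detected by pivoted Cholesky of
#' X'X and constrained to zero (recorded in the solution).  The relative
#' residual of the solved system is checked against `tol`.
#'
#' @param design list from [buildDesign()] (or hand-built y, X, Z, W).
#' @param Kinv inverse relationship matrix over the Z columns (H-inverse,
#'   A-inverse or G-inverse; [Hinverse-class] accepted).
#' @param varcomp list(sigma2a, sigma2pe, sigma2e); `sigma2pe` may be `NULL`
#'   or `includePe = FALSE` to drop the permanent-environment term.
#' @param includePe fit permanent-environment effects (default TRUE when W
#'   and sigma2pe are available).
#' @param tol relative-residual tolerance (default 1e-8).
#' @return A [ModelSolution-class].
#' @export
solveMme <- function(design, Kinv, varcomp, includePe = TRUE, tol = 1e-8) {
  y <- design$y; X <- design$X; Z <- design$Z; W <- design$W
  if (is(Kinv, "Hinverse")) Kinv <- relMatrix(Kinv)
  s2a <- varcomp$sigma2a; s2e <- varcomp$sigma2e
  s2pe <- varcomp$sigma2pe
  if (is.null(s2pe) || is.null(W)) includePe <- FALSE
  stopifnot(s2a > 0, s2e > 0)
  la <- s2e / s2a
  X <- as(X, "CsparseMatrix"); Z <- as(Z, "CsparseMatrix")
  p <- ncol(X); na <- ncol(Z)
  # rank check on X via pivoted Cholesky of X'X
  XtX <- as.matrix(Matrix::crossprod(X))
  ch <- suppressWarnings(chol(XtX, pivot = TRUE))
  r <- attr(ch, "rank")
  constrained <- character(0)
  if (r < p) {
    drop <- sort(attr(ch, "pivot")[(r + 1):p])
    constrained <- colnames(X)[drop]
    X <- X[, -drop, drop = FALSE]
    p <- ncol(X)
  }
  top <- cbind(Matrix::crossprod(X), Matrix::crossprod(X, Z))
  mid <- cbind(Matrix::crossprod(Z, X), Matrix::crossprod(Z) + Kinv * la)
  rhs <- c(as.numeric(Matrix::crossprod(X, y)),
           as.numeric(Matrix::crossprod(Z, y)))
  if (includePe) {
    stopifnot(s2pe > 0)
    lpe <- s2e / s2pe
    W <- as(W, "CsparseMatrix")
    npe <- ncol(W)
    top <- cbind(top, Matrix::crossprod(X, W))
    mid <- cbind(mid, Matrix::crossprod(Z, W))
    bot <- cbind(Matrix::crossprod(W, X), Matrix::crossprod(W, Z),
                 Matrix::crossprod(W) + Matrix::Diagonal(npe) * lpe)
    LHS <- rbind(top, mid, bot)
    rhs <- c(rhs, as.numeric(Matrix::crossprod(W, y)))
  } else {
    npe <- 0L
    LHS <- rbind(top, mid)
  }
  LHS <- Matrix::forceSymmetric(LHS)
  fac <- Matrix::Cholesky(LHS, LDL = FALSE, perm = TRUE)
  sol <- as.numeric(Matrix::solve(fac, rhs))
  res <- as.numeric(LHS %*% sol - rhs)
  rel <- sqrt(sum(res^2)) / max(sqrt(sum(rhs^2)), .Machine$double.eps)
  if (rel > tol)
    warning("MME solved with relative residual ", format(rel, digits = 3),
            " above tolerance ", tol)
  b <- setNames(sol[seq_len(p)], colnames(X))
  a <- setNames(sol[p + seq_len(na)], colnames(Z))
  pe <- if (npe) setNames(sol[p + na + seq_len(npe)], colnames(W)) else numeric(0)
  new("ModelSolution", b = b, a = a, pe = pe,
      xCols = design$xCols %||% colnames(X), constrained = constrained,
      factor = fac, dims = c(p = p, na = na, npe = npe),
      varcomp = list(sigma2a = s2a, sigma2pe = if (includePe) s2pe else NULL,
                     sigma2e = s2e),
      residualNorm = rel)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Prediction-error (co)variance of selected breeding values
#'
#' Extracts the animal-block rows/columns of the inverse LHS for the given
#' animal indices and scales by sigma2e: PEV = C^aa sigma2e.
#'
#' @param solution a [ModelSolution-class].
#' @param idx animal indices (into the Z columns of the solved design).
#' @return dense symmetric PEV matrix.
#' @export
gebvPev <- function(solution, idx) {
  dims <- solution@dims
  rows <- dims[["p"]] + idx
  ntot <- sum(dims)
  E <- Matrix::sparseMatrix(i = rows, j = seq_along(rows), x = 1,
                            dims = c(ntot, length(rows)))
  S <- Matrix::solve(solution@factor, E)
  P <- as.matrix(S[rows, , drop = FALSE]) * solution@varcomp$sigma2e
  P <- (P + t(P)) / 2
  dimnames(P) <- NULL
  P
}

#' Variance of the estimated breeding values of selected animals
#'
#' Var(a_hat) = K sigma2a - PEV, the (co)variance of the BLUP estimator,
#' which is what normal-theory SNP-effect tests propagate.
#'
#' @param solution a [ModelSolution-class].
#' @param idx animal indices into the Z columns.
#' @param K the relationship (sub)matrix of those animals implied by the
#'   model (G for genotyped animals under single-step).
#' @return dense symmetric matrix.
#' @export
gebvVariance <- function(solution, idx, K) {
  K * solution@varcomp$sigma2a - gebvPev(solution, idx)
}

#' Fixed-effect-adjusted per-animal phenotype means
#'
#' y* = y - X b_hat per record, then the arithmetic mean per animal; one
#' value per animal.
#'
#' @param records the records the design was built from.
#' @param design the [buildDesign()] output used to solve.
#' @param solution the [ModelSolution-class].
#' @return named numeric vector of adjusted means (names = animal ids).
#' @export
adjustPhenotypes <- function(records, design, solution) {
  X <- design$X
  keep <- setdiff(colnames(X), solution@constrained)
  adj <- design$y - as.numeric(X[, keep, drop = FALSE] %*% solution@b)
  means <- tapply(adj, records$animal, mean)
  setNames(as.numeric(means), names(means))
}
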