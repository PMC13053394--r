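# Multi-trait (pleiotropy) meta-analysis: Cholesky decorrelation of the
# z-scored adjusted traits (c_n = L^-1 g_n), per-CT GWAS producing signed
# t-values, and the multi-trait statistic
#   chi^2 = t_i' V^-1 t_i  on k degrees of freedom,
# with V the correlation of signed t-values across SNPs.

#' Per-animal fixed-effect-adjusted trait means
#'
#' For each trait, solves the repeatability-model MME, pre-adjusts every
#' record for the estimated fixed effects and averages the adjusted records
#' per animal; this matrix (one row per animal, one column per trait, NA
#' where an animal has no record) is the input to the Cholesky transform.
#'
#' @param records long QC'd records data.frame (animal, trait, value, cg,
#'   parity, ageDays, ageYears).
#' @param ped a [Pedigree-class] with genotyped flags.
#' @param relmats [buildRelationshipMatrices()] output.
#' @param varcompList named list per trait of list(sigma2a, sigma2pe,
#'   sigma2e).
#' @return list(means = animals x traits matrix, nbar = mean records per
#'   animal per trait, solutions).
#' @export
adjustedTraitMeans <- function(records, ped, relmats, varcompList) {
  traits <- names(varcompList)
  adj <- list(); nbar <- numeric(0); sols <- list()
  for (t in traits) {
    rec <- records[records$trait == t, , drop = FALSE]
    if (!nrow(rec)) stop("no records for trait ", t)
    d <- buildDesign(rec, ped)
    sol <- solveMme(d, relmats$Hinv, varcompList[[t]])
    adj[[t]] <- adjustPhenotypes(rec, d, sol)
    nbar[t] <- mean(table(rec$animal))
    sols[[t]] <- sol
  }
  ids <- sort(unique(unlist(lapply(adj, names))))
  means <- sapply(traits, function(t) adj[[t]][match(ids, names(adj[[t]]))])
  rownames(means) <- ids
  list(means = means, nbar = nbar, solutions = sols)
}

#' Z-score and Cholesky-decorrelate correlated traits
#'
#' Traits are centred and scaled by their complete-case means/SDs, the
#' covariance (= correlation) of the z-scores on complete cases is Cholesky
#' factored COV = L L', and each animal's score vector is c = L^-1 g by
#' forward substitution.  Because L is lower triangular, CT_j only needs
#' traits 1..j, so animals observing a prefix of the trait order still get
#' their leading CTs; the first CT equals the z-scored first trait exactly.
#'
#' @param traits numeric matrix animals x traits (NA = unobserved), rownames
#'   = animal ids.
#' @param order trait order of the transform (default: column order).
#' @return A [CholeskyTraits-class].
#' @export
zscoreCholesky <- function(traits, order = colnames(traits)) {
  traits <- as.matrix(traits)[, order, drop = FALSE]
  k <- ncol(traits)
  cc <- complete.cases(traits)
  if (sum(cc) < 2) stop("need at least 2 complete-case animals")
  ctr <- colMeans(traits[cc, , drop = FALSE])
  scl <- apply(traits[cc, , drop = FALSE], 2, sd)
  if (any(scl == 0)) stop("constant trait: cannot z-score")
  z <- sweep(sweep(traits, 2, ctr), 2, scl, "/")
  COV <- cov(z[cc, , drop = FALSE])
  COV <- stats::cov2cor(COV)  # z-scores have unit variance by construction
  L <- tryCatch(t(chol(COV)), error = function(e)
    stop("trait covariance not positive definite (duplicated trait?)"))
  ct <- matrix(NA_real_, nrow(traits), k,
               dimnames = list(rownames(traits), order))
  obs <- !is.na(z)
  # longest observed prefix per animal
  pref <- apply(obs, 1, function(o) { w <- which(!o); if (!length(w)) k else w[1] - 1L })
  for (m in sort(unique(pref[pref > 0]))) {
    rows <- which(pref == m)
    sub <- z[rows, seq_len(m), drop = FALSE]
    ct[rows, seq_len(m)] <- t(forwardsolve(L[seq_len(m), seq_len(m), drop = FALSE],
                                           t(sub)))
  }
  new("CholeskyTraits", ct = ct, L = L, cov = COV, center = ctr, scale = scl,
      order = order)
}

# lambda for a CT analysed as per-animal adjusted means: the residual of the
# mean of n records is sigma2pe + sigma2e / n
.ctLambda <- function(varcomp, nbar) {
  (varcomp$sigma2pe + varcomp$sigma2e / nbar) / varcomp$sigma2a
}

#' GWAS of one Cholesky-transformed trait
#'
#' Animal model with the overall mean as the only fixed effect (CTs are
#' already adjusted), solved with the single-step H-inverse over the full
#' pedigree (or a genotyped-only G-inverse when `singleStep = FALSE`), then
#' SNP effects and SEs back-solved as in the single-trait machinery.
#' CTs are unit-variance by construction, so the variance components are
#' sigma2a = 1/(1+lambda), sigma2e = lambda/(1+lambda).
#'
#' @param ctValues named vector of CT values (names = animal ids; NAs
#'   dropped).
#' @param ped a [Pedigree-class] with genotyped flags.
#' @param relmats [buildRelationshipMatrices()] output.
#' @param lambda shrinkage ratio sigma2e/sigma2a for this CT.
#' @param singleStep use the full pedigree H-inverse (default) or restrict
#'   to genotyped animals with G-inverse.
#' @return list(t, effect, se, solution) with one entry per SNP.
#' @export
ctGwas <- function(ctValues, ped, relmats, lambda, singleStep = TRUE) {
  ctValues <- ctValues[!is.na(ctValues)]
  if (stats::sd(ctValues) == 0) {
    nsnp <- ncol(relmats$G@Z)
    return(list(t = rep(0, nsnp), effect = rep(0, nsnp),
                se = rep(0, nsnp), solution = NULL))
  }
  s2a <- 1 / (1 + lambda); s2e <- lambda / (1 + lambda)
  if (singleStep) {
    keep <- names(ctValues) %in% animalIds(ped)
    ctValues <- ctValues[keep]
    ai <- match(names(ctValues), animalIds(ped))
    nr <- length(ctValues)
    design <- list(y = as.numeric(ctValues),
                   X = Matrix::Matrix(1, nr, 1, sparse = TRUE,
                                      dimnames = list(NULL, "(Intercept)")),
                   Z = Matrix::sparseMatrix(i = seq_len(nr), j = ai, x = 1,
                                            dims = c(nr, nAnimals(ped)),
                                            dimnames = list(NULL, animalIds(ped))),
                   W = NULL, xCols = "(Intercept)", peIds = integer(0))
    sol <- solveMme(design, relmats$Hinv,
                    list(sigma2a = s2a, sigma2pe = NULL, sigma2e = s2e),
                    includePe = FALSE)
    idx <- relmats$genotypedIdx
  } else {
    gids <- animalIds(ped)[relmats$genotypedIdx]
    ctValues <- ctValues[names(ctValues) %in% gids]
    ai <- match(names(ctValues), gids)
    nr <- length(ctValues)
    Ginv <- chol2inv(chol(relMatrix(relmats$G)))
    design <- list(y = as.numeric(ctValues),
                   X = Matrix::Matrix(1, nr, 1, sparse = TRUE,
                                      dimnames = list(NULL, "(Intercept)")),
                   Z = Matrix::sparseMatrix(i = seq_len(nr), j = ai, x = 1,
                                            dims = c(nr, length(gids)),
                                            dimnames = list(NULL, gids)),
                   W = NULL, xCols = "(Intercept)", peIds = integer(0))
    sol <- solveMme(design, Matrix::Matrix(Ginv, sparse = FALSE),
                    list(sigma2a = s2a, sigma2pe = NULL, sigma2e = s2e),
                    includePe = FALSE)
    idx <- seq_along(gids)
  }
  ahat <- sol@a[idx]
  u <- backsolveSnpEffects(relmats$G, ahat)
  varA <- gebvVariance(sol, idx, relMatrix(relmats$G))
  se <- snpEffectSe(relmats$G, varA)
  tv <- ifelse(se > 0, u / se, 0)
  list(t = tv, effect = u, se = se, solution = sol)
}

#' Correlation of signed t-values across SNPs
#'
#' Pearson correlation matrix between CT columns over all SNPs; this is the
#' V of the multi-trait chi-square.
#'
#' @param tmat SNPs x traits matrix of signed t-values.
#' @return k x k correlation matrix.
#' @export
snpTCorrelation <- function(tmat) {
  tmat <- as.matrix(tmat)
  if (nrow(tmat) < 2) stop("need at least 2 SNPs")
  if (any(!is.finite(tmat))) stop("non-finite t-values")
  svals <- apply(tmat, 2, sd)
  if (any(svals == 0)) stop("zero-variance t column: ",
                            paste(colnames(tmat)[svals == 0], collapse = ", "))
  cor(tmat)
}

# inverse with condition warning and eigen pseudo-inverse fallback
.safeInverse <- function(V, condMax = 1e8) {
  e <- eigen(V, symmetric = TRUE)
  if (min(e$values) <= 0 || max(e$values) / min(e$values) > condMax) {
    warning("V ill-conditioned (condition number > ", format(condMax),
            "); using pseudo-inverse")
    keep <- e$values > max(e$values) * 1e-12
    return(e$vectors[, keep, drop = FALSE] %*%
             (t(e$vectors[, keep, drop = FALSE]) / e$values[keep]))
  }
  solve(V)
}

#' Multi-trait chi-square statistic
#'
#' chi^2_i = t_i' V^-1 t_i, tested on k degrees of freedom (upper tail).
#'
#' @param tmat SNPs x k matrix of signed t-values (or a single k-vector).
#' @param V k x k correlation matrix of the t-values.
#' @return data.frame(chisq, pValue).
#' @export
multiTraitChisq <- function(tmat, V) {
  if (is.null(dim(tmat))) tmat <- matrix(tmat, nrow = 1)
  k <- ncol(tmat)
  if (!all(dim(V) == k)) stop("V dimension must match trait count")
  Vi <- .safeInverse(V)
  chisq <- rowSums((tmat %*% Vi) * tmat)
  chisq[chisq < 0] <- 0
  data.frame(chisq = chisq, pValue = pchisq(chisq, df = k, lower.tail = FALSE))
}

#' Flag pleiotropic SNPs against chromosome-wise thresholds
#'
#' @param table per-SNP data.frame with chr and pValue columns.
#' @param thresholds [effectiveSegments()] output.
#' @return table with threshold/significant columns.
#' @export
callPleiotropic <- function(table, thresholds) callSignificant(table, thresholds)

#' Run the full multi-trait pleiotropy analysis
#'
#' Z-scores and Cholesky-decorrelates the per-animal adjusted trait means in
#' the given order, runs a GWAS per CT, assembles the signed-t matrix, its
#' across-SNP correlation V, and the k-df chi-square per SNP with
#' chromosome-wise Bonferroni calls.
#'
#' @param adjusted matrix animals x traits of fixed-effect-adjusted means
#'   (rownames = animal ids).
#' @param ped,geno pedigree (genotyped flags set) and genotype data.
#' @param varcompList named list (per source trait) of
#'   list(sigma2a, sigma2pe, sigma2e), used to derive each CT's lambda.
#' @param nbar mean number of records per animal per trait (vector or
#'   scalar) entering the adjusted-mean residual variance.
#' @param order trait order of the transform.
#' @param relmats optional precomputed relationship matrices.
#' @param thresholds optional [effectiveSegments()] output (defaults to 1
#'   Morgan per chromosome, Ne = 182).
#' @param Ne effective population size for default thresholds.
#' @param singleStep see [ctGwas()].
#' @param varcompCt optional explicit per-CT lambda vector overriding the
#'   source-trait derivation.
#' @return list(result = [MultiTraitResult-class], ctResult (per-CT t/effect/
#'   se), cholesky, relmats).
#' @export
runMultiTraitGwas <- function(adjusted, ped, geno, varcompList,
                              nbar = 1, order = colnames(adjusted),
                              relmats = NULL, thresholds = NULL, Ne = 182,
                              singleStep = TRUE, varcompCt = NULL) {
  if (is.null(relmats)) relmats <- buildRelationshipMatrices(ped, geno)
  chl <- zscoreCholesky(adjusted, order)
  k <- length(order)
  nbar <- rep_len(nbar, k)
  lam <- if (!is.null(varcompCt)) rep_len(varcompCt, k)
         else vapply(seq_len(k),
                     function(j) .ctLambda(varcompList[[order[j]]], nbar[j]),
                     numeric(1))
  per <- lapply(seq_len(k), function(j)
    ctGwas(chl@ct[, j], ped, relmats, lam[j], singleStep = singleStep))
  tmat <- sapply(per, `[[`, "t")
  colnames(tmat) <- paste0("t_", order)
  V <- snpTCorrelation(tmat)
  mt <- multiTraitChisq(tmat, V)
  map <- snpMap(geno)
  if (is.null(thresholds)) {
    chrs <- sort(unique(map$chr))
    thresholds <- effectiveSegments(setNames(rep(1, length(chrs)), chrs),
                                    Ne = Ne)
  }
  tab <- cbind(data.frame(snpId = map$snpId, chr = map$chr, posBp = map$posBp),
               as.data.frame(tmat), mt)
  tab <- callSignificant(tab, thresholds)
  res <- new("MultiTraitResult", table = tab, V = V, order = order)
  list(result = res, ctResult = per, cholesky = chl, relmats = relmats)
}
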