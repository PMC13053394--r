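# Single-step GWAS: SNP effects back-solved from GEBVs,
#   u_hat = Z'(Z I Z')^-1 a_hat,
# normal-theory p-values, per-SNP variance explained, and chromosome-wise
# Bonferroni thresholds from the effective number of independent segments.

#' Back-solve SNP effects from GEBVs
#'
#' u_hat = Z'(ZZ')^-1 a_hat with Z the centred genotype covariates of the G
#' construction.  When ZZ' is near-singular a small trace-scaled ridge
#' (`ridge * mean(diag)`) is added and a message emitted; the reconstruction
#' Z u_hat = a_hat then holds to the ridge's accuracy.
#'
#' @param G a [Gmatrix-class] (provides Z; ZZ' = scale * unblended G).
#' @param ahat GEBVs of the genotyped animals, in G's row order.
#' @param ridge relative ridge magnitude (default 1e-8).
#' @return numeric vector of SNP effects (one per SNP).
#' @export
backsolveSnpEffects <- function(G, ahat, ridge = 1e-8) {
  Z <- G@Z
  if (length(ahat) != nrow(Z)) stop("a_hat length must equal #genotyped animals")
  R <- .zztFactor(Z, ridge)
  w <- backsolve(R, backsolve(R, ahat, transpose = TRUE))
  as.numeric(crossprod(Z, w))
}

# Cholesky factor of ZZ', ridged when ill-conditioned.  Centring Z by the
# in-sample allele frequencies puts the ones vector in the null space of
# ZZ', so the ridge fires routinely; Z' annihilates that direction, which
# keeps u_hat = Z'(ZZ' + eps I)^-1 a_hat stable.
.zztFactor <- function(Z, ridge = 1e-8) {
  ZZt <- tcrossprod(Z)
  if (rcond(ZZt) < 1e-8) {
    message("ZZ' near-singular; adding ridge ", ridge, " * mean(diag)")
    diag(ZZt) <- diag(ZZt) + ridge * mean(diag(ZZt))
  }
  chol(ZZt)
}

#' Standard deviations of back-solved SNP effects
#'
#' Propagates Var(a_hat) through the back-solving map K = Z'(ZZ')^-1:
#' Var(u_hat) = K Var(a_hat) K', returning the square roots of its diagonal.
#'
#' @param G a [Gmatrix-class].
#' @param varAhat (co)variance matrix of the GEBVs (see [gebvVariance()]).
#' @param ridge as in [backsolveSnpEffects()].
#' @return numeric vector of SD(u_hat) per SNP (zeros flag degenerate SNPs).
#' @export
snpEffectSe <- function(G, varAhat, ridge = 1e-8) {
  Z <- G@Z
  R <- .zztFactor(Z, ridge)
  # K Var K' diag with K = Z'(ZZ')^-1, via B = R'^-1 Z (so K = (R^-1 B)')
  B <- backsolve(R, Z, transpose = TRUE)      # n x m
  K <- t(backsolve(R, B))                     # m x n
  v <- rowSums((K %*% varAhat) * K)
  v[v < 0] <- 0                               # numerical guard
  sqrt(v)
}

#' Two-sided normal p-values for SNP effects
#'
#' p_i = 2 (1 - Phi(|u_i / SD(u_i)|)).  SNPs with SD = 0 get `NA` with a
#' warning (degenerate, untestable).
#'
#' @param u,sd effect and SD vectors.
#' @return numeric vector of p-values in (0, 1].
#' @export
snpPvalues <- function(u, sd) {
  p <- rep(NA_real_, length(u))
  ok <- !is.na(sd) & sd > 0
  if (any(!ok)) warning(sum(!ok), " SNP(s) with SD = 0: p-value set missing")
  p[ok] <- 2 * pnorm(abs(u[ok] / sd[ok]), lower.tail = FALSE)
  # numerically, 2*(1 - Phi) can round to 0 for huge ratios; keep it positive
  p[ok] <- pmax(p[ok], .Machine$double.xmin)
  p
}

#' Genetic variance explained per SNP
#'
#' 2 p (1 - p) u^2 / sigma2a per SNP; sums over SNP sets are additive.
#'
#' @param u SNP effects.
#' @param freq allele frequencies from the G construction.
#' @param sigma2a additive genetic variance.
#' @return numeric vector of fractions.
#' @export
varianceExplained <- function(u, freq, sigma2a) {
  if (sigma2a <= 0) stop("sigma2a must be positive")
  2 * freq * (1 - freq) * u^2 / sigma2a
}

#' Effective number of independent chromosomal segments and thresholds
#'
#' Me_c = 2 Ne L_c / ln(4 Ne L_c) per chromosome (Goddard/Corbin form) and
#' the chromosome-wise Bonferroni threshold alpha_c = alpha / Me_c.  With
#' `commonLength = TRUE` the genome-wide average chromosome length is used
#' for every chromosome.
#'
#' @param lengthsMorgans named (by chromosome) vector of genetic lengths.
#' @param Ne effective population size (default 182).
#' @param alpha family-wise level (default 0.05).
#' @param commonLength use the average length for all chromosomes.
#' @return data.frame(chr, lengthMorgans, Me, alpha).
#' @export
effectiveSegments <- function(lengthsMorgans, Ne = 182, alpha = 0.05,
                              commonLength = FALSE) {
  L <- lengthsMorgans
  if (commonLength) L <- rep(mean(L), length(L))
  if (any(4 * Ne * L <= 1)) stop("4 * Ne * L must exceed 1")
  Me <- 2 * Ne * L / log(4 * Ne * L)
  chr <- names(lengthsMorgans)
  if (is.null(chr)) chr <- as.character(seq_along(L))
  data.frame(chr = chr, lengthMorgans = as.numeric(lengthsMorgans),
             Me = as.numeric(Me), alpha = alpha / as.numeric(Me))
}

#' Flag significant SNPs against chromosome-wise thresholds
#'
#' Significant iff p <= alpha_c of the SNP's chromosome (boundary inclusive).
#'
#' @param table per-SNP data.frame with columns chr, pValue.
#' @param thresholds output of [effectiveSegments()].
#' @return the table with `threshold` and `significant` columns added.
#' @export
callSignificant <- function(table, thresholds) {
  i <- match(as.character(table$chr), as.character(thresholds$chr))
  if (anyNA(i))
    stop("SNP on chromosome without threshold: ",
         paste(unique(table$chr[is.na(i)]), collapse = ", "))
  table$threshold <- thresholds$alpha[i]
  table$significant <- !is.na(table$pValue) & table$pValue <= table$threshold
  table
}

#' Run the complete single-step GWAS for one trait
#'
#' Pipeline: relationship matrices, repeatability-model MME, SNP-effect
#' back-solving, SE propagation, p-values, variance explained and
#' chromosome-wise significance.
#'
#' @param records QC'd records of one trait.
#' @param ped a [Pedigree-class] with genotyped flags.
#' @param geno a [GenotypeData-class] (genotyped animals).
#' @param varcomp list(sigma2a, sigma2pe, sigma2e) for the trait.
#' @param relmats optional precomputed [buildRelationshipMatrices()] output.
#' @param thresholds optional precomputed [effectiveSegments()] output;
#'   when `NULL`, built from `chrLengthsMorgans`.
#' @param chrLengthsMorgans named per-chromosome genetic lengths (defaults to
#'   1 Morgan per chromosome present in the map).
#' @param Ne effective population size for the thresholds.
#' @param trait trait label for the result object.
#' @return list(result = [GwasResult-class], solution, adjusted, design,
#'   relmats).
#' @export
runSingleStepGwas <- function(records, ped, geno, varcomp, relmats = NULL,
                              thresholds = NULL, chrLengthsMorgans = NULL,
                              Ne = 182, trait = "trait") {
  if (is.null(relmats)) relmats <- buildRelationshipMatrices(ped, geno)
  design <- buildDesign(records, ped)
  sol <- solveMme(design, relmats$Hinv, varcomp)
  idx <- relmats$genotypedIdx
  ahat <- sol@a[idx]
  u <- backsolveSnpEffects(relmats$G, ahat)
  varA <- gebvVariance(sol, idx, relMatrix(relmats$G))
  se <- snpEffectSe(relmats$G, varA)
  p <- snpPvalues(u, se)
  map <- snpMap(geno)
  if (is.null(thresholds)) {
    chrs <- sort(unique(map$chr))
    if (is.null(chrLengthsMorgans))
      chrLengthsMorgans <- setNames(rep(1, length(chrs)), chrs)
    thresholds <- effectiveSegments(chrLengthsMorgans, Ne = Ne)
  }
  tab <- data.frame(snpId = map$snpId, chr = map$chr, posBp = map$posBp,
                    effect = u, se = se,
                    tValue = ifelse(se > 0, u / se, NA_real_),
                    pValue = p,
                    varExplained = varianceExplained(u, relmats$G@freq,
                                                    varcomp$sigma2a))
  tab <- callSignificant(tab, thresholds)
  res <- new("GwasResult", table = tab, trait = trait, thresholds = thresholds)
  adj <- adjustPhenotypes(records, design, sol)
  list(result = res, solution = sol, adjusted = adj, design = design,
       relmats = relmats)
}
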