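# Pedigree and genomic relationship matrices: tabular A, Henderson-rule
# A-inverse with inbreeding (Meuwissen-Luo), VanRaden G, blending, and the
# single-step H-inverse
#   H^-1 = A^-1 + [0 0; 0 G^-1 - A22^-1].

#' Numerator relationship matrix (tabular method)
#'
#' @param ped a [Pedigree-class].
#' @return dense symmetric matrix with animal-id dimnames; diagonal is
#'   1 + inbreeding coefficient.
#' @export
buildA <- function(ped) {
  A <- cpp_tabular_A(sireIdx(ped), damIdx(ped))
  dimnames(A) <- list(animalIds(ped), animalIds(ped))
  A
}

#' Inbreeding coefficients without forming A
#' @param ped a [Pedigree-class].
#' @return named numeric vector of F coefficients.
#' @export
inbreeding <- function(ped) {
  setNames(as.numeric(cpp_inbreeding(sireIdx(ped), damIdx(ped))),
           animalIds(ped))
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding: for animal i with parents s, d the
#' within-family variance is d_i = 0.5 - 0.25(F_s + F_d) (0.75 - 0.25 F when
#' one parent is known, 1 when none), and alpha_i = 1/d_i contributes
#' alpha to (i,i), -alpha/2 to (i,parent) and alpha/4 to the parent block.
#' Nonzeros arise only among animal/sire/dam triplets.
#'
#' @param ped a [Pedigree-class].
#' @return sparse symmetric `Matrix` equal to solve(buildA(ped)).
#' @export
buildAInverse <- function(ped) {
  n <- nAnimals(ped)
  s <- sireIdx(ped); d <- damIdx(ped)
  F <- as.numeric(cpp_inbreeding(s, d))
  Fs <- ifelse(s > 0L, F[pmax(s, 1L)], NA)
  Fd <- ifelse(d > 0L, F[pmax(d, 1L)], NA)
  di <- ifelse(s > 0L & d > 0L, 0.5 - 0.25 * (Fs + Fd),
        ifelse(s > 0L, 0.75 - 0.25 * Fs,
        ifelse(d > 0L, 0.75 - 0.25 * Fd, 1)))
  al <- 1 / di
  I <- integer(0); J <- integer(0); X <- numeric(0)
  idx <- seq_len(n)
  add <- function(i, j, x) { I <<- c(I, i); J <<- c(J, j); X <<- c(X, x) }
  add(idx, idx, al)
  hs <- s > 0L
  add(idx[hs], s[hs], -al[hs] / 2); add(s[hs], idx[hs], -al[hs] / 2)
  add(s[hs], s[hs], al[hs] / 4)
  hd <- d > 0L
  add(idx[hd], d[hd], -al[hd] / 2); add(d[hd], idx[hd], -al[hd] / 2)
  add(d[hd], d[hd], al[hd] / 4)
  hb <- hs & hd
  add(s[hb], d[hb], al[hb] / 4); add(d[hb], s[hb], al[hb] / 4)
  M <- Matrix::sparseMatrix(i = I, j = J, x = X, dims = c(n, n),
                            dimnames = list(animalIds(ped), animalIds(ped)))
  Matrix::forceSymmetric(M)
}

#' Pedigree relationship matrix among the genotyped animals
#' @param ped a [Pedigree-class] with genotyped flags set.
#' @return dense matrix A22.
#' @export
buildA22 <- function(ped) {
  idx <- which(ped@genotyped)
  if (!length(idx)) stop("no genotyped animals flagged in pedigree")
  buildA(ped)[idx, idx, drop = FALSE]
}

#' VanRaden genomic relationship matrix
#'
#' G = ZZ' / (2 sum p_i (1 - p_i)) with Z the allele counts centred by 2p_i.
#' Frequencies are computed from the genotyped set unless supplied.  Missing
#' genotypes must be imputed first (see [imputeMissing()]).
#'
#' @param geno a [GenotypeData-class] over the genotyped animals.
#' @param freq optional allele frequencies (length = number of SNPs).
#' @return A [Gmatrix-class].
#' @export
buildG <- function(geno, freq = NULL) {
  m <- genotypes(geno)
  if (anyNA(m)) stop("missing genotypes present; run imputeMissing() first")
  p <- if (is.null(freq)) colMeans(m) / 2 else freq
  if (length(p) != ncol(m)) stop("frequency vector length mismatch")
  if (any(p <= 0 | p >= 1))
    stop("monomorphic SNP (p = 0 or 1) present; remove before building G")
  Z <- sweep(m, 2, 2 * p)
  sc <- 2 * sum(p * (1 - p))
  G <- tcrossprod(Z) / sc
  new("Gmatrix", mat = G, Z = Z, freq = as.numeric(p), scale = sc,
      blendWeight = 1)
}

#' Blend G with A22 for invertibility
#'
#' weight * G + (1 - weight) * A22; positive definiteness is verified by a
#' Cholesky attempt.
#'
#' @param G a [Gmatrix-class].
#' @param A22 pedigree relationships of the same animals, same order.
#' @param weight blend weight on G (default 0.95).
#' @return A [Gmatrix-class] with `blendWeight` recorded.
#' @export
blendG <- function(G, A22, weight = 0.95) {
  if (weight == 1) return(G)
  if (!all(dim(relMatrix(G)) == dim(A22))) stop("dimension mismatch G vs A22")
  Gb <- weight * relMatrix(G) + (1 - weight) * A22
  ok <- tryCatch({ chol(Gb); TRUE }, error = function(e) FALSE)
  if (!ok) stop("blended G is not positive definite at weight ", weight)
  new("Gmatrix", mat = Gb, Z = G@Z, freq = G@freq, scale = G@scale,
      blendWeight = weight)
}

#' Inverse of the single-step H matrix
#'
#' H^-1 = A^-1 + [0 0; 0 G^-1 - A22^-1] with the correction block placed on
#' the genotyped animals.  Degenerate identities: with no genotyped animals,
#' or with G = A22, H^-1 equals A^-1.
#'
#' @param Ainv sparse A-inverse over all pedigree animals (see
#'   [buildAInverse()]).
#' @param A22 dense pedigree relationships of the genotyped animals.
#' @param G a (blended) [Gmatrix-class] over the same animals, same order.
#' @param genotypedIdx integer indices of the genotyped animals in pedigree
#'   order.
#' @return An [Hinverse-class].
#' @export
buildHInverse <- function(Ainv, A22, G, genotypedIdx) {
  n <- nrow(Ainv)
  H <- as(Ainv, "CsparseMatrix")
  ids <- rownames(Ainv)
  if (length(genotypedIdx)) {
    Gm <- relMatrix(G)
    if (nrow(Gm) != length(genotypedIdx) || nrow(A22) != length(genotypedIdx))
      stop("G / A22 dimension does not match the genotyped index set")
    Ginv <- tryCatch(chol2inv(chol(Gm)),
                     error = function(e) stop("singular G: ", conditionMessage(e)))
    A22inv <- tryCatch(chol2inv(chol(A22)),
                       error = function(e) stop("singular A22: ", conditionMessage(e)))
    H[genotypedIdx, genotypedIdx] <- H[genotypedIdx, genotypedIdx] +
      (Ginv - A22inv)
  }
  new("Hinverse", mat = Matrix::forceSymmetric(Matrix::drop0(H)),
      ids = if (is.null(ids)) as.character(seq_len(n)) else ids,
      genotypedIdx = as.integer(genotypedIdx))
}

#' Build all relationship matrices for a pedigree + genotype pair
#'
#' Convenience wrapper: A-inverse, A22, G (built, blended) and H-inverse,
#' with genotype rows aligned to the pedigree's genotyped flags.
#'
#' @param ped a [Pedigree-class] with genotyped flags.
#' @param geno a [GenotypeData-class] covering (at least) the flagged
#'   animals.
#' @param blendWeight weight on G in the blend (default 0.95).
#' @return list(Ainv, A22, G, Hinv, genotypedIdx).
#' @export
buildRelationshipMatrices <- function(ped, geno, blendWeight = 0.95) {
  idx <- which(ped@genotyped)
  if (!length(idx)) stop("no genotyped animals flagged")
  ids <- animalIds(ped)[idx]
  miss <- setdiff(ids, animalIds(geno))
  if (length(miss))
    stop("genotyped animals absent from genotype data: ",
         paste(head(miss, 5), collapse = ", "))
  gsub <- GenotypeData(genotypes(geno)[ids, , drop = FALSE], snpMap(geno))
  gsub <- imputeMissing(gsub)
  Ainv <- buildAInverse(ped)
  A22 <- buildA22(ped)
  G <- buildG(gsub)
  Gb <- blendG(G, A22, blendWeight)
  Hinv <- buildHInverse(Ainv, A22, Gb, idx)
  list(Ainv = Ainv, A22 = A22, G = Gb, Hinv = Hinv, genotypedIdx = idx)
}
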