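#' @import methods
#' @importFrom stats cor cov complete.cases pchisq phyper pnorm rnorm runif
#'   rpois rbinom sd var qnorm p.adjust setNames aggregate
#' @importFrom utils read.table write.table head
#' @useDynLib PleioGWAS, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom Matrix Matrix
NULL

# ---------------------------------------------------------------------------
# Pedigree
# ---------------------------------------------------------------------------

#' Pedigree of animals in topological order
#'
#' Holds animal identifiers together with 1-based sire/dam indices into the
#' same ordering (0 = unknown parent).  Validity enforces the topological
#' invariant that parents precede their offspring, which every downstream
#' recursion (tabular A, inbreeding, gene dropping) relies on.
#'
#' @slot id character vector of unique animal identifiers.
#' @slot sire,dam integer indices of the parents (0 when unknown).
#' @slot genotyped logical flag per animal.
#' @slot sex optional character vector ("M"/"F"), used by the simulator.
#' @exportClass Pedigree
setClass("Pedigree",
  slots = c(id = "character", sire = "integer", dam = "integer",
            genotyped = "logical", sex = "character"))

setValidity("Pedigree", function(object) {
  n <- length(object@id)
  msg <- character()
  if (length(object@sire) != n || length(object@dam) != n)
    msg <- c(msg, "sire/dam must have one entry per animal")
  if (anyDuplicated(object@id))
    msg <- c(msg, "duplicate animal id")
  if (length(object@genotyped) != n)
    msg <- c(msg, "genotyped flag must have one entry per animal")
  if (n > 0) {
    idx <- seq_len(n)
    bad <- object@sire >= idx | object@dam >= idx |
      object@sire < 0L | object@dam < 0L
    if (any(bad))
      msg <- c(msg, "parents must precede offspring (topological order)")
  }
  if (length(object@sex) && length(object@sex) != n)
    msg <- c(msg, "sex, when present, must have one entry per animal")
  if (length(msg)) msg else TRUE
})

#' Construct a Pedigree from animal/sire/dam identifier triples
#'
#' Rows may arrive in any order; the constructor topologically sorts them so
#' parents precede offspring and fails on cycles (an animal that is its own
#' ancestor).  Parents that appear only as parents are added as founders.
#'
#' @param id,sire,dam character vectors; `"0"`, `""` or `NA` mark an unknown
#'   parent.
#' @param genotyped logical vector (recycled) flagging genotyped animals.
#' @param sex optional character vector of "M"/"F".
#' @return A [Pedigree-class] object.
#' @export
Pedigree <- function(id, sire, dam, genotyped = FALSE, sex = character()) {
  id <- as.character(id); sire <- as.character(sire); dam <- as.character(dam)
  unknown <- function(x) is.na(x) | x == "0" | x == ""
  sire[unknown(sire)] <- NA_character_
  dam[unknown(dam)] <- NA_character_
  if (anyDuplicated(id))
    stop("duplicate animal id: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  if (any(!is.na(sire) & sire == id) || any(!is.na(dam) & dam == id))
    stop("cycle detected in pedigree: animal is its own parent")
  extra <- setdiff(stats::na.omit(c(sire, dam)), id)
  if (length(extra)) {   # implicit founders
    id <- c(extra, id)
    sire <- c(rep(NA_character_, length(extra)), sire)
    dam <- c(rep(NA_character_, length(extra)), dam)
    genotyped <- c(rep(FALSE, length(extra)), rep_len(genotyped, length(id) - length(extra)))
    if (length(sex)) sex <- c(rep(NA_character_, length(extra)), sex)
  } else {
    genotyped <- rep_len(genotyped, length(id))
  }
  n <- length(id)
  pos <- match(id, id)
  si <- match(sire, id); di <- match(dam, id)
  # Kahn topological sort on parent -> child edges
  indeg <- (!is.na(si)) + (!is.na(di))
  children <- split(rep(seq_len(n), 2L), c(si, di))
  ord <- integer(0)
  queue <- which(indeg == 0L)
  indeg <- as.integer(indeg)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, v)
    ch <- children[[as.character(v)]]
    if (!is.null(ch)) {
      for (c0 in ch) {
        indeg[c0] <- indeg[c0] - 1L
        if (indeg[c0] == 0L) queue <- c(queue, c0)
      }
    }
  }
  if (length(ord) < n)
    stop("cycle detected in pedigree involving: ",
         paste(utils::head(id[setdiff(seq_len(n), ord)], 5L), collapse = ", "))
  id <- id[ord]; si <- si[ord]; di <- di[ord]
  genotyped <- genotyped[ord]
  if (length(sex)) sex <- sex[ord]
  rk <- match(seq_len(n), ord)        # old index -> new position
  s2 <- ifelse(is.na(si), 0L, rk[si])
  d2 <- ifelse(is.na(di), 0L, rk[di])
  new("Pedigree", id = id, sire = as.integer(s2), dam = as.integer(d2),
      genotyped = as.logical(genotyped), sex = as.character(if (length(sex)) sex else character()))
}

# ---------------------------------------------------------------------------
# GenotypeData
# ---------------------------------------------------------------------------

#' Genotype matrix with its SNP map
#'
#' Allele counts (0/1/2, `NA` = missing) for a set of animals, with a map
#' giving chromosome and 1-based bp position per SNP.  SNPs are stored sorted
#' by (chromosome, position); duplicated positions are allowed on input and
#' removed by [filterGenotypes()].
#'
#' @slot geno numeric matrix, animals x SNPs, rownames = animal ids,
#'   colnames = SNP ids.
#' @slot map data.frame with columns `snpId`, `chr`, `posBp`.
#' @exportClass GenotypeData
setClass("GenotypeData", slots = c(geno = "matrix", map = "data.frame"))

setValidity("GenotypeData", function(object) {
  msg <- character()
  g <- object@geno; m <- object@map
  if (!all(c("snpId", "chr", "posBp") %in% names(m)))
    msg <- c(msg, "map must have columns snpId, chr, posBp")
  else {
    if (ncol(g) != nrow(m))
      msg <- c(msg, "SNP count mismatch between matrix and map")
    if (anyDuplicated(m$snpId)) msg <- c(msg, "duplicate SNP ids in map")
    if (any(m$chr < 1) || any(m$posBp < 1))
      msg <- c(msg, "chromosome and position must be positive")
  }
  if (is.null(rownames(g))) msg <- c(msg, "genotype matrix must have animal id rownames")
  bad <- g[!is.na(g)]
  # exact {0,1,2} coding is enforced at the readers; after mean imputation
  # fractional dosages in [0,2] are legal
  if (length(bad) && (min(bad) < 0 || max(bad) > 2))
    msg <- c(msg, "genotype dosages must lie in [0, 2]")
  if (length(msg)) msg else TRUE
})

#' @param geno,map see slots of [GenotypeData-class].
#' @rdname GenotypeData-class
#' @export
GenotypeData <- function(geno, map) {
  map <- as.data.frame(map)
  map$chr <- as.integer(map$chr); map$posBp <- as.integer(map$posBp)
  map$snpId <- as.character(map$snpId)
  o <- order(map$chr, map$posBp)
  map <- map[o, , drop = FALSE]
  rownames(map) <- NULL
  geno <- geno[, o, drop = FALSE]
  colnames(geno) <- map$snpId
  new("GenotypeData", geno = geno, map = map)
}

# ---------------------------------------------------------------------------
# Relationship matrices
# ---------------------------------------------------------------------------

#' VanRaden genomic relationship matrix
#'
#' G = ZZ' / (2 * sum p_i (1 - p_i)) with Z the genotype matrix centred by
#' twice the allele frequency.  Stores the frequencies and centred Z so SNP
#' effects can later be back-solved consistently with the G used in the
#' evaluation.
#'
#' @slot mat symmetric matrix over genotyped animals.
#' @slot Z centred genotype covariates (animals x SNPs).
#' @slot freq allele frequencies used for centring.
#' @slot scale the scalar 2 * sum p(1-p).
#' @slot blendWeight weight w in w*G + (1-w)*A22 (1 = unblended).
#' @exportClass Gmatrix
setClass("Gmatrix",
  slots = c(mat = "matrix", Z = "matrix", freq = "numeric",
            scale = "numeric", blendWeight = "numeric"))

setValidity("Gmatrix", function(object) {
  msg <- character()
  if (nrow(object@mat) != ncol(object@mat)) msg <- c(msg, "G must be square")
  if (length(object@mat) &&
      max(abs(object@mat - t(object@mat))) > 1e-8)
    msg <- c(msg, "G must be symmetric")
  if (length(msg)) msg else TRUE
})

#' Inverse of the combined pedigree-genomic relationship matrix
#'
#' H^-1 = A^-1 + [0 0; 0 G^-1 - A22^-1], the correction block sitting on the
#' genotyped animals.
#'
#' @slot mat sparse symmetric matrix over all pedigree animals.
#' @slot ids animal ids (pedigree order).
#' @slot genotypedIdx integer indices of genotyped animals.
#' @exportClass Hinverse
setClass("Hinverse",
  slots = c(mat = "Matrix", ids = "character", genotypedIdx = "integer"))

# ---------------------------------------------------------------------------
# Model solution / GWAS results
# ---------------------------------------------------------------------------

#' Solution of the mixed-model equations
#'
#' @slot b,a,pe solution vectors for fixed, additive-genetic and
#'   permanent-environment effects.
#' @slot xCols names of the fixed-effect columns (dropped columns recorded in
#'   `constrained`).
#' @slot constrained names of rank-deficient X columns constrained to zero.
#' @slot factor the sparse Cholesky factor of the LHS, kept for
#'   prediction-error-variance extraction.
#' @slot dims integer vector (p, nAnimal, nPe).
#' @slot varcomp the variance components used.
#' @slot residualNorm relative residual of the solved system.
#' @exportClass ModelSolution
setClass("ModelSolution",
  slots = c(b = "numeric", a = "numeric", pe = "numeric", xCols = "character",
            constrained = "character", factor = "ANY", dims = "integer",
            varcomp = "list", residualNorm = "numeric"))

#' Per-SNP single-trait GWAS result
#'
#' @slot table data.frame with one row per SNP: snpId, chr, posBp, effect,
#'   se, tValue, pValue, varExplained, threshold, significant.
#' @slot trait trait label.
#' @slot thresholds per-chromosome significance thresholds used.
#' @exportClass GwasResult
setClass("GwasResult",
  slots = c(table = "data.frame", trait = "character", thresholds = "data.frame"))

setValidity("GwasResult", function(object) {
  tb <- object@table
  msg <- character()
  need <- c("snpId", "chr", "posBp", "effect", "se", "tValue", "pValue")
  if (!all(need %in% names(tb)))
    msg <- c(msg, paste("table must contain", paste(need, collapse = ", ")))
  else {
    p <- tb$pValue[!is.na(tb$pValue)]
    if (length(p) && (any(p <= 0) || any(p > 1)))
      msg <- c(msg, "p-values must lie in (0, 1]")
    if ("significant" %in% names(tb) && "threshold" %in% names(tb)) {
      sig <- tb$significant & !is.na(tb$pValue)
      if (any(sig & tb$pValue > tb$threshold))
        msg <- c(msg, "significant flag inconsistent with threshold")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Cholesky-transformed traits
#'
#' @slot ct matrix animals x traits of Cholesky scores (NA where the trait
#'   prefix needed for the transform is unobserved).
#' @slot L lower-triangular Cholesky factor of the z-scored trait covariance.
#' @slot cov the covariance (= correlation) matrix decomposed.
#' @slot center,scale complete-case means and SDs used for z-scoring.
#' @slot order trait order of the transform.
#' @exportClass CholeskyTraits
setClass("CholeskyTraits",
  slots = c(ct = "matrix", L = "matrix", cov = "matrix",
            center = "numeric", scale = "numeric", order = "character"))

#' Multi-trait (pleiotropy) GWAS result
#'
#' @slot table data.frame: snpId, chr, posBp, t per CT, chisq, pValue,
#'   threshold, significant.
#' @slot V correlation matrix of signed t-values across SNPs.
#' @slot order trait order of the Cholesky transform.
#' @exportClass MultiTraitResult
setClass("MultiTraitResult",
  slots = c(table = "data.frame", V = "matrix", order = "character"))

setValidity("MultiTraitResult", function(object) {
  msg <- character()
  V <- object@V
  if (max(abs(V - t(V))) > 1e-10 || any(abs(diag(V) - 1) > 1e-10))
    msg <- c(msg, "V must be a symmetric correlation matrix with unit diagonal")
  if ("chisq" %in% names(object@table) && any(object@table$chisq < -1e-10, na.rm = TRUE))
    msg <- c(msg, "chi-square statistics must be non-negative")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "Pedigree", function(object) {
  cat("Pedigree with", length(object@id), "animals (",
      sum(object@sire == 0L & object@dam == 0L), "founders,",
      sum(object@genotyped), "genotyped )\n")
})

setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", nrow(object@geno), "animals x", ncol(object@geno),
      "SNPs on", length(unique(object@map$chr)), "chromosome(s);",
      sum(is.na(object@geno)), "missing calls\n")
})

setMethod("show", "Gmatrix", function(object) {
  cat("VanRaden G over", nrow(object@mat), "genotyped animals; scale =",
      format(object@scale, digits = 5), "; blend weight =", object@blendWeight, "\n")
})

setMethod("show", "Hinverse", function(object) {
  cat("H-inverse over", length(object@ids), "animals (",
      length(object@genotypedIdx), "genotyped );",
      length(object@mat@x), "stored entries\n")
})

setMethod("show", "ModelSolution", function(object) {
  cat("ModelSolution:", length(object@b), "fixed effects,",
      length(object@a), "breeding values,", length(object@pe),
      "permanent-environment effects; rel. residual =",
      format(object@residualNorm, digits = 3), "\n")
  if (length(object@constrained))
    cat("  constrained to zero:", paste(object@constrained, collapse = ", "), "\n")
})

setMethod("show", "GwasResult", function(object) {
  cat("GwasResult [", object@trait, "]: ", nrow(object@table), " SNPs, ",
      sum(object@table$significant, na.rm = TRUE), " significant\n", sep = "")
})

setMethod("show", "CholeskyTraits", function(object) {
  cat("CholeskyTraits over", nrow(object@ct), "animals; order:",
      paste(object@order, collapse = " -> "), "\n")
})

setMethod("show", "MultiTraitResult", function(object) {
  cat("MultiTraitResult:", nrow(object@table), "SNPs,",
      sum(object@table$significant, na.rm = TRUE), "significant; traits:",
      paste(object@order, collapse = " -> "), "\n")
})

# ---------------------------------------------------------------------------
# Accessors
# ---------------------------------------------------------------------------

#' @export
setGeneric("animalIds", function(x) standardGeneric("animalIds"))
#' @export
setGeneric("nAnimals", function(x) standardGeneric("nAnimals"))
#' @export
setGeneric("isGenotyped", function(x) standardGeneric("isGenotyped"))
#' @export
setGeneric("isGenotyped<-", function(x, value) standardGeneric("isGenotyped<-"))
#' @export
setGeneric("snpMap", function(x) standardGeneric("snpMap"))
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @export
setGeneric("resultsTable", function(x) standardGeneric("resultsTable"))
#' @export
setGeneric("relMatrix", function(x) standardGeneric("relMatrix"))

#' @describeIn Pedigree-class animal identifiers (topological order).
#' @param x object.
#' @export
setMethod("animalIds", "Pedigree", function(x) x@id)
#' @describeIn Pedigree-class number of animals.
#' @export
setMethod("nAnimals", "Pedigree", function(x) length(x@id))
#' @describeIn Pedigree-class logical genotyped flag.
#' @export
setMethod("isGenotyped", "Pedigree", function(x) setNames(x@genotyped, x@id))

#' @describeIn Pedigree-class set the genotyped flag from a vector of ids.
#' @param value character vector of genotyped animal ids (or logical flag).
#' @export
setMethod("isGenotyped<-", "Pedigree", function(x, value) {
  if (is.character(value)) {
    miss <- setdiff(value, x@id)
    if (length(miss)) stop("unknown animal ids: ", paste(head(miss, 5), collapse = ", "))
    x@genotyped <- x@id %in% value
  } else x@genotyped <- rep_len(as.logical(value), length(x@id))
  validObject(x)
  x
})

#' @describeIn GenotypeData-class animal ids of the genotype rows.
#' @export
setMethod("animalIds", "GenotypeData", function(x) rownames(x@geno))
#' @describeIn GenotypeData-class number of genotyped animals.
#' @export
setMethod("nAnimals", "GenotypeData", function(x) nrow(x@geno))
#' @describeIn GenotypeData-class the SNP map data.frame.
#' @export
setMethod("snpMap", "GenotypeData", function(x) x@map)
#' @describeIn GenotypeData-class the allele-count matrix.
#' @export
setMethod("genotypes", "GenotypeData", function(x) x@geno)

#' @describeIn Gmatrix-class the genomic relationship matrix itself.
#' @param x object.
#' @export
setMethod("relMatrix", "Gmatrix", function(x) x@mat)
#' @describeIn Hinverse-class the sparse H-inverse matrix.
#' @param x object.
#' @export
setMethod("relMatrix", "Hinverse", function(x) x@mat)

#' @describeIn GwasResult-class the per-SNP results data.frame.
#' @param x object.
#' @export
setMethod("resultsTable", "GwasResult", function(x) x@table)
#' @describeIn MultiTraitResult-class the per-SNP results data.frame.
#' @param x object.
#' @export
setMethod("resultsTable", "MultiTraitResult", function(x) x@table)

#' Sire/dam index accessors
#'
#' @param x a [Pedigree-class].
#' @return integer vector of 1-based parent indices, 0 = unknown.
#' @export
sireIdx <- function(x) x@sire
#' @rdname sireIdx
#' @export
damIdx <- function(x) x@dam
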