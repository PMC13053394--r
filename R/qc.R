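# Phenotype and genotype quality control.  Thresholds follow the strict
# inequalities as printed ("<", ">"); every filter's removals are logged in a
# QcReport data.frame (step, unit, removed, retained), counts non-increasing
# along the chain.

.qcStep <- function(report, step, unit, before, after) {
  rbind(report, data.frame(step = step, unit = unit,
                           removed = before - after, retained = after))
}

#' Phenotype quality control
#'
#' Applied in order: age window (records from animals younger than
#' `minAgeYears` or older than `maxAgeYears` removed), contemporary groups
#' with fewer than `cgMin` animals removed, per-CG outliers more than
#' `sdLimit` standard deviations from the CG mean removed for the traits in
#' `sdTraits`, and CGs without variability removed for the traits in
#' `varTraits` (the score-trait rule).  The outlier pass is applied once, not
#' iterated.
#'
#' @param records long data.frame (animal, trait, value, cg, ...; `ageYears`
#'   needed for the age filter).
#' @param cgMin minimum animals per contemporary group (default 3).
#' @param sdLimit outlier cut in CG standard deviations (default 3).
#' @param minAgeYears,maxAgeYears age window in years (default 1-15).
#' @param sdTraits traits subject to the SD-outlier rule.
#' @param varTraits traits subject to the zero-variance-CG rule.
#' @return list(records, report).
#' @export
filterPhenotypes <- function(records, cgMin = 3, sdLimit = 3,
                             minAgeYears = 1, maxAgeYears = 15,
                             sdTraits = c("MWT", "MHT"), varTraits = "BCS") {
  known <- union(sdTraits, varTraits)
  bad <- setdiff(unique(records$trait), known)
  if (length(bad))
    stop("unknown trait label: ", paste(bad, collapse = ", "))
  report <- data.frame(step = character(), unit = character(),
                       removed = integer(), retained = integer())
  n0 <- nrow(records)
  if ("ageYears" %in% names(records)) {
    records <- records[records$ageYears >= minAgeYears &
                         records$ageYears <= maxAgeYears, , drop = FALSE]
  }
  report <- .qcStep(report, "age_window", "records", n0, nrow(records))
  # CG size: animals (not records) per trait x CG
  key <- interaction(records$trait, records$cg, drop = TRUE)
  sizes <- tapply(records$animal, key, function(a) length(unique(a)))
  n1 <- nrow(records)
  records <- records[sizes[as.character(key)] >= cgMin, , drop = FALSE]
  report <- .qcStep(report, "cg_size", "records", n1, nrow(records))
  # 3-SD outliers within CG, size traits only (single pass)
  n2 <- nrow(records)
  isSd <- records$trait %in% sdTraits
  if (any(isSd)) {
    key <- interaction(records$trait, records$cg, drop = TRUE)
    mu <- tapply(records$value, key, mean)
    sdv <- tapply(records$value, key, sd)
    dev <- abs(records$value - mu[as.character(key)])
    lim <- sdLimit * sdv[as.character(key)]
    out <- isSd & !is.na(lim) & lim > 0 & dev > lim
    records <- records[!out, , drop = FALSE]
  }
  report <- .qcStep(report, "sd_outlier", "records", n2, nrow(records))
  # zero-variance CGs for the score trait
  n3 <- nrow(records)
  isVar <- records$trait %in% varTraits
  if (any(isVar)) {
    key <- interaction(records$trait, records$cg, drop = TRUE)
    vr <- tapply(records$value, key, function(v) if (length(v) > 1) var(v) else 0)
    novar <- isVar & vr[as.character(key)] <= 0
    records <- records[!novar, , drop = FALSE]
  }
  report <- .qcStep(report, "cg_no_variability", "records", n3, nrow(records))
  rownames(records) <- NULL
  list(records = records, report = report)
}

#' Genotype quality control
#'
#' Filters applied in order: SNPs with unknown (non-positive) position or
#' duplicated chromosome+position (both members removed), SNPs on
#' chromosomes above `maxAutosome`, SNPs with call rate below `callRate`,
#' animals with call rate below `callRate`, SNPs with minor allele frequency
#' below `maf` (frequencies computed on the retained animals), and SNPs with
#' |observed - expected heterozygosity| above `hetDiff` where expected =
#' 2p(1-p).  All comparisons are strict.  An exact HWE p-value column is
#' included in the report attributes for inspection but plays no role in the
#' filter.
#'
#' @param geno a [GenotypeData-class].
#' @param callRate,maf,hetDiff,maxAutosome thresholds (defaults 0.90, 0.05,
#'   0.15, 29).
#' @return list(geno, report).
#' @export
filterGenotypes <- function(geno, callRate = 0.90, maf = 0.05,
                            hetDiff = 0.15, maxAutosome = 29) {
  m <- genotypes(geno); map <- snpMap(geno)
  report <- data.frame(step = character(), unit = character(),
                       removed = integer(), retained = integer())
  # 1. position validity (duplicates removed pairwise, unknown positions)
  key <- paste(map$chr, map$posBp)
  keep <- map$posBp >= 1 & !(key %in% key[duplicated(key)])
  report <- .qcStep(report, "position", "snps", ncol(m), sum(keep))
  m <- m[, keep, drop = FALSE]; map <- map[keep, , drop = FALSE]
  # 2. autosome
  keep <- map$chr >= 1 & map$chr <= maxAutosome
  report <- .qcStep(report, "autosome", "snps", ncol(m), sum(keep))
  m <- m[, keep, drop = FALSE]; map <- map[keep, , drop = FALSE]
  # 3. SNP call rate
  cr <- colMeans(!is.na(m))
  keep <- !(cr < callRate)
  report <- .qcStep(report, "snp_call_rate", "snps", ncol(m), sum(keep))
  m <- m[, keep, drop = FALSE]; map <- map[keep, , drop = FALSE]
  # 4. animal call rate
  if (ncol(m)) {
    acr <- rowMeans(!is.na(m))
    keepA <- !(acr < callRate)
  } else keepA <- rep(TRUE, nrow(m))
  report <- .qcStep(report, "animal_call_rate", "animals", nrow(m), sum(keepA))
  m <- m[keepA, , drop = FALSE]
  # 5. MAF (on retained animals)
  p <- colMeans(m, na.rm = TRUE) / 2
  mafObs <- pmin(p, 1 - p)
  keep <- !(mafObs < maf)
  report <- .qcStep(report, "maf", "snps", ncol(m), sum(keep))
  m <- m[, keep, drop = FALSE]; map <- map[keep, , drop = FALSE]
  p <- p[keep]
  # 6. heterozygosity deviation from Hardy-Weinberg expectation
  hetObs <- colMeans(m == 1, na.rm = TRUE)
  hetExp <- 2 * p * (1 - p)
  keep <- !(abs(hetObs - hetExp) > hetDiff)
  report <- .qcStep(report, "het_diff", "snps", ncol(m), sum(keep))
  hweP <- .hweExactP(m)
  m <- m[, keep, drop = FALSE]; map <- map[keep, , drop = FALSE]
  attr(report, "hweP") <- data.frame(snpId = names(hweP), hweP = unname(hweP))
  list(geno = GenotypeData(m, map), report = report)
}

# exact Hardy-Weinberg p-values (conditional on allele counts), informational
.hweExactP <- function(m) {
  p <- vapply(seq_len(ncol(m)), function(j) {
    g <- m[, j]; g <- g[!is.na(g)]
    nAA <- sum(g == 0); nAB <- sum(g == 1); nBB <- sum(g == 2)
    n <- nAA + nAB + nBB
    if (n == 0) return(NA_real_)
    nB <- nAB + 2 * nBB
    hets <- seq(nB %% 2, min(nB, 2 * n - nB), by = 2)
    logp <- lchoose(n, (nB - hets) / 2) +
      lchoose(n - (nB - hets) / 2, hets) + hets * log(2) -
      lchoose(2 * n, nB)
    # probability of each heterozygote count given allele counts
    pr <- exp(logp - max(logp)); pr <- pr / sum(pr)
    sum(pr[pr <= pr[match(nAB, hets)] + 1e-12])
  }, numeric(1))
  names(p) <- colnames(m)
  p
}

#' Mean-impute missing genotypes at twice the allele frequency
#'
#' Standard pre-G imputation: a missing call is replaced by 2p of its SNP,
#' computed from the non-missing calls.
#'
#' @param geno a [GenotypeData-class].
#' @return A [GenotypeData-class] without missing values (codes become
#'   fractional, which downstream centring handles).
#' @export
imputeMissing <- function(geno) {
  m <- genotypes(geno)
  if (anyNA(m)) {
    mn <- colMeans(m, na.rm = TRUE)
    idx <- which(is.na(m), arr.ind = TRUE)
    m[idx] <- mn[idx[, 2]]
  }
  new("GenotypeData", geno = m, map = snpMap(geno))
}
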