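# Forward simulator: multi-generation pedigree, linked biallelic SNPs by
# gene dropping, and repeated phenotype records under the repeatability model
# with known QTL architecture.  Every stage is deterministic given the seed.

#' Simulation configuration
#'
#' Defaults describe a desk-scale breeding population with three genetically
#' correlated mature-size-type traits (a score trait and two size traits),
#' repeated records, herd-year-season contemporary groups, and a mix of
#' trait-specific and pleiotropic QTL on top of a pedigree-based polygenic
#' background.
#'
#' @param nFounders,nGenerations,offspringPerMating pedigree shape;
#'   generations are non-overlapping, each female of the previous generation
#'   is mated to a random male (no selfing).
#' @param nSnps,nChromosomes,chrLengthMorgans,chrLengthBp marker panel; SNP
#'   positions are uniform per chromosome, recombination is Haldane with
#'   `chrLengthMorgans` per chromosome.
#' @param mafRange founder minor-allele-frequency range (uniform draw).
#' @param ldDecayRate per-bp decay of the founder-haplotype AR(1) copula
#'   correlation, rho(d) = exp(-ldDecayRate * d); larger = faster LD decay.
#' @param traits data.frame with columns `name`, `sigma2a` (polygenic
#'   additive variance), `sigma2pe`, `sigma2e`.
#' @param geneticCor k x k genetic correlation matrix of the polygenic terms.
#' @param qtl `NULL` for the default architecture (one trait-specific QTL per
#'   trait plus `nPleiotropicQtl` QTL hitting all traits), or a data.frame
#'   with column `snpIdx` and one effect column per trait.
#' @param qtlVarFrac fraction of `sigma2a` each auto-placed QTL explains.
#' @param nPleiotropicQtl number of auto-placed pleiotropic QTL.
#' @param nCg,sigma2cg number of contemporary groups and the variance of
#'   their (fixed) effects.
#' @param parityLevels,recordsRange parity classes and the range of records
#'   per animal.
#' @param ageSlopeSd SD of the per-year-class linear age-in-days slope.
#' @param propGenotyped fraction of animals genotyped.
#' @param recordedSex `"F"`, `"M"` or `"both"`: which animals get records.
#' @param dropMhtFraction fraction of recorded animals whose last-trait
#'   records are dropped (emulates the unbalanced record counts of height
#'   measurements).
#' @param seed integer seed fixing all randomness.
#' @return A classed list (`SimConfig`).
#' @export
simConfig <- function(nFounders = 100, nGenerations = 3, offspringPerMating = 2,
                      nSnps = 2000, nChromosomes = 5, chrLengthMorgans = 1,
                      chrLengthBp = 1e8, mafRange = c(0.05, 0.5),
                      ldDecayRate = 1e-5,
                      traits = data.frame(
                        name = c("BCS", "MWT", "MHT"),
                        sigma2a = c(0.25, 0.45, 0.55),
                        sigma2pe = c(0.20, 0.20, 0.15),
                        sigma2e = c(0.55, 0.35, 0.30)),
                      geneticCor = NULL,
                      qtl = NULL, qtlVarFrac = 0.05, nPleiotropicQtl = 2,
                      nCg = 25, sigma2cg = 0.5, parityLevels = 3,
                      recordsRange = c(1, 3), ageSlopeSd = 5e-4,
                      propGenotyped = 0.5, recordedSex = "F",
                      dropMhtFraction = 0.5, seed = 1) {
  k <- nrow(traits)
  if (is.null(geneticCor)) {
    geneticCor <- diag(k)
    if (k == 3) { # moderate-to-high correlations typical of size traits
      geneticCor[1, 2] <- geneticCor[2, 1] <- 0.5
      geneticCor[1, 3] <- geneticCor[3, 1] <- 0.3
      geneticCor[2, 3] <- geneticCor[3, 2] <- 0.7
    }
  }
  stopifnot(nFounders >= 2, nGenerations >= 0, offspringPerMating >= 1,
            all(traits$sigma2a > 0), all(traits$sigma2pe > 0),
            all(traits$sigma2e > 0), propGenotyped > 0, propGenotyped <= 1,
            mafRange[1] > 0, mafRange[2] <= 0.5)
  cfg <- list(nFounders = nFounders, nGenerations = nGenerations,
              offspringPerMating = offspringPerMating, nSnps = nSnps,
              nChromosomes = nChromosomes, chrLengthMorgans = chrLengthMorgans,
              chrLengthBp = chrLengthBp, mafRange = mafRange,
              ldDecayRate = ldDecayRate, traits = traits,
              geneticCor = geneticCor, qtl = qtl, qtlVarFrac = qtlVarFrac,
              nPleiotropicQtl = nPleiotropicQtl, nCg = nCg,
              sigma2cg = sigma2cg, parityLevels = parityLevels,
              recordsRange = recordsRange, ageSlopeSd = ageSlopeSd,
              propGenotyped = propGenotyped, recordedSex = recordedSex,
              dropMhtFraction = dropMhtFraction, seed = seed)
  class(cfg) <- "SimConfig"
  cfg
}

#' Simulate a multi-generation pedigree
#'
#' Non-overlapping generations; every female of the previous generation is
#' mated to a random male of that generation (no selfing by construction),
#' producing `offspringPerMating` offspring of random sex.
#'
#' @param nFounders,nGenerations,offspringPerMating see [simConfig()].
#' @param seed optional seed (set locally when given).
#' @return A [Pedigree-class] with the `sex` slot filled.
#' @export
simulatePedigree <- function(nFounders, nGenerations, offspringPerMating = 2,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nFounders < 2) stop("need at least 2 founders")
  id <- paste0("G0_", seq_len(nFounders))
  sex <- rep(c("M", "F"), length.out = nFounders)
  sire <- integer(nFounders); dam <- integer(nFounders)
  prev <- seq_len(nFounders)
  n <- nFounders
  for (g in seq_len(nGenerations)) {
    males <- prev[sex[prev] == "M"]; females <- prev[sex[prev] == "F"]
    if (!length(males) || !length(females)) break
    cur <- integer(0)
    cnt <- 0L
    for (f in females) {
      m <- if (length(males) == 1L) males else sample(males, 1L)
      for (o in seq_len(offspringPerMating)) {
        n <- n + 1L; cnt <- cnt + 1L
        id[n] <- paste0("G", g, "_", cnt)
        sire[n] <- m; dam[n] <- f
        sex[n] <- if (runif(1) < 0.5) "M" else "F"
        cur <- c(cur, n)
      }
    }
    prev <- cur
  }
  new("Pedigree", id = id, sire = as.integer(sire), dam = as.integer(dam),
      genotyped = rep(FALSE, n), sex = sex)
}

# one meiosis along one chromosome: Haldane crossovers, random start phase
.meiosis <- function(h1, h2, posM, lenM) {
  nx <- rpois(1L, lenM)
  start <- rbinom(1L, 1L, 0.5)
  if (nx == 0L) return(if (start == 0L) h1 else h2)
  xpos <- sort(runif(nx, 0, lenM))
  seg <- findInterval(posM, xpos)
  ifelse((seg + start) %% 2L == 0L, h1, h2)
}

#' Simulate genotypes by gene dropping
#'
#' Founder haplotypes are drawn from a Gaussian AR(1) copula so each SNP has
#' its configured allele frequency while adjacent SNPs show LD that decays
#' with distance; descendants are produced by gene dropping with Haldane
#' recombination.
#'
#' @param ped a [Pedigree-class].
#' @param config a `SimConfig` (only the marker-panel entries are used).
#' @param seed optional seed.
#' @param keepHaplotypes keep phased haplotypes of every animal (needed for
#'   Mendelian-consistency checks).
#' @return list with `genotypes` ([GenotypeData-class] over all pedigree
#'   animals), `founderFreq` (configured allele frequencies) and, optionally,
#'   `haplotypes` (per chromosome, a list of two n x m 0/1 matrices).
#' @export
simulateGenotypes <- function(ped, config, seed = NULL, keepHaplotypes = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  n <- nAnimals(ped)
  nChr <- config$nChromosomes
  perChr <- rep(config$nSnps %/% nChr, nChr)
  if (config$nSnps %% nChr) perChr[seq_len(config$nSnps %% nChr)] <-
    perChr[seq_len(config$nSnps %% nChr)] + 1L
  founders <- which(sireIdx(ped) == 0L & damIdx(ped) == 0L)
  geno <- matrix(0, n, 0)
  mapL <- list(); freqL <- list(); hapL <- list()
  snpOff <- 0L
  for (ch in seq_len(nChr)) {
    m <- perChr[ch]
    pos <- sort(sample.int(config$chrLengthBp, m))
    posM <- pos * (config$chrLengthMorgans / config$chrLengthBp)
    maf <- runif(m, config$mafRange[1], config$mafRange[2])
    p <- ifelse(runif(m) < 0.5, maf, 1 - maf)  # counted-allele frequency
    # founder haplotypes: AR(1) latent Gaussian thresholded at qnorm(p)
    nh <- 2L * length(founders)
    z <- matrix(0, nh, m)
    z[, 1] <- rnorm(nh)
    if (m > 1) for (j in 2:m) {
      rho <- exp(-config$ldDecayRate * (pos[j] - pos[j - 1]))
      z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * rnorm(nh)
    }
    thr <- qnorm(p)
    hapF <- t(t(z) < thr) + 0L
    h1 <- matrix(0L, n, m); h2 <- matrix(0L, n, m)
    h1[founders, ] <- hapF[seq(1L, nh, 2L), , drop = FALSE]
    h2[founders, ] <- hapF[seq(2L, nh, 2L), , drop = FALSE]
    for (i in seq_len(n)) {
      s <- sireIdx(ped)[i]; d <- damIdx(ped)[i]
      if (s == 0L && d == 0L) next
      h1[i, ] <- if (s > 0L) .meiosis(h1[s, ], h2[s, ], posM, config$chrLengthMorgans)
                 else rbinom(m, 1L, p)
      h2[i, ] <- if (d > 0L) .meiosis(h1[d, ], h2[d, ], posM, config$chrLengthMorgans)
                 else rbinom(m, 1L, p)
    }
    geno <- cbind(geno, h1 + h2)
    ids <- paste0("snp", snpOff + seq_len(m))
    mapL[[ch]] <- data.frame(snpId = ids, chr = ch, posBp = pos)
    freqL[[ch]] <- p
    if (keepHaplotypes) hapL[[ch]] <- list(h1 = h1, h2 = h2)
    snpOff <- snpOff + m
  }
  map <- do.call(rbind, mapL)
  rownames(geno) <- animalIds(ped)
  colnames(geno) <- map$snpId
  storage.mode(geno) <- "double"
  out <- list(genotypes = GenotypeData(geno, map),
              founderFreq = unlist(freqL))
  if (keepHaplotypes) out$haplotypes <- hapL
  out
}

.autoQtl <- function(config, geno) {
  k <- nrow(config$traits)
  p <- colMeans(genotypes(geno)) / 2
  usable <- which(p > 0.15 & p < 0.85)
  nQtl <- k + config$nPleiotropicQtl
  if (length(usable) < nQtl) stop("too few polymorphic SNPs for QTL placement")
  idx <- usable[round(seq(1, length(usable), length.out = nQtl))]
  eff <- matrix(0, nQtl, k)
  for (q in seq_len(nQtl)) {
    tset <- if (q <= k) q else seq_len(k)
    for (t in tset) {
      b <- sqrt(config$qtlVarFrac * config$traits$sigma2a[t] /
                  (2 * p[idx[q]] * (1 - p[idx[q]])))
      eff[q, t] <- b
    }
  }
  out <- data.frame(snpIdx = idx)
  for (t in seq_len(k)) out[[config$traits$name[t]]] <- eff[, t]
  out
}

#' Simulate repeated phenotype records with known ground truth
#'
#' True breeding values are the sum of QTL contributions (effect times
#' centred genotype) and a pedigree-recursion polygenic term (parent average
#' plus Mendelian sampling scaled by the parents' inbreeding), so the
#' polygenic variance equals `sigma2a` by construction and QTL signal sits on
#' top.  Each record adds contemporary-group, parity and nested age effects
#' plus residual noise; repeated records of an animal share its breeding
#' value and permanent-environment effect.
#'
#' @param ped a [Pedigree-class] (with `sex` when `recordedSex != "both"`).
#' @param geno [GenotypeData-class] over all pedigree animals.
#' @param config a `SimConfig`.
#' @param seed optional seed.
#' @return list with `records` (long data.frame: animal, trait, value, cg,
#'   parity, ageDays, ageYears) and `truth` (tbv matrix, qtl table, fixed
#'   effect values, per-animal pe draws).
#' @export
simulatePhenotypes <- function(ped, geno, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nAnimals(ped)
  tr <- config$traits
  k <- nrow(tr)
  qtl <- config$qtl
  if (is.null(qtl)) qtl <- .autoQtl(config, geno)
  if (any(qtl$snpIdx < 1 | qtl$snpIdx > ncol(genotypes(geno))))
    stop("QTL index out of range")
  # QTL contribution on centred genotypes
  M <- genotypes(geno)[animalIds(ped), qtl$snpIdx, drop = FALSE]
  M <- sweep(M, 2, colMeans(M))
  beta <- as.matrix(qtl[, tr$name, drop = FALSE])
  qtlPart <- M %*% beta
  # polygenic recursion with MVN Mendelian sampling
  Sa <- diag(sqrt(tr$sigma2a), nrow = k) %*% config$geneticCor %*%
    diag(sqrt(tr$sigma2a), nrow = k)
  La <- t(chol(Sa))
  Fi <- cpp_inbreeding(sireIdx(ped), damIdx(ped))
  u <- matrix(0, n, k)
  s <- sireIdx(ped); d <- damIdx(ped)
  for (i in seq_len(n)) {
    if (s[i] == 0L && d[i] == 0L) {
      u[i, ] <- La %*% rnorm(k)
    } else {
      pa <- 0.5 * (if (s[i] > 0L) u[s[i], ] else 0) +
            0.5 * (if (d[i] > 0L) u[d[i], ] else 0)
      kM <- if (s[i] > 0L && d[i] > 0L) 0.5 - 0.25 * (Fi[s[i]] + Fi[d[i]])
            else 0.75 - 0.25 * (if (s[i] > 0L) Fi[s[i]] else Fi[d[i]])
      u[i, ] <- pa + sqrt(kM) * (La %*% rnorm(k))
    }
  }
  tbv <- u + qtlPart
  rownames(tbv) <- rownames(u) <- animalIds(ped)
  colnames(tbv) <- colnames(u) <- tr$name
  pe <- sapply(seq_len(k), function(t) rnorm(n, 0, sqrt(tr$sigma2pe[t])))
  colnames(pe) <- tr$name; rownames(pe) <- animalIds(ped)
  # fixed-effect truth
  cgEff <- matrix(rnorm(config$nCg * k, 0, sqrt(config$sigma2cg)),
                  config$nCg, k, dimnames = list(NULL, tr$name))
  parEff <- matrix(rnorm(config$parityLevels * k, 0, 0.3),
                   config$parityLevels, k, dimnames = list(NULL, tr$name))
  maxYear <- 1 + config$parityLevels
  ageSlope <- matrix(rnorm((maxYear + 1) * k, 0, config$ageSlopeSd),
                     maxYear + 1, k, dimnames = list(NULL, tr$name))
  mu <- setNames(rep(5, k), tr$name)
  recAnimals <- if (identical(config$recordedSex, "both") || !length(ped@sex))
    seq_len(n) else which(ped@sex == config$recordedSex)
  dropMht <- if (k >= 2 && config$dropMhtFraction > 0)
    sample(recAnimals, round(config$dropMhtFraction * length(recAnimals)))
  else integer(0)
  rows <- vector("list", length(recAnimals))
  for (ii in seq_along(recAnimals)) {
    i <- recAnimals[ii]
    nrec <- sample(config$recordsRange[1]:config$recordsRange[2], 1L)
    parity <- pmin(seq_len(nrec), config$parityLevels)
    ageYears <- pmin(1L + seq_len(nrec), maxYear)
    ageWithin <- sample(0:364, nrec, replace = TRUE)
    cg <- sample.int(config$nCg, nrec, replace = TRUE)
    per <- vector("list", k)
    for (t in seq_len(k)) {
      if (t == k && i %in% dropMht) next
      e <- rnorm(nrec, 0, sqrt(tr$sigma2e[t]))
      y <- mu[t] + cgEff[cg, t] + parEff[parity, t] +
        ageSlope[ageYears + 1L, t] * ageWithin + tbv[i, t] + pe[i, t] + e
      per[[t]] <- data.frame(animal = animalIds(ped)[i], trait = tr$name[t],
                             value = y, cg = cg, parity = parity,
                             ageDays = ageYears * 365L + ageWithin,
                             ageYears = ageYears)
    }
    rows[[ii]] <- do.call(rbind, per)
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  qtlTab <- cbind(snpMap(geno)[qtl$snpIdx, , drop = FALSE], qtl[, tr$name, drop = FALSE])
  rownames(qtlTab) <- NULL
  list(records = records,
       truth = list(tbv = tbv, polygenic = u, pe = pe, qtl = qtlTab,
                    cgEffects = cgEff, parityEffects = parEff,
                    ageSlopes = ageSlope, mu = mu, varcomp = tr))
}

#' Run the full simulator
#'
#' Seeds once from `config$seed`, simulates pedigree, genotypes and
#' phenotypes, and flags a random subset of animals as genotyped.
#'
#' @param config a `SimConfig`.
#' @param keepHaplotypes see [simulateGenotypes()].
#' @return list: `ped`, `geno` (genotyped subset), `genoAll`, `records`,
#'   `truth`, `founderFreq`, `config` (+ `haplotypes` when requested).
#' @export
simulateStudy <- function(config = simConfig(), keepHaplotypes = FALSE) {
  set.seed(config$seed)
  ped <- simulatePedigree(config$nFounders, config$nGenerations,
                          config$offspringPerMating)
  g <- simulateGenotypes(ped, config, keepHaplotypes = keepHaplotypes)
  ph <- simulatePhenotypes(ped, g$genotypes, config)
  ng <- max(1L, round(config$propGenotyped * nAnimals(ped)))
  gset <- sort(sample.int(nAnimals(ped), ng))
  isGenotyped(ped) <- animalIds(ped)[gset]
  geno <- GenotypeData(genotypes(g$genotypes)[gset, , drop = FALSE],
                       snpMap(g$genotypes))
  out <- list(ped = ped, geno = geno, genoAll = g$genotypes,
              records = ph$records, truth = ph$truth,
              founderFreq = g$founderFreq, config = config)
  if (keepHaplotypes) out$haplotypes <- g$haplotypes
  out
}
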