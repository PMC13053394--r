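test_that("pedigree simulation respects generations, seeds and ancestry", {
  p0 <- simulatePedigree(4, 0, seed = 1)
  expect_equal(nAnimals(p0), 4)
  expect_true(all(sireIdx(p0) == 0))

  pa <- simulatePedigree(4, 2, 2, seed = 1)
  pb <- simulatePedigree(4, 2, 2, seed = 1)
  expect_identical(animalIds(pa), animalIds(pb))
  expect_identical(sireIdx(pa), sireIdx(pb))
  expect_identical(damIdx(pa), damIdx(pb))

  expect_error(simulatePedigree(1, 1), "founders")

  # no animal is its own ancestor (explicit traversal, not the class validity)
  p <- simulatePedigree(10, 3, 2, seed = 3)
  s <- sireIdx(p); d <- damIdx(p)
  for (i in seq_len(nAnimals(p))) {
    stack <- c(s[i], d[i]); seen <- integer(0)
    while (length(stack)) {
      j <- stack[1]; stack <- stack[-1]
      if (j == 0 || j %in% seen) next
      expect_false(j == i)
      seen <- c(seen, j)
      stack <- c(stack, s[j], d[j])
    }
  }
})

test_that("gene dropping is Mendelian-consistent and seed-deterministic", {
  cfg <- simConfig(nFounders = 20, nGenerations = 2, nSnps = 120,
                   nChromosomes = 2, seed = 5)
  ped <- simulatePedigree(20, 2, 2, seed = 5)
  g1 <- simulateGenotypes(ped, cfg, seed = 9, keepHaplotypes = TRUE)
  g2 <- simulateGenotypes(ped, cfg, seed = 9)
  expect_identical(genotypes(g1$genotypes), genotypes(g2$genotypes))

  # every transmitted haplotype allele matches one of the parent's two
  s <- sireIdx(ped); d <- damIdx(ped)
  for (ch in seq_along(g1$haplotypes)) {
    h <- g1$haplotypes[[ch]]
    for (i in which(s > 0)) {
      expect_true(all(h$h1[i, ] == h$h1[s[i], ] | h$h1[i, ] == h$h2[s[i], ]))
      expect_true(all(h$h2[i, ] == h$h1[d[i], ] | h$h2[i, ] == h$h2[d[i], ]))
    }
  }
})

test_that("founder LD decays with distance and vanishes in the fast-decay limit", {
  # fast decay: adjacent-SNP genotype correlation ~ 0
  cfgFast <- simConfig(nFounders = 400, nGenerations = 0, nSnps = 200,
                       nChromosomes = 1, ldDecayRate = 1, seed = 21)
  ped <- simulatePedigree(400, 0, seed = 21)
  gf <- simulateGenotypes(ped, cfgFast, seed = 21)
  m <- genotypes(gf$genotypes)
  adj <- sapply(seq_len(ncol(m) - 1), function(j) {
    if (sd(m[, j]) == 0 || sd(m[, j + 1]) == 0) return(NA_real_)
    cor(m[, j], m[, j + 1])
  })
  expect_lt(abs(mean(adj, na.rm = TRUE)), 0.05)

  # slow decay: mean r2 decreases across distance bins (regression slope < 0)
  cfgSlow <- simConfig(nFounders = 300, nGenerations = 0, nSnps = 300,
                       nChromosomes = 1, ldDecayRate = 2e-5, seed = 22)
  ped2 <- simulatePedigree(300, 0, seed = 22)
  gs <- simulateGenotypes(ped2, cfgSlow, seed = 22)
  m2 <- genotypes(gs$genotypes)
  pos <- snpMap(gs$genotypes)$posBp
  set.seed(22)
  pairs <- cbind(sample(ncol(m2), 3000, TRUE), sample(ncol(m2), 3000, TRUE))
  pairs <- pairs[pairs[, 1] != pairs[, 2], ]
  dist <- abs(pos[pairs[, 1]] - pos[pairs[, 2]])
  r2 <- sapply(seq_len(nrow(pairs)), function(i)
    cor(m2[, pairs[i, 1]], m2[, pairs[i, 2]])^2)
  bins <- cut(dist, quantile(dist, seq(0, 1, 0.2)), include.lowest = TRUE)
  mu <- tapply(r2, bins, mean)
  fit <- lm(mu ~ seq_along(mu))
  expect_lt(coef(fit)[2], 0)
  expect_true(all(diff(rank(mu)) < 0) || mu[1] > mu[5])  # decreasing trend
})

test_that("full sibs share more IBS than unrelated pairs", {
  cfg <- simConfig(nFounders = 220, nGenerations = 1, offspringPerMating = 2,
                   nSnps = 300, nChromosomes = 3, seed = 31)
  ped <- simulatePedigree(220, 1, 2, seed = 31)
  g <- simulateGenotypes(ped, cfg, seed = 31)
  m <- genotypes(g$genotypes)
  s <- sireIdx(ped); d <- damIdx(ped)
  off <- which(s > 0)
  fam <- split(off, paste(s[off], d[off]))
  fam <- fam[lengths(fam) >= 2]
  ibs <- function(i, j) mean(2 - abs(m[i, ] - m[j, ]))
  sibIbs <- sapply(fam[seq_len(min(200, length(fam)))],
                   function(x) ibs(x[1], x[2]))
  founders <- which(s == 0)
  set.seed(31)
  unrel <- replicate(200, { ij <- sample(founders, 2); ibs(ij[1], ij[2]) })
  expect_gt(mean(sibIbs), mean(unrel))
})

test_that("phenotype variance components are realized as configured", {
  # null genetics: heritable fraction of adjusted variance ~ 0
  trNull <- data.frame(name = "MWT", sigma2a = 1e-6, sigma2pe = 1e-6,
                       sigma2e = 1)
  cfg <- simConfig(nFounders = 200, nGenerations = 1, nSnps = 60,
                   nChromosomes = 1, traits = trNull, geneticCor = matrix(1),
                   qtl = data.frame(snpIdx = 1, MWT = 0),
                   recordedSex = "both", dropMhtFraction = 0, seed = 41)
  ped <- simulatePedigree(200, 1, 2, seed = 41)
  g <- simulateGenotypes(ped, cfg, seed = 41)
  ph <- simulatePhenotypes(ped, g$genotypes, cfg, seed = 41)
  expect_lt(var(ph$truth$tbv[, 1]) + var(ph$truth$pe[, 1]), 1e-4)

  # repeatability (sigma2a + sigma2pe) / total ~ 0.6 at n ~ 2000
  tr <- data.frame(name = "MWT", sigma2a = 1, sigma2pe = 0.5, sigma2e = 1)
  cfg2 <- simConfig(nFounders = 1000, nGenerations = 1, nSnps = 60,
                    nChromosomes = 1, traits = tr, geneticCor = matrix(1),
                    qtl = data.frame(snpIdx = 1, MWT = 0),
                    recordedSex = "both", dropMhtFraction = 0,
                    recordsRange = c(2, 2), seed = 42)
  ped2 <- simulatePedigree(1000, 1, 2, seed = 42)
  g2 <- simulateGenotypes(ped2, cfg2, seed = 42)
  ph2 <- simulatePhenotypes(ped2, g2$genotypes, cfg2, seed = 42)
  rec <- ph2$records
  tru <- ph2$truth
  e <- rec$value - tru$mu["MWT"] - tru$cgEffects[rec$cg, "MWT"] -
    tru$parityEffects[rec$parity, "MWT"] -
    tru$ageSlopes[rec$ageYears + 1L, "MWT"] * (rec$ageDays - 365L * rec$ageYears) -
    tru$tbv[rec$animal, "MWT"] - tru$pe[rec$animal, "MWT"]
  num <- var(tru$tbv[, 1]) + var(tru$pe[, 1])
  rep0 <- num / (num + var(e))
  expect_lt(abs(rep0 - 0.6), 0.05)

  # realized var(TBV) within 3 structure-aware MC SEs of sigma2a (no QTL)
  A <- buildA(ped2)
  n <- nrow(A)
  seVar <- 1 * sqrt(2 * sum(A^2) / n^2)
  expect_lt(abs(var(tru$tbv[, 1]) - 1), 3 * seVar)
})

test_that("a shared QTL induces positive cross-trait TBV correlation", {
  tr <- data.frame(name = c("A", "B", "C"), sigma2a = 0.05, sigma2pe = 0.1,
                   sigma2e = 1)
  cfg <- simConfig(nFounders = 300, nGenerations = 1, nSnps = 100,
                   nChromosomes = 1, traits = tr, geneticCor = diag(3),
                   qtl = data.frame(snpIdx = 50, A = 0.5, B = 0.5, C = 0.5),
                   recordedSex = "both", dropMhtFraction = 0, seed = 51)
  ped <- simulatePedigree(300, 1, 2, seed = 51)
  g <- simulateGenotypes(ped, cfg, seed = 51)
  ph <- simulatePhenotypes(ped, g$genotypes, cfg, seed = 51)
  cc <- cor(ph$truth$tbv)
  expect_gt(min(cc[upper.tri(cc)]), 0)
})

test_that("the full study simulation is seed-deterministic", {
  cfg <- simConfig(nFounders = 30, nGenerations = 1, nSnps = 50,
                   nChromosomes = 1, recordedSex = "both", seed = 77)
  s1 <- simulateStudy(cfg)
  s2 <- simulateStudy(cfg)
  expect_identical(genotypes(s1$geno), genotypes(s2$geno))
  expect_identical(s1$records, s2$records)
  expect_identical(s1$truth$tbv, s2$truth$tbv)
})
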