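test_that("design matrices have the expected structure and column counts", {
  ped <- founderPedigree(3)
  # c CGs, q parities, y year classes -> (c-1) + (q-1) + y + 1 columns
  rec <- makeRecords(c("1", "2", "3", "1"), c(5, 6, 7, 8),
                     cg = c(1, 2, 3, 1), parity = c(1, 2, 1, 2),
                     ageYears = c(2, 3, 2, 3),
                     ageDays = c(800, 1200, 790, 1210))
  d <- buildDesign(rec, ped)
  expect_equal(ncol(d$X), (3 - 1) + (2 - 1) + 2 + 1)
  expect_equal(dim(d$Z), c(4, 3))
  expect_equal(dim(d$W), c(4, 3))

  # two records of one animal: identical rows in Z and W
  expect_equal(as.numeric(d$Z[1, ]), as.numeric(d$Z[4, ]))
  expect_equal(as.numeric(d$W[1, ]), as.numeric(d$W[4, ]))

  # degenerate design: 1 CG, 1 parity, constant age collapses to intercept
  rec2 <- makeRecords(c("1", "2"), c(5, 6))
  d2 <- buildDesign(rec2, ped)
  sol <- solveMme(d2, buildAInverse(ped),
                  list(sigma2a = 1, sigma2pe = 1, sigma2e = 1))
  expect_equal(sum(!colnames(d2$X) %in% sol@constrained), 1)

  expect_error(buildDesign(makeRecords("zz", 1), ped), "absent")
})

test_that("noise-free fixtures recover fixed-effect contrasts exactly", {
  ped <- founderPedigree(6)
  cg <- c(1, 1, 2, 2, 3, 3)
  bTrue <- c(0, 1.5, -2)          # CG effects
  rec <- makeRecords(as.character(1:6), 10 + bTrue[cg], cg = cg)
  d <- buildDesign(rec, ped)
  sol <- solveMme(d, buildAInverse(ped),
                  list(sigma2a = 0.5, sigma2pe = 0.3, sigma2e = 1))
  # contrasts vs reference CG level
  expect_lt(abs(sol@b[["cg2"]] - 1.5), 1e-8)
  expect_lt(abs(sol@b[["cg3"]] - (-2)), 1e-8)
  expect_lt(max(abs(sol@a)), 1e-8)
  expect_lt(sol@residualNorm, 1e-10)
})

test_that("infinite shrinkage drives breeding values to zero", {
  set.seed(21)
  ped <- founderPedigree(10)
  rec <- makeRecords(as.character(1:10), rnorm(10, 5), cg = rep(1:2, 5))
  d <- buildDesign(rec, ped)
  sol <- solveMme(d, buildAInverse(ped),
                  list(sigma2a = 1e-10, sigma2pe = 0.5, sigma2e = 1))
  expect_lt(max(abs(sol@a)), 1e-6)
})

test_that("genotyped-only MME matches the closed-form GBLUP oracle", {
  set.seed(22)
  n <- 60; m <- 150
  p <- runif(m, .2, .8)
  geno <- sapply(p, function(pp) rbinom(n, 2, pp))
  G <- buildG(toyGeno(geno, pos = seq_len(m)), freq = p)
  Gm <- relMatrix(G) + diag(1e-6, n)
  s2a <- 0.5; s2e <- 1
  y <- 3 + as.numeric(chol(Gm * s2a) %*% rnorm(n)) + rnorm(n, 0, sqrt(s2e))
  ped <- founderPedigree(n)
  rec <- makeRecords(as.character(1:n), y)
  d <- buildDesign(rec, ped)
  sol <- solveMme(d, Matrix::Matrix(solve(Gm)),
                  list(sigma2a = s2a, sigma2pe = NULL, sigma2e = s2e),
                  includePe = FALSE)
  # oracle: GLS mean, then conditional-mean BLUP
  V <- Gm * s2a + diag(s2e, n)
  Vi <- solve(V)
  one <- rep(1, n)
  muHat <- as.numeric((t(one) %*% Vi %*% y) / (t(one) %*% Vi %*% one))
  aOracle <- as.numeric(Gm %*% Vi %*% (y - muHat) * s2a)
  expect_lt(max(abs(sol@a - aOracle)), 1e-6)
})

test_that("solutions satisfy the MME and PEV behaves like an inverse block", {
  set.seed(23)
  ped <- simulatePedigree(12, 2, 2, seed = 23)
  ids <- animalIds(ped)
  rec <- makeRecords(sample(ids, 40, TRUE), rnorm(40, 6),
                     cg = sample(1:3, 40, TRUE),
                     parity = sample(1:2, 40, TRUE))
  d <- buildDesign(rec, ped)
  vc <- list(sigma2a = 0.4, sigma2pe = 0.2, sigma2e = 0.6)
  sol <- solveMme(d, buildAInverse(ped), vc)
  expect_lt(sol@residualNorm, 1e-10)
  pev <- gebvPev(sol, 1:4)
  expect_equal(pev, t(pev))
  expect_true(all(diag(pev) > 0))
  # PEV of an animal cannot exceed its prior variance
  A <- buildA(ped)
  expect_true(all(diag(pev) <= diag(A)[1:4] * vc$sigma2a + 1e-8))
})

test_that("adjusted phenotypes average records after fixed-effect removal", {
  ped <- founderPedigree(2)
  rec <- makeRecords(c("1", "1", "2"), c(5, 7, 4))
  d <- buildDesign(rec, ped)
  sol <- solveMme(d, buildAInverse(ped),
                  list(sigma2a = 1, sigma2pe = 0.5, sigma2e = 1))
  adj <- adjustPhenotypes(rec, d, sol)
  # animal 1 has records (5, 7): adjusted mean = 6 - common fixed part
  keep <- setdiff(colnames(d$X), sol@constrained)
  fixedPart <- as.numeric((d$X[, keep, drop = FALSE] %*% sol@b)[1])
  expect_equal(unname(adj["1"]), 6 - fixedPart, tolerance = 1e-10)
  expect_equal(unname(adj["1"] - adj["2"]), 2, tolerance = 1e-10)
  # permuting record order leaves the result unchanged
  perm <- c(3, 1, 2)
  d2 <- buildDesign(rec[perm, ], ped)
  sol2 <- solveMme(d2, buildAInverse(ped),
                   list(sigma2a = 1, sigma2pe = 0.5, sigma2e = 1))
  adj2 <- adjustPhenotypes(rec[perm, ], d2, sol2)
  expect_equal(adj2[names(adj)], adj)
})

test_that("GEBV accuracy rises with heritability", {
  acc <- sapply(c(0.1, 0.3, 0.5), function(h2) {
    tr <- data.frame(name = "MWT", sigma2a = h2, sigma2pe = 0.1,
                     sigma2e = 1 - h2)
    cfg <- simConfig(nFounders = 120, nGenerations = 2, nSnps = 300,
                     nChromosomes = 2, traits = tr, geneticCor = matrix(1),
                     qtl = data.frame(snpIdx = 1, MWT = 0),
                     recordedSex = "both", dropMhtFraction = 0,
                     propGenotyped = 0.5, seed = 24)
    sim <- simulateStudy(cfg)
    rec <- sim$records
    d <- buildDesign(rec, sim$ped)
    relm <- buildRelationshipMatrices(sim$ped, sim$geno)
    sol <- solveMme(d, relm$Hinv,
                    list(sigma2a = h2, sigma2pe = 0.1, sigma2e = 1 - h2))
    ids <- unique(rec$animal)
    cor(sol@a[match(ids, animalIds(sim$ped))], sim$truth$tbv[ids, "MWT"])
  })
  expect_true(all(diff(acc) > 0))
})
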