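test_that("windows are flank arithmetic, clamped and unmerged", {
  snps <- data.frame(snpId = c("s1", "s2", "s3"), chr = c(1, 1, 2),
                     posBp = c(150000, 40000, 155000))
  w <- makeWindows(snps)
  expect_equal(GenomicRanges::start(w), c(50000, 1, 55000))
  expect_equal(GenomicRanges::end(w), c(250000, 140000, 255000))
  # two SNPs 10 kb apart: two overlapping windows, both retained
  snps2 <- data.frame(snpId = c("a", "b"), chr = 1, posBp = c(100000, 110000))
  w2 <- makeWindows(snps2)
  expect_equal(length(w2), 2)
  expect_true(GenomicRanges::start(w2)[2] < GenomicRanges::end(w2)[1])
})

test_that("window-feature hits honour 1-based inclusive boundaries", {
  w <- makeWindows(data.frame(snpId = "s", chr = 1, posBp = 150000))
  # window is [50000, 250000]
  gInside <- writeGtfFixture(data.frame(chr = "1", start = 250000,
                                        end = 260000, id = "gIn"))
  gOutside <- writeGtfFixture(data.frame(chr = "1", start = 250001,
                                         end = 260000, id = "gOut"))
  hIn <- annotateWindows(w, readGtf(gInside))
  expect_equal(nrow(hIn), 1)
  expect_equal(hIn$overlapBp, 1)
  hOut <- annotateWindows(w, readGtf(gOutside))
  expect_equal(nrow(hOut), 0)
})

test_that("a constructed fixture yields exactly the designed hit count", {
  snps <- data.frame(snpId = c("s1", "s2", "s3"), chr = c(1, 1, 2),
                     posBp = c(200000, 600000, 200000))
  w <- makeWindows(snps)   # [1e5,3e5], [5e5,7e5] on chr1; [1e5,3e5] on chr2
  genes <- data.frame(
    chr = c("1", "1", "1", "2", "2"),
    start = c(120000, 290000, 650000, 150000, 500000),
    end = c(130000, 310000, 720000, 160000, 550000),
    id = paste0("g", 1:5))
  hits <- annotateWindows(w, readGtf(writeGtfFixture(genes)))
  expect_equal(nrow(hits), 4)   # g1,g2 in w1; g3 in w2; g4 in w3; g5 misses
  expect_setequal(hits$geneId, c("g1", "g2", "g3", "g4"))
  # hits are invariant to window input order
  hits2 <- annotateWindows(rev(w), readGtf(writeGtfFixture(genes)))
  expect_equal(nrow(hits2), nrow(hits))
  expect_setequal(paste(hits2$snpId, hits2$geneId),
                  paste(hits$snpId, hits$geneId))
})

test_that("chromosome naming mismatches fail loudly", {
  w <- makeWindows(data.frame(snpId = "s", chr = 1, posBp = 150000))
  g <- readGtf(writeGtfFixture(data.frame(chr = "7", start = 1e5, end = 2e5,
                                          id = "g")))
  expect_error(annotateWindows(w, g), "chromosome names")
  # a "chr" prefix is normalised, not an error
  g2 <- readGtf(writeGtfFixture(data.frame(chr = "chr1", start = 140000,
                                           end = 160000, id = "g")))
  expect_equal(nrow(annotateWindows(w, g2)), 1)
})

test_that("Venn region counts match set algebra and brute force", {
  out <- overlapSets(list(X = c("a", "b"), Y = c("b", "c"), Z = "b"))
  expect_equal(out$count[out$region == "X&Y&Z"], 1)
  expect_equal(out$count[out$region == "X"], 1)        # just "a"
  expect_equal(out$count[out$region == "Y"], 1)        # just "c"
  expect_equal(sum(out$count), 3)

  disj <- overlapSets(list(A = c("1", "2"), B = c("3"), C = c("4")))
  expect_true(all(disj$count[grepl("&", disj$region)] == 0))

  # randomised fixture vs direct enumeration
  set.seed(51)
  sets <- list(A = sample(letters, 12), B = sample(letters, 10),
               C = sample(letters, 8))
  out2 <- overlapSets(sets)
  brute <- sapply(letters, function(el)
    paste(as.integer(c(el %in% sets$A, el %in% sets$B, el %in% sets$C)),
          collapse = ""))
  brute <- brute[brute != "000"]
  expect_equal(sum(out2$count), length(brute))
  expect_equal(out2$count[out2$region == "A&B&C"],
               sum(brute == "111"))
  expect_equal(out2$count[out2$region == "A&B"], sum(brute == "110"))
})

test_that("hypergeometric enrichment matches an exact tail-sum oracle", {
  # background: 100 records, 10 of term T; hits: 20 records, 10 of term T
  qtl <- data.frame(chr = "1",
                    start = seq(1000, by = 2000, length.out = 100),
                    end = seq(1500, by = 2000, length.out = 100),
                    id = paste0("q", 1:100),
                    trait = c(rep("T", 10), rep("U", 90)),
                    type = "Production")
  feats <- readQtlGff(writeQtlGffFixture(qtl))
  hits <- data.frame(snpId = "s", chr = "1",
                     qtlId = paste0("q", c(1:10, 11:20)),
                     trait = c(rep("T", 10), rep("U", 10)))
  out <- qtlEnrichment(hits, feats)
  # oracle: P(X >= 10), X ~ Hypergeom(N=100, K=10, n=20) by explicit sum
  oracle <- sum(choose(10, 10:10) * choose(90, 10:10) / choose(100, 20))
  oracle <- sum(sapply(10:10, function(k)
    choose(10, k) * choose(90, 20 - k) / choose(100, 20)))
  expect_equal(out$pValue[out$term == "T"], oracle, tolerance = 1e-12)
  expect_equal(out$richness[out$term == "T"], 1)      # 10 of 10
  expect_equal(out$observed[out$term == "T"], 10)

  # proportion equal to background: not enriched
  expect_gt(out$pValue[out$term == "U"], 0.5)

  # single term: FDR equals the p-value
  h1 <- hits[hits$trait == "T", ]
  o1 <- qtlEnrichment(h1, feats)
  expect_equal(o1$fdr, o1$pValue)
})

test_that("BH-FDR is monotone and permutation nulls are uniform", {
  set.seed(52)
  qtl <- data.frame(chr = "1",
                    start = seq(1000, by = 2000, length.out = 200),
                    end = seq(1500, by = 2000, length.out = 200),
                    id = paste0("q", 1:200),
                    trait = sample(LETTERS[1:8], 200, TRUE),
                    type = "Production")
  feats <- readQtlGff(writeQtlGffFixture(qtl))
  ps <- replicate(80, {
    pick <- sample(200, 30)
    hits <- data.frame(snpId = "s", chr = "1", qtlId = paste0("q", pick),
                       trait = sample(qtl$trait)[pick])  # shuffled terms
    out <- qtlEnrichment(hits, feats)
    out$pValue[1]
  })
  # the exact test is discrete, hence super-uniform: the empirical CDF must
  # not exceed the uniform one (type-I control) and must not be degenerate
  grid <- c(0.01, 0.05, 0.1, 0.25, 0.5)
  emp <- ecdf(ps)(grid)
  expect_true(all(emp <= grid + 3 * sqrt(grid * (1 - grid) / length(ps))))
  expect_gt(mean(ps), 0.4)

  hits <- data.frame(snpId = "s", chr = "1", qtlId = paste0("q", 1:40),
                     trait = qtl$trait[1:40])
  out <- qtlEnrichment(hits, feats)
  o <- order(out$pValue)
  expect_true(all(diff(out$fdr[o]) >= -1e-12))
  expect_true(all(out$fdr <= 1))
  expect_true(all(out$fdr >= out$pValue - 1e-12))
})
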