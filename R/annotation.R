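# Window-based gene/QTL annotation around significant SNPs and QTL-category
# enrichment with BH-FDR.  Coordinates are 1-based inclusive throughout.

.normChr <- function(x) sub("^[Cc]hr", "", as.character(x))

#' Windows around significant SNPs
#'
#' One window per SNP spanning `flank` bp up- and downstream, clamped at
#' position 1; overlapping windows are deliberately not merged so each SNP
#' reports its own hits.
#'
#' @param snps data.frame with columns snpId, chr, posBp (e.g. the
#'   significant rows of a results table).
#' @param flank flank size in bp (default 100000).
#' @return A `GRanges` with metadata column `snpId`.
#' @export
makeWindows <- function(snps, flank = 1e5) {
  gr <- GenomicRanges::GRanges(
    seqnames = .normChr(snps$chr),
    ranges = IRanges::IRanges(start = pmax(1, snps$posBp - flank),
                              end = snps$posBp + flank))
  S4Vectors::mcols(gr)$snpId <- snps$snpId
  gr
}

#' Annotate windows with gene or QTL features
#'
#' A feature hits a window iff their intervals intersect on the same
#' chromosome (1-based inclusive; a shared boundary bp counts).  Chromosome
#' names are normalised by stripping a "chr" prefix; if the window and
#' feature chromosome name sets are disjoint the function fails listing the
#' unmatched names.
#'
#' @param windows `GRanges` from [makeWindows()].
#' @param features `GRanges` from [readGtf()] or [readQtlGff()].
#' @return data.frame with one row per (window, feature) hit: snpId, feature
#'   id, the feature's biotype or trait columns, and overlap width in bp.
#' @export
annotateWindows <- function(windows, features) {
  wchr <- unique(.normChr(GenomicRanges::seqnames(windows)))
  fchr <- unique(.normChr(GenomicRanges::seqnames(features)))
  if (!length(intersect(wchr, fchr)))
    stop("chromosome names do not match between windows and annotation; ",
         "windows: ", paste(wchr, collapse = ","),
         " vs features: ", paste(fchr, collapse = ","))
  w2 <- GenomicRanges::GRanges(.normChr(GenomicRanges::seqnames(windows)),
                               IRanges::ranges(windows))
  f2 <- GenomicRanges::GRanges(.normChr(GenomicRanges::seqnames(features)),
                               IRanges::ranges(features))
  hits <- GenomicRanges::findOverlaps(w2, f2, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(IRanges::ranges(w2)[qi],
                                           IRanges::ranges(f2)[si]))
  out <- data.frame(snpId = S4Vectors::mcols(windows)$snpId[qi],
                    chr = .normChr(GenomicRanges::seqnames(f2))[si],
                    featureStart = GenomicRanges::start(f2)[si],
                    featureEnd = GenomicRanges::end(f2)[si],
                    overlapBp = ov)
  mc <- as.data.frame(S4Vectors::mcols(features))[si, , drop = FALSE]
  rownames(mc) <- NULL
  cbind(out, mc)
}

#' Venn region counts for up to three sets
#'
#' @param sets named list of 2 or 3 character vectors (SNP or gene ids per
#'   trait).
#' @return data.frame(region, count) covering every intersection region.
#' @export
overlapSets <- function(sets) {
  k <- length(sets)
  if (k < 2 || k > 3) stop("overlapSets handles 2 or 3 sets")
  nm <- names(sets)
  if (is.null(nm)) nm <- LETTERS[seq_len(k)]
  universe <- unique(unlist(sets))
  member <- sapply(sets, function(s) universe %in% s)
  if (!is.matrix(member)) member <- matrix(member, nrow = length(universe))
  pat <- apply(member, 1, function(r) paste(as.integer(r), collapse = ""))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  region <- apply(combos, 1, function(b) paste(nm[unlist(b)], collapse = "&"))
  key <- apply(combos, 1, function(b) paste(as.integer(unlist(b)), collapse = ""))
  cnt <- as.integer(table(factor(pat, levels = key)))
  data.frame(region = region, count = cnt)
}

#' Six-category QTL classification map
#'
#' Editable mapping from QTLdb `trait_type` attribute values to the six
#' major categories (Production, Meat and Carcass, Health, Milk, Exterior,
#' Reproduction) used for grouping in enrichment analyses.  Ships as a TSV
#' in `inst/extdata`; pass your own file to override.
#'
#' @param path optional path to a two-column TSV (traitType, category).
#' @return data.frame(traitType, category).
#' @export
qtlCategoryMap <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "qtl_categories.tsv", package = "PleioGWAS")
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' QTL-category enrichment of annotated windows
#'
#' For each trait term (optionally within each chromosome) tests
#' over-representation of the term among the window-hit QTL records against
#' the whole QTL database background with the hypergeometric upper tail
#' P(X >= observed), X ~ Hypergeom(N = background records, K = term records,
#' n = hit records), then BH-FDR across terms.  The richness factor is the
#' number of hits of the term divided by the total records of that term in
#' the background.
#'
#' @param hits data.frame from [annotateWindows()] run against QTL features
#'   (must carry the `term` column, and `chr` when `byChromosome`).
#' @param qtlFeatures the full QTL `GRanges` database (background).
#' @param term column holding the trait term (default "trait"); use
#'   "traitType" for the 6-category grouping.
#' @param byChromosome test each term within each chromosome.
#' @param dedup count each QTL record at most once across windows (default
#'   TRUE: the hypergeometric draws records without replacement, so the hit
#'   set must be a subset of the background even when windows overlap).
#' @param fdr FDR cut recorded in the `enriched` flag (default 0.05).
#' @param method `"hypergeometric"` (exact, default) or `"chisq"`
#'   approximation.
#' @return data.frame(term [, chr], observed, background, expected,
#'   richness, pValue, fdr, enriched).
#' @export
qtlEnrichment <- function(hits, qtlFeatures, term = "trait",
                          byChromosome = FALSE, dedup = TRUE, fdr = 0.05,
                          method = c("hypergeometric", "chisq")) {
  method <- match.arg(method)
  bg <- as.data.frame(S4Vectors::mcols(qtlFeatures))
  bg$chr <- .normChr(GenomicRanges::seqnames(qtlFeatures))
  if (!nrow(bg)) stop("empty QTL background")
  if (!term %in% names(bg)) stop("background lacks term column ", term)
  if (!term %in% names(hits)) stop("hits lack term column ", term)
  h <- hits
  if (dedup && "qtlId" %in% names(h)) h <- h[!duplicated(h$qtlId), , drop = FALSE]
  doTest <- function(hsub, bsub) {
    N <- nrow(bsub); n <- nrow(hsub)
    terms <- sort(unique(hsub[[term]]))
    rows <- lapply(terms, function(tm) {
      K <- sum(bsub[[term]] == tm)
      kk <- sum(hsub[[term]] == tm)
      p <- if (method == "hypergeometric") {
        phyper(kk - 1, K, N - K, n, lower.tail = FALSE)
      } else {
        expct <- n * K / N
        stat <- (kk - expct)^2 / max(expct, .Machine$double.eps) +
          (n - kk - (n - expct))^2 / max(n - expct, .Machine$double.eps)
        if (kk > expct) pchisq(stat, 1, lower.tail = FALSE) / 2 else 1
      }
      data.frame(term = tm, observed = kk, background = K,
                 expected = n * K / N,
                 richness = if (K > 0) kk / K else NA_real_, pValue = p)
    })
    do.call(rbind, rows)
  }
  if (byChromosome) {
    chrs <- sort(unique(h$chr))
    out <- do.call(rbind, lapply(chrs, function(cc) {
      r <- doTest(h[h$chr == cc, , drop = FALSE],
                  bg[bg$chr == cc, , drop = FALSE])
      if (nrow(r)) cbind(chr = cc, r) else NULL
    }))
  } else out <- doTest(h, bg)
  out$fdr <- p.adjust(out$pValue, method = "BH")
  out$enriched <- out$fdr < fdr
  rownames(out) <- NULL
  out
}
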