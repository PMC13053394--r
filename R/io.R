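# Readers/writers for the external formats the pipeline touches.
# All coordinates are 1-based inclusive internally (GTF/GFF convention).

.readDelim <- function(path, header = TRUE) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  read.table(path, header = header, sep = sep, stringsAsFactors = FALSE,
             comment.char = "#", quote = "\"", check.names = FALSE)
}

#' Read a pedigree file
#'
#' CSV or TSV with columns `animal`, `sire`, `dam` (header required); `0` or
#' empty denotes an unknown parent.  Rows may be in any order; the result is
#' topologically sorted and reading fails on cycles or duplicated animals.
#'
#' @param path file path.
#' @return A [Pedigree-class].
#' @export
readPedigree <- function(path) {
  df <- .readDelim(path)
  names(df) <- tolower(names(df))
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(df)))
    stop("pedigree file must have columns animal, sire, dam")
  gt <- if ("genotyped" %in% names(df)) as.logical(df$genotyped) else FALSE
  sx <- if ("sex" %in% names(df)) as.character(df$sex) else character()
  Pedigree(df$animal, df$sire, df$dam, genotyped = gt, sex = sx)
}

#' Write a pedigree to CSV
#' @param ped a [Pedigree-class].
#' @param path output path.
#' @export
writePedigree <- function(ped, path) {
  id <- animalIds(ped)
  df <- data.frame(animal = id,
                   sire = ifelse(ped@sire == 0L, "0", id[pmax(ped@sire, 1L)]),
                   dam = ifelse(ped@dam == 0L, "0", id[pmax(ped@dam, 1L)]),
                   genotyped = ped@genotyped)
  if (length(ped@sex)) df$sex <- ped@sex
  write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read genotypes (plain TSV matrix or PLINK text .ped/.map)
#'
#' Two dialects are supported.  A plain tab-separated matrix has a header of
#' SNP ids, the first column holding animal ids and codes in {0,1,2,NA}; the
#' SNP map is read from `mapPath` (columns `snpId`, `chr`, `posBp`).  A PLINK
#' text fileset is given by `path` = prefix of `.ped`/`.map`; alleles are
#' "A"/"B" ("0 0" = missing) and the code is the count of the "B" allele.
#'
#' @param path TSV path or PLINK prefix.
#' @param mapPath map TSV path (plain-matrix dialect only).
#' @return A [GenotypeData-class].
#' @export
readGenotypes <- function(path, mapPath = NULL) {
  if (file.exists(paste0(path, ".ped")) && file.exists(paste0(path, ".map"))) {
    return(.readPlinkText(path))
  }
  if (!file.exists(path)) stop("no such genotype file or PLINK prefix: ", path)
  if (is.null(mapPath)) stop("mapPath is required for the plain-matrix dialect")
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  bad <- m[!is.na(m)]
  if (length(bad) && !all(bad %in% c(0, 1, 2)))
    stop("genotype codes must be 0, 1, 2 or NA; found: ",
         paste(unique(bad[!bad %in% c(0, 1, 2)]), collapse = ", "))
  map <- .readDelim(mapPath)
  if (nrow(map) != ncol(m))
    stop("SNP count mismatch between matrix (", ncol(m), ") and map (", nrow(map), ")")
  if (!is.null(colnames(m)) && !identical(colnames(m), as.character(map$snpId)))
    map <- map[match(colnames(m), map$snpId), , drop = FALSE]
  GenotypeData(m, map)
}

.readPlinkText <- function(prefix) {
  map <- read.table(paste0(prefix, ".map"), header = FALSE,
                    stringsAsFactors = FALSE)
  names(map)[1:4] <- c("chr", "snpId", "cm", "posBp")
  ped <- read.table(paste0(prefix, ".ped"), header = FALSE,
                    stringsAsFactors = FALSE, colClasses = "character")
  nSnp <- nrow(map)
  if (ncol(ped) != 6L + 2L * nSnp)
    stop("SNP count mismatch between .ped (", (ncol(ped) - 6L) / 2L,
         " SNPs) and .map (", nSnp, ")")
  al <- as.matrix(ped[, -(1:6), drop = FALSE])
  a1 <- al[, seq(1L, 2L * nSnp, 2L), drop = FALSE]
  a2 <- al[, seq(2L, 2L * nSnp, 2L), drop = FALSE]
  miss <- a1 == "0" | a2 == "0"
  ok <- c("A", "B")
  vals <- unique(c(a1[!miss], a2[!miss]))
  if (length(vals) && !all(vals %in% ok))
    stop("PLINK alleles must be coded A/B (0 = missing); found: ",
         paste(setdiff(vals, ok), collapse = ", "))
  m <- (a1 == "B") + (a2 == "B")
  m[miss] <- NA
  storage.mode(m) <- "double"
  rownames(m) <- ped[[2L]]
  colnames(m) <- map$snpId
  GenotypeData(m, map[, c("snpId", "chr", "posBp")])
}

#' Write genotypes as plain TSV matrix + map, or PLINK text
#'
#' @param geno a [GenotypeData-class].
#' @param path output path (TSV) or PLINK prefix.
#' @param format `"tsv"` or `"ped"`.
#' @param mapPath map output path (TSV format; default `path` with `.map.tsv`).
#' @export
writeGenotypes <- function(geno, path, format = c("tsv", "ped"),
                           mapPath = NULL) {
  format <- match.arg(format)
  m <- genotypes(geno); map <- snpMap(geno)
  if (format == "tsv") {
    if (is.null(mapPath)) mapPath <- paste0(path, ".map.tsv")
    df <- data.frame(animal = rownames(m), check.names = FALSE)
    df <- cbind(df, as.data.frame(m, check.names = FALSE))
    write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(map, mapPath, sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    a1 <- ifelse(is.na(m), "0", ifelse(m >= 1, "B", "A"))
    a2 <- ifelse(is.na(m), "0", ifelse(m == 2, "B", "A"))
    inter <- matrix("", nrow(m), 2L * ncol(m))
    inter[, seq(1L, 2L * ncol(m), 2L)] <- a1
    inter[, seq(2L, 2L * ncol(m), 2L)] <- a2
    ped <- cbind("FAM", rownames(m), "0", "0", "0", "-9", inter)
    write.table(ped, paste0(path, ".ped"), sep = " ", row.names = FALSE,
                col.names = FALSE, quote = FALSE)
    write.table(data.frame(map$chr, map$snpId, 0, map$posBp),
                paste0(path, ".map"), sep = "\t", row.names = FALSE,
                col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read gene features from a GTF file
#'
#' Keeps gene-level features only; when a file carries several lines for one
#' gene id (e.g. transcripts only), the union span per gene id is used.
#'
#' @param path GTF path.
#' @return A `GRanges` with metadata columns `geneId` and `biotype`.
#' @export
readGtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  if ("type" %in% names(mc) && any(mc$type == "gene"))
    gr <- gr[mc$type == "gene"]
  gid <- S4Vectors::mcols(gr)$gene_id
  if (is.null(gid)) stop("malformed GTF: no gene_id attribute")
  if (any(is.na(gid) | gid == "")) stop("malformed GTF: empty gene_id attribute")
  bio <- S4Vectors::mcols(gr)$gene_biotype
  if (is.null(bio)) bio <- rep(NA_character_, length(gr))
  # union span per gene id (dedup rule)
  spl <- split(seq_along(gr), gid)
  keep <- vapply(spl, `[`, integer(1), 1L)
  out <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(gr)[keep],
    ranges = IRanges::IRanges(
      start = vapply(spl, function(i) min(GenomicRanges::start(gr)[i]), numeric(1)),
      end = vapply(spl, function(i) max(GenomicRanges::end(gr)[i]), numeric(1))))
  S4Vectors::mcols(out)$geneId <- names(spl)
  S4Vectors::mcols(out)$biotype <- bio[keep]
  names(out) <- NULL
  out
}

#' Read QTL features from an Animal-QTLdb-style GFF3 file
#'
#' Each record carries a QTL name and a trait term (attribute `trait` if
#' present, otherwise `Name`) plus an optional `trait_type` category.
#'
#' @param path GFF3 path.
#' @return A `GRanges` with metadata columns `qtlId`, `trait`, `traitType`.
#' @export
readQtlGff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  trait <- if ("trait" %in% names(mc)) as.character(mc$trait)
           else if ("Name" %in% names(mc)) as.character(mc$Name)
           else stop("malformed QTL GFF: no trait or Name attribute")
  qid <- if ("QTL_ID" %in% names(mc)) as.character(mc$QTL_ID)
         else if ("ID" %in% names(mc)) as.character(mc$ID)
         else paste0("QTL", seq_along(gr))
  ttype <- if ("trait_type" %in% names(mc)) as.character(mc$trait_type)
           else rep(NA_character_, length(gr))
  out <- GenomicRanges::granges(gr)
  S4Vectors::mcols(out)$qtlId <- qid
  S4Vectors::mcols(out)$trait <- trait
  S4Vectors::mcols(out)$traitType <- ttype
  names(out) <- NULL
  out
}

#' Write a per-SNP results table as TSV
#' @param x a [GwasResult-class] or [MultiTraitResult-class].
#' @param path output path.
#' @export
writeResults <- function(x, path) {
  write.table(resultsTable(x), path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
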