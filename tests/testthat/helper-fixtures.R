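# Shared fixture builders.  Everything is generated in code; no binary data.

# the 4-animal textbook pedigree: 1,2 founders; 3 = 1x2; 4 = 1x3
toyPedigree <- function() {
  Pedigree(id = c("1", "2", "3", "4"), sire = c("0", "0", "1", "1"),
           dam = c("0", "0", "2", "3"))
}

# founders-only pedigree of size n
founderPedigree <- function(n) {
  Pedigree(id = as.character(seq_len(n)), sire = rep("0", n), dam = rep("0", n))
}

# random valid pedigree with up to nMax animals (topological by construction)
randomPedigree <- function(nMax = 200) {
  n <- sample(5:nMax, 1)
  sire <- dam <- integer(n)
  for (i in 3:n) {
    if (runif(1) < 0.7) {
      sire[i] <- sample(i - 1L, 1)
      dam[i] <- sample(i - 1L, 1)
      if (dam[i] == sire[i]) dam[i] <- 0L
    }
  }
  new("Pedigree", id = as.character(seq_len(n)), sire = sire, dam = dam,
      genotyped = rep(FALSE, n), sex = character())
}

# small GenotypeData from a matrix (one chromosome unless chr given)
toyGeno <- function(m, chr = NULL, pos = NULL) {
  if (is.null(rownames(m))) rownames(m) <- paste0("a", seq_len(nrow(m)))
  if (is.null(chr)) chr <- rep(1L, ncol(m))
  if (is.null(pos)) pos <- seq_len(ncol(m)) * 1000L
  GenotypeData(m, data.frame(snpId = paste0("s", seq_len(ncol(m))),
                             chr = chr, posBp = pos))
}

# write a tiny GTF with given gene rows: data.frame(chr, start, end, id, biotype)
writeGtfFixture <- function(genes, path = tempfile(fileext = ".gtf")) {
  lines <- sprintf(
    '%s\ttest\tgene\t%d\t%d\t.\t+\t.\tgene_id "%s"; gene_biotype "%s";',
    genes$chr, genes$start, genes$end, genes$id,
    if (is.null(genes$biotype)) "protein_coding" else genes$biotype)
  writeLines(lines, path)
  path
}

# write a tiny QTLdb-style GFF3: data.frame(chr, start, end, id, trait, type)
writeQtlGffFixture <- function(qtl, path = tempfile(fileext = ".gff")) {
  lines <- c("##gff-version 3", sprintf(
    "%s\tQTLdb\tQTL\t%d\t%d\t.\t.\t.\tID=%s;Name=%s;trait=%s;trait_type=%s",
    qtl$chr, qtl$start, qtl$end, qtl$id, gsub(" ", "%20", qtl$trait),
    gsub(" ", "%20", qtl$trait), qtl$type))
  writeLines(lines, path)
  path
}

# simple record builder for QC/MME tests
makeRecords <- function(animal, value, trait = "MWT", cg = 1, parity = 1,
                        ageYears = 3, ageDays = NULL) {
  n <- length(value)
  if (is.null(ageDays)) ageDays <- rep(3 * 365L, n)
  data.frame(animal = as.character(animal), trait = trait, value = value,
             cg = cg, parity = parity, ageDays = ageDays,
             ageYears = ageYears)
}
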