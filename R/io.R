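# File I/O: TSV dosage matrices, phenotype tables, gene BED, partition
# tables, and a minimal PLINK-1 binary (.bed/.bim/.fam) codec. The PLINK
# codec is written here because no installed R package reads the 2-bit
# format; it covers the SNP-major layout only.

#' Write/read a dosage matrix as TSV
#'
#' Layout: first columns `snp_id`, `chrom`, `pos`, `alleleA`, `alleleB`,
#' then one column per sample (dosage of the B allele, empty for
#' missing). SNPs in rows for readability at large p.
#'
#' @param g A [genotype_matrix()].
#' @param path Output file.
#' @return `path` invisibly; `read_dosage_tsv()` returns a
#'   `genotype_matrix`.
#' @export
write_dosage_tsv <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  tab <- cbind(g$snp_meta[, c("id", "chrom", "pos", "alleleA", "alleleB")],
               as.data.frame(t(g$dosages)))
  names(tab)[1] <- "snp_id"
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = c(snp_id = "character",
                                          chrom = "character"))
  meta_cols <- c("snp_id", "chrom", "pos", "alleleA", "alleleB")
  meta <- tab[, meta_cols]
  names(meta)[1] <- "id"
  dos <- t(as.matrix(tab[, setdiff(names(tab), meta_cols), drop = FALSE]))
  storage.mode(dos) <- "integer"
  genotype_matrix(dos, meta, rownames(dos))
}

#' Write/read a phenotype table as TSV
#'
#' Columns: `animal_id`, `scr`, `evaluation`, `breedings`.
#'
#' @param records Phenotype data frame.
#' @param path File path.
#' @export
write_phenotype_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotype_tsv
#' @export
read_phenotype_tsv <- function(path) {
  utils::read.delim(path, colClasses = c(animal_id = "character",
                                         evaluation = "character"))
}

#' Write/read gene models as BED with a strand column
#'
#' Standard 6-column BED (0-based, half-open): chrom, start, end, name,
#' score (gene_type is stored here), strand.
#'
#' @param genes Gene data frame (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`, optional `gene_type`).
#' @param path File path.
#' @export
write_gene_bed <- function(genes, path) {
  bed <- data.frame(chrom = genes$chrom, start = genes$start,
                    end = genes$end, name = genes$gene_id,
                    score = genes$gene_type %||% ".",
                    strand = genes$strand)
  utils::write.table(bed, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_gene_bed
#' @export
read_gene_bed <- function(path) {
  bed <- utils::read.delim(path, header = FALSE,
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand"),
                           colClasses = c("character", "integer",
                                          "integer", "character",
                                          "character", "character"))
  data.frame(gene_id = bed$name, chrom = bed$chrom, start = bed$start,
             end = bed$end, strand = bed$strand, gene_type = bed$score,
             stringsAsFactors = FALSE)
}

#' Write a SNP-class partition as TSV
#'
#' @param partition A `snp_class_partition`.
#' @param path File path.
#' @export
write_partition_tsv <- function(partition, path) {
  utils::write.table(data.frame(snp_id = names(partition$class_of),
                                class = unname(partition$class_of)),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write genotypes as PLINK-1 binary (.bed/.bim/.fam)
#'
#' SNP-major .bed with the standard magic bytes. A1 is the B (counted)
#' allele, so the 2-bit codes are: 00 = BB, 10 = AB, 11 = AA,
#' 01 = missing.
#'
#' @param g A [genotype_matrix()].
#' @param prefix Path prefix; writes `<prefix>.bed`, `.bim`, `.fam`.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(g, prefix) {
  stopifnot(inherits(g, "genotype_matrix"))
  n <- nrow(g$dosages); p <- ncol(g$dosages)
  bim <- data.frame(chrom = g$snp_meta$chrom, id = g$snp_meta$id,
                    cm = 0, pos = g$snp_meta$pos,
                    a1 = g$snp_meta$alleleB, a2 = g$snp_meta$alleleA)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  fam <- data.frame(fid = g$sample_ids, iid = g$sample_ids,
                    pat = 0, mat = 0, sex = 0, pheno = -9)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  # 2-bit codes indexed by dosage of A1 (+1): 0 -> 11, 1 -> 10, 2 -> 00
  code_of <- c(3L, 2L, 0L)
  bytes_per_snp <- ceiling(n / 4)
  for (j in seq_len(p)) {
    dos <- g$dosages[, j]
    codes <- ifelse(is.na(dos), 1L, code_of[dos + 1L])
    codes <- c(codes, rep(0L, bytes_per_snp * 4 - n))
    m <- matrix(codes, nrow = 4)
    bytes <- m[1, ] + m[2, ] * 4L + m[3, ] * 16L + m[4, ] * 64L
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}

#' Read PLINK-1 binary genotypes
#'
#' @param prefix Path prefix of `.bed/.bim/.fam` files.
#' @return A [genotype_matrix()] with dosages counting the A1 allele.
#' @export
read_plink <- function(prefix) {
  bim <- utils::read.delim(paste0(prefix, ".bim"), header = FALSE,
                           col.names = c("chrom", "id", "cm", "pos",
                                         "a1", "a2"),
                           colClasses = c("character", "character",
                                          "numeric", "integer",
                                          "character", "character"))
  fam <- utils::read.delim(paste0(prefix, ".fam"), header = FALSE,
                           colClasses = "character")
  n <- nrow(fam); p <- nrow(bim)
  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L)))
    stop("not a SNP-major PLINK-1 .bed file")
  bytes_per_snp <- ceiling(n / 4)
  raw <- readBin(con, "raw", bytes_per_snp * p)
  b <- as.integer(raw)
  two_bits <- rbind(b %% 4L, (b %/% 4L) %% 4L, (b %/% 16L) %% 4L,
                    b %/% 64L)
  dim(two_bits) <- c(4L * bytes_per_snp, p)
  two_bits <- two_bits[seq_len(n), , drop = FALSE]
  # 00 -> 2 copies of A1, 10 -> 1, 11 -> 0, 01 -> missing
  dos_of <- c(2L, NA_integer_, 1L, 0L)
  dos <- matrix(dos_of[two_bits + 1L], n, p)
  meta <- data.frame(id = bim$id, chrom = bim$chrom, pos = bim$pos,
                     alleleA = bim$a2, alleleB = bim$a1,
                     stringsAsFactors = FALSE)
  genotype_matrix(dos, meta, fam[[2]])
}

#' Write the truth ledger of a simulation as structured text
#'
#' @param truth A `true_parameters` object.
#' @param path YAML file path.
#' @export
write_truth_yaml <- function(truth, path) {
  stopifnot(inherits(truth, "true_parameters"))
  yaml::write_yaml(list(
    realized_h2 = truth$realized_h2,
    dominance_qtl_ids = as.list(truth$dominance_qtl_ids),
    dominance_effects = as.list(truth$dominance_effects),
    eval_class_effects = as.list(truth$eval_class_effects),
    additive_effects = as.list(truth$additive_effects)), path)
  invisible(path)
}
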