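# Sequence-Ontology-style effect terms recognised on input, mapped to the
# six analysis classes. Unknown terms fall through to the positional rules.
.SO_TERM_MAP <- c(missense = "non_synonymous",
                  missense_variant = "non_synonymous",
                  nonsense = "non_synonymous",
                  stop_gained = "non_synonymous",
                  synonymous = "synonymous",
                  synonymous_variant = "synonymous",
                  ncRNA = "ncRNA",
                  nc_transcript_variant = "ncRNA",
                  non_coding_transcript_variant = "ncRNA")

# Regulatory windows of a gene in 0-based coordinates: positions whose
# distance to the 5' (resp. 3') terminus is between 1 and 5000 bases,
# inclusive of base 5000, strand-aware. Gene intervals are BED half-open
# [start, end): on '+' the 5' terminus is `start` and the 3' terminus is
# `end - 1`; on '-' they swap.
.flank_windows <- function(gene) {
  w <- 5000L
  if (gene$strand == "+") {
    list(five = c(gene$start - w, gene$start - 1L),
         three = c(gene$end, gene$end + w - 1L))
  } else {
    list(five = c(gene$end, gene$end + w - 1L),
         three = c(gene$start - w, gene$start - 1L))
  }
}

#' Classify one SNP into a functional class
#'
#' Coding/ncRNA labels take precedence: a recognised effect term
#' (missense, nonsense/stop_gained -> `non_synonymous`; synonymous ->
#' `synonymous`; non-coding-transcript terms -> `ncRNA`) decides the class
#' outright. Otherwise positional rules apply: a SNP within 5000 bases
#' (inclusive) of a gene's 5' end, strand-aware, is `5region`; the
#' mirrored 3' rule gives `3region`; `5region` wins when both apply;
#' anything else is `intergenic`. Unknown effect terms fall through to the
#' positional rules with a message.
#'
#' @param position 0-based SNP position.
#' @param chromosome Chromosome label.
#' @param gene_models Data frame of gene intervals (`chrom`, `start`,
#'   `end`, `strand`; 0-based half-open), or a `gene_models` object.
#' @param effect_label Optional effect term for this SNP.
#' @return One of `"5region"`, `"3region"`, `"non_synonymous"`,
#'   `"synonymous"`, `"ncRNA"`, `"intergenic"`.
#' @export
classify_snp <- function(position, chromosome, gene_models,
                         effect_label = NULL) {
  genes <- if (inherits(gene_models, "gene_models")) gene_models$genes
           else gene_models
  if (!is.null(effect_label) && !is.na(effect_label) &&
      nzchar(effect_label)) {
    cls <- .SO_TERM_MAP[effect_label]
    if (!is.na(cls)) return(unname(cls))
    message("unknown effect term '", effect_label,
            "'; falling back to positional rules")
  }
  if (nrow(genes) == 0) return("intergenic")
  on_chr <- genes[genes$chrom == as.character(chromosome), , drop = FALSE]
  hit3 <- FALSE
  for (i in seq_len(nrow(on_chr))) {
    fw <- .flank_windows(on_chr[i, ])
    if (position >= fw$five[1] && position <= fw$five[2]) return("5region")
    if (position >= fw$three[1] && position <= fw$three[2]) hit3 <- TRUE
  }
  if (hit3) "3region" else "intergenic"
}

#' Partition all SNPs into functional classes
#'
#' Applies [classify_snp()] to every SNP of a genotype matrix, yielding an
#' exhaustive, mutually exclusive partition over the five functional
#' classes plus intergenic.
#'
#' @param g A [genotype_matrix()].
#' @param gene_models Gene intervals (see [classify_snp()]); may be empty.
#' @param labels Optional data frame (`snp_id`, `so_term`) of per-variant
#'   effect terms.
#' @return An object of class `snp_class_partition`: list with `class_of`
#'   (named character vector, SNP id -> class) and `counts` (per-class
#'   totals summing to p).
#' @export
partition_snps <- function(g, gene_models, labels = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  genes <- if (inherits(gene_models, "gene_models")) gene_models$genes
           else gene_models
  if (is.null(labels) && inherits(gene_models, "gene_models"))
    labels <- gene_models$effect_labels
  meta <- g$snp_meta
  p <- nrow(meta)
  cls <- rep("intergenic", p)
  names(cls) <- meta$id

  # effect labels first (coding classes are label-only)
  if (!is.null(labels) && nrow(labels)) {
    mapped <- .SO_TERM_MAP[labels$so_term]
    unknown <- is.na(mapped)
    if (any(unknown))
      message(sum(unknown), " unknown effect term(s) ignored: ",
              paste(unique(labels$so_term[unknown]), collapse = ", "))
    ok <- labels$snp_id[!unknown] %in% meta$id
    cls[labels$snp_id[!unknown][ok]] <- mapped[!unknown][ok]
  }

  # positional rules for the rest, vectorised per gene
  if (!is.null(genes) && nrow(genes)) {
    unlabeled <- cls == "intergenic"
    in5 <- rep(FALSE, p); in3 <- rep(FALSE, p)
    for (i in seq_len(nrow(genes))) {
      gi <- genes[i, ]
      on_chr <- meta$chrom == gi$chrom
      if (!any(on_chr)) next
      fw <- .flank_windows(gi)
      in5 <- in5 | (on_chr & meta$pos >= fw$five[1] &
                      meta$pos <= fw$five[2])
      in3 <- in3 | (on_chr & meta$pos >= fw$three[1] &
                      meta$pos <= fw$three[2])
    }
    cls[unlabeled & in5] <- "5region"
    cls[unlabeled & !in5 & in3] <- "3region"
  }

  counts <- table(factor(cls, levels = snp_class_levels()))
  structure(list(class_of = cls,
                 counts = stats::setNames(as.integer(counts),
                                          names(counts))),
            class = "snp_class_partition")
}

#' @export
print.snp_class_partition <- function(x, ...) {
  cat("snp_class_partition over", sum(x$counts), "SNPs:\n")
  print(x$counts)
  invisible(x)
}
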