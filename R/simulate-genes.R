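#' Simulate gene models and per-SNP functional labels
#'
#' Assigns each SNP a functional class drawn from
#' `config$class_proportions` (remainder intergenic) and emits gene
#' intervals consistent with those labels:
#'
#' * `5region` / `3region` SNPs get a gene whose 5' (resp. 3') end lies
#'   within 5000 bases of the SNP on a random strand, so the positional
#'   5 kb rule re-derives the label;
#' * `non_synonymous`, `synonymous` and `ncRNA` SNPs get a gene containing
#'   them plus an explicit Sequence-Ontology-style effect label (these
#'   classes cannot be derived from position alone);
#' * `intergenic` SNPs get no gene.
#'
#' Genes are short relative to the inter-SNP spacing, so a gene emitted for
#' one SNP never changes the class of another.
#'
#' @param config A [sim_config()].
#' @param genotypes Optional [genotype_matrix()] whose SNP map should be
#'   used; defaults to the map implied by `config`.
#' @return A list of class `gene_models` with elements `genes` (data frame:
#'   `gene_id`, `chrom`, `start`, `end`, `strand`, `gene_type`; 0-based
#'   half-open intervals), `effect_labels` (data frame: `snp_id`,
#'   `so_term`) and `true_class` (named character vector, the generator's
#'   label per SNP).
#' @export
simulate_gene_models <- function(config, genotypes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "genes"))
  meta <- if (is.null(genotypes)) snp_map(config) else genotypes$snp_meta
  p <- nrow(meta)
  props <- config$class_proportions
  if (sum(props) > 1) stop("class proportions sum to more than 1")
  classes <- c(names(props), "intergenic")
  probs <- c(props, intergenic = 1 - sum(props))
  lab <- sample(classes, p, replace = TRUE, prob = probs)
  names(lab) <- meta$id

  so_term_of <- c(non_synonymous = "missense", synonymous = "synonymous",
                  ncRNA = "ncRNA")
  gene_len <- 2000L
  sel <- which(lab != "intergenic")
  cls <- lab[sel]
  pos <- meta$pos[sel]
  strand <- sample(c("+", "-"), length(sel), replace = TRUE)
  d <- sample.int(5000L, length(sel), replace = TRUE)  # SNP -> terminus
  positional <- cls %in% c("5region", "3region")
  upstream <- cls == "5region"
  # on '+' the 5' terminus is `start`, the 3' terminus is `end - 1`;
  # on '-' they swap
  right_of_snp <- (upstream & strand == "+") | (!upstream & strand == "-")
  start <- ifelse(right_of_snp, pos + d, pos - d + 1L - gene_len)
  end <- start + gene_len
  # coding/ncRNA variants sit inside their gene; their class is carried by
  # an explicit effect label, not by position
  start[!positional] <- pos[!positional] - 1000L
  end[!positional] <- pos[!positional] + 1000L
  genes <- data.frame(gene_id = paste0("gene_", meta$id[sel]),
                      chrom = meta$chrom[sel],
                      start = as.integer(start), end = as.integer(end),
                      strand = strand,
                      gene_type = ifelse(cls == "ncRNA", "ncRNA",
                                         "protein_coding"),
                      stringsAsFactors = FALSE)
  labels <- data.frame(snp_id = meta$id[sel][!positional],
                       so_term = unname(so_term_of[cls[!positional]]),
                       stringsAsFactors = FALSE)
  structure(list(genes = genes, effect_labels = labels, true_class = lab),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, %d labelled variants\n",
              nrow(x$genes), nrow(x$effect_labels)))
  print(table(x$true_class))
  invisible(x)
}
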