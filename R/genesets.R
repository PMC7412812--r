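#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (wraps `stats::p.adjust(method = "BH")`),
#' validating that inputs are probabilities.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' A named gene set
#'
#' @param name Set name.
#' @param genes Character vector of gene ids (deduplicated).
#' @param provenance Non-empty description of how the set was derived.
#' @return Object of class `gene_set`.
#' @export
gene_set <- function(name, genes, provenance) {
  stopifnot(nzchar(name), nzchar(provenance))
  structure(list(name = name, genes = unique(as.character(genes)),
                 provenance = provenance), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d genes (%s)\n", x$name, length(x$genes),
              x$provenance))
  invisible(x)
}

#' Threshold-filter a differential-expression table
#'
#' Applies the study's literal threshold rules: the fold-change bound is
#' inclusive (`|log2FC| >= min_abs_lfc`, signed by `direction`) and the
#' FDR bound is strict (`padj < max_fdr`).  The RNA-Seq rule is
#' `min_abs_lfc = 1`; the RIP-Seq association rule is `min_abs_lfc = 0.5`
#' with `direction = "up"`.
#'
#' @param table data.frame with `gene_id`, `log2FoldChange` (or `log2fc`),
#'   and `padj` and/or `pvalue`; if `padj` is absent it is computed from
#'   `pvalue` with [bh_adjust()].
#' @param min_abs_lfc Inclusive fold-change bound on the log2 scale.
#' @param max_fdr Strict adjusted-p bound.
#' @param direction `"up"` (log2FC >= bound), `"down"` (<= -bound) or
#'   `"both"` (absolute value).
#' @param name Name for the resulting set.
#' @param strip_versions If TRUE, trailing `.N` version suffixes are
#'   stripped from gene ids before matching.
#' @return A [gene_set()].
#' @export
filter_de <- function(table, min_abs_lfc, max_fdr = 0.05,
                      direction = c("up", "down", "both"),
                      name = "de_set", strip_versions = FALSE) {
  direction <- match.arg(direction)
  lfc <- if ("log2FoldChange" %in% names(table)) table$log2FoldChange else table$log2fc
  if (is.null(lfc)) stop("no log2 fold-change column")
  if (any(!is.finite(lfc))) stop("non-finite log2 fold changes")
  if (anyDuplicated(table$gene_id)) stop("duplicate gene_ids")
  padj <- table$padj
  if (is.null(padj)) {
    if (is.null(table$pvalue)) stop("neither padj nor pvalue present")
    padj <- bh_adjust(table$pvalue)
  }
  pass_fc <- switch(direction,
                    up = lfc >= min_abs_lfc,
                    down = lfc <= -min_abs_lfc,
                    both = abs(lfc) >= min_abs_lfc)
  keep <- pass_fc & !is.na(padj) & padj < max_fdr
  ids <- table$gene_id[keep]
  if (strip_versions) ids <- sub("\\.\\d+$", "", ids)
  gene_set(name, ids,
           sprintf("%s-regulated: %s log2FC >= %g & BH-adjusted p < %g",
                   direction, if (direction == "both") "absolute" else "signed",
                   min_abs_lfc, max_fdr))
}

#' Integrate the study's gene sets
#'
#' Annotates every gene upregulated upon knockdown with whether it is
#' down in GBM versus LGG, down in GBM versus normal cortex, and
#' H3K27me3-methylated in GBM cells, and tabulates every flag combination.
#'
#' @param up_in_kd,methylated,gbm_down_vs_lgg,gbm_down_vs_cortex
#'   [gene_set()] objects sharing a gene-id namespace.
#' @return `list(annotation = <data.frame>, counts = <data.frame of flag
#'   combinations>)`.
#' @export
integrate_sets <- function(up_in_kd, methylated, gbm_down_vs_lgg,
                           gbm_down_vs_cortex) {
  g <- up_in_kd$genes
  ann <- data.frame(gene_id = g,
                    down_vs_lgg = g %in% gbm_down_vs_lgg$genes,
                    down_vs_cortex = g %in% gbm_down_vs_cortex$genes,
                    h3k27me3 = g %in% methylated$genes,
                    stringsAsFactors = FALSE)
  counts <- stats::aggregate(list(n = seq_len(nrow(ann))),
                             ann[c("down_vs_lgg", "down_vs_cortex", "h3k27me3")],
                             FUN = length)
  list(annotation = ann, counts = counts)
}

#' Hypergeometric overlap test between two gene sets
#'
#' Upper-tail probability of observing at least the given intersection
#' when `|A|` genes are drawn from the universe, plus the fold enrichment
#' `(|A∩B| / |A|) / (|B| / |U|)`.
#'
#' @param a,b [gene_set()] objects (subsets of `universe`).
#' @param universe A [gene_set()] defining the sampling universe.
#' @return `list` with set sizes, `overlap`, `hypergeometric_p`,
#'   `fold_enrichment`.
#' @export
overlap_test <- function(a, b, universe) {
  U <- length(universe$genes)
  if (U == 0L) stop("empty universe")
  if (!all(a$genes %in% universe$genes) || !all(b$genes %in% universe$genes))
    stop("sets must be subsets of the universe")
  nA <- length(a$genes); nB <- length(b$genes)
  x <- length(intersect(a$genes, b$genes))
  p <- stats::phyper(x - 1L, nB, U - nB, nA, lower.tail = FALSE)
  fold <- if (nA == 0L || nB == 0L) NA_real_ else (x / nA) / (nB / U)
  list(set_a = a$name, set_b = b$name, universe_size = U,
       size_a = nA, size_b = nB, overlap = x,
       hypergeometric_p = p, fold_enrichment = fold)
}
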