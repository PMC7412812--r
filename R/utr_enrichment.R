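#' Motif query for 3'UTR scanning
#'
#' Either a list of exact 7-mers (default the GC-rich 7-mer GCGCGGG) or a
#' position-frequency matrix scored by log-odds against a uniform
#' background, thresholded at a fraction of the maximal attainable score.
#'
#' @param kmers Character vector of k-mers (RNA or DNA alphabet).
#' @param pfm Optional [top_kmer_pfm()] motif (or bare 4 x w matrix with
#'   rows A, C, G, U) switching the query to PFM mode.
#' @param pfm_threshold Fraction of the maximal log-odds score a window
#'   must reach to count as a hit, in (0, 1] (default 0.8).
#' @param pseudocount Added to PFM counts before log-odds (default 0.5).
#' @return Object of class `motif_query`.
#' @export
motif_query <- function(kmers = "GCGCGGG", pfm = NULL, pfm_threshold = 0.8,
                        pseudocount = 0.5) {
  if (is.null(pfm) && length(kmers) == 0L)
    stop("need at least one k-mer or a PFM")
  stopifnot(pfm_threshold > 0, pfm_threshold <= 1)
  mode <- if (is.null(pfm)) "kmer_list" else "pfm"
  lom <- NULL
  if (!is.null(pfm)) {
    m <- if (inherits(pfm, "motif_model")) pfm$pfm else pfm
    stopifnot(nrow(m) == 4L)
    m <- m + pseudocount
    p <- sweep(m, 2L, colSums(m), "/")
    lom <- log2(p / 0.25)
    rownames(lom) <- c("A", "C", "G", "U")
  }
  structure(list(mode = mode, kmers = toupper(dna_to_rna(kmers)),
                 log_odds = lom, pfm_threshold = pfm_threshold),
            class = "motif_query")
}

#' Scan one sequence for the motif
#'
#' Exact (overlapping) substring matching in k-mer mode; windowed log-odds
#' scoring against a uniform background in PFM mode.  T and U are
#' equivalent; windows containing N never match.
#'
#' @param seq A single RNA or DNA sequence.
#' @param query A [motif_query()].
#' @return `list(has_motif = <logical>, n_hits = <integer>)`.
#' @export
scan_utr <- function(seq, query = motif_query()) {
  s <- toupper(dna_to_rna(seq))
  if (query$mode == "kmer_list") {
    n <- sum(vapply(query$kmers, count_fixed, 0L, str = s))
  } else {
    w <- ncol(query$log_odds)
    L <- nchar(s)
    if (L < w) return(list(has_motif = FALSE, n_hits = 0L))
    maxs <- sum(apply(query$log_odds, 2L, max))
    cutoff <- query$pfm_threshold * maxs
    b <- strsplit(s, "")[[1L]]
    row <- match(b, c("A", "C", "G", "U"))      # N -> NA, never matches
    n <- 0L
    for (i in seq_len(L - w + 1L)) {
      r <- row[i:(i + w - 1L)]
      if (anyNA(r)) next
      sc <- sum(query$log_odds[cbind(r, seq_len(w))])
      if (sc >= cutoff) n <- n + 1L
    }
  }
  list(has_motif = n > 0L, n_hits = as.integer(n))
}

#' Background gene universe from a count table
#'
#' Genes expressed in at least one sample, defined as a count of at least
#' `min_count` in some sample.
#'
#' @param counts data.frame with a `gene_id` column and one column per
#'   sample (non-negative integer counts), or a numeric matrix with gene
#'   rownames.
#' @param min_count Expression threshold (default 2).
#' @return Sorted character vector of gene ids.
#' @export
build_background <- function(counts, min_count = 2L) {
  if (is.data.frame(counts)) {
    genes <- counts$gene_id
    m <- as.matrix(counts[, setdiff(names(counts), "gene_id"), drop = FALSE])
  } else {
    genes <- rownames(counts)
    m <- counts
  }
  if (length(genes) == 0L || ncol(m) == 0L) stop("empty count table")
  if (any(m < 0)) stop("negative counts")
  keep <- apply(m, 1L, max) >= min_count
  sort(unique(genes[keep]))
}

#' Fraction of genes whose 3'UTR carries the motif
#'
#' A gene has the motif if any of its annotated 3'UTR isoforms matches the
#' query; genes with no UTR are dropped (with a warning) from the
#' denominator.
#'
#' @param genes Character vector of gene ids.
#' @param utrs data.frame with `gene_id` and `utr_seq` (one row per
#'   isoform; genes may repeat).
#' @param query A [motif_query()].
#' @return Proportion in `[0, 1]`.
#' @export
motif_proportion <- function(genes, utrs, query = motif_query()) {
  if (length(genes) == 0L) stop("empty gene list")
  flags <- gene_motif_flags(utrs, query)
  known <- genes[genes %in% names(flags)]
  if (length(known) < length(genes))
    warning(length(genes) - length(known), " gene(s) lack a UTR and were dropped")
  if (length(known) == 0L) stop("no gene has a UTR")
  mean(flags[known])
}

## per-gene any-isoform motif presence
gene_motif_flags <- function(utrs, query) {
  hit <- vapply(utrs$utr_seq, function(s) scan_utr(s, query)$has_motif, TRUE,
                USE.NAMES = FALSE)
  tapply(hit, utrs$gene_id, any)
}

#' Permutation test for motif enrichment among target genes
#'
#' Compares the observed motif proportion among target genes with a null
#' built by repeatedly sampling the same number of genes without
#' replacement from the background universe (10,000 iterations by
#' default), as in RIP-Seq target enrichment analyses.  The empirical p
#' uses the add-one (permutation-inclusive) correction and is therefore
#' never zero.
#'
#' @param targets Character vector of target gene ids (subset of
#'   `background`).
#' @param background Character vector of background gene ids.
#' @param utrs data.frame with `gene_id`, `utr_seq`.
#' @param query A [motif_query()].
#' @param n_iterations Number of resampling iterations (default 10000).
#' @param seed Integer seed for the sampler (recorded in the result).
#' @param hist_breaks Number of histogram bins summarizing the null.
#' @return Object of class `permutation_result`.
#' @export
permutation_test <- function(targets, background, utrs, query = motif_query(),
                             n_iterations = 10000L, seed = 1L,
                             hist_breaks = 30L) {
  if (n_iterations < 1L) stop("n_iterations must be >= 1")
  if (length(targets) < 1L) stop("empty target list")
  if (!all(targets %in% background)) stop("targets must be a subset of background")
  flags <- gene_motif_flags(utrs, query)
  if (!all(background %in% names(flags)))
    stop("background gene(s) lack a UTR")
  bg_flags <- as.logical(flags[background])
  obs <- mean(flags[targets])
  n_t <- length(targets); n_b <- length(background)

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  null_prop <- vapply(seq_len(n_iterations), function(i)
    mean(bg_flags[sample.int(n_b, n_t)]), 0)

  h <- graphics::hist(null_prop, breaks = hist_breaks, plot = FALSE)
  p <- (1 + sum(null_prop >= obs)) / (n_iterations + 1)
  structure(list(n_targets = n_t, n_background = n_b,
                 observed_proportion = obs,
                 null_mean = mean(null_prop), null_sd = stats::sd(null_prop),
                 null_breaks = h$breaks, null_counts = h$counts,
                 n_iterations = as.integer(n_iterations),
                 empirical_p = p, seed = as.integer(seed)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(paste0("Motif enrichment permutation test\n",
                     "  targets: %d of %d background genes\n",
                     "  observed proportion: %.4f\n",
                     "  null: mean %.4f, sd %.4f (%d iterations)\n",
                     "  empirical p: %.4g\n"),
              x$n_targets, x$n_background, x$observed_proportion,
              x$null_mean, x$null_sd, x$n_iterations, x$empirical_p))
  invisible(x)
}
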