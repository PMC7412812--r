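#' Promoter windows around transcription start sites
#'
#' Builds the symmetric flanking window (default −3 kb to +3 kb) around
#' each TSS, clipped at the chromosome origin.  Coordinates are 0-based
#' half-open (BED convention).  Strand is ignored for the symmetric window
#' but retained upstream for provenance; a gene with several TSS gets one
#' window per TSS.
#'
#' @param tss data.frame with `gene_id`, `chrom`, `pos` (0-based TSS
#'   coordinate) and optionally `strand`.
#' @param flank Window half-width in bp (default 3000).
#' @return data.frame (`gene_id`, `window_id`, `chrom`, `start`, `end`).
#' @export
make_promoters <- function(tss, flank = 3000L) {
  stopifnot(flank > 0L, all(tss$pos >= 0L))
  data.frame(gene_id = tss$gene_id,
             window_id = sprintf("%s_w%d", tss$gene_id,
                                 stats::ave(seq_len(nrow(tss)), tss$gene_id,
                                            FUN = seq_along)),
             chrom = tss$chrom,
             start = pmax(0L, as.integer(tss$pos) - as.integer(flank)),
             end = as.integer(tss$pos) + as.integer(flank),
             stringsAsFactors = FALSE)
}

#' Union overlap of peaks with one window
#'
#' Total base pairs of the window covered by the union of the peaks
#' (overlapping peaks are not double counted).  All intervals are 0-based
#' half-open on one chromosome.
#'
#' @param window `list` or one-row data.frame with `start`, `end`.
#' @param peaks data.frame with `start`, `end` for one sample (already
#'   FDR-filtered and on the window's chromosome).
#' @return Integer overlap in bp.
#' @export
peak_overlap <- function(window, peaks) {
  if (window$end <= window$start) stop("malformed window")
  if (nrow(peaks) == 0L) return(0L)
  if (any(peaks$end <= peaks$start)) stop("malformed peak interval")
  pk <- IRanges::reduce(IRanges::IRanges(start = peaks$start + 1L,
                                         end = peaks$end))
  w <- IRanges::IRanges(start = window$start + 1L, end = window$end)
  sum(IRanges::width(IRanges::intersect(pk, w)))
}

#' Call promoter H3K27me3 status per gene
#'
#' A promoter window "has a peak" in a sample when the union of that
#' sample's FDR-passing peaks covers at least `min_overlap_bp` of the
#' window; a gene is methylated when at least one of its windows has a
#' peak in at least `min_samples` samples (the multi-sample consensus
#' rule, default 3 of 9).
#'
#' @param promoters Output of [make_promoters()].
#' @param peak_sets Named list (one element per sample) of data.frames
#'   with `chrom`, `start`, `end` and optionally `fdr_p`; peaks without an
#'   `fdr_p` column are treated as pre-filtered.
#' @param min_samples Consensus rule (default 3).
#' @param fdr_max Peaks with `fdr_p >= fdr_max` are discarded (default 0.05).
#' @param min_overlap_bp Minimum union overlap for a window to count as
#'   hit in a sample (default 1, i.e. any overlap).
#' @return data.frame sorted by `gene_id` with `n_samples_with_peak`,
#'   `samples` (comma-separated, for the best window), `methylated`, and
#'   one `overlap_<sample>` column per sample (summed over the gene's
#'   windows).
#' @export
call_methylation <- function(promoters, peak_sets, min_samples = 3L,
                             fdr_max = 0.05, min_overlap_bp = 1L) {
  stopifnot(nrow(promoters) > 0L, length(peak_sets) >= 1L)
  if (is.null(names(peak_sets)))
    names(peak_sets) <- sprintf("s%d", seq_along(peak_sets))
  if (min_samples > length(peak_sets))
    warning("min_samples exceeds the number of samples; nothing can be called")

  nw <- nrow(promoters)
  ns <- length(peak_sets)
  ov <- matrix(0L, nrow = nw, ncol = ns,
               dimnames = list(promoters$window_id, names(peak_sets)))
  for (s in seq_len(ns)) {
    pk <- peak_sets[[s]]
    if (!is.null(pk$fdr_p)) pk <- pk[pk$fdr_p < fdr_max, , drop = FALSE]
    if (nrow(pk) == 0L) next
    for (chr in unique(promoters$chrom)) {
      wi <- which(promoters$chrom == chr)
      pc <- pk[pk$chrom == chr, , drop = FALSE]
      if (nrow(pc) == 0L) next
      pr <- IRanges::reduce(IRanges::IRanges(start = pc$start + 1L, end = pc$end))
      wr <- IRanges::IRanges(start = promoters$start[wi] + 1L,
                             end = promoters$end[wi])
      hits <- IRanges::findOverlaps(wr, pr)
      if (length(hits) == 0L) next
      iw <- IRanges::pintersect(wr[S4Vectors::queryHits(hits)],
                                pr[S4Vectors::subjectHits(hits)])
      tot <- tapply(IRanges::width(iw), S4Vectors::queryHits(hits), sum)
      ov[wi[as.integer(names(tot))], s] <- as.integer(tot)
    }
  }
  hit <- ov >= min_overlap_bp
  win_n <- rowSums(hit)

  genes <- sort(unique(promoters$gene_id))
  res <- lapply(genes, function(g) {
    wi <- which(promoters$gene_id == g)
    best <- wi[which.max(win_n[wi])]
    n <- win_n[best]
    smp <- names(peak_sets)[hit[best, ]]
    tot <- if (length(wi) == 1L) ov[wi, , drop = TRUE] else colSums(ov[wi, , drop = FALSE])
    c(list(gene_id = g, n_samples_with_peak = as.integer(n),
           samples = paste(smp, collapse = ","),
           methylated = n >= min_samples),
      stats::setNames(as.list(as.integer(tot)), paste0("overlap_", names(peak_sets))))
  })
  out <- do.call(rbind, lapply(res, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}
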