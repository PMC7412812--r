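#' Z-score k-mers from probe intensity data
#'
#' For every k-mer with enough supporting probes, the raw score is the
#' two-sided trimmed mean of log intensities of the probes containing it;
#' the Z-score standardizes raw scores across the k-mer population.  Scores
#' are computed within set A, within set B, and over the combined pool; the
#' one-sided reading is that only large positive Z indicates binding.
#'
#' @param table data.frame with columns `probe_id`, `set_label`, `intensity`
#'   (positive, finite).
#' @param pool Probe sequences: either a data.frame with `probe_id` and a
#'   sequence column (`rna_seq` preferred, else `variable_seq`), or a named
#'   character vector keyed by probe_id.  T and U are equivalent.
#' @param k k-mer width (default 7).
#' @param min_probes Minimum number of supporting probes for a k-mer to be
#'   scored in a scope (default 10).
#' @param trim Fraction trimmed from each tail of the log-intensity
#'   distribution before averaging (default 0.05).
#' @return data.frame (`kmer` in RNA alphabet, `set_label` in
#'   `{A, B, combined}`, `n_probes`, `raw_score`, `z`), sorted by `z`
#'   descending within scope.
#' @export
kmer_zscores <- function(table, pool, k = 7L, min_probes = 10L, trim = 0.05) {
  if (is.data.frame(pool)) {
    seq_col <- if ("rna_seq" %in% names(pool)) "rna_seq" else "variable_seq"
    seqs <- stats::setNames(pool[[seq_col]], pool$probe_id)
  } else seqs <- pool
  if (nrow(table) < 2L) stop("insufficient data: need at least 2 probes")
  if (anyDuplicated(table$probe_id)) stop("duplicate probe_ids")
  if (any(!is.finite(table$intensity)) || any(table$intensity <= 0))
    stop("intensities must be finite and positive")
  missing <- setdiff(table$probe_id, names(seqs))
  if (length(missing)) stop("probes without sequence: ", missing[1L], " ...")

  s <- rna_to_dna(seqs[table$probe_id])     # count in one alphabet space
  nw <- nchar(s) - k + 1L
  ok <- nw >= 1L
  idx <- rep(which(ok), nw[ok])
  kmers <- substring(s[idx], sequence(nw[ok]), sequence(nw[ok]) + k - 1L)
  pk <- unique(data.frame(probe = idx, kmer = kmers, stringsAsFactors = FALSE))
  if (length(unique(pk$kmer)) < 2L) stop("fewer than 2 distinct k-mers")

  logint <- log(table$intensity)
  score_scope <- function(label, keep) {
    sub <- pk[keep[pk$probe], , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    raw <- tapply(logint[sub$probe], sub$kmer,
                  function(x) if (length(x) >= min_probes)
                    mean(x, trim = trim) else NA_real_)
    n <- tapply(sub$probe, sub$kmer, length)
    raw <- raw[!is.na(raw)]
    if (length(raw) == 0L) return(NULL)
    sdv <- stats::sd(raw)
    z <- if (length(raw) < 2L || sdv == 0) rep(0, length(raw))
         else (raw - mean(raw)) / sdv
    out <- data.frame(kmer = dna_to_rna(names(raw)), set_label = label,
                      n_probes = as.integer(n[names(raw)]),
                      raw_score = as.numeric(raw), z = as.numeric(z),
                      stringsAsFactors = FALSE)
    out[order(-out$z, out$kmer), ]
  }
  res <- rbind(score_scope("A", table$set_label == "A"),
               score_scope("B", table$set_label == "B"),
               score_scope("combined", rep(TRUE, nrow(table))))
  if (is.null(res) || !any(res$set_label == "combined"))
    stop("no k-mer reaches the minimum probe support")
  rownames(res) <- NULL
  res
}

#' Assemble a position-frequency motif from top-scoring k-mers
#'
#' Stacks the `top_n` k-mers by combined-scope Z-score, aligned ungapped at
#' offset 0, into a 4 x width position frequency matrix and reports the
#' column-wise argmax consensus (ties broken in A < C < G < U order).
#'
#' @param scores Output of [kmer_zscores()].
#' @param top_n Number of k-mers stacked (default 10).
#' @param normalize If TRUE, columns are scaled to sum to 1.
#' @return Object of class `motif_model`: list with `width`, `pfm` (rows
#'   A, C, G, U), `consensus`, `kmers`.
#' @export
top_kmer_pfm <- function(scores, top_n = 10L, normalize = FALSE) {
  comb <- scores[scores$set_label == "combined", , drop = FALSE]
  comb <- comb[order(-comb$z, comb$kmer), , drop = FALSE]
  if (nrow(comb) < top_n) stop("fewer than top_n scored k-mers")
  kmers <- comb$kmer[seq_len(top_n)]
  width <- unique(nchar(kmers))
  stopifnot(length(width) == 1L)
  rna_alphabet <- c("A", "C", "G", "U")
  pfm <- matrix(0, nrow = 4L, ncol = width,
                dimnames = list(rna_alphabet, NULL))
  for (km in kmers) {
    b <- strsplit(km, "")[[1L]]
    for (j in seq_len(width)) pfm[b[j], j] <- pfm[b[j], j] + 1
  }
  if (normalize) pfm <- sweep(pfm, 2L, colSums(pfm), "/")
  consensus <- paste(rna_alphabet[apply(pfm, 2L, which.max)], collapse = "")
  structure(list(width = width, pfm = pfm, consensus = consensus,
                 kmers = kmers), class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat("motif_model: width", x$width, "consensus", x$consensus, "\n")
  print(x$pfm)
  invisible(x)
}
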