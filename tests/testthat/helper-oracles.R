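# Independent oracles, deliberately implemented without the package's own
# machinery (no Biostrings, no p.adjust, no IRanges).

# Exhaustive k-mer counts over sequences by integer rolling codes.
# Returns a named vector over all 4^k k-mers in A<C<G<T lexicographic order.
oracle_kmer_counts <- function(seqs, k) {
  counts <- integer(4^k)
  for (L in unique(nchar(seqs))) {
    ss <- seqs[nchar(seqs) == L]
    if (L < k) next
    m <- matrix(match(unlist(strsplit(ss, "")), c("A", "C", "G", "T")) - 1L,
                nrow = L)
    for (i in 1:(L - k + 1L)) {
      code <- 0
      for (j in 0:(k - 1L)) code <- code * 4 + m[i + j, ]
      counts <- counts + tabulate(code + 1L, nbins = 4^k)
    }
  }
  idx <- expand.grid(rep(list(c("A", "C", "G", "T")), k))[, k:1, drop = FALSE]
  names(counts) <- apply(as.matrix(idx), 1L, paste, collapse = "")
  counts
}

# Brute-force occurrence count of a pattern in one string.
oracle_count_pattern <- function(s, pat) {
  n <- nchar(s) - nchar(pat) + 1L
  if (n < 1L) return(0L)
  sum(substring(s, 1:n, nchar(pat):(nchar(pat) + n - 1L)) == pat)
}

# Step-up BH adjustment written from the definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  adj <- pmin(1, cummin(p[o] * n / (n:1)))
  adj[ro]
}

# Per-base boolean-array union overlap of peaks with a window.
oracle_overlap_bp <- function(win_start, win_end, starts, ends, chrom_len) {
  cov <- logical(chrom_len)
  for (i in seq_along(starts))
    if (ends[i] > starts[i]) cov[(starts[i] + 1L):ends[i]] <- TRUE
  sum(cov[(win_start + 1L):win_end])
}

# Toy pool spec used across tests: order-5 backbone.  Audit widths are
# scaled down (4 and 3): at width 4 every k-mer occurs 4 times cyclically,
# so restriction-site excision cannot zero one out, whereas unique 5-mers
# around an excised site would be destroyed in a pool this tight.
toy_pool_spec <- function(...) {
  pool_design_spec(order = 5L, probe_count = 100L, variable_length = 15L,
                   max_rna_length = 21L, min_9mer_count = 1L,
                   min_7mer_per_set = 1L, audit_k_pool = 4L, audit_k_set = 3L,
                   ...)
}

# Random 4000-probe pool for intensity-scoring tests, with the GC-rich
# 7-mer planted into 20 probes (10 per set).  Random probes keep a 7-mer's
# supporting probes disjoint from its sequence neighbors', which a
# single-locus toy de Bruijn tiling would not.
scoring_pool <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(4242)
      n <- 4000L
      seqs <- vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), 35L, replace = TRUE),
              collapse = ""), "")
      plant <- 1:20                                  # alternating sets: 10 + 10
      for (i in plant) {
        pos <- sample.int(35L - 7L + 1L, 1L)
        substr(seqs[i], pos, pos + 6L) <- "GCGCGGG"
      }
      cache <<- data.frame(probe_id = sprintf("r%05d", seq_len(n)),
                           set_label = rep_len(c("A", "B"), n),
                           start = -1L, variable_seq = seqs,
                           stringsAsFactors = FALSE)
    }
    cache
  }
})
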