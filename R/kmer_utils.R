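DNA_ALPHABET <- c("A", "C", "G", "T")

#' @importFrom Biostrings DNAStringSet oligonucleotideFrequency vmatchPattern
NULL

## All k-mer bookkeeping is in DNA space (the template pool); RNA output is a
## final T->U transcription step.

dna_to_rna <- function(x) chartr("T", "U", x)
rna_to_dna <- function(x) chartr("Uu", "Tt", toupper(x))

## Exhaustive k-mer counts (with multiplicity) summed over sequences.
## Counts come back named in Biostrings' lexicographic (A<C<G<T) order.
count_kmers <- function(seqs, k) {
  stopifnot(k >= 1L)
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::oligonucleotideFrequency(x, width = k, simplify.as = "collapse")
}

#' Enumerate k-mers containing a forbidden 7-mer
#'
#' All k-mers that contain one of the forbidden 7-mers as a substring.
#' These cannot occur in an excised pool, so coverage audits at widths
#' above 7 must treat them as structurally excluded (at width 7 the
#' enumeration is the forbidden set itself).
#'
#' @param k k-mer width.
#' @param forbidden Character vector of forbidden 7-mers.
#' @return Sorted character vector of excluded k-mers.
#' @export
forbidden_supersets <- function(k, forbidden) {
  if (length(forbidden) == 0L || k < min(nchar(forbidden))) return(character(0))
  out <- character(0)
  for (f in forbidden) {
    w <- nchar(f)
    if (k < w) next
    if (k == w) { out <- c(out, f); next }
    pad <- k - w
    fills <- expand.grid(rep(list(DNA_ALPHABET), pad), stringsAsFactors = FALSE)
    fills <- apply(as.matrix(fills), 1L, paste, collapse = "")
    for (off in 0:pad) {
      left <- if (off > 0L) substr(fills, 1L, off) else ""
      right <- if (pad - off > 0L) substr(fills, off + 1L, pad) else ""
      out <- c(out, unique(paste0(left, f, right)))
    }
  }
  sort(unique(out))
}

contains_any <- function(str, patterns) {
  for (p in patterns) if (grepl(p, str, fixed = TRUE)) return(TRUE)
  FALSE
}

## Count occurrences (overlapping) of a fixed pattern in one string.
count_fixed <- function(str, pattern) {
  if (nchar(str) < nchar(pattern)) return(0L)
  m <- gregexpr(paste0("(?=", pattern, ")"), str, perl = TRUE)[[1L]]
  if (m[1L] == -1L) 0L else length(m)
}
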