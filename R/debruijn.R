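#' Generate a de Bruijn sequence
#'
#' Constructs the lexicographically least de Bruijn sequence of the given
#' order over an ordered alphabet, by concatenation of Lyndon words whose
#' length divides the order (the classic
#' Fredricksen--Kessler--Maiorana construction).  The cyclic sequence has
#' length `|alphabet|^order` and contains every `order`-length word exactly
#' once; the returned string is linearized by appending the first
#' `order - 1` letters, so that every cyclic word also occurs as a plain
#' substring.
#'
#' @param order Word length of the de Bruijn property (positive integer).
#' @param alphabet Character vector of distinct single letters, in the
#'   order that defines "lexicographically least". Default `c("A","C","G","T")`.
#' @return A single string of length `|alphabet|^order + order - 1`.
#' @examples
#' generate_de_bruijn(2)          # 17 nt, every dinucleotide once
#' @export
generate_de_bruijn <- function(order, alphabet = DNA_ALPHABET) {
  if (length(order) != 1L || is.na(order) || order < 1L || order != round(order))
    stop("'order' must be a positive integer")
  order <- as.integer(order)
  if (length(alphabet) == 0L || anyDuplicated(alphabet) || any(nchar(alphabet) != 1L))
    stop("'alphabet' must be distinct single letters")
  k <- length(alphabet)

  n <- order
  a <- integer(n + 1L)                 # a[t+1] holds position t (1-based shim)
  out <- integer(k^n)
  pos <- 0L
  rec <- function(t, p) {
    if (t > n) {
      if (n %% p == 0L) {
        out[(pos + 1L):(pos + p)] <<- a[2L:(p + 1L)]
        pos <<- pos + p
      }
    } else {
      a[t + 1L] <<- a[t - p + 1L]
      rec(t + 1L, p)
      j <- a[t - p + 1L] + 1L
      while (j < k) {
        a[t + 1L] <<- j
        rec(t + 1L, t)
        j <- j + 1L
      }
    }
  }
  rec(1L, 1L)
  lin <- c(out, out[seq_len(order - 1L)])
  paste(alphabet[lin + 1L], collapse = "")
}
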