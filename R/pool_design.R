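#' Pool design specification
#'
#' Parameter object for the RNAcompete-style probe pool: an order-11
#' de Bruijn backbone tiled into fixed-length variable regions, with two
#' restriction-site 7-mers (SapI/BspQI) excised, an A/B set split, a T7
#' phi2.5 initiation trinucleotide prefix, and combinatorial coverage
#' quotas (every attainable 9-mer at least `min_9mer_count` times in the
#' pool; every 7-mer except the forbidden pair at least `min_7mer_per_set`
#' times in each set).
#'
#' @param order de Bruijn order (default 11).
#' @param alphabet Ordered DNA alphabet.
#' @param probe_count Number of probes in the final pool (default 241399).
#' @param variable_length Length of each probe's variable region, nt (default 35).
#' @param max_rna_length Maximum transcribed RNA length including the
#'   initiation trinucleotide, nt (default 41).
#' @param forbidden_kmers DNA 7-mers that must not occur in any variable
#'   region (default the SapI/BspQI sites GCTCTTC and CGAGAAG).
#' @param min_9mer_count Pool-wide minimum multiplicity for attainable
#'   k-mers at width `audit_k_pool` (default 16).
#' @param min_7mer_per_set Per-set minimum multiplicity at width
#'   `audit_k_set`, excluding the forbidden 7-mers (default 155).
#' @param init_trinucleotides Allowed transcript starts, tried in order
#'   (default AGA then AGG).
#' @param audit_k_pool,audit_k_set k-mer widths of the pool-wide and
#'   per-set audits (defaults 9 and 7; reduce for toy orders).
#' @param patch_budget Maximum fraction of probes that may be replaced by
#'   synthetic patch probes to restore coverage after excision (default 0.001).
#' @param seed Seed recorded with the design (the default construction is
#'   fully deterministic; the seed governs any randomized fallback).
#' @return An object of class `pool_design_spec`.
#' @export
pool_design_spec <- function(order = 11L,
                             alphabet = DNA_ALPHABET,
                             probe_count = 241399L,
                             variable_length = 35L,
                             max_rna_length = 41L,
                             forbidden_kmers = c("GCTCTTC", "CGAGAAG"),
                             min_9mer_count = 16L,
                             min_7mer_per_set = 155L,
                             init_trinucleotides = c("AGA", "AGG"),
                             audit_k_pool = 9L,
                             audit_k_set = 7L,
                             patch_budget = 0.001,
                             seed = 17L) {
  stopifnot(order >= 2L, probe_count >= 1L,
            variable_length + 3L <= max_rna_length,
            all(nchar(forbidden_kmers) == 7L) || length(forbidden_kmers) == 0L,
            min_9mer_count >= 1L, min_7mer_per_set >= 1L,
            audit_k_pool >= 1L, audit_k_set >= 1L,
            audit_k_pool <= variable_length, audit_k_set <= variable_length,
            length(init_trinucleotides) >= 1L,
            all(nchar(init_trinucleotides) == 3L),
            patch_budget >= 0)
  structure(list(order = as.integer(order), alphabet = alphabet,
                 probe_count = as.integer(probe_count),
                 variable_length = as.integer(variable_length),
                 max_rna_length = as.integer(max_rna_length),
                 forbidden_kmers = forbidden_kmers,
                 min_9mer_count = as.integer(min_9mer_count),
                 min_7mer_per_set = as.integer(min_7mer_per_set),
                 init_trinucleotides = init_trinucleotides,
                 audit_k_pool = as.integer(audit_k_pool),
                 audit_k_set = as.integer(audit_k_set),
                 patch_budget = patch_budget,
                 seed = as.integer(seed)),
            class = "pool_design_spec")
}

#' Tile a sequence into probe windows
#'
#' Cuts `probe_count` windows of `variable_length` nt out of the linearized
#' de Bruijn sequence.  The first window starts at offset 0 and the last
#' ends at the sequence end; intermediate starts follow the
#' error-accumulating schedule `floor(i * (N - L) / (P - 1))`, so steps take
#' at most two adjacent integer values spread evenly (at default scale,
#' 150,885 steps of 17 and 90,513 of 18).  Consecutive overlap of at least
#' `audit_k_pool - 1` nt guarantees no audited k-mer occurrence is orphaned;
#' a smaller overlap triggers a warning, not an error.
#'
#' @param sequence DNA string to tile.
#' @param spec A [pool_design_spec()].
#' @return A data.frame of probe records (`probe_id`, `set_label`, `start`
#'   0-based, `variable_seq`).
#' @export
tile_probes <- function(sequence, spec) {
  N <- nchar(sequence); L <- spec$variable_length; P <- spec$probe_count
  if (N < L) stop("sequence shorter than variable_length")
  if (P == 1L) {
    starts <- 0
  } else {
    if (P - 1L > N - L)
      stop("infeasible tiling: ", P, " distinct windows of ", L,
           " nt cannot fit in ", N, " nt")
    starts <- floor(as.numeric(0:(P - 1L)) * (N - L) / (P - 1L))
    max_step <- max(diff(starts))
    if (L - max_step < spec$audit_k_pool - 1L)
      warning("window overlap below ", spec$audit_k_pool - 1L,
              " nt: some ", spec$audit_k_pool,
              "-mer occurrences of the source sequence are not contained in any window")
  }
  data.frame(probe_id = sprintf("p%07d", seq_along(starts)),
             set_label = NA_character_,
             start = as.integer(starts),
             variable_seq = substring(sequence, starts + 1, starts + L),
             stringsAsFactors = FALSE)
}

## Deterministic single-probe repair: for each forbidden occurrence,
## substitute one base (center first, then center-out) with the first
## alphabet-order base that introduces no forbidden 7-mer within +/- 6 nt.
repair_variable <- function(v, forbidden, alphabet = DNA_ALPHABET) {
  log <- list()
  guard <- 0L
  repeat {
    hit <- NA_integer_
    for (f in forbidden) {
      p <- regexpr(f, v, fixed = TRUE)
      if (p > 0L && (is.na(hit) || p < hit)) hit <- as.integer(p)
    }
    if (is.na(hit)) break
    guard <- guard + 1L
    if (guard > 4L * nchar(v)) stop("repair loop failed to converge")
    offsets <- c(3L, 2L, 4L, 1L, 5L, 0L, 6L)   # center-out within the 7-mer
    fixed <- FALSE
    for (off in offsets) {
      pos <- hit + off
      old <- substr(v, pos, pos)
      for (b in alphabet) {
        if (b == old) next
        w <- v
        substr(w, pos, pos) <- b
        ctx <- substr(w, max(1L, pos - 6L), min(nchar(w), pos + 6L))
        if (!contains_any(ctx, forbidden)) {
          v <- w
          log[[length(log) + 1L]] <- list(position = pos, old = old, new = b)
          fixed <- TRUE
          break
        }
      }
      if (fixed) break
    }
    if (!fixed) stop("no substitution removes forbidden 7-mer at position ", hit)
  }
  list(variable_seq = v, log = log)
}

#' Excise forbidden 7-mers from tiled probes
#'
#' Locates every occurrence of the forbidden (restriction-site) 7-mers in
#' the probe variable regions and repairs each by a minimal deterministic
#' base substitution (center base first) that creates no new forbidden
#' site.  Returns the repaired probes and a log of every edit.
#'
#' @param probes Probe data.frame from [tile_probes()].
#' @param spec A [pool_design_spec()].
#' @return `list(probes = <repaired data.frame>, log = <data.frame of
#'   probe_id, position, old, new>)`.
#' @export
excise_forbidden <- function(probes, spec) {
  forbidden <- spec$forbidden_kmers
  if (length(forbidden) == 0L)
    return(list(probes = probes, log = data.frame(probe_id = character(0),
                position = integer(0), old = character(0), new = character(0))))
  x <- Biostrings::DNAStringSet(probes$variable_seq)
  nhit <- rep(0L, nrow(probes))
  for (f in forbidden)
    nhit <- nhit + S4Vectors::elementNROWS(Biostrings::vmatchPattern(f, x))
  idx <- which(nhit > 0L)
  logs <- vector("list", length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    r <- repair_variable(probes$variable_seq[i], forbidden, spec$alphabet)
    probes$variable_seq[i] <- r$variable_seq
    if (length(r$log))
      logs[[j]] <- data.frame(probe_id = probes$probe_id[i],
                              position = vapply(r$log, `[[`, 0L, "position"),
                              old = vapply(r$log, `[[`, "", "old"),
                              new = vapply(r$log, `[[`, "", "new"),
                              stringsAsFactors = FALSE)
  }
  log <- if (length(logs)) do.call(rbind, logs[!vapply(logs, is.null, TRUE)])
         else data.frame(probe_id = character(0), position = integer(0),
                         old = character(0), new = character(0))
  list(probes = probes, log = log)
}

#' Split the pool into sets A and B
#'
#' Alternating assignment in probe order (first probe to set A), so the two
#' set sizes differ by at most one.
#'
#' @param probes Probe data.frame ordered by start.
#' @return The data.frame with `set_label` filled in.
#' @export
assign_sets <- function(probes) {
  probes$set_label <- rep_len(c("A", "B"), nrow(probes))
  probes
}

#' Add the transcription-initiation prefix
#'
#' Prepends the phi2.5 T7 initiation trinucleotide (AGA, falling back to
#' AGG) to each variable region and transcribes T to U, producing the RNA
#' probe sequence.  A trinucleotide is rejected if its junction with the
#' variable region would recreate a forbidden 7-mer in DNA space; if every
#' allowed trinucleotide fails, the first variable base is mutated (and
#' logged) to clear the junction.
#'
#' @param probes Probe data.frame with `variable_seq`.
#' @param spec A [pool_design_spec()].
#' @return The data.frame with an `rna_seq` column added.
#' @export
add_initiation_prefix <- function(probes, spec) {
  tris <- spec$init_trinucleotides
  forbidden <- spec$forbidden_kmers
  v <- probes$variable_seq
  chosen <- rep(NA_character_, length(v))
  head6 <- substr(v, 1L, 6L)
  for (tri in tris) {
    junction_bad <- vapply(paste0(tri, head6), contains_any, TRUE,
                           patterns = forbidden, USE.NAMES = FALSE)
    take <- is.na(chosen) & !junction_bad
    chosen[take] <- tri
  }
  stuck <- which(is.na(chosen))
  for (i in stuck) {    # unreachable with the default forbidden set
    for (b in spec$alphabet) {
      w <- v[i]; substr(w, 1L, 1L) <- b
      if (!contains_any(paste0(tris[1L], substr(w, 1L, 6L)), forbidden) &&
          !contains_any(substr(w, 1L, 7L), forbidden)) {
        v[i] <- w; chosen[i] <- tris[1L]
        warning("mutated junction base of probe ", probes$probe_id[i])
        break
      }
    }
    if (is.na(chosen[i])) stop("cannot clear initiation junction for probe ",
                               probes$probe_id[i])
  }
  probes$variable_seq <- v
  probes$rna_seq <- dna_to_rna(paste0(chosen, v))
  if (any(nchar(probes$rna_seq) > spec$max_rna_length))
    stop("rna_seq exceeds max_rna_length")
  probes
}

#' Audit k-mer coverage of a probe pool
#'
#' Exhaustively counts all `4^k` k-mers (with multiplicity) over the
#' variable regions of the probes in scope and reports the minimum count
#' over k-mers not in `excluded`, compared against a threshold.
#'
#' @param probes Probe data.frame.
#' @param k k-mer width.
#' @param scope `"pool"`, `"setA"` or `"setB"`.
#' @param threshold Minimum required multiplicity.
#' @param excluded k-mers excluded from the minimum (e.g. the forbidden
#'   7-mers at `k = 7`, or their supersets at `k = 9`; see
#'   [forbidden_supersets()]).
#' @param max_argmin Cap on the number of minimum-attaining k-mers listed.
#' @return An object of class `kmer_coverage_report`.
#' @export
verify_coverage <- function(probes, k, scope = c("pool", "setA", "setB"),
                            threshold, excluded = character(0),
                            max_argmin = 50L) {
  scope <- match.arg(scope)
  if (nrow(probes) == 0L) stop("no probes")
  if (k > min(nchar(probes$variable_seq)))
    stop("k exceeds variable region length")
  sel <- switch(scope, pool = rep(TRUE, nrow(probes)),
                setA = probes$set_label == "A",
                setB = probes$set_label == "B")
  counts <- count_kmers(probes$variable_seq[sel], k)
  eligible <- setdiff(names(counts), excluded)
  mn <- min(counts[eligible])
  argmin <- eligible[counts[eligible] == mn]
  structure(list(k = as.integer(k), scope = scope,
                 threshold = as.integer(threshold),
                 min_count = as.integer(mn),
                 n_argmin = length(argmin),
                 argmin_kmers = utils::head(argmin, max_argmin),
                 excluded_kmers = excluded,
                 total_kmers_counted = sum(as.numeric(counts[eligible])),
                 passed = mn >= threshold),
            class = "kmer_coverage_report")
}

#' @export
print.kmer_coverage_report <- function(x, ...) {
  cat(sprintf("k-mer coverage audit: k=%d scope=%s min=%d threshold=%d [%s]\n",
              x$k, x$scope, x$min_count, x$threshold,
              if (x$passed) "PASS" else "FAIL"))
  invisible(x)
}

## --- patch machinery ------------------------------------------------------

## Build fixed-length patch sequences packing copies of deficient k-mers
## (shortfalls in `needs`), never introducing a forbidden 7-mer.
build_patch_seqs <- function(needs, L, forbidden, alphabet = DNA_ALPHABET) {
  needs <- needs[needs > 0]
  storage.mode(needs) <- "integer"
  seqs <- character(0)
  pad_to <- function(s) {
    while (nchar(s) < L) {
      placed <- FALSE
      for (b in alphabet) {
        cand <- paste0(s, b)
        tail7 <- substr(cand, max(1L, nchar(cand) - 6L), nchar(cand))
        if (!contains_any(tail7, forbidden)) { s <- cand; placed <- TRUE; break }
      }
      if (!placed) stop("cannot pad patch probe")
    }
    s
  }
  while (length(needs) > 0L) {
    s <- ""
    repeat {
      ## residual need net of what the probe under construction already holds
      res <- needs - vapply(names(needs), count_fixed, 0L, str = s)
      res <- sort(res[res > 0L], decreasing = TRUE)
      if (length(res) == 0L) break
      grown <- FALSE
      for (km in names(res)) {
        if (nchar(s) + nchar(km) > L) next
        for (spacer in c("", alphabet)) {
          cand <- paste0(s, spacer, km)
          if (nchar(cand) > L) next
          ctx <- substr(cand, max(1L, nchar(s) - 5L), nchar(cand))
          if (!contains_any(ctx, forbidden)) { s <- cand; grown <- TRUE; break }
        }
        if (grown) break
      }
      if (!grown) break
    }
    if (nchar(s) == 0L) stop("patch construction stalled")
    s <- pad_to(s)
    if (contains_any(s, forbidden)) stop("patch probe contains forbidden 7-mer")
    needs <- needs - vapply(names(needs), count_fixed, 0L, str = s)
    needs <- needs[needs > 0L]
    seqs <- c(seqs, s)
    if (length(seqs) > 10000L) stop("patch construction runaway")
  }
  seqs
}

## k-mers of one sequence, with multiplicity
seq_kmer_table <- function(s, k) {
  n <- nchar(s) - k + 1L
  if (n < 1L) return(table(character(0)))
  table(substring(s, 1:n, k:(k + n - 1L)))
}

#' Design the full probe pool
#'
#' Composes the whole pipeline: de Bruijn backbone generation, window
#' tiling, forbidden-site excision, A/B set split, coverage patching, and
#' initiation-prefix addition, then audits the result.  Excision damages a
#' handful of k-mers around the removed restriction sites, so a small
#' number of windows (bounded by `patch_budget`, 0.1% by default) are
#' replaced by synthetic patch probes packed with the deficient k-mers;
#' donors are windows whose removal leaves every k-mer above threshold.
#' The construction is deterministic.
#'
#' @param spec A [pool_design_spec()].
#' @return `list(probes = <data.frame>, reports = <list of three
#'   kmer_coverage_report>, excision_log = <data.frame>, n_patched =
#'   <integer>)`.
#' @export
design_pool <- function(spec = pool_design_spec()) {
  backbone <- generate_de_bruijn(spec$order, spec$alphabet)
  probes <- tile_probes(backbone, spec)
  exc <- excise_forbidden(probes, spec)
  probes <- assign_sets(exc$probes)

  kp <- spec$audit_k_pool; ks <- spec$audit_k_set
  excl_pool <- forbidden_supersets(kp, spec$forbidden_kmers)
  excl_set <- forbidden_supersets(ks, spec$forbidden_kmers)
  budget <- max(1L, floor(spec$patch_budget * spec$probe_count))
  n_patched <- 0L

  for (round in 1:3) {
    cnt9 <- count_kmers(probes$variable_seq, kp)
    selA <- probes$set_label == "A"
    cnt7A <- count_kmers(probes$variable_seq[selA], ks)
    cnt7B <- count_kmers(probes$variable_seq[!selA], ks)
    elig9 <- setdiff(names(cnt9), excl_pool)
    eligS <- setdiff(names(cnt7A), excl_set)
    def9 <- cnt9[elig9][cnt9[elig9] < spec$min_9mer_count]
    defA <- cnt7A[eligS][cnt7A[eligS] < spec$min_7mer_per_set]
    defB <- cnt7B[eligS][cnt7B[eligS] < spec$min_7mer_per_set]
    if (length(def9) == 0L && length(defA) == 0L && length(defB) == 0L) break
    if (round == 3L)
      stop("coverage not restorable within patch budget; deficient k-mers: ",
           paste(utils::head(c(names(def9), names(defA), names(defB)), 20L),
                 collapse = ", "))

    needsA <- spec$min_7mer_per_set - defA
    needsB <- spec$min_7mer_per_set - defB
    needs9 <- spec$min_9mer_count - def9
    ## cheap lower bound on patch demand, before constructing anything
    lb <- ceiling(sum(needs9) / (spec$variable_length - kp + 1L)) +
      ceiling(sum(needsA) / (spec$variable_length - ks + 1L)) +
      ceiling(sum(needsB) / (spec$variable_length - ks + 1L))
    if (n_patched + lb > budget) {
      warning("coverage deficits need at least ", lb,
              " patch probes, beyond the budget of ", budget,
              "; emitting unpatched audits")
      break
    }
    patchA <- if (length(needsA)) build_patch_seqs(needsA, spec$variable_length,
                                                   spec$forbidden_kmers, spec$alphabet) else character(0)
    patchB <- if (length(needsB)) build_patch_seqs(needsB, spec$variable_length,
                                                   spec$forbidden_kmers, spec$alphabet) else character(0)
    patchP <- if (length(needs9)) build_patch_seqs(needs9, spec$variable_length,
                                                   spec$forbidden_kmers, spec$alphabet) else character(0)
    ## pool-scope (9-mer) patches alternate between sets to keep balance
    sets_p <- rep_len(c("A", "B"), length(patchP))
    patch_seq <- c(patchA, patchB, patchP)
    patch_set <- c(rep("A", length(patchA)), rep("B", length(patchB)), sets_p)
    if (n_patched + length(patch_seq) > budget) {
      warning("coverage deficits need ", length(patch_seq),
              " patch probes, beyond the budget of ", budget,
              "; emitting unpatched audits")
      break
    }

    ## credit patch content before choosing donors
    for (s in patch_seq) {
      tb <- seq_kmer_table(s, kp)
      cnt9[names(tb)] <- cnt9[names(tb)] + as.integer(tb)
    }
    for (i in seq_along(patch_seq)) {
      tb <- seq_kmer_table(patch_seq[i], ks)
      if (patch_set[i] == "A") cnt7A[names(tb)] <- cnt7A[names(tb)] + as.integer(tb)
      else cnt7B[names(tb)] <- cnt7B[names(tb)] + as.integer(tb)
    }

    ## choose donor windows (scanned from the pool end) whose removal keeps
    ## every eligible k-mer at or above threshold
    donor_of <- integer(0)
    is_patch <- probes$start < 0L
    cand <- rev(seq_len(nrow(probes)))
    for (i in seq_along(patch_seq)) {
      found <- NA_integer_
      for (j in cand) {
        if (is_patch[j] || j %in% donor_of) next
        if (probes$set_label[j] != patch_set[i]) next
        v <- probes$variable_seq[j]
        t9 <- seq_kmer_table(v, kp)
        keep9 <- names(t9)[!(names(t9) %in% excl_pool)]
        if (any(cnt9[keep9] - as.integer(t9[keep9]) < spec$min_9mer_count)) next
        t7 <- seq_kmer_table(v, ks)
        cnt7 <- if (patch_set[i] == "A") cnt7A else cnt7B
        keep7 <- names(t7)[!(names(t7) %in% excl_set)]
        if (any(cnt7[keep7] - as.integer(t7[keep7]) < spec$min_7mer_per_set)) next
        found <- j; break
      }
      if (is.na(found)) stop("no safe donor window for patch probe")
      ## debit the donor
      v <- probes$variable_seq[found]
      t9 <- seq_kmer_table(v, kp); cnt9[names(t9)] <- cnt9[names(t9)] - as.integer(t9)
      t7 <- seq_kmer_table(v, ks)
      if (patch_set[i] == "A") cnt7A[names(t7)] <- cnt7A[names(t7)] - as.integer(t7)
      else cnt7B[names(t7)] <- cnt7B[names(t7)] - as.integer(t7)
      donor_of <- c(donor_of, found)
      n_patched <- n_patched + 1L
      probes$variable_seq[found] <- patch_seq[i]
      probes$start[found] <- -1L
      probes$probe_id[found] <- sprintf("patch%04d", n_patched)
    }
  }

  probes <- add_initiation_prefix(probes, spec)
  reports <- list(
    pool_9mer = verify_coverage(probes, kp, "pool", spec$min_9mer_count, excl_pool),
    setA_7mer = verify_coverage(probes, ks, "setA", spec$min_7mer_per_set, excl_set),
    setB_7mer = verify_coverage(probes, ks, "setB", spec$min_7mer_per_set, excl_set))
  list(probes = probes, reports = reports, excision_log = exc$log,
       n_patched = n_patched)
}

#' Optional hairpin screen
#'
#' Flags probes whose variable region contains a perfect inverted repeat
#' (stem) of at least `min_stem` bp with a loop of at least `min_loop` nt.
#' The original pool was additionally optimized against secondary
#' structure by an unspecified procedure; this screen is a simple stand-in
#' and is not applied by [design_pool()].
#'
#' @param probes Probe data.frame.
#' @param min_stem Minimum perfect stem length, bp (default 8).
#' @param min_loop Minimum loop length, nt (default 3).
#' @return Logical vector, one flag per probe.
#' @export
flag_hairpins <- function(probes, min_stem = 8L, min_loop = 3L) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(probes$variable_seq, function(v) {
    L <- nchar(v)
    if (L < 2L * min_stem + min_loop) return(FALSE)
    b <- strsplit(v, "")[[1L]]
    for (i in seq_len(L - 2L * min_stem - min_loop + 1L)) {
      stem <- b[i:(i + min_stem - 1L)]
      rc <- paste(rev(comp[stem]), collapse = "")
      rest <- substr(v, i + min_stem + min_loop, L)
      if (nchar(rest) >= min_stem && grepl(rc, rest, fixed = TRUE))
        return(TRUE)
    }
    FALSE
  }, TRUE, USE.NAMES = FALSE)
}
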