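## Seeded generators for every input the pipeline consumes, each returning
## its planted ground truth so downstream stages can be tested for exact
## recovery without external data.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

random_seq <- function(len, gc_content) {
  p <- c((1 - gc_content) / 2, gc_content / 2, gc_content / 2,
         (1 - gc_content) / 2)
  paste(sample(DNA_ALPHABET, len, replace = TRUE, prob = p), collapse = "")
}

## motif-free baseline by rejection sampling
random_seq_without <- function(len, gc_content, motif) {
  repeat {
    s <- random_seq(len, gc_content)
    if (!grepl(motif, s, fixed = TRUE)) return(s)
  }
}

#' Simulate a transcriptome with planted 3'UTR motifs
#'
#' Generates per-gene 3'UTR sequences in which a designated target subset
#' carries the motif at a controlled excess rate: every UTR starts
#' motif-free (rejection sampling), then one motif copy is inserted at a
#' uniform position with probability `spike_rate_targets` for targets and
#' `spike_rate_background` otherwise.  The accompanying count table makes
#' every gene pass the expression filter, so [build_background()] recovers
#' exactly the intended universe.
#'
#' @param n_genes Number of genes (default 1000).
#' @param utr_len_range Min/max UTR length, nt (default 100-300).
#' @param gc_content Background GC fraction (default 0.5).
#' @param target_fraction Fraction of genes designated as targets (default 0.1).
#' @param spike_rate_targets,spike_rate_background Motif insertion
#'   probabilities (defaults 0.4 and 0.15).
#' @param motif The planted 7-mer (DNA alphabet; default GCGCGGG).
#' @param n_samples Columns of the count table (default 3).
#' @param seed RNG seed.
#' @return `list(utrs, targets, counts, truth)`; `truth` records the
#'   parameters, target set and per-gene motif presence.
#' @export
sim_transcriptome <- function(n_genes = 1000L, utr_len_range = c(100L, 300L),
                              gc_content = 0.5, target_fraction = 0.1,
                              spike_rate_targets = 0.4,
                              spike_rate_background = 0.15,
                              motif = "GCGCGGG", n_samples = 3L, seed = 1L) {
  stopifnot(spike_rate_targets >= 0, spike_rate_targets <= 1,
            spike_rate_background >= 0, spike_rate_background <= 1,
            min(utr_len_range) >= nchar(motif))
  with_seed(seed, {
    genes <- sprintf("g%05d", seq_len(n_genes))
    n_t <- round(target_fraction * n_genes)
    targets <- sample(genes, n_t)
    is_target <- genes %in% targets
    lens <- sample(utr_len_range[1]:utr_len_range[2], n_genes, replace = TRUE)
    rate <- ifelse(is_target, spike_rate_targets, spike_rate_background)
    has_motif <- stats::runif(n_genes) < rate
    utr <- character(n_genes)
    for (i in seq_len(n_genes)) {
      s <- random_seq_without(lens[i], gc_content, motif)
      if (has_motif[i]) {
        pos <- sample.int(lens[i] - nchar(motif) + 1L, 1L)
        substr(s, pos, pos + nchar(motif) - 1L) <- motif
      }
      utr[i] <- s
    }
    counts <- matrix(2L + stats::rpois(n_genes * n_samples, 50),
                     nrow = n_genes,
                     dimnames = list(NULL, sprintf("s%d", seq_len(n_samples))))
    list(utrs = data.frame(gene_id = genes, utr_seq = utr,
                           stringsAsFactors = FALSE),
         targets = sort(targets),
         counts = data.frame(gene_id = genes, counts,
                             stringsAsFactors = FALSE),
         truth = list(seed = seed, n_genes = n_genes, motif = motif,
                      target_fraction = target_fraction,
                      spike_rate_targets = spike_rate_targets,
                      spike_rate_background = spike_rate_background,
                      targets = sort(targets),
                      has_motif = stats::setNames(has_motif, genes)))
  })
}

#' Simulate multi-sample promoter peak collections
#'
#' One toy chromosome; TSS placed on a regular grid so their +/- flank
#' windows are disjoint.  Each planted methylated gene receives a peak
#' overlapping its promoter in exactly `k_samples` samples; decoy peaks
#' are placed strictly between promoter windows and never overlap any.
#'
#' @param n_samples Number of ChIP samples (default 9).
#' @param chrom_length Toy chromosome length, bp (default 1e6).
#' @param tss_count Number of genes/TSS (default 50).
#' @param methylated_fraction Fraction of genes planted methylated (default 0.3).
#' @param k_samples Samples carrying the planted peak (default 3).
#' @param flank Promoter half-width matching the caller (default 3000).
#' @param peak_width_range Peak widths, bp (default 500-2000).
#' @param decoy_peaks Decoy peaks per sample (default 20).
#' @param seed RNG seed.
#' @return `list(tss, peaks = <named list of data.frames>, truth)`.
#' @export
sim_peaks <- function(n_samples = 9L, chrom_length = 1e6, tss_count = 50L,
                      methylated_fraction = 0.3, k_samples = 3L,
                      flank = 3000L, peak_width_range = c(500L, 2000L),
                      decoy_peaks = 20L, seed = 1L) {
  stopifnot(k_samples <= n_samples)
  spacing <- floor(chrom_length / (tss_count + 1L))
  if (spacing <= 2L * flank + max(peak_width_range) + 10L)
    stop("promoter windows exceed the toy chromosome")
  with_seed(seed, {
    genes <- sprintf("g%04d", seq_len(tss_count))
    pos <- spacing * seq_len(tss_count)
    tss <- data.frame(gene_id = genes, chrom = "chr1", pos = pos,
                      strand = sample(c("+", "-"), tss_count, replace = TRUE),
                      stringsAsFactors = FALSE)
    meth <- sort(sample(genes, round(methylated_fraction * tss_count)))
    peaks <- stats::setNames(
      lapply(seq_len(n_samples), function(s)
        data.frame(chrom = character(0), start = integer(0), end = integer(0),
                   fdr_p = numeric(0), stringsAsFactors = FALSE)),
      sprintf("s%d", seq_len(n_samples)))
    for (g in meth) {
      tpos <- pos[match(g, genes)]
      in_samples <- sample.int(n_samples, k_samples)
      for (s in in_samples) {
        w <- sample(peak_width_range[1]:peak_width_range[2], 1L)
        ## anywhere overlapping [tpos - flank, tpos + flank)
        start <- tpos - flank + sample.int(2L * flank - 1L, 1L) - w %/% 2L
        start <- max(0L, start)
        peaks[[s]] <- rbind(peaks[[s]],
                            data.frame(chrom = "chr1", start = start,
                                       end = start + w,
                                       fdr_p = stats::runif(1, 0, 0.049),
                                       stringsAsFactors = FALSE))
      }
    }
    ## decoys live in the dead zone between window end and next window start
    gap_starts <- pos + flank + 1L
    gap_len <- spacing - 2L * flank - max(peak_width_range) - 2L
    for (s in seq_len(n_samples)) {
      for (d in seq_len(decoy_peaks)) {
        gi <- sample.int(tss_count, 1L)
        w <- sample(peak_width_range[1]:peak_width_range[2], 1L)
        start <- gap_starts[gi] + sample.int(max(1L, gap_len - w), 1L)
        peaks[[s]] <- rbind(peaks[[s]],
                            data.frame(chrom = "chr1", start = start,
                                       end = start + w,
                                       fdr_p = stats::runif(1, 0, 0.049),
                                       stringsAsFactors = FALSE))
      }
    }
    list(tss = tss, peaks = peaks,
         truth = list(seed = seed, methylated = meth, k_samples = k_samples,
                      flank = flank, n_samples = n_samples))
  })
}

#' Simulate a differential-expression result table
#'
#' Per-gene true log2 effects of `+lfc_effect`, `-lfc_effect` or 0;
#' replicate-level values are the effect plus Gaussian noise, summarized
#' by the observed mean difference and a two-sample t-test, with BH
#' adjustment.
#'
#' @param n_genes Number of genes (default 1000).
#' @param frac_up,frac_down Fractions of planted up/down genes (defaults 0.05).
#' @param lfc_effect Planted absolute log2 fold change (default 2).
#' @param n_reps Replicates per group (default 3).
#' @param noise_sd Replicate noise sd on the log2 scale (default 0.5).
#' @param seed RNG seed.
#' @return `list(table = <data.frame gene_id, log2FoldChange, pvalue,
#'   padj>, truth)`.
#' @export
sim_de_table <- function(n_genes = 1000L, frac_up = 0.05, frac_down = 0.05,
                         lfc_effect = 2, n_reps = 3L, noise_sd = 0.5,
                         seed = 1L) {
  stopifnot(frac_up + frac_down <= 1, n_reps >= 2L)
  with_seed(seed, {
    genes <- sprintf("g%05d", seq_len(n_genes))
    n_up <- round(frac_up * n_genes); n_down <- round(frac_down * n_genes)
    status <- rep("null", n_genes)
    idx <- sample.int(n_genes, n_up + n_down)
    status[idx[seq_len(n_up)]] <- "up"
    status[idx[n_up + seq_len(n_down)]] <- "down"
    true_lfc <- ifelse(status == "up", lfc_effect,
                       ifelse(status == "down", -lfc_effect, 0))
    lfc <- numeric(n_genes); p <- numeric(n_genes)
    for (i in seq_len(n_genes)) {
      a <- stats::rnorm(n_reps, 0, noise_sd)
      b <- stats::rnorm(n_reps, true_lfc[i], noise_sd)
      lfc[i] <- mean(b) - mean(a)
      p[i] <- stats::t.test(b, a)$p.value
    }
    list(table = data.frame(gene_id = genes, log2FoldChange = lfc,
                            pvalue = p, padj = bh_adjust(p),
                            stringsAsFactors = FALSE),
         truth = list(seed = seed, up = genes[status == "up"],
                      down = genes[status == "down"],
                      lfc_effect = lfc_effect, noise_sd = noise_sd))
  })
}

#' Simulate a fluorescence-polarization titration
#'
#' Closed-form one-site values on a concentration grid plus Gaussian
#' noise.  Defaults mirror the study's assay: 0-1000 nM protein and a
#' dissociation constant of 47 nM.
#'
#' @param kd,fp0,fpmax True parameters (defaults 47 nM, 60, 160).
#' @param conc_grid Concentration grid, nM.
#' @param noise_sd Gaussian noise sd on FP units (default 0).
#' @param n_replicates Replicates per concentration (default 1).
#' @param seed RNG seed.
#' @return `list(data = <data.frame conc_nM, fp>, truth)`.
#' @export
sim_fp <- function(kd = 47, fp0 = 60, fpmax = 160,
                   conc_grid = c(0, 5, 10, 25, 50, 100, 250, 500, 1000),
                   noise_sd = 0, n_replicates = 1L, seed = 1L) {
  if (length(conc_grid) == 0L) stop("empty concentration grid")
  with_seed(seed, {
    conc <- rep(conc_grid, each = n_replicates)
    fp <- fp_one_site(conc, kd, fp0, fpmax) +
      stats::rnorm(length(conc), 0, noise_sd)
    list(data = data.frame(conc_nM = conc, fp = fp),
         truth = list(seed = seed, kd = kd, fp0 = fp0, fpmax = fpmax,
                      noise_sd = noise_sd))
  })
}

#' Simulate a metabolite feature table
#'
#' QC replicates are built with exact per-feature coefficients of
#' variation (a fixed unit-mean pattern rescaled to the requested CV), so
#' the 25% filter has known pass/fail truth.  Group samples start from the
#' feature-wise QC median (the PQN reference), receive the planted fold
#' change on effect features (knockdown group), multiplicative lognormal
#' noise of sd `group_noise_sd`, and finally a per-sample dilution factor
#' -- so with `group_noise_sd = 0` PQN recovers the dilution factors
#' exactly.
#'
#' @param n_features Number of features (default 200).
#' @param n_per_group Samples per biological group (default 5).
#' @param n_qc QC injections (default 5).
#' @param dilution_factors Per-sample dilution multipliers, recycled over
#'   the `2 * n_per_group` group samples (default `c(0.5, 1, 2, 4)`).
#' @param frac_effect Fraction of features with a planted group effect
#'   (default 0.1).
#' @param fold_change Linear fold change on effect features (default 2).
#' @param high_cv_fraction Fraction of features given QC CV `high_cv`
#'   (default 0.2); the rest get `low_cv`.
#' @param low_cv,high_cv The two exact QC CV levels (defaults 0.05, 0.30).
#' @param group_noise_sd Lognormal sdlog of group-sample noise (default 0.05).
#' @param seed RNG seed.
#' @return `list(table = <metabolite_table>, truth)`.
#' @export
sim_metabolites <- function(n_features = 200L, n_per_group = 5L, n_qc = 5L,
                            dilution_factors = c(0.5, 1, 2, 4),
                            frac_effect = 0.1, fold_change = 2,
                            high_cv_fraction = 0.2, low_cv = 0.05,
                            high_cv = 0.30, group_noise_sd = 0.05,
                            seed = 1L) {
  stopifnot(n_qc >= 2L, n_per_group >= 2L, all(dilution_factors > 0))
  with_seed(seed, {
    feats <- sprintf("f%04d", seq_len(n_features))
    base <- stats::rlnorm(n_features, meanlog = log(1e4), sdlog = 1)
    high <- seq_len(n_features) %in%
      sample.int(n_features, round(high_cv_fraction * n_features))
    cv <- ifelse(high, high_cv, low_cv)
    ## unit-mean pattern with nonzero sd, rescaled to the exact CV
    pat <- seq_len(n_qc) - mean(seq_len(n_qc))
    pat <- pat / sqrt(sum(pat^2) / (n_qc - 1L))        # mean 0, sd 1
    qc <- t(vapply(seq_len(n_features),
                   function(i) base[i] * (1 + cv[i] * pat),
                   numeric(n_qc)))
    if (any(qc <= 0)) stop("QC CV too large for the positive-value pattern")

    eff <- sort(sample(feats, round(frac_effect * n_features)))
    is_eff <- feats %in% eff
    ref <- apply(qc, 1L, stats::median)                # = base for odd n_qc
    ns <- 2L * n_per_group
    dil <- rep_len(dilution_factors, ns)
    grp <- rep(c("control", "knockdown"), each = n_per_group)
    gm <- matrix(0, n_features, ns)
    for (j in seq_len(ns)) {
      mu <- ref * ifelse(is_eff & grp[j] == "knockdown", fold_change, 1)
      noise <- if (group_noise_sd > 0)
        stats::rlnorm(n_features, 0, group_noise_sd) else 1
      gm[, j] <- mu * noise * dil[j]
    }
    mat <- cbind(qc, gm)
    colnames(mat) <- c(sprintf("QC%d", seq_len(n_qc)),
                       sprintf("%s%d", grp, rep(seq_len(n_per_group), 2L)))
    rownames(mat) <- feats
    roles <- c(rep("QC", n_qc), grp)
    list(table = metabolite_table(mat, roles),
         truth = list(seed = seed, effect_features = eff,
                      fold_change = fold_change,
                      dilution_factors = stats::setNames(dil, colnames(mat)[-seq_len(n_qc)]),
                      qc_cv = stats::setNames(cv, feats),
                      high_cv_features = feats[high]))
  })
}

#' Simulate probe hybridization intensities
#'
#' Lognormal baseline intensities; probes whose sequence contains the
#' spiked 7-mer are multiplied by `effect_multiplier`.
#'
#' @param pool Probe data.frame (from [design_pool()]) or named character
#'   vector of sequences.
#' @param spiked_kmer The high-affinity 7-mer (default GCGCGGG).
#' @param effect_multiplier Intensity multiplier for spiked probes (default 10).
#' @param noise_sd Lognormal sdlog of multiplicative noise (default 0.25).
#' @param seed RNG seed.
#' @return `list(table = <data.frame probe_id, set_label, intensity>, truth)`.
#' @export
sim_intensities <- function(pool, spiked_kmer = "GCGCGGG",
                            effect_multiplier = 10, noise_sd = 0.25,
                            seed = 1L) {
  stopifnot(nchar(spiked_kmer) == 7L)
  if (is.data.frame(pool)) {
    ids <- pool$probe_id
    sets <- if ("set_label" %in% names(pool)) pool$set_label
            else rep_len(c("A", "B"), nrow(pool))
    seqs <- if ("variable_seq" %in% names(pool)) pool$variable_seq else pool$rna_seq
  } else {
    ids <- names(pool); seqs <- unname(pool)
    sets <- rep_len(c("A", "B"), length(pool))
  }
  km <- rna_to_dna(spiked_kmer)
  has <- grepl(km, rna_to_dna(seqs), fixed = TRUE)
  if (!any(has)) warning("spiked k-mer absent from the pool")
  with_seed(seed, {
    base <- stats::rlnorm(length(seqs), meanlog = log(100), sdlog = 0.5)
    intensity <- base * ifelse(has, effect_multiplier, 1) *
      stats::rlnorm(length(seqs), 0, noise_sd)
    list(table = data.frame(probe_id = ids, set_label = sets,
                            intensity = intensity, stringsAsFactors = FALSE),
         truth = list(seed = seed, spiked_kmer = dna_to_rna(spiked_kmer),
                      effect_multiplier = effect_multiplier,
                      spiked_probes = ids[has]))
  })
}
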