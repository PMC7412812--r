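test_that("tiling spreads windows deterministically with exact endpoints", {
  spec <- pool_design_spec(order = 2L, probe_count = 3L, variable_length = 5L,
                           max_rna_length = 11L, min_9mer_count = 1L,
                           min_7mer_per_set = 1L, audit_k_pool = 2L,
                           audit_k_set = 2L)
  seqs <- "ACGTACGTACGT"     # length 12
  p <- tile_probes(seqs, spec)
  expect_equal(p$start, c(0L, 3L, 7L))
  expect_equal(p$variable_seq, c("ACGTA", "TACGT", "TACGT"))
  expect_equal(tile_probes(seqs, spec)$start, p$start)  # deterministic
})

test_that("single-window tiling returns the sequence prefix", {
  spec <- pool_design_spec(order = 2L, probe_count = 1L, variable_length = 5L,
                           max_rna_length = 11L, min_9mer_count = 1L,
                           min_7mer_per_set = 1L, audit_k_pool = 2L,
                           audit_k_set = 2L)
  p <- tile_probes("ACGTACGT", spec)
  expect_equal(nrow(p), 1L)
  expect_equal(p$variable_seq, "ACGTA")
})

test_that("infeasible tilings error", {
  spec <- pool_design_spec(order = 2L, probe_count = 50L, variable_length = 5L,
                           max_rna_length = 11L, min_9mer_count = 1L,
                           min_7mer_per_set = 1L, audit_k_pool = 2L,
                           audit_k_set = 2L)
  expect_error(tile_probes("ACGTACGTAC", spec), "infeasible")
  expect_error(tile_probes("ACG", spec), "shorter")
})

test_that("steps take two adjacent values spread evenly", {
  spec <- pool_design_spec(order = 5L, probe_count = 100L, variable_length = 15L,
                           max_rna_length = 21L, min_9mer_count = 1L,
                           min_7mer_per_set = 1L, audit_k_pool = 5L,
                           audit_k_set = 3L)
  s <- generate_de_bruijn(5)
  p <- tile_probes(s, spec)
  st <- diff(p$start)
  expect_lte(diff(range(st)), 1L)
  expect_equal(p$start[1], 0L)
  expect_equal(p$start[100] + 15L, nchar(s))
})

test_that("forbidden 7-mers are excised by minimal logged substitutions", {
  spec <- toy_pool_spec()
  probes <- data.frame(probe_id = c("p1", "p2"),
                       set_label = NA_character_, start = c(0L, 15L),
                       variable_seq = c("AAGCTCTTCAAACGT", "ACGTACGTACGTACG"),
                       stringsAsFactors = FALSE)
  r <- excise_forbidden(probes, spec)
  for (f in spec$forbidden_kmers) {
    expect_equal(oracle_count_pattern(r$probes$variable_seq[1], f), 0L)
    expect_equal(oracle_count_pattern(r$probes$variable_seq[2], f), 0L)
  }
  expect_equal(nrow(r$log), 1L)
  expect_equal(r$log$position, 6L)         # center base of the occurrence
  expect_equal(r$log$old, "C")
  expect_equal(r$probes$variable_seq[2], probes$variable_seq[2])  # untouched
})

test_that("set assignment alternates and balances", {
  p4 <- data.frame(probe_id = paste0("p", 1:4), set_label = NA, start = 0:3,
                   variable_seq = "ACGT")
  expect_equal(assign_sets(p4)$set_label, c("A", "B", "A", "B"))
  p1 <- p4[1, ]
  expect_equal(assign_sets(p1)$set_label, "A")
})

test_that("initiation prefix transcribes and respects the length bound", {
  spec <- toy_pool_spec()
  probes <- data.frame(probe_id = "p1", set_label = "A", start = 0L,
                       variable_seq = "GCGCGGGTTTTTTTT", stringsAsFactors = FALSE)
  out <- add_initiation_prefix(probes, spec)
  expect_equal(out$rna_seq, "AGAGCGCGGGUUUUUUUU")
  expect_equal(nchar(out$rna_seq), 3L + spec$variable_length)
  expect_lte(nchar(out$rna_seq), spec$max_rna_length)
})

test_that("coverage audit matches a hand count on a tiny pool", {
  probes <- data.frame(probe_id = c("p1", "p2"), set_label = c("A", "B"),
                       start = c(0L, 1L), variable_seq = c("ACGT", "ACGT"),
                       stringsAsFactors = FALSE)
  rep <- verify_coverage(probes, k = 2L, scope = "pool", threshold = 2L)
  expect_equal(rep$min_count, 0L)          # e.g. AA never occurs
  expect_false(rep$passed)
  expect_equal(rep$total_kmers_counted, 6) # 3 windows x 2 probes
  expect_error(verify_coverage(probes, k = 5L, scope = "pool", threshold = 1L),
               "exceeds")
})

test_that("coverage audit agrees with the independent dictionary oracle", {
  probes <- assign_sets(tile_probes(generate_de_bruijn(6),
                                    pool_design_spec(order = 6L,
                                                     probe_count = 300L,
                                                     variable_length = 20L,
                                                     max_rna_length = 26L,
                                                     min_9mer_count = 1L,
                                                     min_7mer_per_set = 1L,
                                                     audit_k_pool = 6L,
                                                     audit_k_set = 4L)))
  for (k in c(2L, 4L, 6L)) {
    rep <- verify_coverage(probes, k, "pool", threshold = 1L)
    counts <- oracle_kmer_counts(probes$variable_seq, k)
    expect_equal(rep$min_count, min(counts))
    rep_a <- verify_coverage(probes, k, "setA", threshold = 1L)
    counts_a <- oracle_kmer_counts(probes$variable_seq[probes$set_label == "A"], k)
    expect_equal(rep_a$min_count, min(counts_a))
  }
})

test_that("forbidden_supersets enumerates exactly the containing k-mers", {
  sup <- forbidden_supersets(9L, c("GCTCTTC", "CGAGAAG"))
  expect_true(all(grepl("GCTCTTC", sup, fixed = TRUE) |
                    grepl("CGAGAAG", sup, fixed = TRUE)))
  expect_equal(length(sup), length(unique(sup)))
  # brute-force check of the count: offsets 0..2, 16 flanking fills each
  brute <- unique(unlist(lapply(c("GCTCTTC", "CGAGAAG"), function(f) {
    out <- character(0)
    for (off in 0:2) {
      fills <- expand.grid(rep(list(c("A", "C", "G", "T")), 2))
      for (r in seq_len(nrow(fills))) {
        fl <- paste(unlist(fills[r, ]), collapse = "")
        out <- c(out, paste0(substr(fl, 1, off), f,
                             substr(fl, off + 1, 2)))
      }
    }
    out
  })))
  expect_setequal(sup, brute)
})

test_that("toy pool design passes its audits and matches the oracle", {
  d <- design_pool(toy_pool_spec())
  expect_equal(nrow(d$probes), 100L)
  expect_true(all(vapply(d$reports, `[[`, TRUE, "passed")))
  # forbidden 7-mers absent everywhere (exhaustive scan)
  for (f in c("GCTCTTC", "CGAGAAG"))
    expect_equal(sum(vapply(d$probes$variable_seq, oracle_count_pattern, 0L,
                            pat = f)), 0L)
  # audit equivalence with the naive counter
  counts <- oracle_kmer_counts(d$probes$variable_seq, 4L)
  expect_equal(d$reports$pool_9mer$min_count, min(counts))
  # every RNA record starts with an allowed trinucleotide
  expect_true(all(substr(d$probes$rna_seq, 1, 3) %in% c("AGA", "AGG")))
})

test_that("a 1-probe design reports failed audits honestly instead of erroring", {
  spec <- pool_design_spec(order = 5L, probe_count = 1L, variable_length = 15L,
                           max_rna_length = 21L, min_9mer_count = 16L,
                           min_7mer_per_set = 1L, audit_k_pool = 9L,
                           audit_k_set = 3L)
  expect_warning(d <- design_pool(spec), "budget")
  expect_equal(nrow(d$probes), 1L)
  expect_false(d$reports$pool_9mer$passed)
})

test_that("window containment: every audited k-mer occurrence lies in a window", {
  s <- generate_de_bruijn(6)
  spec <- pool_design_spec(order = 6L, probe_count = 500L,
                           variable_length = 20L, max_rna_length = 26L,
                           min_9mer_count = 1L, min_7mer_per_set = 1L,
                           audit_k_pool = 6L, audit_k_set = 4L)
  p <- tile_probes(s, spec)
  k <- 6L
  covered <- logical(nchar(s) - k + 1L)
  for (i in seq_len(nrow(p))) {
    a <- p$start[i] + 1L
    b <- p$start[i] + spec$variable_length - k + 1L
    covered[a:b] <- TRUE
  }
  expect_true(all(covered))
})

test_that("design is byte-identical across runs and FASTA round-trips", {
  d1 <- design_pool(toy_pool_spec())
  d2 <- design_pool(toy_pool_spec())
  expect_identical(d1$probes, d2$probes)
  f <- tempfile(fileext = ".fasta")
  write_pool_fasta(d1$probes, f)
  back <- read_pool_fasta(f)
  expect_equal(back$rna_seq, d1$probes$rna_seq)
  expect_equal(back$set_label, d1$probes$set_label)
  unlink(f)
})

test_that("hairpin screen flags a planted perfect stem", {
  probes <- data.frame(variable_seq = c(
    paste0("GCGCGCGC", "AAATTT", "GCGCGCGC", "AAAAA"),   # stem is own RC
    paste0("ACGTAAGG", "TTTAAA", "CCTTACGT", "CCCCC"),   # planted RC stem
    strrep("A", 27)), stringsAsFactors = FALSE)
  fl <- flag_hairpins(probes, min_stem = 8L)
  expect_true(fl[2])
  expect_false(fl[3])
})
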