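test_that("promoter windows are symmetric, clipped and per-TSS", {
  tss <- data.frame(gene_id = c("g1", "g2", "g3", "g3"),
                    chrom = "chr1", pos = c(5000L, 100L, 9000L, 20000L),
                    strand = c("+", "-", "+", "+"))
  pr <- make_promoters(tss)
  expect_equal(pr$start[1], 2000L)
  expect_equal(pr$end[1], 8000L)
  expect_equal(pr$start[2], 0L)            # clipped at the origin
  expect_equal(pr$end[2], 3100L)
  expect_equal(sum(pr$gene_id == "g3"), 2L)
})

test_that("union overlap never double-counts overlapping peaks", {
  w <- list(start = 0L, end = 100L)
  expect_equal(peak_overlap(w, data.frame(start = 50L, end = 200L)), 50L)
  expect_equal(peak_overlap(w, data.frame(start = c(10L, 20L),
                                          end = c(30L, 60L))), 50L)
  expect_equal(peak_overlap(w, data.frame(start = integer(0),
                                          end = integer(0))), 0L)
  expect_error(peak_overlap(list(start = 5L, end = 5L),
                            data.frame(start = 1L, end = 2L)), "malformed")
})

test_that("union overlap equals the per-base oracle on random instances", {
  set.seed(99)
  for (i in 1:60) {
    clen <- 1000L
    n <- sample(1:8, 1)
    starts <- sample(0:(clen - 10L), n)
    ends <- pmin(clen, starts + sample(5:200, n, replace = TRUE))
    ws <- sample(0:(clen - 50L), 1)
    we <- ws + sample(20:300, 1)
    got <- peak_overlap(list(start = ws, end = we),
                        data.frame(start = starts, end = ends))
    want <- oracle_overlap_bp(ws, we, starts, ends, clen + 400L)
    expect_equal(got, want)
  }
})

toy_caller_fixture <- function() {
  tss <- data.frame(gene_id = c("gA", "gB", "gC"), chrom = "chr1",
                    pos = c(10000L, 30000L, 50000L), strand = "+")
  promoters <- make_promoters(tss)
  peak_at <- function(pos, w = 200L)
    data.frame(chrom = "chr1", start = pos, end = pos + w)
  list(tss = tss, promoters = promoters, peak_at = peak_at)
}

test_that("the >= 3-sample consensus rule decides methylation", {
  fx <- toy_caller_fixture()
  peaks <- list(s1 = fx$peak_at(10000L), s2 = fx$peak_at(9000L),
                s3 = fx$peak_at(11000L), s4 = fx$peak_at(30000L),
                s5 = fx$peak_at(30100L))
  calls <- call_methylation(fx$promoters, peaks)
  expect_true(calls$methylated[calls$gene_id == "gA"])     # 3 samples
  expect_equal(calls$n_samples_with_peak[calls$gene_id == "gA"], 3L)
  expect_false(calls$methylated[calls$gene_id == "gB"])    # 2 < 3
  expect_false(calls$methylated[calls$gene_id == "gC"])    # none
})

test_that("the consensus rule applies per window, any window qualifies", {
  tss <- data.frame(gene_id = "g1", chrom = "chr1",
                    pos = c(10000L, 50000L), strand = "+")
  promoters <- make_promoters(tss)
  peaks <- list(s1 = data.frame(chrom = "chr1", start = 10000L, end = 10100L),
                s2 = data.frame(chrom = "chr1", start = 10000L, end = 10100L),
                s3 = data.frame(chrom = "chr1", start = 50000L, end = 50100L),
                s4 = data.frame(chrom = "chr1", start = 50000L, end = 50100L),
                s5 = data.frame(chrom = "chr1", start = 50000L, end = 50100L))
  calls <- call_methylation(promoters, peaks)
  expect_true(calls$methylated)            # window 2 hit in s3, s4, s5
  expect_equal(calls$n_samples_with_peak, 3L)
})

test_that("FDR filtering and the overlap floor gate the calls", {
  fx <- toy_caller_fixture()
  good <- cbind(fx$peak_at(10000L), fdr_p = 0.01)
  bad <- cbind(fx$peak_at(10000L), fdr_p = 0.2)
  calls <- call_methylation(fx$promoters,
                            list(s1 = good, s2 = good, s3 = bad),
                            min_samples = 3L)
  expect_false(calls$methylated[calls$gene_id == "gA"])    # s3 peak removed
  calls2 <- call_methylation(fx$promoters,
                             list(s1 = good, s2 = good,
                                  s3 = cbind(fx$peak_at(10000L), fdr_p = 0.04)))
  expect_true(calls2$methylated[calls2$gene_id == "gA"])
  expect_warning(call_methylation(fx$promoters, list(s1 = good),
                                  min_samples = 3L), "exceeds")
})

test_that("calls are invariant to peak order and to splitting a peak", {
  fx <- toy_caller_fixture()
  whole <- data.frame(chrom = "chr1", start = 9000L, end = 11000L)
  split <- data.frame(chrom = "chr1", start = c(10000L, 9000L),
                      end = c(11000L, 10000L))       # abutting, out of order
  p1 <- list(s1 = whole, s2 = whole, s3 = whole)
  p2 <- list(s1 = split, s2 = split, s3 = split)
  expect_equal(call_methylation(fx$promoters, p1),
               call_methylation(fx$promoters, p2))
})

test_that("adding a peak never revokes a methylation call", {
  fx <- toy_caller_fixture()
  base <- list(s1 = fx$peak_at(10000L), s2 = fx$peak_at(10000L),
               s3 = fx$peak_at(10000L))
  before <- call_methylation(fx$promoters, base)
  base$s1 <- rbind(base$s1, fx$peak_at(30000L))
  after <- call_methylation(fx$promoters, base)
  expect_true(all(after$methylated >= before$methylated))
})

test_that("planted-peak simulations are recalled at k >= 3 and not below", {
  sim3 <- sim_peaks(tss_count = 30L, k_samples = 3L, seed = 8)
  calls3 <- call_methylation(make_promoters(sim3$tss), sim3$peaks)
  called <- calls3$gene_id[calls3$methylated]
  expect_setequal(called, sim3$truth$methylated)          # recall 1, FPR 0

  sim2 <- sim_peaks(tss_count = 30L, k_samples = 2L, seed = 8)
  calls2 <- call_methylation(make_promoters(sim2$tss), sim2$peaks)
  expect_equal(sum(calls2$methylated), 0L)
})

test_that("caller agrees with a per-base oracle on randomized instances", {
  set.seed(123)
  for (rep in 1:40) {
    clen <- 100000L
    n_genes <- sample(2:4, 1)
    n_samp <- 4L
    flank <- 500L
    tss <- data.frame(gene_id = sprintf("g%d", seq_len(n_genes)),
                      chrom = "chr1",
                      pos = sample(1000:(clen - 1000L), n_genes),
                      strand = "+")
    promoters <- make_promoters(tss, flank = flank)
    peaks <- lapply(seq_len(n_samp), function(s) {
      n <- sample(0:6, 1)
      if (n == 0)
        return(data.frame(chrom = character(0), start = integer(0),
                          end = integer(0)))
      st <- sample(0:(clen - 300L), n)
      data.frame(chrom = "chr1", start = st,
                 end = st + sample(50:2000, n, replace = TRUE))
    })
    names(peaks) <- sprintf("s%d", seq_len(n_samp))
    calls <- call_methylation(promoters, peaks, min_samples = 2L)
    for (g in tss$gene_id) {
      wi <- which(promoters$gene_id == g)
      per_window_n <- vapply(wi, function(w) {
        sum(vapply(peaks, function(pk) {
          if (nrow(pk) == 0L) return(FALSE)
          oracle_overlap_bp(promoters$start[w], promoters$end[w],
                            pk$start, pk$end, clen + 3000L) >= 1L
        }, TRUE))
      }, 0L)
      expect_equal(calls$methylated[calls$gene_id == g],
                   max(per_window_n) >= 2L)
      expect_equal(calls$n_samples_with_peak[calls$gene_id == g],
                   max(per_window_n))
    }
  }
})
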