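#' One-site specific binding model
#'
#' Fluorescence polarization as a function of protein concentration under
#' the single-site law `FP(c) = fp0 + (fpmax - fp0) * c / (kd + c)`:
#' baseline at zero protein, half-saturation at `c = kd`, plateau `fpmax`.
#'
#' @param conc Protein concentration(s), nM, non-negative.
#' @param kd Equilibrium dissociation constant, nM, positive.
#' @param fp0 Baseline polarization (arbitrary units).
#' @param fpmax Saturation polarization.
#' @return FP value(s).
#' @export
fp_one_site <- function(conc, kd, fp0, fpmax) {
  if (kd <= 0) stop("kd must be positive")
  if (any(conc < 0)) stop("concentrations must be non-negative")
  fp0 + (fpmax - fp0) * conc / (kd + conc)
}

#' Fit the one-site binding model to a titration
#'
#' Nonlinear least squares (Levenberg-Marquardt) on the closed-form
#' one-site law, initialized from the data (baseline = minimum reading,
#' plateau = maximum, kd = concentration nearest mid-saturation) with a
#' positivity bound on kd.  A case-resampling bootstrap yields a 95%
#' confidence interval for kd.
#'
#' @param data data.frame with `conc_nM` and `fp` (at least 5 points,
#'   including concentrations below and above apparent half-saturation),
#'   or a list with `concentrations` and `fp_values`.
#' @param n_boot Bootstrap replicates for the kd CI (default 1000; 0
#'   disables the bootstrap).
#' @param seed Seed for the bootstrap resampler.
#' @return Object of class `fp_fit`: `kd`, `fp0`, `fpmax`,
#'   `residual_sse`, `kd_ci` (NULL when `n_boot = 0`), `n_points`.
#' @export
fit_fp <- function(data, n_boot = 1000L, seed = 1L) {
  if (is.list(data) && !is.data.frame(data) &&
      all(c("concentrations", "fp_values") %in% names(data)))
    data <- data.frame(conc_nM = data$concentrations, fp = data$fp_values)
  stopifnot(all(c("conc_nM", "fp") %in% names(data)))
  if (nrow(data) < 5L) stop("need at least 5 titration points")
  if (any(data$conc_nM < 0)) stop("negative concentrations")
  if (stats::sd(data$fp) == 0) stop("degenerate flat titration data")

  fp0_0 <- min(data$fp); fpmax_0 <- max(data$fp)
  mid <- (fp0_0 + fpmax_0) / 2
  pos <- data$conc_nM[data$conc_nM > 0]
  kd_0 <- if (length(pos)) pos[which.min(abs(data$fp[data$conc_nM > 0] - mid))]
          else 1
  if (kd_0 <= 0) kd_0 <- 1

  fit_once <- function(d) {
    minpack.lm::nlsLM(fp ~ fp0 + (fpmax - fp0) * conc_nM / (kd + conc_nM),
                      data = d,
                      start = list(fp0 = fp0_0, fpmax = fpmax_0, kd = kd_0),
                      lower = c(fp0 = -Inf, fpmax = -Inf, kd = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  fit <- tryCatch(fit_once(data),
                  error = function(e) stop("one-site fit did not converge: ",
                                           conditionMessage(e)))
  cf <- stats::coef(fit)
  sse <- sum(stats::resid(fit)^2)

  kd_ci <- NULL
  if (n_boot > 0L) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    kds <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
      d <- data[sample.int(nrow(data), replace = TRUE), , drop = FALSE]
      if (length(unique(d$conc_nM)) < 3L || stats::sd(d$fp) == 0) next
      f <- tryCatch(fit_once(d), error = function(e) NULL)
      if (!is.null(f)) kds[b] <- stats::coef(f)[["kd"]]
    }
    kds <- kds[is.finite(kds)]
    if (length(kds) >= 10L)
      kd_ci <- unname(stats::quantile(kds, c(0.025, 0.975)))
  }
  structure(list(kd = unname(cf[["kd"]]), fp0 = unname(cf[["fp0"]]),
                 fpmax = unname(cf[["fpmax"]]), residual_sse = sse,
                 kd_ci = kd_ci, n_points = nrow(data)),
            class = "fp_fit")
}

#' @export
print.fp_fit <- function(x, ...) {
  cat(sprintf("one-site FP fit: kd = %.3g nM (fp0 = %.3g, fpmax = %.3g, SSE = %.3g)\n",
              x$kd, x$fp0, x$fpmax, x$residual_sse))
  if (!is.null(x$kd_ci))
    cat(sprintf("  bootstrap 95%% CI for kd: [%.3g, %.3g] nM\n",
                x$kd_ci[1], x$kd_ci[2]))
  invisible(x)
}

#' Metabolite feature table
#'
#' Container for a features x samples intensity matrix with sample roles
#' (`QC`, `control`, `knockdown`).
#'
#' @param mat Numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns, non-negative intensities.
#' @param roles Character vector, one role per column.
#' @return Object of class `metabolite_table`.
#' @export
metabolite_table <- function(mat, roles) {
  stopifnot(is.matrix(mat), ncol(mat) == length(roles),
            all(roles %in% c("QC", "control", "knockdown")))
  if (any(mat < 0)) stop("negative intensities")
  if (is.null(rownames(mat))) rownames(mat) <- sprintf("f%04d", seq_len(nrow(mat)))
  structure(list(mat = mat, roles = roles), class = "metabolite_table")
}

#' Probabilistic quotient normalization
#'
#' Scales each sample by the median, over features, of its ratio to a
#' reference spectrum (feature-wise median of the QC samples by default),
#' removing per-sample dilution.  Features that are zero or missing in
#' either the sample or the reference are excluded from the quotient.
#'
#' @param table A [metabolite_table()].
#' @param reference `"median_of_QC"` (default) or `"median_of_all"`.
#' @return `list(table = <normalized metabolite_table>, quotients =
#'   <named numeric>)`.
#' @export
pqn_normalize <- function(table, reference = c("median_of_QC", "median_of_all")) {
  reference <- match.arg(reference)
  m <- table$mat
  ref_cols <- if (reference == "median_of_QC") which(table$roles == "QC")
              else seq_len(ncol(m))
  if (length(ref_cols) == 0L) stop("no QC samples for the reference spectrum")
  ref <- apply(m[, ref_cols, drop = FALSE], 1L, stats::median)
  q <- vapply(seq_len(ncol(m)), function(j) {
    r <- m[, j] / ref
    r <- r[is.finite(r) & r > 0]
    if (length(r) == 0L) stop("no valid features for sample quotient ", j)
    stats::median(r)
  }, 0)
  names(q) <- colnames(m)
  norm <- sweep(m, 2L, q, "/")
  list(table = metabolite_table(norm, table$roles), quotients = q)
}

#' QC coefficient-of-variation filter
#'
#' Keeps features whose CV (sd/mean) over the QC samples is strictly below
#' `max_cv` (default 25%); features with zero QC mean are dropped with a
#' warning.
#'
#' @param table A [metabolite_table()].
#' @param max_cv Strict upper bound on the QC CV (default 0.25).
#' @return `list(table = <filtered metabolite_table>, dropped = <character>,
#'   cv = <named numeric>)`.
#' @export
qc_cv_filter <- function(table, max_cv = 0.25) {
  qc <- which(table$roles == "QC")
  if (length(qc) < 2L) stop("need at least 2 QC samples")
  mu <- rowMeans(table$mat[, qc, drop = FALSE])
  sdv <- apply(table$mat[, qc, drop = FALSE], 1L, stats::sd)
  cv <- sdv / mu
  zero <- mu == 0
  if (any(zero)) warning(sum(zero), " feature(s) with zero QC mean dropped")
  keep <- !zero & cv < max_cv
  list(table = metabolite_table(table$mat[keep, , drop = FALSE], table$roles),
       dropped = rownames(table$mat)[!keep],
       cv = cv)
}

#' Volcano selection of significant metabolites
#'
#' Per feature: the log2 fold change between knockdown and control group
#' means (difference of group means of log2 intensities) and a Welch
#' two-sample t-test on log2 intensities.  Selected features pass both
#' `|log2fc| >= fc_threshold` (default 0.4 on the log2 scale) and
#' `p < alpha` (default 0.05).  Setting `fc_scale = "linear"` reads the
#' threshold as a linear fold change instead.
#'
#' @param table A [metabolite_table()].
#' @param fc_threshold Fold-change gate (default 0.4, log2 scale).
#' @param alpha Significance gate on the t-test p (default 0.05).
#' @param fc_scale `"log2"` (default) or `"linear"`.
#' @return data.frame (`feature`, `log2fc`, `t_p`, `selected`).
#' @export
volcano_select <- function(table, fc_threshold = 0.4, alpha = 0.05,
                           fc_scale = c("log2", "linear")) {
  fc_scale <- match.arg(fc_scale)
  thr <- if (fc_scale == "log2") fc_threshold else log2(fc_threshold)
  kd <- which(table$roles == "knockdown")
  ct <- which(table$roles == "control")
  if (length(kd) < 2L || length(ct) < 2L)
    stop("need at least 2 samples per group")
  lm2 <- log2(table$mat + .Machine$double.eps)
  lfc <- rowMeans(lm2[, kd, drop = FALSE]) - rowMeans(lm2[, ct, drop = FALSE])
  p <- vapply(seq_len(nrow(lm2)), function(i) {
    if (stats::sd(lm2[i, kd]) == 0 && stats::sd(lm2[i, ct]) == 0)
      return(if (lfc[i] == 0) 1 else 0)
    stats::t.test(lm2[i, kd], lm2[i, ct])$p.value
  }, 0)
  data.frame(feature = rownames(table$mat), log2fc = lfc, t_p = p,
             selected = abs(lfc) >= thr & p < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}
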