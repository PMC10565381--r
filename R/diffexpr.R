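# Differential expression: FPKM computation, a negative-binomial Wald test
# (a transparent stand-in for a full DE package, isolated behind one function
# so externally computed DE tables can be injected instead), BH adjustment,
# threshold-based calling, and the clustering/heatmap transform.

#' Compute FPKM from counts
#'
#' `FPKM[g, s] = counts[g, s] / (length_kb[g] * totals[s] / 1e6)` — fragments
#' per kilobase of exon per million mapped fragments. Multiplying back by
#' `length_kb * totals / 1e6` recovers the counts exactly.
#'
#' @param counts Count matrix (genes x samples) or tibble with an id column.
#' @param lengths Named numeric vector of transcript/gene lengths in nt, or a
#'   two-column tibble (`id`, `length`). All lengths must be positive.
#' @param totals Per-sample total mapped fragments; defaults to column sums.
#' @return FPKM in the same container type as `counts`.
#' @export
compute_fpkm <- function(counts, lengths, totals = NULL) {
  tib_in <- is.data.frame(counts)
  m <- as_expr_matrix(counts)
  if (is.data.frame(lengths)) {
    lengths <- setNames(lengths[[2]], as.character(lengths[[1]]))
  }
  if (!is.null(names(lengths))) {
    missing <- setdiff(rownames(m), names(lengths))
    if (length(missing) > 0) {
      abort(sprintf("no length for %d gene(s), e.g. %s", length(missing), missing[1]))
    }
    lengths <- lengths[rownames(m)]
  }
  if (any(lengths <= 0)) abort("transcript lengths must be positive")
  if (is.null(totals)) totals <- colSums(m)
  if (any(totals <= 0)) abort("per-sample totals must be positive")
  fpkm <- sweep(m / (lengths / 1000), 2, totals / 1e6, "/")
  if (tib_in) expr_as_tibble(fpkm) else fpkm
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: the median across genes of the ratio of
#' a sample's counts to the genewise geometric mean, computed over genes with
#' nonzero counts in every sample.
#'
#' @param counts Count matrix or tibble with an id column.
#' @return Named numeric vector of size factors.
#' @export
size_factors <- function(counts) {
  m <- as_expr_matrix(counts)
  keep <- rowSums(m == 0) == 0
  if (!any(keep)) {
    warn("no gene has nonzero counts in all samples; size factors set to 1")
    return(setNames(rep(1, ncol(m)), colnames(m)))
  }
  logm <- log(m[keep, , drop = FALSE])
  loggeo <- rowMeans(logm)
  apply(logm, 2, function(x) exp(median(x - loggeo)))
}

#' Negative-binomial Wald test for two groups
#'
#' Per-gene two-sided Wald test of a group difference under a
#' negative-binomial model with variance `mu + alpha * mu^2`. Counts are
#' divided by size factors; the log2 fold change is
#' `log2((meanB + pc) / (meanA + pc))` on normalized counts (B over A, i.e.
#' treated over control). Dispersion is estimated per gene by method of
#' moments from pooled within-group variances and, by default, moderated by
#' a mean–dispersion trend (per-gene estimates pooled over quantile bins of
#' the mean and interpolated), which shares information across genes the way
#' established DE tools do; the raw per-gene estimate is available with
#' `dispersion = "per-gene"` but is poorly calibrated at small n. Dispersions
#' are floored at 1e-8. Genes with all-zero counts in both groups get
#' `log2FC = 0`, `p = 1`.
#'
#' @param counts Count matrix or tibble; columns are samples.
#' @param groups Two-level factor/character vector along columns; the first
#'   level is the reference (control) group A.
#' @param sf Size factors; computed by [size_factors()] when `NULL`.
#' @param pseudocount Added to normalized group means for the fold change and
#'   the Wald contrast (default 0.5 normalized counts).
#' @param dispersion `"trend"` (default) or `"per-gene"`.
#' @return Tibble with `id`, `base_mean`, `log2FC`, `p`.
#' @export
nb_test <- function(counts, groups, sf = NULL, pseudocount = 0.5,
                    dispersion = c("trend", "per-gene")) {
  dispersion <- match.arg(dispersion)
  m <- as_expr_matrix(counts)
  groups <- as.factor(groups)
  if (length(groups) != ncol(m)) abort("one group label per sample column is required")
  if (nlevels(groups) != 2) abort("nb_test compares exactly two groups")
  if (any(table(groups) < 2)) abort("at least two replicates per group are required")
  if (any(m < 0) || any(m != floor(m))) abort("counts must be nonnegative integers")

  if (is.null(sf)) sf <- size_factors(m)
  nm <- sweep(m, 2, sf, "/")
  A <- nm[, groups == levels(groups)[1], drop = FALSE]
  B <- nm[, groups == levels(groups)[2], drop = FALSE]
  nA <- ncol(A)
  nB <- ncol(B)
  mA <- rowMeans(A)
  mB <- rowMeans(B)
  vA <- apply(A, 1, var)
  vB <- apply(B, 1, var)
  pooled_var <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
  mu <- (mA + mB) / 2

  alpha_gene <- pmax((pooled_var - mu) / pmax(mu, 1e-8)^2, 0)
  alpha <- switch(dispersion,
    "per-gene" = pmax(alpha_gene, 1e-8),
    "trend" = dispersion_trend(alpha_gene, mu)
  )

  pc <- pseudocount
  lfc <- log2((mB + pc) / (mA + pc))
  var_logA <- (mA + alpha * mA^2) / (nA * (mA + pc)^2)
  var_logB <- (mB + alpha * mB^2) / (nB * (mB + pc)^2)
  z <- (log(mB + pc) - log(mA + pc)) / sqrt(var_logA + var_logB)
  p <- 2 * pnorm(-abs(z))

  allzero <- mA == 0 & mB == 0
  lfc[allzero] <- 0
  p[allzero] <- 1

  tibble(
    id = rownames(m) %||% as.character(seq_len(nrow(m))),
    base_mean = unname(mu), log2FC = unname(lfc), p = unname(p)
  )
}

# Mean-dispersion trend: pool per-gene MoM estimates in quantile bins of the
# mean and interpolate linearly; constant extrapolation outside the bin range.
dispersion_trend <- function(alpha_gene, mu, nbins = 20) {
  ok <- mu > 0
  if (sum(ok) < 2 * nbins) {
    return(pmax(
      rep(if (any(ok)) mean(alpha_gene[ok]) else 0, length(mu)),
      1e-8
    ))
  }
  q <- unique(quantile(mu[ok], probs = seq(0, 1, length.out = nbins + 1)))
  if (length(q) < 3) {
    return(pmax(rep(mean(alpha_gene[ok]), length(mu)), 1e-8))
  }
  bin <- cut(mu[ok], q, include.lowest = TRUE)
  ab <- tapply(alpha_gene[ok], bin, mean)
  mids <- tapply(mu[ok], bin, median)
  keep <- !is.na(ab)
  fit <- approx(mids[keep], ab[keep], xout = mu, rule = 2)$y
  pmax(fit, 1e-8)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement, order-preserving
#' with the input. Values outside [0, 1] (or missing) are an error.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    abort("p-values must be in [0, 1] with no missing values")
  }
  p.adjust(p, method = "BH")
}

#' Flag differentially expressed features at fixed thresholds
#'
#' `significant` iff `|log2FC|` is strictly greater than `lfc_threshold` and
#' the BH-adjusted p-value is strictly below `alpha` (both inequalities
#' strict). The conventional thresholds are `lfc_threshold = 2` for lncRNA
#' calling and `1` for mRNA DEG calling, both at `alpha = 0.05`.
#'
#' @param results Tibble with `log2FC` and `p` (and optionally `p_adj`;
#'   computed by [bh_adjust()] when absent).
#' @param lfc_threshold Absolute log2-fold-change threshold (exclusive).
#' @param alpha Adjusted-p threshold (exclusive).
#' @return `results` with `p_adj` and logical `significant` columns.
#' @export
call_de <- function(results, lfc_threshold = 2, alpha = 0.05) {
  stopifnot(lfc_threshold > 0, alpha > 0, alpha < 1)
  check_columns(results, c("log2FC", "p"), "DE results")
  if (!"p_adj" %in% names(results)) {
    results$p_adj <- bh_adjust(results$p)
  }
  results %>%
    mutate(significant = abs(.data$log2FC) > lfc_threshold & .data$p_adj < alpha)
}

#' Transform an FPKM matrix for expression-profile clustering
#'
#' The heatmap-convention transform: `log10(FPKM + 1e-6)` followed by
#' per-row z-scoring (`(x - row mean) / row sd`). Rows that are constant
#' after the log step map to all zeros. Set `zscore = FALSE` to stop after
#' the log step.
#'
#' @param fpkm Nonnegative matrix or tibble with an id column.
#' @param zscore Apply per-row standardization (default `TRUE`).
#' @return Transformed matrix (or tibble, matching the input container).
#' @export
cluster_transform <- function(fpkm, zscore = TRUE) {
  tib_in <- is.data.frame(fpkm)
  m <- as_expr_matrix(fpkm)
  if (any(m < 0)) abort("FPKM values must be nonnegative")
  y <- log10(m + 1e-6)
  if (zscore) {
    mu <- rowMeans(y)
    s <- apply(y, 1, sd)
    y <- (y - mu) / ifelse(s == 0, 1, s)
    y[s == 0, ] <- 0
  }
  if (tib_in) expr_as_tibble(y) else y
}

#' Two-group differential expression analysis
#'
#' Wrapper around [nb_test()], [bh_adjust()] and [call_de()] returning a
#' tidy result object with [tidy()], [glance()] and [autoplot()] (volcano)
#' methods.
#'
#' @inheritParams nb_test
#' @inheritParams call_de
#' @return A `lnc_de` object; `tidy()` returns the per-feature table.
#' @export
de_analysis <- function(counts, groups, lfc_threshold = 2, alpha = 0.05,
                        sf = NULL, pseudocount = 0.5,
                        dispersion = c("trend", "per-gene")) {
  res <- nb_test(counts, groups,
    sf = sf, pseudocount = pseudocount,
    dispersion = match.arg(dispersion)
  )
  res <- call_de(res, lfc_threshold = lfc_threshold, alpha = alpha)
  out <- list(
    table = res,
    params = list(
      lfc_threshold = lfc_threshold, alpha = alpha,
      pseudocount = pseudocount,
      groups = levels(as.factor(groups)),
      method = "nb_wald_standin"
    )
  )
  class(out) <- "lnc_de"
  out
}

#' @export
print.lnc_de <- function(x, ...) {
  cat(sprintf(
    "NB Wald differential expression (stand-in test): %d features, %d significant at |log2FC| > %g, adj p < %g\n",
    nrow(x$table), sum(x$table$significant),
    x$params$lfc_threshold, x$params$alpha
  ))
  invisible(x)
}
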