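# Knockout-vs-wildtype double-ratio screen: low-count removal, the induction
# difference ratio and relative fold-change ratio computed on group-mean FPKM
# over a WT/KO x 0h/4h design, conjunctive selection, and hierarchical
# clustering of the selected genes' expression profiles into three classes.

#' Screen configuration
#'
#' @param ratio_hi,ratio_lo Acceptance bounds: a ratio counts as extreme when
#'   it is `> ratio_hi` or `< ratio_lo` (strict inequalities).
#' @param min_reads Low-count threshold in total reads per group.
#' @param eps Pseudocount (FPKM units) added to each FPKM term of the
#'   relative fold-change ratio; must be positive whenever any FPKM is 0.
#' @param low_count_rule `"all"` (default): a gene is removed when its read
#'   total is below `min_reads` in every one of the four groups; `"any"`:
#'   removed when below threshold in at least one group.
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(ratio_hi = 2, ratio_lo = 0.5, min_reads = 5,
                          eps = 0.01, low_count_rule = c("all", "any")) {
  stopifnot(ratio_lo < 1, ratio_hi > 1, min_reads >= 0, eps >= 0)
  structure(
    list(
      ratio_hi = ratio_hi, ratio_lo = ratio_lo, min_reads = min_reads,
      eps = eps, low_count_rule = match.arg(low_count_rule)
    ),
    class = "screen_config"
  )
}

SCREEN_FPKM_COLS <- c("fpkm_wt0", "fpkm_wt4", "fpkm_ko0", "fpkm_ko4")
SCREEN_READ_COLS <- c("reads_wt0", "reads_wt4", "reads_ko0", "reads_ko4")

#' Build per-gene screen records from replicate matrices
#'
#' Collapses replicate-level FPKM and count matrices to the four group-mean
#' FPKM values and four group read totals per gene, keyed by the sample
#' config (`group` WT/KO, `timepoint` 0h/4h).
#'
#' @param fpkm,counts Matrices or tibbles (genes x samples).
#' @param samples Sample config tibble (`sample`, `group`, `timepoint`).
#' @return Tibble with `gene_id`, `fpkm_wt0` ... `fpkm_ko4`,
#'   `reads_wt0` ... `reads_ko4`.
#' @export
screen_records <- function(fpkm, counts, samples) {
  check_columns(samples, c("sample", "group", "timepoint"), "sample config")
  fm <- as_expr_matrix(fpkm)
  cm <- as_expr_matrix(counts)
  stopifnot(identical(rownames(fm), rownames(cm)))
  key <- paste0(
    tolower(samples$group), sub("h$", "", samples$timepoint)
  ) # wt0, wt4, ko0, ko4
  expected <- c("wt0", "wt4", "ko0", "ko4")
  if (!setequal(unique(key), expected)) {
    abort(sprintf(
      "sample config must cover the four groups WT/KO x 0h/4h, found: %s",
      paste(sort(unique(key)), collapse = ", ")
    ))
  }
  samples_in <- match(samples$sample, colnames(fm))
  if (anyNA(samples_in)) {
    abort("every configured sample must be a column of the FPKM matrix")
  }
  out <- tibble(gene_id = rownames(fm))
  for (g in expected) {
    cols <- samples$sample[key == g]
    out[[paste0("fpkm_", g)]] <- rowMeans(fm[, cols, drop = FALSE])
    out[[paste0("reads_", g)]] <- rowSums(cm[, cols, drop = FALSE])
  }
  out
}

#' Flag genes with extremely low expression
#'
#' Marks genes for removal by read totals before the ratio screen. Under the
#' default `"all"` rule a gene is removed iff its total reads are below
#' `min_reads` in every one of the four groups (the literal reading of
#' "fewer than five total reads in each group"); `"any"` removes a gene that
#' is low in at least one group.
#'
#' @param records Screen records ([screen_records()]).
#' @param min_reads Threshold in reads (exclusive: removal needs `< min_reads`).
#' @param rule `"all"` or `"any"`.
#' @return `records` with a logical `retained` column.
#' @export
low_count_filter <- function(records, min_reads = 5, rule = c("all", "any")) {
  rule <- match.arg(rule)
  check_columns(records, SCREEN_READ_COLS, "screen records")
  low <- as.matrix(records[SCREEN_READ_COLS]) < min_reads
  removed <- if (rule == "all") rowSums(low) == 4 else rowSums(low) > 0
  records %>% mutate(retained = !removed)
}

#' Induction difference ratio (knockout vs wildtype)
#'
#' `r_diff = (FPKM_KO4h - FPKM_KO0h) / (FPKM_WT4h - FPKM_WT0h)`: the ratio of
#' absolute induction in the knockout to that in the wildtype. A pseudocount
#' added to each term cancels in the differences, so none is applied. A
#' denominator of exactly zero yields a signed-infinity sentinel (`Inf` for a
#' positive numerator, `-Inf` for a negative one, and 1 when both difference
#' are zero — no induction anywhere is a neutral ratio).
#'
#' @param records Screen records ([screen_records()]).
#' @return `records` with an `r_diff` column.
#' @export
induction_difference_ratio <- function(records) {
  check_columns(records, SCREEN_FPKM_COLS, "screen records")
  num <- records$fpkm_ko4 - records$fpkm_ko0
  den <- records$fpkm_wt4 - records$fpkm_wt0
  r <- num / den
  r[den == 0] <- sign(num[den == 0]) * Inf
  r[den == 0 & num == 0] <- 1
  records %>% mutate(r_diff = r)
}

#' Relative fold-change ratio (knockout vs wildtype)
#'
#' `r_fc = (FPKM_KO4h / FPKM_KO0h) / (FPKM_WT4h / FPKM_WT0h)`: the knockout's
#' induction fold change relative to the wildtype's. A pseudocount `eps`
#' (FPKM units) is added to every term; with `eps = 0` a zero in any
#' denominator position is an error instructing a nonzero `eps`.
#'
#' @param records Screen records ([screen_records()]).
#' @param eps Pseudocount in FPKM units (default 0.01).
#' @return `records` with an `r_fc` column.
#' @export
relative_foldchange_ratio <- function(records, eps = 0.01) {
  check_columns(records, SCREEN_FPKM_COLS, "screen records")
  stopifnot(eps >= 0)
  if (eps == 0 &&
    any(records$fpkm_ko0 == 0 | records$fpkm_wt0 == 0 | records$fpkm_wt4 == 0)) {
    abort(paste(
      "zero FPKM in a denominator position with eps = 0;",
      "supply a positive eps pseudocount"
    ))
  }
  r <- ((records$fpkm_ko4 + eps) / (records$fpkm_ko0 + eps)) /
    ((records$fpkm_wt4 + eps) / (records$fpkm_wt0 + eps))
  records %>% mutate(r_fc = r)
}

ratio_extreme <- function(r, hi, lo) {
  (r > hi) | (r < lo)
}

#' Select knockout-regulated genes by the double-ratio criterion
#'
#' A gene is selected iff its induction difference ratio is extreme
#' (`> ratio_hi` or `< ratio_lo`) AND its relative fold-change ratio is
#' extreme — both criteria are required. Negative or `-Inf` ratios satisfy
#' the `< ratio_lo` arm; `+Inf` satisfies `> ratio_hi`. Genes flagged by the
#' low-count filter are never selected.
#'
#' @param records Screen records; ratios and `retained` are computed here if
#'   absent.
#' @param config A [screen_config()].
#' @return `records` with `retained`, `r_diff`, `r_fc` and logical `selected`.
#' @export
select_regulated <- function(records, config = screen_config()) {
  if (!"retained" %in% names(records)) {
    records <- low_count_filter(records, config$min_reads, config$low_count_rule)
  }
  if (!"r_diff" %in% names(records)) {
    records <- induction_difference_ratio(records)
  }
  if (!"r_fc" %in% names(records)) {
    records <- relative_foldchange_ratio(records, config$eps)
  }
  records %>%
    mutate(
      selected = .data$retained &
        ratio_extreme(.data$r_diff, config$ratio_hi, config$ratio_lo) &
        ratio_extreme(.data$r_fc, config$ratio_hi, config$ratio_lo)
    )
}

#' Cluster selected genes into expression-profile classes
#'
#' Rows are transformed with [cluster_transform()] (log10 with the 1e-6
#' pseudocount, then per-row z-score), hierarchically clustered with
#' Euclidean distance and complete linkage, and the tree is cut at `k`
#' clusters. Cluster labels `I`, `II`, `III`, ... are assigned by descending
#' cluster size, ties broken by the lexicographically smallest member id.
#' When every transformed profile is identical the clustering is degenerate:
#' a warning is raised and all genes get class `I`.
#'
#' @param fpkm FPKM matrix (rows = selected genes) or tibble with id column.
#' @param k Number of classes (default 3).
#' @return Tibble with `gene_id` and factor `class` (levels in roman
#'   numerals).
#' @export
cluster_classes <- function(fpkm, k = 3) {
  m <- as_expr_matrix(fpkm)
  if (nrow(m) < k) {
    abort(sprintf("need at least k = %d genes to cut %d classes, got %d", k, k, nrow(m)))
  }
  z <- cluster_transform(m)
  d <- dist(z, method = "euclidean")
  labels_roman <- as.character(utils::as.roman(seq_len(k)))
  if (all(d == 0)) {
    warn("all expression profiles are identical after transformation; single degenerate cluster")
    return(tibble(
      gene_id = rownames(m),
      class = factor(rep(labels_roman[1], nrow(m)), levels = labels_roman)
    ))
  }
  tree <- hclust(d, method = "complete")
  cut <- cutree(tree, k = k)
  sizes <- table(cut)
  first_member <- vapply(
    names(sizes),
    function(cl) min(rownames(m)[cut == as.integer(cl)]),
    character(1)
  )
  ord <- order(-as.integer(sizes), first_member)
  relabel <- setNames(labels_roman, names(sizes)[ord])
  tibble(
    gene_id = rownames(m),
    class = factor(unname(relabel[as.character(cut)]), levels = labels_roman)
  )
}

#' Run the knockout-regulation screen end to end
#'
#' Builds screen records from replicate FPKM/count matrices, removes
#' low-count genes, computes both ratios, selects regulated genes (both
#' criteria required) and clusters the selected genes' group-mean profiles
#' into `k` classes. The returned object keeps full bookkeeping:
#' `n_input = n_removed + n_rejected + n_selected`.
#'
#' @param fpkm,counts Replicate-level matrices or tibbles (genes x samples).
#' @param samples Sample config tibble (`sample`, `group`, `timepoint`).
#' @param config A [screen_config()].
#' @param k Number of expression-profile classes.
#' @return A `ko_screen` object; `tidy()` returns the per-gene table,
#'   `glance()` the bookkeeping counts.
#' @export
ko_screen <- function(fpkm, counts, samples, config = screen_config(), k = 3) {
  records <- screen_records(fpkm, counts, samples)
  records <- select_regulated(records, config)
  sel <- records %>% filter(.data$selected)
  classes <- NULL
  if (nrow(sel) >= k) {
    profile <- as.matrix(sel[SCREEN_FPKM_COLS])
    rownames(profile) <- sel$gene_id
    colnames(profile) <- c("WT0h", "WT4h", "KO0h", "KO4h")
    classes <- cluster_classes(profile, k = k)
    records <- records %>% left_join(classes, by = "gene_id")
  } else {
    records$class <- factor(NA_character_,
      levels = as.character(utils::as.roman(seq_len(k)))
    )
  }
  out <- list(
    table = records,
    counts = list(
      n_input = nrow(records),
      n_removed = sum(!records$retained),
      n_rejected = sum(records$retained & !records$selected),
      n_selected = sum(records$selected)
    ),
    config = config,
    k = k
  )
  stopifnot(
    out$counts$n_input ==
      out$counts$n_removed + out$counts$n_rejected + out$counts$n_selected
  )
  class(out) <- "ko_screen"
  out
}

#' @export
print.ko_screen <- function(x, ...) {
  cat(sprintf(
    "Knockout double-ratio screen: %d genes in, %d low-count removed, %d selected\n",
    x$counts$n_input, x$counts$n_removed, x$counts$n_selected
  ))
  if (!all(is.na(x$table$class))) {
    tab <- table(x$table$class[x$table$selected])
    cat(
      "  classes:",
      paste(sprintf("%s = %d", names(tab), as.integer(tab)), collapse = ", "),
      "\n"
    )
  }
  invisible(x)
}
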