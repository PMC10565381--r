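# The knockout double-ratio screen: low-count removal, both ratio statistics,
# conjunctive selection, profile clustering, and bookkeeping.

rec <- function(wt0, wt4, ko0, ko4, reads = 100, id = "g") {
  tibble::tibble(
    gene_id = id,
    fpkm_wt0 = wt0, fpkm_wt4 = wt4, fpkm_ko0 = ko0, fpkm_ko4 = ko4,
    reads_wt0 = reads, reads_wt4 = reads, reads_ko0 = reads, reads_ko4 = reads
  )
}

test_that("low-count removal requires sub-threshold totals in every group by default", {
  records <- dplyr::bind_rows(
    rec(1, 1, 1, 1, reads = 0, id = "all_zero"),
    rec(1, 1, 1, 1, reads = 4, id = "all_four"),
    rec(1, 1, 1, 1, reads = 5, id = "at_threshold"),
    dplyr::mutate(rec(1, 1, 1, 1, reads = 0, id = "one_high"), reads_wt4 = 100)
  )
  res <- low_count_filter(records, min_reads = 5)
  expect_equal(res$retained, c(FALSE, FALSE, TRUE, TRUE))

  strict <- low_count_filter(records, min_reads = 5, rule = "any")
  expect_equal(strict$retained, c(FALSE, FALSE, TRUE, FALSE))
})

test_that("the induction difference ratio matches hand arithmetic and handles flat wildtype", {
  expect_equal(induction_difference_ratio(rec(2, 10, 2, 4))$r_diff, 0.25)
  expect_equal(induction_difference_ratio(rec(3, 7, 5, 9))$r_diff, 1)
  expect_equal(induction_difference_ratio(rec(5, 5, 5, 9))$r_diff, Inf)
  expect_equal(induction_difference_ratio(rec(5, 5, 9, 5))$r_diff, -Inf)
  expect_equal(induction_difference_ratio(rec(5, 5, 7, 7))$r_diff, 1)
})

test_that("the relative fold-change ratio matches hand arithmetic and needs eps at zero", {
  expect_equal(relative_foldchange_ratio(rec(2, 10, 2, 4), eps = 0)$r_fc, 0.4)
  expect_equal(relative_foldchange_ratio(rec(6, 6, 6, 6), eps = 0)$r_fc, 1)
  expect_error(
    relative_foldchange_ratio(rec(2, 10, 0, 4), eps = 0),
    "eps"
  )
  expect_silent(relative_foldchange_ratio(rec(2, 10, 0, 4), eps = 0.01))

  # swapping WT and KO inverts the ratio
  a <- relative_foldchange_ratio(rec(2, 10, 3, 4), eps = 0)$r_fc
  b <- relative_foldchange_ratio(rec(3, 4, 2, 10), eps = 0)$r_fc
  expect_equal(a, 1 / b)
})

test_that("selection requires both ratio criteria (conjunction)", {
  cases <- tibble::tribble(
    ~r_diff, ~r_fc, ~selected,
    0.25, 0.4, TRUE, # both low
    3, 3, TRUE, # both high
    3, 0.3, TRUE, # mixed extremes both count
    1, 1, FALSE,
    3, 1, FALSE, # second criterion fails
    1, 3, FALSE, # first criterion fails
    -0.5, 0.1, TRUE, # negative counts as < 0.5
    Inf, 4, TRUE, # +Inf counts as > 2
    2, 3, FALSE, # boundary: strict inequality
    3, 0.5, FALSE # boundary: strict inequality
  )
  records <- rec(1, 1, 1, 1, id = paste0("g", seq_len(nrow(cases)))) |>
    dplyr::mutate(
      retained = TRUE, r_diff = cases$r_diff, r_fc = cases$r_fc
    )
  res <- select_regulated(records, screen_config())
  expect_equal(res$selected, cases$selected)
})

test_that("selection is invariant under rescaling and under WT/KO exchange", {
  set.seed(8)
  for (i in 1:50) {
    v <- runif(4, 0.5, 50)
    r <- rec(v[1], v[2], v[3], v[4])
    base <- select_regulated(r, screen_config(eps = 0))$selected

    scaled <- select_regulated(
      rec(10 * v[1], 10 * v[2], 10 * v[3], 10 * v[4]),
      screen_config(eps = 0)
    )$selected
    expect_equal(base, scaled)

    sw <- select_regulated(
      rec(v[3], v[4], v[1], v[2]),
      screen_config(eps = 0)
    )
    # finite positive ratios: the acceptance region (>2 or <0.5) maps to
    # itself under r -> 1/r, so selection status is preserved
    if (is.finite(sw$r_diff) && sw$r_diff > 0) {
      expect_equal(base, sw$selected)
    }
  }
})

test_that("profile clustering recovers three planted archetypes and is order-invariant", {
  arch <- list(
    up_up = c(1, 2, 1, 16),
    down_down = c(1, 0.5, 2.5, 0.25),
    reversed = c(1, 8, 1, 0.2)
  )
  m <- do.call(rbind, lapply(names(arch), function(a) {
    base <- seq(20, 200, length.out = 10)
    out <- outer(base, arch[[a]])
    rownames(out) <- sprintf("%s_%02d", a, 1:10)
    out
  }))
  colnames(m) <- c("wt0", "wt4", "ko0", "ko4")
  cl <- cluster_classes(m, k = 3)
  truth <- sub("_[0-9]+$", "", cl$gene_id)
  expect_equal(length(unique(paste(cl$class, truth))), 3)

  perm <- sample(nrow(m))
  cl2 <- cluster_classes(m[perm, ], k = 3)
  expect_equal(
    cl2$class[match(cl$gene_id, cl2$gene_id)],
    cl$class
  )
})

test_that("clustering degenerates gracefully and enforces k", {
  same <- matrix(5, 4, 4, dimnames = list(paste0("g", 1:4), NULL))
  expect_warning(cl <- cluster_classes(same, k = 3), "identical")
  expect_true(all(cl$class == "I"))
  expect_error(cluster_classes(same[1:2, ], k = 3), "at least k")
})

test_that("class labels are ordered by size with ties broken by smallest member id", {
  m <- rbind(
    a1 = c(1, 1, 1, 100), a2 = c(1, 1, 1, 110), a3 = c(1, 1.1, 1, 105),
    z1 = c(100, 1, 1, 1), z2 = c(110, 1, 1.2, 1),
    m1 = c(1, 100, 100, 1), m2 = c(1.4, 110, 95, 1)
  )
  colnames(m) <- c("wt0", "wt4", "ko0", "ko4")
  cl <- cluster_classes(m, k = 3)
  lab <- setNames(as.character(cl$class), cl$gene_id)
  expect_equal(unname(lab["a1"]), "I") # size 3
  # two clusters of size 2: the one containing the smaller id ("m1" < "z1")
  expect_equal(unname(lab["m1"]), "II")
  expect_equal(unname(lab["z1"]), "III")
})

test_that("the end-to-end screen recovers planted truth exactly at zero noise", {
  cfg <- generator_config(noise_cv = 0, n_background = 800)
  ko <- gen_ko_screen_data(cfg)
  scr <- ko_screen(ko$fpkm, ko$counts, ko$samples)
  tab <- tidy(scr)

  truth <- ko$truth
  sel <- tab$gene_id[tab$selected]
  planted <- truth$gene_id[truth$regulated]
  expect_setequal(sel, planted)

  # low-count stratum fully removed
  expect_true(all(!tab$retained[match(
    truth$gene_id[truth$low_count], tab$gene_id
  )]))

  # bookkeeping identity
  g <- glance(scr)
  expect_equal(g$n_input, g$n_removed + g$n_rejected + g$n_selected)

  # class partition is pure with respect to the planted archetypes
  joined <- dplyr::inner_join(
    dplyr::filter(tab, selected), truth,
    by = "gene_id"
  )
  purity <- table(joined$class, joined$archetype)
  expect_equal(sum(apply(purity, 1, function(r) sum(r > 0))), 3)
})

test_that("the screen stays sensitive at the generator's default noise", {
  cfg <- generator_config(n_background = 800) # noise_cv = 0.1
  ko <- gen_ko_screen_data(cfg)
  scr <- ko_screen(ko$fpkm, ko$counts, ko$samples)
  tab <- tidy(scr)
  planted <- ko$truth$gene_id[ko$truth$regulated]
  sens <- mean(tab$selected[match(planted, tab$gene_id)])
  spec <- 1 - mean(tab$selected[!tab$gene_id %in% planted], na.rm = TRUE)
  expect_gte(sens, 0.9)
  expect_gte(spec, 0.99)
})
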