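# Candidate filtering, coding-potential consensus, positional classification,
# composition arithmetic, and the three-frame ORF screen.

metrics_row <- function(len, exons, annotated = FALSE, id = "t") {
  tibble::tibble(
    transcript_id = id, transcript_length = len,
    n_exons = exons, annotated = annotated
  )
}

test_that("candidate filter applies length, exon and novelty rules in order", {
  cases <- tibble::tribble(
    ~len, ~exons, ~annotated, ~pass, ~reason,
    1925, 3, FALSE, TRUE, NA_character_, # the featured transcript's metrics
    150, 2, FALSE, FALSE, "length",
    200, 2, FALSE, FALSE, "length", # strict: > 200 required
    201, 2, FALSE, TRUE, NA_character_,
    300, 1, FALSE, FALSE, "exons",
    1925, 3, TRUE, FALSE, "annotated"
  )
  res <- candidate_filter(
    metrics_row(cases$len, cases$exons, cases$annotated, paste0("t", 1:6))
  )
  expect_equal(res$pass, cases$pass)
  expect_equal(res$reason, cases$reason)
})

test_that("the literal more-than-two-exons reading is selectable", {
  res <- candidate_filter(metrics_row(500, 2), min_exons = 3)
  expect_false(res$pass)
  expect_equal(res$reason, "exons")
  expect_true(candidate_filter(metrics_row(500, 3), min_exons = 3)$pass)
})

test_that("consensus requires unanimity and errors on missing verdicts", {
  v <- tibble::tibble(
    transcript_id = c("a", "b"),
    cpc_like = c("noncoding", "coding"),
    cnci_like = "noncoding", cpat_like = "noncoding", pfam_like = "noncoding"
  )
  res <- consensus_noncoding(v)
  expect_equal(res$noncoding_consensus, c(TRUE, FALSE))

  v$cnci_like[1] <- NA
  expect_error(consensus_noncoding(v), "missing.*verdict.*a")
  v$cnci_like[1] <- "maybe"
  expect_error(consensus_noncoding(v), "coding.*noncoding")

  expect_error(
    consensus_noncoding(v[, -2]),
    class = "lncscreen_schema_error"
  )
})

test_that("consensus is monotone: flipping any verdict to coding never rescues", {
  set.seed(1)
  cols <- c("cpc_like", "cnci_like", "cpat_like", "pfam_like")
  for (i in 1:50) {
    v <- tibble::tibble(transcript_id = "t")
    for (cl in cols) v[[cl]] <- sample(c("coding", "noncoding"), 1)
    before <- consensus_noncoding(v)$noncoding_consensus
    flip <- sample(cols, 1)
    v[[flip]] <- "coding"
    after <- consensus_noncoding(v)$noncoding_consensus
    expect_false(!before && after)
  }
})

test_that("venn counts report per-tool noncoding sets and their intersection", {
  v <- tibble::tibble(
    transcript_id = paste0("t", 1:4),
    cpc_like = c("noncoding", "noncoding", "noncoding", "coding"),
    cnci_like = c("noncoding", "noncoding", "coding", "noncoding"),
    cpat_like = "noncoding",
    pfam_like = "noncoding"
  )
  vc <- venn_counts(v)
  expect_equal(unname(vc$per_tool), c(3, 3, 4, 4))
  expect_equal(vc$intersection, 2)
})

# Reference for classification cases: gene G1 ("+") with exons 1001-1100 and
# 1201-1300 (intron 1101-1200), and gene G2 ("-") spanning 2001-2500.
ref_fixture <- function() {
  dplyr::bind_rows(
    make_tx("R1", c(1001, 1201), c(1100, 1300), "+", "G1", annotated = TRUE),
    make_tx("R2", c(2001, 2401), c(2100, 2500), "-", "G2", annotated = TRUE)
  )
}

test_that("positional classes follow the documented rules and precedence", {
  ref <- ref_fixture()
  cases <- list(
    list(tx = make_tx("c_linc", 5000, 5400, "+"), class = "lincRNA"),
    list(tx = make_tx("c_intr", 1120, 1180, "+"), class = "intronic"),
    list(tx = make_tx("c_anti", 2050, 2200, "+"), class = "antisense"),
    list(tx = make_tx("c_sens", 1050, 1150, "+"), class = "sense"),
    # opposite strand within G1's intron: not intronic (strand-defined),
    # but antisense via G1's extent
    list(tx = make_tx("c_anti2", 1120, 1180, "-"), class = "antisense"),
    # same-strand exon overlap wins over any opposite-strand gene overlap
    list(
      tx = make_tx("c_prec", c(1050, 2050), c(1120, 2100), "+"),
      class = "sense"
    )
  )
  for (cs in cases) {
    got <- classify_position(cs$tx, ref)
    expect_equal(
      as.character(got$positional_class), cs$class,
      label = cs$tx$transcript_id[1]
    )
  }
})

test_that("classification is invariant under translation and exon permutation", {
  ref <- ref_fixture()
  cand <- dplyr::bind_rows(
    make_tx("a", c(1120, 1160), c(1140, 1180), "+"),
    make_tx("b", c(1050, 1210), c(1120, 1250), "+"),
    make_tx("c", 2050, 2200, "+"),
    make_tx("d", c(9000, 9500), c(9100, 9600), "-")
  )
  base <- classify_position(cand, ref)

  shift <- function(tbl, k) dplyr::mutate(tbl, start = start + k, end = end + k)
  shifted <- classify_position(shift(cand, 10000L), shift(ref, 10000L))
  expect_equal(base$positional_class, shifted$positional_class)

  permuted <- classify_position(cand[sample(nrow(cand)), ], ref)
  expect_equal(
    base$positional_class[match(permuted$transcript_id, base$transcript_id)],
    permuted$positional_class
  )
})

test_that("every candidate gets exactly one class and counts sum to total", {
  gen <- gen_annotation(generator_config(seed = 5))
  novel <- dplyr::filter(gen$annotation, !annotated)
  lnc_ids <- gen$truth$transcript_id[gen$truth$is_lncrna]
  cl <- classify_position(
    dplyr::filter(novel, transcript_id %in% lnc_ids),
    dplyr::filter(gen$annotation, annotated)
  )
  expect_setequal(cl$transcript_id, lnc_ids)
  expect_false(anyNA(cl$positional_class))
  comp <- summarize_composition(cl)
  expect_equal(sum(comp$count), attr(comp, "total"))
})

test_that("composition arithmetic matches hand-checked cases", {
  one_each <- tibble::tibble(
    positional_class = c("lincRNA", "intronic", "antisense", "sense")
  )
  comp <- summarize_composition(one_each)
  expect_equal(comp$percentage, rep(25.0, 4))

  empty <- summarize_composition(one_each[0, , drop = FALSE])
  expect_equal(attr(empty, "total"), 0)
  expect_true(all(is.na(empty$percentage)))
  expect_equal(sum(empty$count), 0)
})

test_that("percentages are rounded half away from zero", {
  expect_equal(round_half_up(56.25, 1), 56.3)
  expect_equal(round_half_up(11.05, 1), 11.1)
  expect_equal(round_half_up(-2.45, 1), -2.5)
  expect_equal(round_half_up(2.5), 3)
})

test_that("three-frame ORF screen handles hand-computed cases", {
  none <- three_frame_orf_screen("CCCCCCCCC")
  expect_equal(none$longest_orf_nt, c(0L, 0L, 0L))
  expect_equal(attr(none, "max_orf_nt"), 0L)

  one <- three_frame_orf_screen("ATGAAATAG")
  expect_equal(one$longest_orf_nt, c(9L, 0L, 0L))

  # frame 2: offset by one base; RNA alphabet accepted
  shifted <- three_frame_orf_screen("CAUGAAAUAGC")
  expect_equal(shifted$longest_orf_nt, c(0L, 9L, 0L))

  # no in-frame stop -> no ORF counted
  expect_equal(attr(three_frame_orf_screen("ATGAAAAAA"), "max_orf_nt"), 0L)

  expect_error(three_frame_orf_screen("ATGNNNTAG"), class = "lncscreen_alphabet_error")
})

test_that("ORF screen agrees with a brute-force scan on random sequences", {
  set.seed(7)
  for (i in 1:300) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(30:400, 1), replace = TRUE),
      collapse = ""
    )
    expect_equal(
      three_frame_orf_screen(s)$longest_orf_nt, oracle_orf(s),
      label = paste("seq", i)
    )
  }
})

test_that("ORF-based fallback verdicts flag long-ORF sequences as coding", {
  long_orf <- paste0("ATG", strrep("GCA", 120), "TAA")
  v <- orf_verdicts(c(coding_like = long_orf, short = "ATGAAATAGCCC"))
  expect_equal(v$cpc_like, c("coding", "noncoding"))
  expect_equal(attr(v, "source"), "orf_heuristic")
  expect_equal(consensus_noncoding(v)$noncoding_consensus, c(FALSE, TRUE))
})

test_that("discovery wrapper ties the stages together with full bookkeeping", {
  gen <- gen_annotation(generator_config(seed = 2))
  disc <- discover_lncrnas(gen$annotation, gen$verdicts)
  cand <- tidy(disc)
  truth <- dplyr::inner_join(cand, gen$truth, by = "transcript_id")
  expect_equal(truth$pass, truth$passes_filter)
  expect_equal(truth$is_lncrna.x, truth$is_lncrna.y)
  classified <- dplyr::filter(truth, is_lncrna.x)
  expect_equal(as.character(classified$positional_class), classified$true_class)
  g <- glance(disc)
  expect_equal(g$total_classified, sum(cand$is_lncrna))
})
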