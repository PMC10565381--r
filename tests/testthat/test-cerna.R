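# Seed extraction, canonical site scanning, sponge candidate discovery, and
# deletion-mutant construction.

MIR <- "UACGGAUCAGGCUAAGCUAA" # seed 2-7 ACGGAU, 2-8 ACGGAUC

test_that("seed regions are extracted at the documented 1-based positions", {
  expect_equal(seed_region(MIR, "2-8"), "ACGGAUC")
  expect_equal(seed_region(MIR, "2-7"), "ACGGAU")
  expect_equal(seed_region("uacggauca", "2-8"), "ACGGAUC") # lowercase DNA/RNA ok
  expect_error(seed_region("UACGGAU", "2-8"), "at least 8")
})

test_that("each canonical site class is detected with correct span and priority", {
  core <- revcomp_rna(seed_region(MIR, "2-7")) # AUCCGU
  m8 <- revcomp_rna(seed_region(MIR, "2-8")) # GAUCCGU
  pad <- function(x) paste0("CCC", x, "CCC")

  cases <- list(
    list(seq = pad(paste0(m8, "A")), type = "8mer", len = 8),
    list(seq = pad(paste0(m8, "G")), type = "7mer-m8", len = 7),
    list(seq = pad(paste0("C", core, "A")), type = "7mer-A1", len = 7),
    list(seq = pad(paste0("C", core, "G")), type = "6mer", len = 6)
  )
  for (cs in cases) {
    hits <- find_seed_sites(cs$seq, MIR)
    expect_equal(nrow(hits), 1, label = cs$type)
    expect_equal(as.character(hits$site_type), cs$type)
    expect_equal(hits$end - hits$start + 1L, cs$len)
    # the reported subsequence really is at the reported span
    expect_equal(substr(cs$seq, hits$start, hits$end), hits$site_seq)
  }

  # worked example: GAUCCGUA in the target is one 8mer
  hits <- find_seed_sites("CCCGAUCCGUACCC", MIR)
  expect_equal(nrow(hits), 1)
  expect_equal(as.character(hits$site_type), "8mer")

  expect_equal(nrow(find_seed_sites("CCCCCCCCCCCC", MIR)), 0)
  expect_equal(nrow(find_seed_sites("ACG", MIR)), 0)
})

test_that("site complementarity holds for every reported site", {
  set.seed(31)
  for (i in 1:50) {
    target <- random_rna_str(200)
    mir <- random_rna_str(21)
    hits <- find_seed_sites(target, mir)
    core <- revcomp_rna(seed_region(mir, "2-7"))
    for (j in seq_len(nrow(hits))) {
      expect_true(grepl(core, hits$site_seq[j], fixed = TRUE))
    }
  }
})

test_that("site starts are equivariant under prefix padding", {
  set.seed(32)
  target <- random_rna_str(300)
  mir <- random_rna_str(22)
  base <- find_seed_sites(target, mir)
  shifted <- find_seed_sites(paste0(random_rna_str(17), target), mir)
  # restrict to sites fully inside the original sequence region
  shifted <- shifted[shifted$start > 17, , drop = FALSE]
  expect_equal(shifted$start, base$start + 17L)
  expect_equal(shifted$site_type, base$site_type)
})

test_that("the scanner agrees with the brute-force oracle on random pairs", {
  set.seed(33)
  for (i in 1:200) {
    target <- random_rna_str(sample(40:250, 1))
    mir <- random_rna_str(sample(18:24, 1))
    got <- find_seed_sites(target, mir)
    want <- oracle_seed_sites(target, mir)
    expect_equal(got$start, want$start, label = paste("pair", i))
    expect_equal(got$end, want$end)
    expect_equal(as.character(got$site_type), want$site_type)
  }
})

test_that("sponge screening finds exactly the planted dual binders", {
  ce <- gen_cerna_panel(generator_config(seed = 77))
  sp <- shared_sponging_mirnas(ce$lnc, ce$utr, ce$panel)
  expect_setequal(
    sp$summary$name[sp$summary$dual_binder],
    ce$truth$dual_binders
  )
  expect_equal(sp$venn$both, length(ce$truth$dual_binders))

  # the featured miRNA carries exactly two sites per target at truth coordinates
  feat <- dplyr::filter(ce$truth$sites, mirna == ce$truth$featured)
  got <- dplyr::filter(sp$sites, mirna == ce$truth$featured)
  expect_equal(nrow(dplyr::filter(got, target == "lncRNA")), 2)
  expect_equal(nrow(dplyr::filter(got, target == "3'UTR")), 2)
  expect_equal(
    dplyr::arrange(got[c("target", "start", "end")], target, start),
    dplyr::arrange(feat[c("target", "start", "end")], target, start)
  )

  # empty panel, and monotonicity in min_sites
  empty <- shared_sponging_mirnas(ce$lnc, ce$utr, ce$panel[0, ])
  expect_equal(nrow(empty$summary), 0)
  two <- shared_sponging_mirnas(ce$lnc, ce$utr, ce$panel, min_sites = 2)
  expect_true(all(
    two$summary$dual_binder <= sp$summary$dual_binder
  ))
  expect_setequal(two$summary$name[two$summary$dual_binder], ce$truth$featured)
})

test_that("the venn 'both' set is the intersection of the single-target sets", {
  ce <- gen_cerna_panel(generator_config(seed = 12))
  sp <- shared_sponging_mirnas(ce$lnc, ce$utr, ce$panel)
  on_lnc <- sp$summary$name[sp$summary$n_sites_lnc >= 1]
  on_utr <- sp$summary$name[sp$summary$n_sites_utr >= 1]
  expect_setequal(
    sp$summary$name[sp$summary$dual_binder],
    intersect(on_lnc, on_utr)
  )
  expect_equal(sp$venn$lnc_only, length(setdiff(on_lnc, on_utr)))
  expect_equal(sp$venn$utr_only, length(setdiff(on_utr, on_lnc)))
})

test_that("site deletion excises spans, remaps coordinates, and kills the sites", {
  ce <- gen_cerna_panel(generator_config(seed = 5))
  mir_seq <- ce$panel$sequence[ce$panel$name == ce$truth$featured]
  sites <- dplyr::filter(
    ce$truth$sites,
    mirna == ce$truth$featured, target == "lncRNA"
  )
  del <- delete_sites(ce$lnc, sites)

  expect_equal(
    nchar(del$sequence),
    nchar(ce$lnc) - sum(sites$end - sites$start + 1)
  )
  rescanned <- rescan_mutant(del, mir_seq, ce$truth$featured)
  expect_equal(nrow(rescanned), 0)

  # coordinate map round-trip on retained positions
  expect_equal(
    substr(ce$lnc, map_to_original(del, 1), map_to_original(del, 1)),
    substr(del$sequence, 1, 1)
  )
  pos <- c(1, 50, nchar(del$sequence))
  orig <- map_to_original(del, pos)
  expect_equal(
    vapply(seq_along(pos), function(i) substr(ce$lnc, orig[i], orig[i]), ""),
    vapply(pos, function(p) substr(del$sequence, p, p), "")
  )
})

test_that("deletion edge cases: empty site list, overlapping spans, bad spans", {
  s <- "ACGUACGUACGU"
  none <- delete_sites(s, tibble::tibble(start = integer(), end = integer()))
  expect_equal(none$sequence, s)

  expect_error(
    delete_sites(s, tibble::tibble(start = c(2, 4), end = c(5, 8))),
    "overlap"
  )
  expect_error(
    delete_sites(s, tibble::tibble(start = 10, end = 20)),
    "within the sequence"
  )

  one <- delete_sites(s, tibble::tibble(start = 5, end = 8))
  expect_equal(one$sequence, "ACGUACGU")
  expect_equal(map_to_original(one, 5), 9L)
})
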