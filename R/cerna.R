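# Transparent miRNA seed-site scanning and ceRNA (miRNA sponge) candidate
# discovery. Canonical seed-match classes (6mer, 7mer-A1, 7mer-m8, 8mer),
# strict Watson-Crick pairing (no G:U wobble), matching performed in RNA
# space on the target sense strand. This is a transparent rule-based scanner,
# not a trained target-prediction model.

SITE_TYPES <- c("8mer", "7mer-m8", "7mer-A1", "6mer")

#' Extract the seed region of a miRNA
#'
#' The seed is the 5'-proximal block that nucleates target pairing:
#' positions 2-7 (6-nt core) or 2-8 (core plus position 8), 1-based from the
#' miRNA 5' end.
#'
#' @param mirna miRNA sequence, 5'->3' (RNA or DNA alphabet).
#' @param span `"2-8"` (default) or `"2-7"`.
#' @return The seed subsequence as an RNA string.
#' @export
#' @examples
#' seed_region("UACGGAUCAGGCUAAGCUAA", "2-8")
seed_region <- function(mirna, span = c("2-8", "2-7")) {
  span <- match.arg(span)
  stopifnot(is.character(mirna), length(mirna) == 1)
  m <- as_rna(mirna)
  check_alphabet(m, c("A", "C", "G", "U"), "miRNA sequence")
  if (nchar(m) < 8) {
    abort("miRNA sequence must be at least 8 nt to define a seed region")
  }
  substr(m, 2, if (span == "2-8") 8 else 7)
}

#' Find canonical miRNA seed-match sites on a target sequence
#'
#' Scans the target (given 5'->3', sense strand) for the four canonical
#' seed-match classes, anchored at the 6-nt seed core (reverse complement of
#' miRNA positions 2-7):
#' \describe{
#'   \item{8mer}{reverse complement of seed 2-8 followed by an `A` anchor;}
#'   \item{7mer-m8}{reverse complement of seed 2-8;}
#'   \item{7mer-A1}{reverse complement of seed 2-7 followed by an `A` anchor;}
#'   \item{6mer}{reverse complement of seed 2-7 alone.}
#' }
#' At one core locus only the highest-priority class is reported
#' (8mer > 7mer-m8 > 7mer-A1 > 6mer); distinct (possibly overlapping) core
#' loci are all reported, sorted by start. Matching is strict Watson-Crick.
#'
#' @param target Target sequence, 5'->3' (RNA or DNA; matched in RNA space).
#' @param mirna miRNA sequence, 5'->3'.
#' @param mirna_name,target_name Labels carried into the output.
#' @return Tibble with columns `mirna`, `target`, `start`, `end` (1-based
#'   inclusive on the target), `site_type`, `site_seq`.
#' @export
#' @examples
#' find_seed_sites("CCCGAUCCGUACCC", "UACGGAUCAGGCUAAGCUAA")
find_seed_sites <- function(target, mirna, mirna_name = "miRNA",
                            target_name = "target") {
  stopifnot(is.character(target), length(target) == 1)
  t <- as_rna(target)
  check_alphabet(t, c("A", "C", "G", "U"), "target sequence")
  if (nchar(t) < 6) return(empty_sites())

  core <- revcomp_rna(seed_region(mirna, "2-7")) # 6 nt
  m8_base <- substr(revcomp_rna(seed_region(mirna, "2-8")), 1, 1)

  hits <- Biostrings::matchPattern(core, Biostrings::RNAString(t))
  starts <- Biostrings::start(hits)
  if (length(starts) == 0) return(empty_sites())

  n <- nchar(t)
  has_m8 <- starts > 1 &
    substring(t, starts - 1, starts - 1) == m8_base
  has_a1 <- starts + 6 <= n &
    substring(t, starts + 6, starts + 6) == "A"

  type <- dplyr::case_when(
    has_m8 & has_a1 ~ "8mer",
    has_m8 ~ "7mer-m8",
    has_a1 ~ "7mer-A1",
    TRUE ~ "6mer"
  )
  start <- ifelse(has_m8, starts - 1L, starts)
  end <- ifelse(has_a1, starts + 6L, starts + 5L)

  out <- tibble(
    mirna = mirna_name, target = target_name,
    start = as.integer(start), end = as.integer(end),
    site_type = factor(type, levels = SITE_TYPES),
    site_seq = substring(t, start, end)
  ) %>% arrange(.data$start)
  out
}

empty_sites <- function() {
  tibble(
    mirna = character(), target = character(),
    start = integer(), end = integer(),
    site_type = factor(character(), levels = SITE_TYPES),
    site_seq = character()
  )
}

#' Scan a miRNA panel against two targets and find shared spongers
#'
#' ceRNA candidate discovery: every panel miRNA is scanned against both the
#' lncRNA and the mRNA 3'UTR; sponge candidates are miRNAs with at least
#' `min_sites` seed sites on *both* targets. Venn counts (lncRNA-only,
#' UTR-only, both, at the same `min_sites` cutoff) are reported alongside.
#'
#' @param lnc lncRNA sequence (5'->3').
#' @param utr mRNA 3'UTR sequence (5'->3').
#' @param panel Tibble with columns `name`, `sequence`, or a named character
#'   vector of miRNA sequences.
#' @param min_sites Minimum sites per target for candidacy (default 1).
#' @return A `sponge_screen` object with elements `summary` (per miRNA:
#'   site counts per target, `dual_binder` flag), `sites` (every site on
#'   either target), `venn`, `min_sites`. `tidy()` returns the site table,
#'   `glance()` the Venn counts.
#' @export
shared_sponging_mirnas <- function(lnc, utr, panel, min_sites = 1) {
  stopifnot(min_sites >= 1)
  if (is.character(panel)) {
    panel <- tibble(name = names(panel), sequence = unname(panel))
  }
  check_columns(panel, c("name", "sequence"), "miRNA panel")

  sites <- purrr::map2_dfr(panel$name, panel$sequence, function(nm, sq) {
    bind_rows(
      find_seed_sites(lnc, sq, mirna_name = nm, target_name = "lncRNA"),
      find_seed_sites(utr, sq, mirna_name = nm, target_name = "3'UTR")
    )
  })

  summary <- panel %>%
    mutate(
      n_sites_lnc = vapply(.data$name, function(nm) {
        sum(sites$mirna == nm & sites$target == "lncRNA")
      }, integer(1)),
      n_sites_utr = vapply(.data$name, function(nm) {
        sum(sites$mirna == nm & sites$target == "3'UTR")
      }, integer(1)),
      dual_binder = .data$n_sites_lnc >= min_sites & .data$n_sites_utr >= min_sites
    )

  venn <- list(
    lnc_only = sum(summary$n_sites_lnc >= min_sites & summary$n_sites_utr < min_sites),
    utr_only = sum(summary$n_sites_utr >= min_sites & summary$n_sites_lnc < min_sites),
    both = sum(summary$dual_binder)
  )

  out <- list(
    summary = summary, sites = sites, venn = venn, min_sites = min_sites,
    method = "canonical_seed_match"
  )
  class(out) <- "sponge_screen"
  out
}

#' @export
print.sponge_screen <- function(x, ...) {
  cat(sprintf(
    "ceRNA sponge screen (canonical seed matching): %d miRNAs, %d dual binders (>= %d site(s) on both targets)\n",
    nrow(x$summary), sum(x$summary$dual_binder), x$min_sites
  ))
  cat(sprintf(
    "  Venn: lncRNA-only %d | both %d | 3'UTR-only %d\n",
    x$venn$lnc_only, x$venn$both, x$venn$utr_only
  ))
  invisible(x)
}

#' Delete seed sites from a sequence (reporter mutant construction)
#'
#' Excises the given (mutually non-overlapping) site spans from the sequence,
#' as in binding-site-deletion reporter constructs, and returns the mutant
#' together with a coordinate map of the retained segments. Re-scanning the
#' mutant finds no site at the deleted loci by construction; sites spanning
#' an excision junction are possible and can be audited with
#' [rescan_mutant()].
#'
#' @param seq Sequence (RNA or DNA; alphabet preserved via RNA space).
#' @param sites Tibble with `start`, `end` columns (1-based inclusive spans
#'   to delete); overlapping spans are an error.
#' @return A `site_deletion` list: `sequence` (mutant), `map` (tibble with
#'   `new_start`, `new_end`, `old_start`, `old_end` per retained segment),
#'   `deleted` (the excised spans).
#' @export
delete_sites <- function(seq, sites) {
  stopifnot(is.character(seq), length(seq) == 1)
  s <- as_rna(seq)
  n <- nchar(s)
  if (nrow(sites) == 0) {
    out <- list(
      sequence = s,
      map = tibble(new_start = 1L, new_end = n, old_start = 1L, old_end = n),
      deleted = tibble(start = integer(), end = integer())
    )
    class(out) <- "site_deletion"
    return(out)
  }
  check_columns(sites, c("start", "end"), "sites")
  spans <- sites %>%
    select("start", "end") %>%
    arrange(.data$start)
  if (any(spans$start < 1 | spans$end > n | spans$end < spans$start)) {
    abort("site spans must lie within the sequence")
  }
  if (nrow(spans) > 1 && any(spans$start[-1] <= spans$end[-nrow(spans)])) {
    abort("site spans overlap; deletions must be mutually non-overlapping")
  }

  keep_start <- c(1L, spans$end + 1L)
  keep_end <- c(spans$start - 1L, n)
  keep <- keep_start <= keep_end
  keep_start <- keep_start[keep]
  keep_end <- keep_end[keep]
  segs <- substring(s, keep_start, keep_end)
  lens <- keep_end - keep_start + 1L
  new_end <- cumsum(lens)
  new_start <- new_end - lens + 1L

  out <- list(
    sequence = paste(segs, collapse = ""),
    map = tibble(
      new_start = new_start, new_end = new_end,
      old_start = keep_start, old_end = keep_end
    ),
    deleted = spans
  )
  class(out) <- "site_deletion"
  out
}

#' Map mutant coordinates back to the original sequence
#'
#' @param deletion A [delete_sites()] result.
#' @param pos Positions on the mutant sequence.
#' @return Integer vector of original-sequence positions.
#' @export
map_to_original <- function(deletion, pos) {
  stopifnot(inherits(deletion, "site_deletion"))
  map <- deletion$map
  idx <- findInterval(pos, map$new_start)
  if (any(pos < 1 | pos > max(map$new_end))) {
    abort("positions outside the mutant sequence")
  }
  as.integer(map$old_start[idx] + (pos - map$new_start[idx]))
}

#' Re-scan a deletion mutant and audit junction-created sites
#'
#' Scans the mutant for the same miRNA and maps each found site back to
#' original coordinates. Sites whose mapped-back span is non-contiguous
#' (i.e., they straddle an excision junction) are flagged `junction = TRUE`
#' and reported with a warning; no reported site overlaps a deleted span.
#'
#' @param deletion A [delete_sites()] result.
#' @param mirna miRNA sequence to re-scan with.
#' @param mirna_name Label for the output.
#' @return Site tibble with `orig_start`, `orig_end` and logical `junction`.
#' @export
rescan_mutant <- function(deletion, mirna, mirna_name = "miRNA") {
  stopifnot(inherits(deletion, "site_deletion"))
  sites <- find_seed_sites(deletion$sequence, mirna,
    mirna_name = mirna_name, target_name = "mutant"
  )
  if (nrow(sites) == 0) {
    return(sites %>% mutate(
      orig_start = integer(), orig_end = integer(), junction = logical()
    ))
  }
  o_start <- map_to_original(deletion, sites$start)
  o_end <- map_to_original(deletion, sites$end)
  width <- sites$end - sites$start
  sites <- sites %>% mutate(
    orig_start = o_start, orig_end = o_end,
    junction = (o_end - o_start) != width
  )
  if (any(sites$junction)) {
    warn(sprintf(
      "%d site(s) created across an excision junction", sum(sites$junction)
    ))
  }
  sites
}
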