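# Novel-lncRNA calling: candidate filters, four-predictor coding-potential
# consensus, positional classification against a reference annotation, class
# composition, and a three-frame ORF screen usable as a built-in
# coding-potential heuristic when external predictor tables are unavailable.

VERDICT_COLS <- c("cpc_like", "cnci_like", "cpat_like", "pfam_like")
POSITIONAL_CLASSES <- c("lincRNA", "intronic", "antisense", "sense")

#' Filter assembled transcripts to lncRNA candidates
#'
#' A novel transcript passes iff its spliced length is strictly greater than
#' `min_length` nt, it has at least `min_exons` exons, and it is not already
#' annotated in the reference. The multi-exon criterion defaults to 2, the
#' community multi-exon convention; set `min_exons = 3` for a literal
#' "more than two exons" reading. The failure `reason` names the first
#' criterion that failed, in the order annotated, length, exons.
#'
#' @param metrics Per-transcript table from [transcript_metrics()] (columns
#'   `transcript_id`, `transcript_length`, `n_exons`, `annotated`).
#' @param min_length Minimum spliced length in nt (exclusive bound).
#' @param min_exons Minimum exon count (inclusive bound).
#' @return `metrics` with logical `pass` and character `reason` columns
#'   (`NA` reason when passed).
#' @export
candidate_filter <- function(metrics, min_length = 200, min_exons = 2) {
  check_columns(
    metrics,
    c("transcript_id", "transcript_length", "n_exons"),
    "transcript metrics"
  )
  if (!"annotated" %in% names(metrics)) metrics$annotated <- NA
  metrics %>%
    mutate(
      reason = case_when(
        !is.na(.data$annotated) & .data$annotated ~ "annotated",
        .data$transcript_length <= min_length ~ "length",
        .data$n_exons < min_exons ~ "exons",
        TRUE ~ NA_character_
      ),
      pass = is.na(.data$reason)
    )
}

#' Coding-potential consensus over four predictor verdicts
#'
#' A transcript is called noncoding only when all four predictors
#' (CPC-like, CNCI-like, CPAT-like and a protein-domain search, where
#' "noncoding" means no domain hit) agree — the intersection rule. Verdicts
#' must be exactly `"coding"` or `"noncoding"`; a missing verdict is an
#' error rather than a silent drop, so incompletely scored transcripts are
#' handled explicitly by the caller.
#'
#' @param verdicts Tibble with `transcript_id` and the four verdict columns
#'   `cpc_like`, `cnci_like`, `cpat_like`, `pfam_like`.
#' @return Tibble with `transcript_id` and logical `noncoding_consensus`.
#' @export
consensus_noncoding <- function(verdicts) {
  check_columns(verdicts, c("transcript_id", VERDICT_COLS), "verdict table")
  vals <- as.matrix(verdicts[VERDICT_COLS])
  if (anyNA(vals)) {
    bad <- verdicts$transcript_id[which(rowSums(is.na(vals)) > 0)[1]]
    abort(
      sprintf("missing coding-potential verdict for transcript %s", bad),
      class = "lncscreen_verdict_error"
    )
  }
  if (!all(vals %in% c("coding", "noncoding"))) {
    abort(
      "verdicts must be exactly 'coding' or 'noncoding'",
      class = "lncscreen_verdict_error"
    )
  }
  tibble(
    transcript_id = verdicts$transcript_id,
    noncoding_consensus = rowSums(vals == "noncoding") == length(VERDICT_COLS)
  )
}

#' Per-predictor noncoding sets and their intersection
#'
#' The counts behind the predictor Venn diagram: how many transcripts each
#' coding-potential method calls noncoding, and the size of the four-way
#' intersection (the consensus lncRNA set).
#'
#' @inheritParams consensus_noncoding
#' @return A list with `per_tool` (named integer vector) and
#'   `intersection` (integer).
#' @export
venn_counts <- function(verdicts) {
  check_columns(verdicts, c("transcript_id", VERDICT_COLS), "verdict table")
  vals <- as.matrix(verdicts[VERDICT_COLS])
  per_tool <- colSums(vals == "noncoding")
  list(
    per_tool = per_tool,
    intersection = sum(rowSums(vals == "noncoding") == length(VERDICT_COLS))
  )
}

#' Classify lncRNA candidates by position relative to reference genes
#'
#' Assigns exactly one positional class per candidate transcript, by
#' precedence:
#' \describe{
#'   \item{sense}{any same-strand exon–exon overlap with a reference
#'     transcript;}
#'   \item{intronic}{otherwise, the candidate lies entirely within a single
#'     intron of a same-strand reference transcript;}
#'   \item{antisense}{otherwise, any overlap with a reference gene's genomic
#'     extent on the opposite strand;}
#'   \item{lincRNA}{otherwise (intergenic).}
#' }
#'
#' @param candidates Exon table of candidate transcripts.
#' @param reference Exon table of annotated reference transcripts.
#' @return Tibble with `transcript_id` and factor `positional_class` with
#'   levels `lincRNA`, `intronic`, `antisense`, `sense`.
#' @export
classify_position <- function(candidates, reference) {
  validate_annotation(candidates)
  validate_annotation(reference)

  cand_ids <- unique(candidates$transcript_id)
  if (length(cand_ids) == 0) {
    return(tibble(
      transcript_id = character(),
      positional_class = factor(character(), levels = POSITIONAL_CLASSES)
    ))
  }

  ref_exons <- ann_to_granges(reference)

  # Reference transcript extents, their introns, and gene extents.
  ref_tx <- reference %>%
    group_by(.data$transcript_id) %>%
    summarise(
      gene_id = first(.data$gene_id), chrom = first(.data$chrom),
      strand = first(.data$strand),
      start = min(.data$start), end = max(.data$end), .groups = "drop"
    )
  ref_tx_gr <- GenomicRanges::GRanges(
    ref_tx$chrom, IRanges::IRanges(ref_tx$start, ref_tx$end),
    strand = ref_tx$strand, transcript_id = ref_tx$transcript_id
  )
  introns <- GenomicRanges::psetdiff(
    ref_tx_gr,
    S4Vectors::split(ref_exons, ref_exons$transcript_id)[ref_tx$transcript_id]
  )
  introns <- unlist(introns)
  ref_genes <- reference %>%
    group_by(.data$gene_id) %>%
    summarise(
      chrom = first(.data$chrom), strand = first(.data$strand),
      start = min(.data$start), end = max(.data$end), .groups = "drop"
    )
  ref_gene_gr <- GenomicRanges::GRanges(
    ref_genes$chrom, IRanges::IRanges(ref_genes$start, ref_genes$end),
    strand = ref_genes$strand
  )

  cand_exons <- ann_to_granges(candidates)
  cand_extent <- candidates %>%
    group_by(.data$transcript_id) %>%
    summarise(
      chrom = first(.data$chrom), strand = first(.data$strand),
      start = min(.data$start), end = max(.data$end), .groups = "drop"
    )
  cand_extent <- cand_extent[match(cand_ids, cand_extent$transcript_id), ]
  extent_gr <- GenomicRanges::GRanges(
    cand_extent$chrom, IRanges::IRanges(cand_extent$start, cand_extent$end),
    strand = cand_extent$strand
  )

  # sense: same-strand exon-exon overlap (GRanges overlap is strand-aware).
  sense_hit <- GenomicRanges::findOverlaps(cand_exons, ref_exons)
  sense_ids <- unique(cand_exons$transcript_id[S4Vectors::queryHits(sense_hit)])

  # intronic: candidate extent fully inside one intron, same strand.
  intronic_hit <- GenomicRanges::findOverlaps(extent_gr, introns, type = "within")
  intronic_ids <- unique(cand_ids[S4Vectors::queryHits(intronic_hit)])

  # antisense: extent overlaps a gene extent on the opposite strand.
  anti_gr <- extent_gr
  GenomicRanges::strand(anti_gr) <- ifelse(
    as.character(GenomicRanges::strand(extent_gr)) == "+", "-", "+"
  )
  anti_hit <- GenomicRanges::findOverlaps(anti_gr, ref_gene_gr)
  anti_ids <- unique(cand_ids[S4Vectors::queryHits(anti_hit)])

  cls <- dplyr::case_when(
    cand_ids %in% sense_ids ~ "sense",
    cand_ids %in% intronic_ids ~ "intronic",
    cand_ids %in% anti_ids ~ "antisense",
    TRUE ~ "lincRNA"
  )
  tibble(
    transcript_id = cand_ids,
    positional_class = factor(cls, levels = POSITIONAL_CLASSES)
  )
}

#' Class composition of a classified candidate set
#'
#' Counts and percentages (of the total, rounded half-up to one decimal) per
#' positional class. An empty input yields total 0 and `NA` percentages.
#'
#' @param classified Tibble with a `positional_class` column (any additional
#'   columns are ignored).
#' @return A `lnc_composition` tibble with columns `positional_class`,
#'   `count`, `percentage`, and a `total` attribute.
#' @export
#' @examples
#' x <- tibble::tibble(positional_class = factor(
#'   rep(c("lincRNA", "intronic", "antisense", "sense"), c(1721, 337, 896, 102)),
#'   levels = c("lincRNA", "intronic", "antisense", "sense")
#' ))
#' summarize_composition(x)
summarize_composition <- function(classified) {
  check_columns(classified, "positional_class", "classified candidates")
  cls <- factor(classified$positional_class, levels = POSITIONAL_CLASSES)
  counts <- as.integer(table(cls))
  total <- sum(counts)
  out <- tibble(
    positional_class = factor(POSITIONAL_CLASSES, levels = POSITIONAL_CLASSES),
    count = counts,
    percentage = if (total == 0) NA_real_ else round_half_up(100 * counts / total, 1)
  )
  attr(out, "total") <- total
  class(out) <- c("lnc_composition", class(out))
  out
}

#' Three-frame open reading frame screen
#'
#' For each of the three forward reading frames, the length (in nt, including
#' the stop codon) of the longest AUG-to-stop ORF; 0 when a frame has none.
#' Transcripts whose maximal ORF reaches `threshold` are flagged
#' coding-suspect. This is a transparent heuristic stand-in for trained
#' coding-potential predictors, intended as a fallback when external verdict
#' tables are not available; it is not a CPC/CNCI/CPAT reimplementation.
#'
#' @param seq A single nucleotide sequence (ACGT/U; ambiguity codes are an
#'   error).
#' @param threshold ORF length (nt) at or above which the sequence is
#'   flagged coding-suspect. Default 300 nt (a 100-codon ORF).
#' @return A tibble with columns `frame` (1:3) and `longest_orf_nt`, plus
#'   attributes `max_orf_nt` and `coding_suspect`.
#' @export
#' @examples
#' three_frame_orf_screen("ATGAAATAG")
three_frame_orf_screen <- function(seq, threshold = 300) {
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- as_dna(seq)
  if (nchar(seq) < 3) abort("sequence must be at least 3 nt")
  check_alphabet(seq, c("A", "C", "G", "T"), "sequence")

  longest <- vapply(0:2, function(off) longest_orf_in_frame(seq, off), integer(1))
  out <- tibble(frame = 1:3, longest_orf_nt = longest)
  attr(out, "max_orf_nt") <- max(longest)
  attr(out, "coding_suspect") <- max(longest) >= threshold
  attr(out, "threshold") <- threshold
  out
}

# Longest ATG..stop ORF (nt, stop included) in the frame starting at offset.
longest_orf_in_frame <- function(seq, offset) {
  n <- nchar(seq)
  n_codon <- (n - offset) %/% 3
  if (n_codon < 2) return(0L)
  pos <- offset + 3 * (seq_len(n_codon) - 1) + 1
  codons <- substring(seq, pos, pos + 2)
  stops <- which(codons %in% c("TAA", "TAG", "TGA"))
  starts <- which(codons == "ATG")
  if (length(starts) == 0 || length(stops) == 0) return(0L)
  best <- 0L
  for (s in starts) {
    nxt <- stops[stops > s]
    if (length(nxt) == 0) break
    best <- max(best, (nxt[1] - s + 1L) * 3L)
  }
  best
}

#' Coding-potential verdicts from the built-in ORF heuristic
#'
#' Fallback verdict table for [consensus_noncoding()] when external predictor
#' outputs are unavailable: each of the four verdict columns is filled from
#' the single ORF-screen call (coding-suspect iff the longest three-frame ORF
#' reaches `threshold`). The `source` attribute is set to `"orf_heuristic"`
#' so downstream outputs can label the fallback clearly.
#'
#' @param seqs Named character vector of transcript sequences.
#' @param threshold Passed to [three_frame_orf_screen()].
#' @return A verdict tibble (see [consensus_noncoding()]).
#' @export
orf_verdicts <- function(seqs, threshold = 300) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  suspect <- vapply(seqs, function(s) {
    attr(three_frame_orf_screen(s, threshold), "coding_suspect")
  }, logical(1))
  verdict <- unname(ifelse(suspect, "coding", "noncoding"))
  out <- tibble(
    transcript_id = names(seqs),
    cpc_like = verdict, cnci_like = verdict,
    cpat_like = verdict, pfam_like = verdict
  )
  attr(out, "source") <- "orf_heuristic"
  out
}

#' Discover and classify novel lncRNAs
#'
#' End-to-end discovery stage: filter novel transcripts by length and exon
#' count, keep those the four coding-potential predictors unanimously call
#' noncoding, classify survivors positionally against the reference, and
#' summarize class composition. Transcripts lacking any verdict are reported
#' in `$unscored`, not silently dropped.
#'
#' @param annotation Exon table containing reference (annotated) and novel
#'   transcripts (the `annotated` column distinguishes them).
#' @param verdicts Coding-potential verdict table (see
#'   [consensus_noncoding()]); transcripts without a row are unscored.
#' @param min_length,min_exons Passed to [candidate_filter()].
#' @return A `lnc_discovery` object (list) with elements `candidates` (per
#'   novel transcript: metrics, filter outcome, consensus, class),
#'   `composition`, `venn`, `unscored`, and `params`.
#' @export
discover_lncrnas <- function(annotation, verdicts, min_length = 200,
                             min_exons = 2) {
  validate_annotation(annotation)
  if (!"annotated" %in% names(annotation) || anyNA(annotation$annotated)) {
    abort("annotation must carry a complete 'annotated' flag to separate novel transcripts")
  }
  reference <- annotation %>% filter(.data$annotated)
  novel <- annotation %>% filter(!.data$annotated)

  metrics <- transcript_metrics(novel)
  filtered <- candidate_filter(metrics, min_length, min_exons)

  scored_ids <- intersect(filtered$transcript_id, verdicts$transcript_id)
  unscored <- filtered %>%
    filter(.data$pass, !.data$transcript_id %in% scored_ids)
  consensus <- consensus_noncoding(
    verdicts %>% filter(.data$transcript_id %in% scored_ids)
  )

  candidates <- filtered %>%
    left_join(consensus, by = "transcript_id") %>%
    mutate(
      is_lncrna = .data$pass & !is.na(.data$noncoding_consensus) &
        .data$noncoding_consensus
    )

  lnc_ids <- candidates$transcript_id[candidates$is_lncrna]
  classes <- classify_position(
    novel %>% filter(.data$transcript_id %in% lnc_ids),
    reference
  )
  candidates <- candidates %>% left_join(classes, by = "transcript_id")

  res <- list(
    candidates = candidates,
    composition = summarize_composition(
      candidates %>% filter(.data$is_lncrna)
    ),
    venn = venn_counts(verdicts %>% filter(.data$transcript_id %in% scored_ids)),
    unscored = unscored,
    params = list(min_length = min_length, min_exons = min_exons)
  )
  class(res) <- "lnc_discovery"
  res
}

#' @export
print.lnc_discovery <- function(x, ...) {
  comp <- x$composition
  cat("Novel lncRNA discovery\n")
  cat(sprintf(
    "  %d novel transcripts, %d passed filters, %d consensus lncRNAs\n",
    nrow(x$candidates), sum(x$candidates$pass), sum(x$candidates$is_lncrna)
  ))
  for (i in seq_len(nrow(comp))) {
    cat(sprintf(
      "  %-10s %5d (%s%%)\n", comp$positional_class[i], comp$count[i],
      format(comp$percentage[i], nsmall = 1)
    ))
  }
  invisible(x)
}
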