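# Synthetic-data generators with planted ground truth. Every generator emits
# the exact structures the pipeline consumes plus a truth table, so each
# stage can be verified against a known answer at zero noise and exercised
# at realistic noise, with no external downloads.

#' Generator configuration
#'
#' One configuration object drives all synthetic generators. Defaults encode
#' the study conditions the pipeline is designed around: a 0/2/8/24 h
#' LPS time course with n = 3 replicates; a WT/KO x 0h/4h knockout design
#' with 53 planted regulated genes in three expression-profile archetypes
#' among 5000 background genes; a 10-miRNA panel with 6 dual binders whose
#' featured member carries two seed sites on each target.
#'
#' @param seed Integer RNG seed (default 20369).
#' @param n_ref_genes Reference genes in the synthetic annotation.
#' @param n_novel_per_class Planted novel lncRNAs per positional class.
#' @param n_genes Genes in the time-course count matrix.
#' @param timepoints Time-course design, hours post treatment.
#' @param n_reps Replicates per timepoint/group.
#' @param dispersion NB dispersion alpha (variance = mu + alpha * mu^2).
#' @param n_de Named integer vector: planted DE lncRNAs per non-zero
#'   timepoint.
#' @param de_lfc Absolute planted log2 fold change for DE genes.
#' @param n_background Background genes in the knockout screen.
#' @param n_regulated Planted knockout-regulated genes.
#' @param n_low_count Planted genes below the read-count floor in all groups.
#' @param noise_cv Lognormal coefficient of variation of replicate FPKM in
#'   the knockout screen (0 = noise-free).
#' @param gene_length_nt Transcript length used to convert FPKM to counts.
#' @param depth Total mapped fragments per sample.
#' @param panel_size miRNA panel size.
#' @param n_dual_binders Planted miRNAs with sites on both targets.
#' @param featured_sites Sites per target for the featured dual binder.
#' @param lnc_length,utr_length,mirna_length Sequence lengths (nt).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 20369,
                             n_ref_genes = 12,
                             n_novel_per_class = 4,
                             n_genes = 2000,
                             timepoints = c(0, 2, 8, 24),
                             n_reps = 3,
                             dispersion = 0.05,
                             n_de = c("2" = 81, "8" = 433, "24" = 83),
                             de_lfc = 4,
                             n_background = 5000,
                             n_regulated = 53,
                             n_low_count = 200,
                             noise_cv = 0.1,
                             gene_length_nt = 1000,
                             depth = 2e7,
                             panel_size = 10,
                             n_dual_binders = 6,
                             featured_sites = 2,
                             lnc_length = 1925,
                             utr_length = 800,
                             mirna_length = 22) {
  stopifnot(
    seed == floor(seed), n_ref_genes >= 3 * n_novel_per_class,
    n_reps >= 2, dispersion >= 0, all(n_de >= 0),
    sum(n_de) + 1 <= n_genes, n_regulated >= 3, noise_cv >= 0,
    n_dual_binders <= panel_size, featured_sites >= 1,
    mirna_length >= 8
  )
  structure(as.list(environment()), class = "generator_config")
}

# ---- annotation ------------------------------------------------------------

new_tx <- function(id, gene, chrom, starts, ends, strand, annotated) {
  tibble(
    transcript_id = id, gene_id = gene, chrom = chrom,
    start = as.integer(starts), end = as.integer(ends),
    strand = strand, annotated = annotated
  )
}

#' Generate a synthetic annotation with planted positional classes
#'
#' Builds a reference annotation (multi-exon genes with long introns) and
#' plants novel transcripts whose positional class is fixed by construction:
#' intergenic placement (lincRNA), containment in a single intron of a
#' same-strand gene (intronic), opposite-strand overlap with a gene extent
#' (antisense), and same-strand exon overlap (sense). Also plants filter
#' failures (a 150-nt transcript and a single-exon transcript) and two
#' filter-passing transcripts that one coding-potential predictor calls
#' coding, plus the matching four-predictor verdict table.
#'
#' @param cfg A [generator_config()].
#' @return A list: `annotation` (exon table, reference + novel), `verdicts`
#'   (four-predictor table for all novel transcripts), and `truth` (per novel
#'   transcript: `true_class`, `passes_filter`, `fail_reason`,
#'   `noncoding_consensus`, `is_lncrna`).
#' @export
gen_annotation <- function(cfg = generator_config()) {
  set.seed(cfg$seed + 1L)
  n <- cfg$n_novel_per_class
  chrom <- "chr1"
  exon_len <- 300L
  intron_len <- 5000L

  # Reference genes, one 3-exon transcript each, spaced 60 kb apart.
  n_ref <- cfg$n_ref_genes
  base <- 100000L + 60000L * (seq_len(n_ref) - 1L) +
    sample.int(10000L, n_ref, replace = TRUE)
  strands <- sample(c("+", "-"), n_ref, replace = TRUE)
  ref <- purrr::map_dfr(seq_len(n_ref), function(i) {
    s <- base[i]
    starts <- c(s, s + exon_len + intron_len, s + 2L * (exon_len + intron_len))
    new_tx(
      sprintf("ref_tx_%02d", i), sprintf("ref_gene_%02d", i), chrom,
      starts, starts + exon_len - 1L, strands[i], TRUE
    )
  })

  novel <- list()
  truth <- list()
  add_novel <- function(tx, class, passes = TRUE, reason = NA_character_,
                        noncoding = TRUE) {
    novel[[length(novel) + 1]] <<- tx
    truth[[length(truth) + 1]] <<- tibble(
      transcript_id = tx$transcript_id[1],
      true_class = class, passes_filter = passes, fail_reason = reason,
      noncoding_consensus = noncoding,
      is_lncrna = passes && noncoding
    )
  }

  # intronic: inside intron 1 of hosts 1..n, same strand.
  for (i in seq_len(n)) {
    hs <- base[i]
    j <- sample(0:500, 1)
    starts <- c(hs + 1300L + j, hs + 2600L + j)
    add_novel(
      new_tx(
        sprintf("novel_intronic_%02d", i), sprintf("novel_gene_i%02d", i),
        chrom, starts, starts + 249L, strands[i], FALSE
      ),
      "intronic"
    )
  }
  # antisense: opposite strand inside the extent of hosts n+1..2n.
  for (i in seq_len(n)) {
    h <- n + i
    hs <- base[h]
    j <- sample(0:500, 1)
    starts <- c(hs + 1000L + j, hs + 3200L + j)
    add_novel(
      new_tx(
        sprintf("novel_antisense_%02d", i), sprintf("novel_gene_a%02d", i),
        chrom, starts, starts + 299L,
        if (strands[h] == "+") "-" else "+", FALSE
      ),
      "antisense"
    )
  }
  # sense: same strand, first exon overlapping host exon 1 (hosts 2n+1..3n).
  for (i in seq_len(n)) {
    h <- 2L * n + i
    hs <- base[h]
    j <- sample(0:100, 1)
    starts <- c(hs + 100L + j, hs + 1600L + j)
    add_novel(
      new_tx(
        sprintf("novel_sense_%02d", i), sprintf("novel_gene_s%02d", i),
        chrom, starts, starts + c(349L, 299L), strands[h], FALSE
      ),
      "sense"
    )
  }
  # lincRNA: intergenic, in the gap downstream of hosts 3n+1..4n (or wrap).
  for (i in seq_len(n)) {
    h <- (3L * n + i - 1L) %% n_ref + 1L
    hs <- base[h] + 2L * (exon_len + intron_len) + exon_len # gene end
    j <- sample(0:5000, 1)
    starts <- c(hs + 20000L + j, hs + 20700L + j)
    add_novel(
      new_tx(
        sprintf("novel_lincRNA_%02d", i), sprintf("novel_gene_l%02d", i),
        chrom, starts, starts + 399L, sample(c("+", "-"), 1), FALSE
      ),
      "lincRNA"
    )
  }
  # Filter failures and coding-consensus failures, all intergenic.
  tail_pos <- max(base) + 80000L
  add_novel(
    new_tx(
      "novel_short_01", "novel_gene_short", chrom,
      c(tail_pos, tail_pos + 200L), c(tail_pos + 74L, tail_pos + 274L),
      "+", FALSE
    ),
    NA_character_,
    passes = FALSE, reason = "length"
  )
  add_novel(
    new_tx(
      "novel_monoexon_01", "novel_gene_mono", chrom,
      tail_pos + 5000L, tail_pos + 5499L, "+", FALSE
    ),
    NA_character_,
    passes = FALSE, reason = "exons"
  )
  for (i in 1:2) {
    p <- tail_pos + 10000L + 3000L * i
    add_novel(
      new_tx(
        sprintf("novel_coding_%02d", i), sprintf("novel_gene_c%02d", i),
        chrom, c(p, p + 800L), c(p + 399L, p + 1199L), "+", FALSE
      ),
      NA_character_,
      noncoding = FALSE
    )
  }

  novel <- bind_rows(novel)
  truth <- bind_rows(truth)

  verdicts <- tibble(
    transcript_id = truth$transcript_id,
    cpc_like = "noncoding", cnci_like = "noncoding",
    cpat_like = ifelse(truth$noncoding_consensus, "noncoding", "coding"),
    pfam_like = "noncoding"
  )

  annotation <- bind_rows(ref, novel) %>%
    arrange(.data$transcript_id, .data$start) %>%
    group_by(.data$transcript_id) %>%
    mutate(exon_number = row_number()) %>%
    ungroup()

  list(annotation = annotation, verdicts = verdicts, truth = truth)
}

# ---- time-course counts ----------------------------------------------------

#' Generate time-course counts with planted differential expression
#'
#' Negative-binomial counts for a 0/2/8/24 h design with `n_reps` replicates
#' per timepoint. Baseline means are lognormal; a configurable number of
#' genes per non-zero timepoint receives a planted log2 fold change of
#' `de_lfc` magnitude (random sign) at that timepoint only. One designated
#' transcript gets an induction profile peaking at 2 h (16-fold at 2 h,
#' 4-fold at 8 h, back to baseline at 24 h), emulating an acutely
#' LPS-induced lncRNA.
#'
#' @param cfg A [generator_config()].
#' @return A list: `counts` (tibble, genes x samples), `lengths` (tibble
#'   `id`/`length`), `samples` (sample config with `timepoint`), `truth`
#'   (per gene and timepoint: `true_lfc`, `is_de`), `featured_id`.
#' @export
gen_timecourse_counts <- function(cfg = generator_config()) {
  set.seed(cfg$seed + 2L)
  tps <- cfg$timepoints
  stopifnot(tps[1] == 0)
  n <- cfg$n_genes
  ids <- sprintf("lnc_%04d", seq_len(n))
  featured_id <- ids[1]

  base_mu <- rlnorm(n, log(100), 1)
  lfc <- matrix(0, n, length(tps), dimnames = list(ids, paste0("t", tps)))

  # featured transcript: sharp induction at the second timepoint (2 h),
  # partial decay at the third, back to baseline afterwards
  peak <- rep(0, length(tps))
  peak[2] <- 4
  if (length(tps) >= 3) peak[3] <- 2
  lfc[1, ] <- peak

  pool <- 2:n
  for (tp in names(cfg$n_de)) {
    k <- cfg$n_de[[tp]]
    pick <- pool[seq_len(k)]
    pool <- pool[-seq_len(k)]
    sgn <- sample(c(1, -1), k, replace = TRUE, prob = c(0.6, 0.4))
    lfc[pick, paste0("t", tp)] <- sgn * cfg$de_lfc
  }

  samples <- tibble(
    sample = as.vector(outer(
      paste0("t", tps), seq_len(cfg$n_reps),
      function(t, r) sprintf("%s_r%d", t, r)
    )),
    group = rep(paste0("t", tps), cfg$n_reps),
    timepoint = rep(paste0(tps, "h"), cfg$n_reps)
  ) %>% arrange(match(.data$group, paste0("t", tps)))

  counts <- matrix(0L, n, nrow(samples), dimnames = list(ids, samples$sample))
  for (j in seq_len(nrow(samples))) {
    mu <- base_mu * 2^lfc[, samples$group[j]]
    counts[, j] <- if (cfg$dispersion == 0) {
      as.integer(round(mu))
    } else {
      rnbinom(n, mu = mu, size = 1 / cfg$dispersion)
    }
  }

  truth <- as_tibble(lfc) %>%
    mutate(gene_id = ids) %>%
    tidyr::pivot_longer(-"gene_id",
      names_to = "timepoint", values_to = "true_lfc",
      names_prefix = "t"
    ) %>%
    filter(.data$timepoint != "0") %>%
    mutate(is_de = abs(.data$true_lfc) > 2)

  lengths <- tibble(
    id = ids,
    length = round(runif(n, 500, 3000))
  )

  list(
    counts = expr_as_tibble(counts), lengths = lengths, samples = samples,
    truth = truth, featured_id = featured_id
  )
}

# ---- knockout screen -------------------------------------------------------

# Archetype multipliers (wt0, wt4, ko0, ko4) relative to a gene's base FPKM.
# Each satisfies both double-ratio criteria with margin >= 2x:
#   up_up:     r_diff = 15,    r_fc = 8
#   down_down: r_diff = 4.5,   r_fc = 0.2
#   wt_up_ko_down: r_diff ~ -0.11, r_fc = 0.025
KO_ARCHETYPES <- list(
  up_up = c(1, 2, 1, 16),
  down_down = c(1, 0.5, 2.5, 0.25),
  wt_up_ko_down = c(1, 8, 1, 0.2)
)

#' Generate knockout-screen FPKM and count matrices with planted truth
#'
#' Plants `n_regulated` regulated genes whose group-mean FPKM profiles follow
#' three archetypes (knockout hyper-induction; concordant down-regulation
#' with a stronger knockout drop; wildtype induction lost and reversed in the
#' knockout), each with both screen ratios beyond 4 or below 0.25; background
#' genes with both ratios planted in [0.85, 1.2]; and a low-count stratum
#' below the read floor in all four groups. Replicate FPKM values are the
#' group means under multiplicative lognormal noise of coefficient of
#' variation `noise_cv` (0 = exact); counts are derived from FPKM at the
#' configured depth and transcript length.
#'
#' @param cfg A [generator_config()].
#' @return A list: `fpkm`, `counts` (tibbles, genes x 4 groups x `n_reps`
#'   samples), `samples` (sample config), `truth` (per gene: `regulated`,
#'   `archetype`, `low_count`).
#' @export
gen_ko_screen_data <- function(cfg = generator_config()) {
  set.seed(cfg$seed + 3L)
  n_bg <- cfg$n_background
  n_reg <- cfg$n_regulated
  n_low <- cfg$n_low_count

  # background: both ratios in [0.85, 1.2] by construction
  w <- rlnorm(n_bg, log(50), 0.8)
  f <- runif(n_bg, 1.5, 3)
  rho <- runif(n_bg, 0.85, 1.2)
  t_diff <- runif(n_bg, 0.85, 1.2)
  cc <- t_diff * (f - 1) / (f * rho - 1)
  bg <- cbind(w, f * w, cc * w, f * rho * cc * w)

  # regulated: three archetypes, sizes as equal as possible
  arche_names <- names(KO_ARCHETYPES)
  arche_sizes <- c(
    ceiling(n_reg / 3), ceiling(n_reg / 3),
    n_reg - 2 * ceiling(n_reg / 3)
  )
  arche <- rep(arche_names, times = arche_sizes)
  b <- rlnorm(n_reg, log(100), 0.5) + 10
  reg <- t(vapply(
    seq_len(n_reg),
    function(i) b[i] * KO_ARCHETYPES[[arche[i]]],
    numeric(4)
  ))

  # low-count stratum: tiny FPKM everywhere
  low <- matrix(runif(n_low * 4, 0.001, 0.05), ncol = 4)

  means <- rbind(bg, reg, low)
  ids <- c(
    sprintf("bg_%04d", seq_len(n_bg)),
    sprintf("reg_%03d", seq_len(n_reg)),
    sprintf("low_%03d", seq_len(n_low))
  )
  rownames(means) <- ids
  colnames(means) <- c("wt0", "wt4", "ko0", "ko4")

  groups <- c("wt0", "wt4", "ko0", "ko4")
  labels <- c(
    wt0 = "WT_0h", wt4 = "WT_4h", ko0 = "KO_0h", ko4 = "KO_4h"
  )
  samples <- tibble(
    sample = as.vector(vapply(
      groups,
      function(g) sprintf("%s_r%d", labels[g], seq_len(cfg$n_reps)),
      character(cfg$n_reps)
    )),
    group = rep(c("WT", "WT", "KO", "KO"), each = cfg$n_reps),
    timepoint = rep(c("0h", "4h", "0h", "4h"), each = cfg$n_reps)
  )

  n_genes <- nrow(means)
  fpkm <- matrix(0, n_genes, nrow(samples), dimnames = list(ids, samples$sample))
  for (gi in seq_along(groups)) {
    for (r in seq_len(cfg$n_reps)) {
      j <- (gi - 1) * cfg$n_reps + r
      mu <- means[, gi]
      fpkm[, j] <- if (cfg$noise_cv == 0) {
        mu
      } else {
        sdlog <- sqrt(log(1 + cfg$noise_cv^2))
        mu * rlnorm(n_genes, -sdlog^2 / 2, sdlog)
      }
    }
  }
  # counts consistent with FPKM at the configured depth and length
  scale <- (cfg$gene_length_nt / 1000) * (cfg$depth / 1e6)
  counts <- round(fpkm * scale)

  truth <- tibble(
    gene_id = ids,
    regulated = grepl("^reg_", ids),
    archetype = c(rep(NA_character_, n_bg), arche, rep(NA_character_, n_low)),
    low_count = grepl("^low_", ids)
  )

  list(
    fpkm = expr_as_tibble(fpkm, "gene_id"),
    counts = expr_as_tibble(counts, "gene_id"),
    samples = samples, truth = truth
  )
}

# ---- ceRNA panel -----------------------------------------------------------

random_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

plant_site <- function(seq, text, at) {
  stopifnot(at >= 1, at + nchar(text) - 1 <= nchar(seq))
  paste0(
    substr(seq, 1, at - 1), text,
    substr(seq, at + nchar(text), nchar(seq))
  )
}

#' Generate a miRNA panel and target sequences with planted seed sites
#'
#' Random lncRNA and 3'UTR sequences carry planted 8mer seed sites at
#' recorded coordinates: the featured miRNA gets `featured_sites` sites on
#' each target, the remaining dual binders one site on each target, and the
#' rest of the panel one site on at most one target. Panel seeds are
#' rejection-sampled so that no seed core occurs in either target outside
#' the planted loci, and the finished instance is audited with the scanner:
#' the recorded truth is therefore exact (every truth site is found, and no
#' unplanned site exists) for any seed.
#'
#' @param cfg A [generator_config()].
#' @return A list: `lnc`, `utr` (sequences), `panel` (tibble
#'   `name`/`sequence`), `truth` (list with `sites` tibble, `dual_binders`,
#'   `featured`).
#' @export
gen_cerna_panel <- function(cfg = generator_config()) {
  set.seed(cfg$seed + 4L)
  for (attempt in seq_len(25)) {
    inst <- try(build_cerna_instance(cfg), silent = TRUE)
    if (!inherits(inst, "try-error")) {
      return(inst)
    }
  }
  abort("could not generate a clean ceRNA instance in 25 attempts")
}

build_cerna_instance <- function(cfg) {
  lnc <- random_rna(cfg$lnc_length)
  utr <- random_rna(cfg$utr_length)

  # rejection-sample miRNAs whose 6-nt seed core complement is absent from
  # both pristine targets
  seqs <- character(cfg$panel_size)
  cores <- character(cfg$panel_size)
  for (i in seq_len(cfg$panel_size)) {
    repeat {
      s <- random_rna(cfg$mirna_length)
      core <- revcomp_rna(substr(s, 2, 7))
      if (!grepl(core, lnc, fixed = TRUE) && !grepl(core, utr, fixed = TRUE) &&
        !core %in% cores[seq_len(i - 1)]) {
        seqs[i] <- s
        cores[i] <- core
        break
      }
    }
  }
  panel <- tibble(
    name = sprintf("mir%02d", seq_len(cfg$panel_size)),
    sequence = seqs
  )

  # planting plan: which miRNA gets how many sites on which target
  n_dual <- cfg$n_dual_binders
  n_single <- cfg$panel_size - n_dual
  plan_lnc <- c(
    rep(1L, cfg$featured_sites), # featured
    seq_len(n_dual)[-1], # other dual binders
    if (n_single > 0) n_dual + seq_len(ceiling(n_single / 2))
  )
  plan_utr <- c(
    rep(1L, cfg$featured_sites),
    seq_len(n_dual)[-1],
    if (n_single > 1) n_dual + ceiling(n_single / 2) + seq_len(floor(n_single / 2))
  )

  site_text <- function(i) paste0(revcomp_rna(substr(seqs[i], 2, 8)), "A")

  plant_all <- function(seq, mirna_idx, target_label) {
    slots <- 60 + 80 * (seq_along(mirna_idx) - 1) +
      sample(0:20, length(mirna_idx), replace = TRUE)
    planned <- purrr::map2_dfr(mirna_idx, slots, function(i, at) {
      tibble(
        mirna = sprintf("mir%02d", i), target = target_label,
        start = as.integer(at), end = as.integer(at + 7L),
        site_type = factor("8mer", levels = SITE_TYPES)
      )
    })
    for (r in seq_along(mirna_idx)) {
      seq <- plant_site(seq, site_text(mirna_idx[r]), slots[r])
    }
    list(seq = seq, planned = planned)
  }

  pl <- plant_all(lnc, plan_lnc, "lncRNA")
  pu <- plant_all(utr, plan_utr, "3'UTR")
  lnc <- pl$seq
  utr <- pu$seq
  planned <- bind_rows(pl$planned, pu$planned) %>%
    arrange(.data$target, .data$mirna, .data$start)

  # audit: the scanner must find exactly the planned sites
  audit <- shared_sponging_mirnas(lnc, utr, panel, min_sites = 1)
  found <- audit$sites %>%
    select("mirna", "target", "start", "end", "site_type") %>%
    arrange(.data$target, .data$mirna, .data$start)
  same <- nrow(found) == nrow(planned) &&
    isTRUE(all.equal(
      as.data.frame(found), as.data.frame(planned),
      check.attributes = FALSE
    ))
  if (!same) abort("audit mismatch")

  list(
    lnc = lnc, utr = utr, panel = panel,
    truth = list(
      sites = planned,
      dual_binders = sprintf("mir%02d", seq_len(n_dual)),
      featured = "mir01"
    )
  )
}

#' Write a complete synthetic workspace to disk
#'
#' Materializes every pipeline input in its interchange format: annotation
#' GTF, coding-potential verdict TSV, time-course counts/lengths TSVs with a
#' YAML sample config, knockout-screen FPKM/counts TSVs with their config,
#' target/panel FASTA files, and a `truth.json` holding all planted truth.
#'
#' @param cfg A [generator_config()].
#' @param dir Output directory (created if needed).
#' @return Named list of written file paths, invisibly.
#' @export
gen_workspace <- function(cfg = generator_config(), dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)

  ann <- gen_annotation(cfg)
  write_annotation(ann$annotation, p("annotation.gtf"))
  readr::write_tsv(ann$verdicts, p("coding_verdicts.tsv"), progress = FALSE)

  tc <- gen_timecourse_counts(cfg)
  write_expression_table(tc$counts, p("timecourse_counts.tsv"))
  readr::write_tsv(tc$lengths, p("timecourse_lengths.tsv"), progress = FALSE)
  write_sample_config(tc$samples, p("timecourse_samples.yaml"))

  ko <- gen_ko_screen_data(cfg)
  write_expression_table(ko$fpkm, p("ko_fpkm.tsv"))
  write_expression_table(ko$counts, p("ko_counts.tsv"))
  write_sample_config(ko$samples, p("ko_samples.yaml"))

  ce <- gen_cerna_panel(cfg)
  write_fasta(c(lncRNA = ce$lnc), p("lncrna.fa"))
  write_fasta(c(utr = ce$utr), p("utr.fa"))
  write_fasta(setNames(ce$panel$sequence, ce$panel$name), p("mirna_panel.fa"))

  truth <- list(
    annotation = ann$truth,
    timecourse = tc$truth,
    timecourse_featured = tc$featured_id,
    ko_screen = ko$truth,
    cerna_sites = ce$truth$sites,
    cerna_dual_binders = ce$truth$dual_binders,
    cerna_featured = ce$truth$featured,
    config = unclass(cfg)
  )
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(
    annotation = p("annotation.gtf"),
    verdicts = p("coding_verdicts.tsv"),
    timecourse_counts = p("timecourse_counts.tsv"),
    timecourse_lengths = p("timecourse_lengths.tsv"),
    timecourse_samples = p("timecourse_samples.yaml"),
    ko_fpkm = p("ko_fpkm.tsv"),
    ko_counts = p("ko_counts.tsv"),
    ko_samples = p("ko_samples.yaml"),
    lncrna = p("lncrna.fa"),
    utr = p("utr.fa"),
    panel = p("mirna_panel.fa"),
    truth = p("truth.json")
  ))
}
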