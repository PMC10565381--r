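# End-to-end orchestration. Stages communicate only via files in the run
# directory, so any stage's inputs can be replaced by externally produced
# tables (e.g. a DE table from a dedicated DE package) without touching the
# others. Pre-flight validation rejects bad configs before any computation.

PIPELINE_STAGES <- c("generate", "discover", "de", "screen", "cerna")

#' Pipeline run configuration
#'
#' @param outdir Output directory for all stage artifacts and the report.
#' @param seed Seed forwarded to the synthetic generators.
#' @param stages Character vector of stages to run, in fixed order
#'   `generate`, `discover`, `de`, `screen`, `cerna`.
#' @param inputs Named list of input paths (as produced by
#'   [gen_workspace()]); filled in automatically when the `generate` stage is
#'   enabled.
#' @param generator A [generator_config()]; built from `seed` when `NULL`.
#' @param de_lfc_threshold,de_alpha DE calling thresholds (lncRNA default:
#'   `|log2FC| > 2`, adjusted p < 0.05).
#' @param screen A [screen_config()].
#' @param min_sites ceRNA candidacy threshold (sites per target).
#' @return A list of class `run_config`.
#' @export
run_config <- function(outdir, seed = 20369, stages = PIPELINE_STAGES,
                       inputs = list(), generator = NULL,
                       de_lfc_threshold = 2, de_alpha = 0.05,
                       screen = screen_config(), min_sites = 1) {
  stopifnot(all(stages %in% PIPELINE_STAGES))
  if (is.null(generator)) generator <- generator_config(seed = seed)
  structure(
    list(
      outdir = outdir, seed = seed,
      stages = PIPELINE_STAGES[PIPELINE_STAGES %in% stages],
      inputs = inputs, generator = generator,
      de_lfc_threshold = de_lfc_threshold, de_alpha = de_alpha,
      screen = screen, min_sites = min_sites
    ),
    class = "run_config"
  )
}

stage_inputs <- list(
  discover = c("annotation", "verdicts"),
  de = c("timecourse_counts", "timecourse_samples"),
  screen = c("ko_fpkm", "ko_counts", "ko_samples"),
  cerna = c("lncrna", "utr", "panel")
)

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — synthetic-input generation, novel
#' lncRNA discovery, per-timepoint differential expression, the knockout
#' double-ratio screen, and ceRNA candidate discovery — writing each stage's
#' tables before the next starts, then a JSON run report whose counts are
#' asserted to equal the counts in the emitted tables. Re-running with the
#' same config and inputs reproduces identical tables.
#'
#' @param config A [run_config()].
#' @return A `run_report` list (also written to `report.json`), with
#'   per-stage counts, parameter echo, package version and wall-clock time.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(config$outdir, ...)

  # pre-flight: every enabled non-generate stage must have its inputs,
  # either from an enabled generate stage or from the config
  inputs <- config$inputs
  generating <- "generate" %in% config$stages
  for (st in setdiff(config$stages, "generate")) {
    if (generating) next
    missing <- setdiff(stage_inputs[[st]], names(inputs))
    if (length(missing) > 0) {
      abort(sprintf(
        "stage '%s': missing input path(s): %s",
        st, paste(missing, collapse = ", ")
      ), class = "lncscreen_preflight_error")
    }
    absent <- inputs[stage_inputs[[st]]][
      !file.exists(unlist(inputs[stage_inputs[[st]]]))
    ]
    if (length(absent) > 0) {
      abort(sprintf(
        "stage '%s': input file(s) not found: %s",
        st, paste(unlist(absent), collapse = ", ")
      ), class = "lncscreen_preflight_error")
    }
  }

  report <- list(
    package = "lncscreen",
    version = as.character(packageVersion("lncscreen")),
    seed = config$seed,
    stages = list()
  )

  run_stage <- function(name, fn) {
    t0 <- Sys.time()
    out <- fn()
    out$wall_clock_s <- round(as.numeric(Sys.time() - t0, units = "secs"), 3)
    report$stages[[name]] <<- out
  }

  if (generating) {
    run_stage("generate", function() {
      inputs <<- gen_workspace(config$generator, p("inputs"))
      list(n_files = length(inputs))
    })
  }

  if ("discover" %in% config$stages) {
    run_stage("discover", function() {
      ann <- read_annotation(inputs$annotation)
      verdicts <- readr::read_tsv(inputs$verdicts,
        show_col_types = FALSE, progress = FALSE
      )
      disc <- discover_lncrnas(ann, verdicts)
      readr::write_tsv(disc$candidates, p("discovery_candidates.tsv"),
        progress = FALSE
      )
      jsonlite::write_json(
        list(
          composition = as.data.frame(disc$composition),
          total = attr(disc$composition, "total"),
          venn = disc$venn
        ),
        p("discovery_composition.json"),
        auto_unbox = TRUE, digits = NA
      )
      stopifnot(sum(disc$composition$count) == attr(disc$composition, "total"))
      list(
        n_novel = nrow(disc$candidates),
        n_pass_filter = sum(disc$candidates$pass),
        n_lncrna = sum(disc$candidates$is_lncrna),
        composition = setNames(
          as.list(disc$composition$count),
          as.character(disc$composition$positional_class)
        )
      )
    })
  }

  if ("de" %in% config$stages) {
    run_stage("de", function() {
      counts <- read_expression_table(inputs$timecourse_counts)
      samples <- read_sample_config(inputs$timecourse_samples)
      m <- as_expr_matrix(counts)
      tps <- unique(samples$timepoint)
      baseline <- tps[1]
      per_tp <- list()
      for (tp in setdiff(tps, baseline)) {
        keep <- samples$timepoint %in% c(baseline, tp)
        de <- de_analysis(
          m[, samples$sample[keep], drop = FALSE],
          factor(samples$timepoint[keep], levels = c(baseline, tp)),
          lfc_threshold = config$de_lfc_threshold, alpha = config$de_alpha
        )
        tab <- tidy(de) %>% mutate(timepoint = tp, .before = 1)
        per_tp[[tp]] <- tab
      }
      all_de <- bind_rows(per_tp)
      readr::write_tsv(all_de, p("de_results.tsv"), progress = FALSE)
      n_sig <- vapply(per_tp, function(t) sum(t$significant), integer(1))
      list(
        n_genes = nrow(m),
        n_significant = as.list(n_sig)
      )
    })
  }

  if ("screen" %in% config$stages) {
    run_stage("screen", function() {
      fpkm <- read_expression_table(inputs$ko_fpkm)
      counts <- read_expression_table(inputs$ko_counts)
      samples <- read_sample_config(inputs$ko_samples)
      scr <- ko_screen(fpkm, counts, samples, config$screen)
      readr::write_tsv(tidy(scr), p("screen_results.tsv"), progress = FALSE)
      sel <- tidy(scr) %>% filter(.data$selected)
      jsonlite::write_json(
        split(sel$gene_id, as.character(sel$class)),
        p("screen_classes.json"),
        auto_unbox = FALSE
      )
      c(scr$counts, list(classes = as.list(table(droplevels(sel$class)))))
    })
  }

  if ("cerna" %in% config$stages) {
    run_stage("cerna", function() {
      lnc <- read_fasta(inputs$lncrna)[1]
      utr <- read_fasta(inputs$utr)[1]
      panel_seqs <- read_fasta(inputs$panel)
      sponge <- shared_sponging_mirnas(
        unname(lnc), unname(utr),
        tibble(name = names(panel_seqs), sequence = unname(panel_seqs)),
        min_sites = config$min_sites
      )
      readr::write_tsv(sponge$sites, p("cerna_sites.tsv"), progress = FALSE)
      jsonlite::write_json(
        c(sponge$venn, list(
          method = sponge$method,
          dual_binders = sponge$summary$name[sponge$summary$dual_binder]
        )),
        p("cerna_venn.json"),
        auto_unbox = TRUE
      )
      list(
        n_mirnas = nrow(sponge$summary),
        n_sites = nrow(sponge$sites),
        venn = sponge$venn
      )
    })
  }

  report$params <- list(
    de_lfc_threshold = config$de_lfc_threshold, de_alpha = config$de_alpha,
    screen = unclass(config$screen), min_sites = config$min_sites
  )
  class(report) <- "run_report"
  jsonlite::write_json(unclass(report), p("report.json"),
    auto_unbox = TRUE, digits = NA, force = TRUE
  )
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("lncscreen pipeline report (v%s, seed %d)\n", x$version, x$seed))
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  %-9s %6.2fs\n", nm, st$wall_clock_s))
  }
  invisible(x)
}
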