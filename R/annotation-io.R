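# Annotation and tabular/sequence IO: the genomic data model shared by all
# downstream stages is a tidy exon table, one row per exon, 1-based inclusive
# coordinates (GTF convention), with strand restricted to "+"/"-" because the
# positional lncRNA classes are strand-defined.

GTF_COLS <- c(
  "chrom", "source", "feature", "start", "end",
  "score", "strand", "frame", "attributes"
)

abort_format <- function(msg, line = NULL) {
  if (!is.null(line)) msg <- sprintf("line %d: %s", line, msg)
  abort(msg, class = "lncscreen_format_error")
}

gtf_attr <- function(attrs, key) {
  m <- stringr::str_match(attrs, paste0(key, '\\s+"([^"]*)"'))
  m[, 2]
}

#' Read a transcript annotation from a GTF file
#'
#' Parses the exon records of a 9-column GTF file into a tidy exon table:
#' one row per exon, coordinates 1-based inclusive. Every exon record must
#' carry `transcript_id` and `gene_id` attributes; an optional boolean
#' `annotated` attribute marks transcripts present in the reference (as
#' opposed to assembled novel transcripts). Strand must be `+` or `-`:
#' unstranded transcripts cannot be positionally classified and are rejected.
#'
#' @param path Path to a GTF file.
#' @return A tibble with columns `transcript_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `annotated` (logical, `NA` when the attribute
#'   is absent) and `exon_number`, exons sorted by start within transcript.
#' @export
#' @seealso [write_annotation()], [transcript_metrics()]
read_annotation <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("annotation file not found: %s", path))
  }
  lines <- readr::read_lines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) return(empty_annotation())

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9)) {
    i <- which(nf != 9)[1]
    abort_format(
      sprintf("expected 9 tab-separated columns, found %d", nf[i]),
      line_no[i]
    )
  }
  m <- matrix(unlist(fields), ncol = 9, byrow = TRUE)
  colnames(m) <- GTF_COLS
  is_exon <- m[, "feature"] == "exon"
  m <- m[is_exon, , drop = FALSE]
  line_no <- line_no[is_exon]
  if (nrow(m) == 0) return(empty_annotation())

  start <- suppressWarnings(as.integer(m[, "start"]))
  end <- suppressWarnings(as.integer(m[, "end"]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    abort_format("non-integer start/end coordinate", line_no[bad[1]])
  }
  bad <- which(end < start)
  if (length(bad) > 0) {
    abort_format(
      sprintf("end (%d) < start (%d)", end[bad[1]], start[bad[1]]),
      line_no[bad[1]]
    )
  }
  if (any(start < 1)) {
    abort_format("start < 1 (coordinates are 1-based)", line_no[which(start < 1)[1]])
  }
  bad <- which(!m[, "strand"] %in% c("+", "-"))
  if (length(bad) > 0) {
    abort_format(
      sprintf(
        "strand '%s' is not allowed (transcripts must be stranded '+'/'-')",
        m[bad[1], "strand"]
      ),
      line_no[bad[1]]
    )
  }

  tid <- gtf_attr(m[, "attributes"], "transcript_id")
  gid <- gtf_attr(m[, "attributes"], "gene_id")
  for (key in c("transcript_id", "gene_id")) {
    val <- if (key == "transcript_id") tid else gid
    bad <- which(is.na(val) | val == "")
    if (length(bad) > 0) {
      abort_format(sprintf("missing required attribute %s", key), line_no[bad[1]])
    }
  }
  annotated_chr <- gtf_attr(m[, "attributes"], "annotated")
  annotated <- ifelse(is.na(annotated_chr), NA, tolower(annotated_chr) == "true")

  ann <- tibble(
    transcript_id = tid, gene_id = gid,
    chrom = m[, "chrom"], start = start, end = end,
    strand = m[, "strand"], annotated = annotated
  ) %>%
    arrange(.data$transcript_id, .data$start) %>%
    group_by(.data$transcript_id) %>%
    mutate(exon_number = row_number()) %>%
    ungroup()

  validate_annotation(ann)
}

empty_annotation <- function() {
  tibble(
    transcript_id = character(), gene_id = character(),
    chrom = character(), start = integer(), end = integer(),
    strand = character(), annotated = logical(), exon_number = integer()
  )
}

# Structural invariants of the exon table: one chrom/strand per transcript,
# exons sorted and non-overlapping.
validate_annotation <- function(ann) {
  check_columns(
    ann,
    c("transcript_id", "gene_id", "chrom", "start", "end", "strand"),
    "annotation"
  )
  by_tx <- split(seq_len(nrow(ann)), ann$transcript_id)
  for (idx in by_tx) {
    tx <- ann[idx, ]
    if (length(unique(tx$chrom)) > 1 || length(unique(tx$strand)) > 1) {
      abort_format(sprintf(
        "transcript %s has exons on multiple chromosomes or strands",
        tx$transcript_id[1]
      ))
    }
    o <- order(tx$start)
    s <- tx$start[o]
    e <- tx$end[o]
    if (length(s) > 1 && any(s[-1] <= e[-length(e)])) {
      abort_format(sprintf(
        "transcript %s has overlapping exons", tx$transcript_id[1]
      ))
    }
  }
  ann
}

#' Write an exon table back to GTF
#'
#' Inverse of [read_annotation()]: `read -> write -> read` is the identity on
#' transcript ids, exon coordinates and strand.
#'
#' @param ann Exon table as returned by [read_annotation()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(ann, path) {
  ann <- validate_annotation(ann)
  ann <- ann %>%
    group_by(.data$transcript_id) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    mutate(exon_number = row_number()) %>%
    ungroup() %>%
    arrange(.data$chrom, .data$transcript_id, .data$start)
  annot_attr <- ifelse(
    is.na(ann$annotated), "",
    sprintf(' annotated "%s";', ifelse(ann$annotated, "true", "false"))
  )
  lines <- sprintf(
    '%s\tlncscreen\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; exon_number "%d";%s',
    ann$chrom, ann$start, ann$end, ann$strand,
    ann$gene_id, ann$transcript_id, ann$exon_number, annot_attr
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Per-transcript genomic span and spliced length
#'
#' `genome_span()` is the genomic footprint, `max(end) - min(start) + 1`,
#' the "genome span" of a transcript in bp. `transcript_length()` is the
#' spliced (exonic) length in nt, `sum(end - start + 1)` over exons. The
#' span is always `>=` the spliced length, with equality exactly for
#' single-exon transcripts.
#'
#' @param ann Exon table (see [read_annotation()]).
#' @return A tibble with `transcript_id` and the requested quantity.
#' @export
#' @examples
#' exons <- tibble::tibble(
#'   transcript_id = "tx1", gene_id = "g1", chrom = "chr3",
#'   start = c(115636959L, 115638000L, 115641000L),
#'   end = c(115637458L, 115638699L, 115641530L), strand = "+"
#' )
#' genome_span(exons) # 4572 bp
genome_span <- function(ann) {
  check_columns(ann, c("transcript_id", "start", "end"), "annotation")
  ann %>%
    group_by(.data$transcript_id) %>%
    summarise(
      genome_span = max(.data$end) - min(.data$start) + 1L,
      .groups = "drop"
    )
}

#' @rdname genome_span
#' @export
transcript_length <- function(ann) {
  check_columns(ann, c("transcript_id", "start", "end"), "annotation")
  ann %>%
    group_by(.data$transcript_id) %>%
    summarise(
      transcript_length = sum(.data$end - .data$start + 1L),
      .groups = "drop"
    )
}

#' Summarize transcripts of an exon table
#'
#' One row per transcript with exon count, spliced length, genomic span,
#' strand and the `annotated` flag — the working unit for lncRNA candidate
#' filtering.
#'
#' @param ann Exon table (see [read_annotation()]).
#' @return A tibble with one row per transcript.
#' @export
transcript_metrics <- function(ann) {
  check_columns(
    ann,
    c("transcript_id", "gene_id", "chrom", "start", "end", "strand"),
    "annotation"
  )
  if (!"annotated" %in% names(ann)) ann$annotated <- NA
  ann %>%
    group_by(.data$transcript_id) %>%
    summarise(
      gene_id = first(.data$gene_id),
      chrom = first(.data$chrom),
      strand = first(.data$strand),
      annotated = first(.data$annotated),
      n_exons = n(),
      transcript_length = sum(.data$end - .data$start + 1L),
      genome_span = max(.data$end) - min(.data$start) + 1L,
      .groups = "drop"
    )
}

# Exon table -> GRanges (one range per exon) carrying transcript/gene ids.
ann_to_granges <- function(ann) {
  GenomicRanges::GRanges(
    seqnames = ann$chrom,
    ranges = IRanges::IRanges(start = ann$start, end = ann$end),
    strand = ann$strand,
    transcript_id = ann$transcript_id,
    gene_id = ann$gene_id
  )
}

#' Transcripts overlapping a genomic interval
#'
#' Interval lookup over the exon table: a transcript is returned iff at least
#' one of its exons overlaps the query. With `strand = NULL` both strands
#' match; otherwise only exons on the given strand.
#'
#' @param ann Exon table (see [read_annotation()]).
#' @param chrom,start,end Query interval (1-based inclusive).
#' @param strand Optional `"+"`/`"-"` restriction.
#' @return Character vector of transcript ids, sorted.
#' @export
query_overlaps <- function(ann, chrom, start, end, strand = NULL) {
  stopifnot(start >= 1, end >= start)
  gr <- ann_to_granges(ann)
  q <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start, end),
    strand = if (is.null(strand)) "*" else strand
  )
  hits <- GenomicRanges::findOverlaps(q, gr, ignore.strand = is.null(strand))
  sort(unique(gr$transcript_id[S4Vectors::subjectHits(hits)]))
}

#' Read and write FASTA sequence files
#'
#' Sequences are uppercased on read; both `U` and `T` are accepted and
#' preserved as given. Names are truncated at the first whitespace.
#' Duplicate sequence names are an error.
#'
#' @param path File path.
#' @param x Named character vector of sequences (for `write_fasta`).
#' @param width Line width used when writing.
#' @return `read_fasta`: a named character vector (empty for an empty file).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  if (file.size(path) == 0) return(setNames(character(0), character(0)))
  set <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) {
    abort(
      sprintf(
        "duplicate sequence name(s): %s",
        paste(unique(nm[duplicated(nm)]), collapse = ", ")
      ),
      class = "lncscreen_format_error"
    )
  }
  setNames(toupper(as.character(set)), nm)
}

#' @rdname read_fasta
#' @export
write_fasta <- function(x, path, width = 60) {
  stopifnot(is.character(x), !is.null(names(x)))
  set <- Biostrings::BStringSet(x)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read and write labelled expression tables (TSV)
#'
#' Tab-separated matrices with one header row and row labels in the first
#' column — the interchange format for count and FPKM matrices. Non-numeric
#' data cells are an error; duplicate row labels are an error.
#'
#' @param path File path.
#' @param x A tibble whose first column holds row labels, or a matrix with
#'   rownames (for `write_expression_table`).
#' @return `read_expression_table`: a tibble, first column `id`.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("table not found: %s", path))
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tbl)[1] <- "id"
  tbl$id <- as.character(tbl$id)
  if (anyDuplicated(tbl$id)) {
    abort("duplicate row labels in expression table",
      class = "lncscreen_format_error"
    )
  }
  numeric_ok <- vapply(tbl[-1], is.numeric, logical(1))
  if (!all(numeric_ok)) {
    abort(
      sprintf(
        "non-numeric cell(s) in column(s): %s",
        paste(names(tbl[-1])[!numeric_ok], collapse = ", ")
      ),
      class = "lncscreen_format_error"
    )
  }
  tbl
}

#' @rdname read_expression_table
#' @export
write_expression_table <- function(x, path) {
  if (is.matrix(x)) x <- expr_as_tibble(x)
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read and write the sample-design sidecar config (YAML)
#'
#' Maps sample (column) names to their experimental group and timepoint, the
#' metadata the differential-expression and knockout-screen stages need.
#'
#' @param path File path.
#' @param samples A tibble with columns `sample`, `group`, `timepoint`
#'   (for `write_sample_config`).
#' @return `read_sample_config`: a tibble `sample`/`group`/`timepoint`.
#' @export
read_sample_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("sample config not found: %s", path))
  y <- yaml::read_yaml(path)
  if (is.null(y$samples)) abort("sample config must contain a 'samples' list")
  purrr::map_dfr(y$samples, function(s) {
    tibble(
      sample = as.character(s$sample),
      group = as.character(s$group),
      timepoint = as.character(s$timepoint %||% NA_character_)
    )
  })
}

#' @rdname read_sample_config
#' @export
write_sample_config <- function(samples, path) {
  check_columns(samples, c("sample", "group"), "sample config")
  if (!"timepoint" %in% names(samples)) samples$timepoint <- NA_character_
  recs <- purrr::pmap(samples[c("sample", "group", "timepoint")], function(sample, group, timepoint) {
    r <- list(sample = sample, group = group)
    if (!is.na(timepoint)) r$timepoint <- timepoint
    r
  })
  yaml::write_yaml(list(samples = recs), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
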