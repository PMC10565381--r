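# Independent reference implementations used as oracles. These deliberately
# share no code with the package: different algorithms, different string
# handling, so agreement is meaningful.

# Benjamini-Hochberg step-up, written directly from the definition:
# adj_(i) = min_{j >= i} min(1, n * p_(j) / j) on the sorted p-values.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(n)
  running <- 1
  for (i in n:1) {
    running <- min(running, n * ps[i] / i)
    adj[i] <- running
  }
  out <- numeric(n)
  out[o] <- adj
  out
}

# Reverse complement via explicit lookup, independent of the package helper.
oracle_rc <- function(x) {
  comp <- c(A = "U", C = "G", G = "C", U = "A", T = "A")
  paste(rev(comp[strsplit(toupper(x), "")[[1]]]), collapse = "")
}

# Brute-force seed-site scan: test every 6-nt window of the target against
# the seed core, then extend by the m8 base and the A1 anchor, reporting the
# highest-priority class per core locus.
oracle_seed_sites <- function(target, mirna) {
  t <- chartr("T", "U", toupper(target))
  m <- chartr("T", "U", toupper(mirna))
  core <- oracle_rc(substr(m, 2, 7))
  m8 <- substr(oracle_rc(substr(m, 2, 8)), 1, 1)
  n <- nchar(t)
  rows <- list()
  for (j in seq_len(max(n - 5, 0))) {
    if (substr(t, j, j + 5) != core) next
    has_m8 <- j > 1 && substr(t, j - 1, j - 1) == m8
    has_a1 <- j + 6 <= n && substr(t, j + 6, j + 6) == "A"
    if (has_m8 && has_a1) {
      rows[[length(rows) + 1]] <- c(j - 1, j + 6, "8mer")
    } else if (has_m8) {
      rows[[length(rows) + 1]] <- c(j - 1, j + 5, "7mer-m8")
    } else if (has_a1) {
      rows[[length(rows) + 1]] <- c(j, j + 6, "7mer-A1")
    } else {
      rows[[length(rows) + 1]] <- c(j, j + 5, "6mer")
    }
  }
  if (length(rows) == 0) {
    return(data.frame(
      start = integer(), end = integer(), site_type = character()
    ))
  }
  m <- do.call(rbind, rows)
  data.frame(
    start = as.integer(m[, 1]), end = as.integer(m[, 2]),
    site_type = m[, 3], stringsAsFactors = FALSE
  )
}

# Brute-force longest-ORF search: every ATG, scan forward codon by codon.
oracle_orf <- function(seq) {
  s <- chartr("U", "T", toupper(seq))
  n <- nchar(s)
  stops <- c("TAA", "TAG", "TGA")
  vapply(0:2, function(off) {
    best <- 0L
    i <- off + 1
    while (i + 2 <= n) {
      if (substr(s, i, i + 2) == "ATG") {
        j <- i + 3
        while (j + 2 <= n) {
          if (substr(s, j, j + 2) %in% stops) {
            best <- max(best, j + 2 - i + 1L)
            break
          }
          j <- j + 3
        }
      }
      i <- i + 3
    }
    as.integer(best)
  }, integer(1))
}

# Brute-force interval overlap scan over an exon table.
oracle_overlaps <- function(ann, chrom, qs, qe, strand = NULL) {
  hit <- ann$chrom == chrom & ann$start <= qe & ann$end >= qs
  if (!is.null(strand)) hit <- hit & ann$strand == strand
  sort(unique(ann$transcript_id[hit]))
}

# Small constructor for exon tables in classification tests.
make_tx <- function(id, starts, ends, strand = "+", gene = paste0("g_", id),
                    chrom = "chr1", annotated = FALSE) {
  tibble::tibble(
    transcript_id = id, gene_id = gene, chrom = chrom,
    start = as.integer(starts), end = as.integer(ends),
    strand = strand, annotated = annotated
  )
}

random_rna_str <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}
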