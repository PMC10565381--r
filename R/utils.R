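# Shared internal helpers: rounding, sequence alphabets, input checks.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed composition percentages use
#' the conventional half-up rule, so exact halves move away from zero.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(56.25, 3.35), 1)
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Normalize a nucleotide sequence to the RNA or DNA alphabet
#'
#' Sequences are uppercased; `T` and `U` are interchangeable on input. The
#' conversion is lossless, so `as_dna(as_rna(x))` returns the uppercased input.
#'
#' @param x Character vector of sequences.
#' @return Character vector in the requested alphabet.
#' @export
as_rna <- function(x) {
  chartr("Tt", "UU", toupper(x))
}

#' @rdname as_rna
#' @export
as_dna <- function(x) {
  chartr("Uu", "TT", toupper(x))
}

#' Reverse complement in RNA space
#'
#' @param x Character vector of RNA (or DNA; converted) sequences.
#' @return Reverse complement as RNA strings.
#' @export
#' @examples
#' revcomp_rna("ACGGAUC")
revcomp_rna <- function(x) {
  x <- as_rna(x)
  check_alphabet(x, c("A", "C", "G", "U"), what = "sequence")
  vapply(strsplit(chartr("ACGU", "UGCA", x), ""), function(s) {
    paste(rev(s), collapse = "")
  }, character(1))
}

# Abort unless every character of every sequence is in `allowed`.
check_alphabet <- function(x, allowed, what = "sequence") {
  bad <- !vapply(
    strsplit(x, ""),
    function(s) all(s %in% allowed),
    logical(1)
  )
  if (any(bad)) {
    abort(
      sprintf(
        "%s contains characters outside {%s} (ambiguity codes are not supported)",
        what, paste(allowed, collapse = "")
      ),
      class = "lncscreen_alphabet_error"
    )
  }
  invisible(x)
}

# Require named columns in a data frame, with a caller-facing error.
check_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(
      sprintf(
        "%s is missing required column(s): %s",
        what, paste(missing, collapse = ", ")
      ),
      class = "lncscreen_schema_error"
    )
  }
  invisible(df)
}

# Convert an expression tibble (id column + numeric sample columns) to a
# matrix with ids as rownames. Accepts matrices unchanged.
as_expr_matrix <- function(x, id_col = 1L) {
  if (is.matrix(x)) return(x)
  stopifnot(is.data.frame(x))
  ids <- as.character(x[[id_col]])
  m <- as.matrix(x[, -id_col, drop = FALSE])
  if (!is.numeric(m)) {
    abort("expression table contains non-numeric cells",
      class = "lncscreen_format_error"
    )
  }
  rownames(m) <- ids
  m
}

# Matrix -> tibble with an id column, inverse of as_expr_matrix().
expr_as_tibble <- function(m, id_col = "id") {
  out <- as_tibble(m)
  out[[id_col]] <- rownames(m)
  out[, c(id_col, setdiff(names(out), id_col))]
}
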