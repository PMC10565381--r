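# broom-style accessors for the package's result objects.

#' Tidy and glance methods for lncscreen result objects
#'
#' `tidy()` returns the per-feature result table of an object; `glance()`
#' returns a one-row summary.
#'
#' @param x A `lnc_de`, `ko_screen`, `sponge_screen` or `lnc_discovery`
#'   object.
#' @param ... Unused.
#' @return A tibble.
#' @name lncscreen-tidiers
NULL

#' @rdname lncscreen-tidiers
#' @method tidy lnc_de
#' @export
tidy.lnc_de <- function(x, ...) x$table

#' @rdname lncscreen-tidiers
#' @method glance lnc_de
#' @export
glance.lnc_de <- function(x, ...) {
  tibble(
    n_features = nrow(x$table),
    n_significant = sum(x$table$significant),
    lfc_threshold = x$params$lfc_threshold,
    alpha = x$params$alpha,
    method = x$params$method
  )
}

#' @rdname lncscreen-tidiers
#' @method tidy ko_screen
#' @export
tidy.ko_screen <- function(x, ...) x$table

#' @rdname lncscreen-tidiers
#' @method glance ko_screen
#' @export
glance.ko_screen <- function(x, ...) {
  tibble(
    n_input = x$counts$n_input,
    n_removed = x$counts$n_removed,
    n_rejected = x$counts$n_rejected,
    n_selected = x$counts$n_selected,
    ratio_hi = x$config$ratio_hi,
    ratio_lo = x$config$ratio_lo,
    min_reads = x$config$min_reads,
    k = x$k
  )
}

#' @rdname lncscreen-tidiers
#' @method tidy sponge_screen
#' @export
tidy.sponge_screen <- function(x, ...) x$sites

#' @rdname lncscreen-tidiers
#' @method glance sponge_screen
#' @export
glance.sponge_screen <- function(x, ...) {
  tibble(
    n_mirnas = nrow(x$summary),
    n_dual_binders = sum(x$summary$dual_binder),
    lnc_only = x$venn$lnc_only,
    utr_only = x$venn$utr_only,
    both = x$venn$both,
    min_sites = x$min_sites
  )
}

#' @rdname lncscreen-tidiers
#' @method tidy lnc_discovery
#' @export
tidy.lnc_discovery <- function(x, ...) x$candidates

#' @rdname lncscreen-tidiers
#' @method glance lnc_discovery
#' @export
glance.lnc_discovery <- function(x, ...) {
  tibble(
    n_novel = nrow(x$candidates),
    n_pass_filter = sum(x$candidates$pass),
    n_lncrna = sum(x$candidates$is_lncrna),
    total_classified = attr(x$composition, "total")
  )
}
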