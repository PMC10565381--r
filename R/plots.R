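# ggplot2 visualizations for result objects.

#' Plot methods for lncscreen results
#'
#' `autoplot()` renders the standard figure for each result type: a volcano
#' plot for differential expression (`lnc_de`), a profile heatmap ordered by
#' class for the knockout screen (`ko_screen`), a per-miRNA site-count chart
#' for the sponge screen (`sponge_screen`), and a class-composition bar chart
#' for discovery results (`lnc_discovery` or `lnc_composition`).
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name lncscreen-autoplot
NULL

#' @rdname lncscreen-autoplot
#' @method autoplot lnc_de
#' @export
autoplot.lnc_de <- function(object, ...) {
  tab <- object$table %>%
    mutate(neglog10p = -log10(pmax(.data$p_adj, 1e-300)))
  ggplot2::ggplot(tab, ggplot2::aes(
    x = .data$log2FC, y = .data$neglog10p, colour = .data$significant
  )) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_vline(
      xintercept = c(-1, 1) * object$params$lfc_threshold,
      linetype = "dashed", linewidth = 0.3
    ) +
    ggplot2::geom_hline(
      yintercept = -log10(object$params$alpha),
      linetype = "dashed", linewidth = 0.3
    ) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey60", `TRUE` = "firebrick")
    ) +
    ggplot2::labs(
      x = "log2 fold change", y = "-log10 adjusted p",
      colour = "significant", title = "Differential expression (volcano)"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname lncscreen-autoplot
#' @method autoplot ko_screen
#' @export
autoplot.ko_screen <- function(object, ...) {
  sel <- object$table %>% filter(.data$selected)
  if (nrow(sel) == 0) {
    abort("no selected genes to plot")
  }
  m <- as.matrix(sel[SCREEN_FPKM_COLS])
  rownames(m) <- sel$gene_id
  z <- cluster_transform(m)
  long <- expr_as_tibble(z, "gene_id") %>%
    mutate(class = sel$class) %>%
    tidyr::pivot_longer(
      dplyr::all_of(SCREEN_FPKM_COLS),
      names_to = "group", values_to = "z"
    ) %>%
    mutate(
      group = factor(.data$group, levels = SCREEN_FPKM_COLS,
        labels = c("WT 0h", "WT 4h", "KO 0h", "KO 4h")
      ),
      gene_id = factor(.data$gene_id, levels = sel$gene_id[order(sel$class)])
    )
  ggplot2::ggplot(long, ggplot2::aes(.data$group, .data$gene_id, fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "forestgreen", mid = "black", high = "red"
    ) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$class), scales = "free_y", space = "free_y") +
    ggplot2::labs(
      x = NULL, y = NULL, fill = "z(log10 FPKM)",
      title = "Knockout-regulated genes by expression-profile class"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' @rdname lncscreen-autoplot
#' @method autoplot sponge_screen
#' @export
autoplot.sponge_screen <- function(object, ...) {
  long <- object$summary %>%
    tidyr::pivot_longer(c("n_sites_lnc", "n_sites_utr"),
      names_to = "target", values_to = "n_sites"
    ) %>%
    mutate(target = ifelse(.data$target == "n_sites_lnc", "lncRNA", "3'UTR"))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$name, y = .data$n_sites, fill = .data$target,
    alpha = .data$dual_binder
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_alpha_manual(values = c(`FALSE` = 0.4, `TRUE` = 1)) +
    ggplot2::labs(
      x = "miRNA", y = "seed sites", fill = "target", alpha = "dual binder",
      title = "Seed sites per panel miRNA and target"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname lncscreen-autoplot
#' @method autoplot lnc_composition
#' @export
autoplot.lnc_composition <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$positional_class, y = .data$count, fill = .data$positional_class
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.1f%%", .data$percentage)
    ), vjust = -0.3, size = 3) +
    ggplot2::labs(
      x = NULL, y = "candidates",
      title = sprintf("lncRNA positional classes (n = %d)", attr(object, "total"))
    ) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' @rdname lncscreen-autoplot
#' @method autoplot lnc_discovery
#' @export
autoplot.lnc_discovery <- function(object, ...) {
  autoplot.lnc_composition(object$composition)
}
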