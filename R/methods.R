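# tidy()/glance() and autoplot() methods for the pipeline's result classes.

strip_class <- function(x) {
  as_tibble(x)
}

#' @method tidy aging_dmp
#' @export
tidy.aging_dmp <- function(x, ...) strip_class(x)

#' @method glance aging_dmp
#' @export
glance.aging_dmp <- function(x, ...) {
  tibble(n_tested = nrow(x), n_dmp = sum(x$is_dmp),
         n_untestable = attr(x, "n_untestable") %||% 0L,
         frac_positive = mean(x$direction[x$is_dmp] > 0))
}

#' @method tidy aging_deg
#' @export
tidy.aging_deg <- function(x, ...) strip_class(x)

#' @method glance aging_deg
#' @export
glance.aging_deg <- function(x, ...) {
  tibble(n_tested = nrow(x), n_deg = sum(x$is_deg),
         n_fallback = sum(x$fallback),
         n_dropped = attr(x, "n_dropped") %||% 0L)
}

#' @method tidy dmp_tf_link
#' @export
tidy.dmp_tf_link <- function(x, ...) strip_class(x)

#' @method glance dmp_tf_link
#' @export
glance.dmp_tf_link <- function(x, ...) {
  tibble(n_links = nrow(x), n_tf = length(unique(x$tf_gene_id)),
         n_representative = sum(x$representative))
}

#' @method tidy aging_dac
#' @export
tidy.aging_dac <- function(x, ...) strip_class(x)

#' @method glance aging_dac
#' @export
glance.aging_dac <- function(x, ...) {
  tibble(n_output = nrow(x),
         n_significant = sum(x$class != "nonsignificant"),
         n_consistent = sum(x$class == "consistent"),
         n_inconsistent = sum(x$class == "inconsistent"))
}

#' @method tidy target_scan
#' @export
tidy.target_scan <- function(x, ...) strip_class(select(x, -"reversed_ids"))

#' @method tidy target_rank
#' @export
tidy.target_rank <- function(x, ...) strip_class(x)

#' @method glance target_rank
#' @export
glance.target_rank <- function(x, ...) {
  tibble(n_scanned = nrow(x), n_candidate = sum(x$candidate),
         best_node = x$node_id[1], best_n_reversed = x$n_reversed[1])
}

#' @method tidy drug_screen
#' @export
tidy.drug_screen <- function(x, ...) strip_class(x)

#' @method glance drug_screen
#' @export
glance.drug_screen <- function(x, ...) {
  tibble(n_drugs = nrow(x), n_candidate = sum(x$candidate),
         best_drug = x$drug[1], best_n_reversed = x$n_reversed[1])
}

#' Volcano-style plot of age-associated expression changes
#'
#' @param object An `aging_deg` tibble from [call_degs()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot aging_deg
#' @export
autoplot.aging_deg <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lfc_per_year,
                                  y = -log10(pmax(.data$p_adj, 1e-300)),
                                  colour = .data$is_deg)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                                 name = "DEG") +
    ggplot2::labs(x = "log2 fold change per year of age",
                  y = "-log10 adjusted P") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.aging_deg
#' @method autoplot aging_dmp
#' @export
autoplot.aging_dmp <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$r,
                                  y = -log10(pmax(.data$p, 1e-300)),
                                  colour = .data$is_dmp)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "steelblue"),
                                 name = "DMP") +
    ggplot2::labs(x = "Pearson correlation of beta with age", y = "-log10 P") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.aging_deg
#' @method autoplot aging_dac
#' @export
autoplot.aging_dac <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$gene_id, .data$r_age),
                                  y = .data$r_age, fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "correlation of predicted activity with age",
                  fill = "DAC class") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.aging_deg
#' @method autoplot target_rank
#' @export
autoplot.target_rank <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$node_id, -.data$rank),
                                  y = .data$n_reversed, colour = .data$candidate)) +
    ggplot2::geom_segment(ggplot2::aes(xend = stats::reorder(.data$node_id, -.data$rank),
                                       y = 0, yend = .data$n_reversed)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_flip() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                                 name = "candidate") +
    ggplot2::labs(x = NULL, y = "validated DEGs reversed") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.aging_deg
#' @method autoplot drug_screen
#' @export
autoplot.drug_screen <- function(object, ...) {
  d <- as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$drug, .data$n_reversed),
                                  y = .data$n_reversed, fill = .data$candidate)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$n_screenable[1] / 2),
                        linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "seagreen"),
                               name = "candidate") +
    ggplot2::labs(x = NULL, y = "DEG markers reversed (best condition)") +
    ggplot2::theme_minimal()
}
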