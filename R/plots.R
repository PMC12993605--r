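# ggplot2 views of the pipeline's result types. These render the substance
# (fractions, statuses, counts); publication styling is left to the caller.

#' @importFrom ggplot2 aes autoplot geom_boxplot geom_col geom_hline
#'   geom_jitter geom_point facet_wrap ggplot labs scale_x_log10
#'   scale_y_log10 theme_minimal
NULL

#' Plot partner calls as evidence space
#'
#' Maximum MiPner masked fraction against total Binder reads, coloured by
#' status, with the high-tier threshold drawn. Taxa with zero MiPner signal
#' are omitted; zero Binder reads are shown at the axis floor.
#'
#' @param object A `mipner_calls` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mipner_calls <- function(object, ...) {
  cfg <- attr(object, "config")
  df <- as_tibble(as.data.frame(object)) %>%
    filter(.data$max_mipner_fraction > 0) %>%
    mutate(binder_shown = .data$binder_read_total + 0.5)
  ggplot(df, aes(x = .data$binder_shown, y = .data$max_mipner_fraction,
                 colour = .data$status)) +
    geom_point(alpha = 0.8) +
    geom_hline(yintercept = cfg$high_tier_threshold, linetype = "dashed") +
    scale_x_log10() + scale_y_log10() +
    labs(x = "Binder reads (total + 0.5)",
         y = "max MiPner fraction (bait-masked)",
         colour = "status",
         title = "Partner calls: MiPner signal vs Binder presence") +
    theme_minimal()
}

#' Boxplots of per-sample diversity by condition
#'
#' @param diversity Output of [alpha_diversity()].
#' @param metadata Sample metadata tibble.
#' @return A ggplot with one facet per measure.
#' @export
plot_diversity <- function(diversity, metadata) {
  df <- inner_join(diversity, metadata, by = "sample_id") %>%
    tidyr::pivot_longer(all_of(c("richness", "simpson")),
                        names_to = "measure", values_to = "value")
  ggplot(df, aes(x = .data$condition, y = .data$value)) +
    geom_boxplot(outlier.shape = NA) +
    geom_jitter(width = 0.15, height = 0, alpha = 0.7) +
    facet_wrap(~measure, scales = "free_y") +
    labs(x = NULL, y = NULL, title = "Alpha diversity by condition") +
    theme_minimal()
}

#' Stacked composition bars of the most abundant taxa
#'
#' Shows the `top_n` taxa by overall mean fraction; the rest are pooled into
#' "Other".
#'
#' @param rel Relative-abundance tibble.
#' @param metadata Sample metadata tibble.
#' @param top_n Number of taxa shown individually (default 10).
#' @return A ggplot.
#' @export
plot_composition <- function(rel, metadata, top_n = 10) {
  smp <- sample_columns(rel)
  keep <- rel %>%
    mutate(overall = rowMeans(as.matrix(rel[smp]))) %>%
    arrange(desc(.data$overall)) %>%
    slice_head(n = top_n) %>%
    pull(.data$name)
  df <- rel %>%
    mutate(taxon = ifelse(.data$name %in% keep, .data$name, "Other")) %>%
    tidyr::pivot_longer(all_of(smp), names_to = "sample_id", values_to = "fraction") %>%
    group_by(.data$taxon, .data$sample_id) %>%
    summarise(fraction = sum(.data$fraction), .groups = "drop") %>%
    inner_join(metadata, by = "sample_id")
  ggplot(df, aes(x = .data$sample_id, y = .data$fraction, fill = .data$taxon)) +
    geom_col() +
    facet_wrap(~condition, scales = "free_x") +
    labs(x = NULL, y = "relative abundance", fill = NULL,
         title = sprintf("Community composition (top %d taxa)", top_n)) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Bar chart of shared-taxa intersection regions
#'
#' Upset-style counts of the nonempty disjoint regions.
#'
#' @param object A [shared_taxa()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.shared_taxa <- function(object, ...) {
  df <- filter(object$regions, .data$n_taxa > 0) %>%
    arrange(desc(.data$n_taxa)) %>%
    mutate(region = factor(.data$region, levels = .data$region))
  ggplot(df, aes(x = .data$region, y = .data$n_taxa)) +
    geom_col() +
    labs(x = "condition combination (exactly these)", y = "taxa",
         title = "Shared taxa across conditions") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
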