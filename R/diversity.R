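# Alpha diversity, group comparisons and shared-taxa set intersections used in
# the culture-bias analysis.

#' Per-sample richness and Simpson's index of diversity
#'
#' Richness is the number of taxa with at least one read (no abundance floor).
#' Simpson's index of diversity is 1 - sum(p_i^2), the probability that two
#' randomly drawn reads belong to different taxa; an even, diverse community
#' approaches 1. Both are computed with vegan on the table as given (one rank;
#' no bait masking), and the index is invariant to rescaling all counts.
#'
#' @param table Count tibble at a single rank.
#' @return Tibble with columns `sample_id`, `rank`, `richness`, `simpson`.
#'   A sample with zero reads has richness 0 and `simpson = NA`.
#' @export
alpha_diversity <- function(table) {
  assert_count_table(table)
  smp <- sample_columns(table)
  if (length(smp) == 0) abort("table has no sample columns")
  rk <- unique(table$rank)
  rank_label <- if (length(rk) == 1) rk else "MIXED"
  m <- t(as.matrix(table[smp]))  # vegan expects samples as rows
  richness <- if (nrow(table) == 0) rep(0L, length(smp)) else
    as.integer(vegan::specnumber(m))
  simpson <- if (nrow(table) == 0) rep(NA_real_, length(smp)) else
    as.numeric(vegan::diversity(m, index = "simpson"))
  simpson[richness == 0] <- NA_real_
  tibble(sample_id = smp, rank = rank_label,
         richness = richness, simpson = simpson)
}

#' One-way fixed-effects ANOVA
#'
#' Standard between/within mean-squares F with p from the F distribution,
#' computed via [stats::aov()]. The degenerate case of all values identical
#' (both sums of squares zero) is defined as F = 0, p = 1.
#'
#' @param values Numeric response values.
#' @param groups Group labels, same length as `values`; at least two groups
#'   and at least one group with two or more values.
#' @return One-row tibble with `f_stat`, `df_between`, `df_within`, `p_value`,
#'   and a `groups` list-column of the group labels.
#' @export
one_way_anova <- function(values, groups) {
  groups <- as.character(groups)
  if (length(values) != length(groups)) abort("values and groups differ in length")
  k <- length(unique(groups))
  if (k < 2) abort("need at least two groups")
  if (length(values) - k < 1) abort("need at least one group with >= 2 values")
  df_b <- k - 1L
  df_w <- length(values) - k
  if (all(values == values[1])) {
    return(tibble(f_stat = 0, df_between = df_b, df_within = df_w,
                  p_value = 1, groups = list(sort(unique(groups)))))
  }
  fit <- aov(values ~ factor(groups))
  tab <- summary(fit)[[1]]
  f <- tab[["F value"]][1]
  p <- tab[["Pr(>F)"]][1]
  tibble(f_stat = f, df_between = as.integer(tab[["Df"]][1]),
         df_within = as.integer(tab[["Df"]][2]), p_value = p,
         groups = list(sort(unique(groups))))
}

#' Tukey HSD pairwise comparisons
#'
#' All pairwise mean differences with studentized-range adjusted p-values,
#' via [stats::TukeyHSD()]. Requires every group to have at least two values.
#'
#' @inheritParams one_way_anova
#' @return Tibble with one row per pair: `group_a`, `group_b`, `mean_diff`
#'   (a minus b), `adjusted_p`.
#' @export
tukey_hsd <- function(values, groups) {
  groups <- as.character(groups)
  if (length(values) != length(groups)) abort("values and groups differ in length")
  sizes <- table(groups)
  if (length(sizes) < 2) abort("need at least two groups")
  if (any(sizes < 2)) {
    abort(sprintf("group(s) with a single value (%s): Tukey HSD undefined",
                  paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  fit <- aov(values ~ factor(groups))
  hsd <- stats::TukeyHSD(fit)[[1]]
  pairs <- strsplit(rownames(hsd), "-", fixed = TRUE)
  tibble(group_a = vapply(pairs, `[[`, character(1), 1L),
         group_b = vapply(pairs, `[[`, character(1), 2L),
         mean_diff = unname(hsd[, "diff"]),
         adjusted_p = unname(hsd[, "p adj"]))
}

#' Culture-bias comparison across source, culture and co-culture
#'
#' The three-group design used for the culture-bias analysis: soil source
#' (n replicates), soil culture (n), and the two bait co-culture dosages
#' pooled into one "Mixners" group (2n) — giving, with triplicates, an F on
#' (2, 9) degrees of freedom. Runs the one-way ANOVA and Tukey HSD on a
#' per-sample diversity measure.
#'
#' @param diversity Output of [alpha_diversity()].
#' @param metadata Sample metadata tibble.
#' @param response `"richness"` or `"simpson"`.
#' @return List of class `culture_bias_test` with elements `anova` (one-row
#'   tibble), `tukey` (pairwise tibble), `response`, and `data` (the values
#'   and pooled group labels used).
#' @export
culture_bias_test <- function(diversity, metadata,
                              response = c("richness", "simpson")) {
  response <- match.arg(response)
  assert_metadata(metadata)
  df <- inner_join(diversity, metadata, by = "sample_id") %>%
    mutate(group = case_when(
      .data$condition == "SOIL_SOURCE" ~ "soil_source",
      .data$condition == "SOIL_CULTURE" ~ "soil_culture",
      .data$condition %in% c("MIXNER_A", "MIXNER_B") ~ "mixners",
      TRUE ~ NA_character_
    )) %>%
    filter(!is.na(.data$group))
  if (length(unique(df$group)) < 3) {
    abort("need SOIL_SOURCE, SOIL_CULTURE and MIXNER_A/B samples for the culture-bias design")
  }
  vals <- df[[response]]
  if (any(is.na(vals))) abort("diversity values contain NA (all-zero samples?)")
  structure(list(anova = one_way_anova(vals, df$group),
                 tukey = tukey_hsd(vals, df$group),
                 response = response,
                 data = tibble(sample_id = df$sample_id, group = df$group,
                               value = vals)),
            class = "culture_bias_test")
}

#' @export
print.culture_bias_test <- function(x, ...) {
  a <- x$anova
  cat(sprintf("Culture-bias ANOVA on %s: F(%d,%d) = %.4g, p = %.3g\n",
              x$response, a$df_between, a$df_within, a$f_stat, a$p_value))
  invisible(x)
}

#' @rdname culture_bias_test
#' @param x A `culture_bias_test` object.
#' @param ... Unused.
#' @export
tidy.culture_bias_test <- function(x, ...) x$tukey

#' @rdname culture_bias_test
#' @export
glance.culture_bias_test <- function(x, ...) {
  select(x$anova, -all_of("groups"))
}

#' Shared-taxa sets and upset-style region counts
#'
#' A taxon belongs to a condition's set iff any replicate of that condition
#' has at least one read. All `2^k - 1` disjoint intersection regions are
#' enumerated, so the counts satisfy inclusion-exclusion exactly and sum to
#' the size of the union.
#'
#' @param table Count tibble at one rank.
#' @param metadata Sample metadata tibble (>= 2 conditions present).
#' @return List of class `shared_taxa` with elements `sets` (named list of
#'   taxid vectors per condition) and `regions` (tibble with `region` — the
#'   `+`-joined condition combination — `degree`, and `n_taxa`, the count of
#'   taxa in exactly that combination).
#' @export
shared_taxa <- function(table, metadata) {
  assert_count_table(table)
  assert_metadata(metadata)
  smp <- sample_columns(table)
  conds <- intersect(CONDITION_LEVELS,
                     unique(as.character(metadata$condition[metadata$sample_id %in% smp])))
  if (length(conds) < 2) abort("need at least two conditions")
  sets <- lapply(conds, function(cc) {
    ids <- intersect(condition_samples(metadata, cc), smp)
    table$taxid[rowSums(as.matrix(table[ids])) > 0]
  })
  names(sets) <- conds
  membership <- vapply(sets, function(s) table$taxid %in% s,
                       logical(nrow(table)))
  if (nrow(table) == 1) membership <- matrix(membership, nrow = 1,
                                             dimnames = list(NULL, conds))
  k <- length(conds)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  names(combos) <- conds
  regions <- purrr::map_dfr(seq_len(nrow(combos)), function(i) {
    pat <- as.logical(combos[i, ])
    inside <- rep(TRUE, nrow(table))
    for (j in seq_len(k)) {
      inside <- inside & (membership[, j] == pat[j])
    }
    tibble(region = paste(conds[pat], collapse = "+"),
           degree = sum(pat),
           n_taxa = sum(inside))
  })
  structure(list(sets = sets,
                 regions = arrange(regions, desc(.data$degree), .data$region)),
            class = "shared_taxa")
}

#' @export
print.shared_taxa <- function(x, ...) {
  cat(sprintf("Shared taxa across %d conditions; union size %d\n",
              length(x$sets), sum(x$regions$n_taxa)))
  print(filter(x$regions, .data$n_taxa > 0), n = 20)
  invisible(x)
}

#' Taxa lost through culturing
#'
#' The number of taxa present in the reference (source) condition but absent
#' from every replicate of all cultured conditions.
#'
#' @param table Count tibble at one rank.
#' @param metadata Sample metadata tibble.
#' @param reference Source condition (default `"SOIL_SOURCE"`).
#' @param cultured Conditions whose union defines "recovered by culturing"
#'   (default the plated conditions without bait capture: soil culture and the
#'   two co-culture dosages).
#' @return Integer count of lost taxa.
#' @export
taxa_lost <- function(table, metadata, reference = "SOIL_SOURCE",
                      cultured = c("SOIL_CULTURE", "MIXNER_A", "MIXNER_B")) {
  assert_count_table(table)
  assert_metadata(metadata)
  smp <- sample_columns(table)
  present <- function(cond) {
    ids <- intersect(condition_samples(metadata, cond), smp)
    table$taxid[rowSums(as.matrix(table[ids])) > 0]
  }
  ref_set <- present(reference)
  cult_set <- unique(unlist(lapply(cultured, present)))
  length(setdiff(ref_set, cult_set))
}
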