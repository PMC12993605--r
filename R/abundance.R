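# Domain filtering, rank views, relative abundance, bait masking, condition
# means and fold enrichment. All functions take the combined count/abundance
# tibble first and return a tibble, so stages chain with the pipe.
#
# Relative abundances are always fractions in [0, 1] internally; percentages
# appear only in rendered reports.

#' Remove excluded domains and taxid subtrees
#'
#' Drops rows whose `domain` is in `excluded_domains` or whose `taxid` is in
#' `excluded_taxids`. Defaults remove archaeal, viral and human
#' (taxid 9606) reads, the standard cleanup before summarizing bacterial
#' genus/species abundances. A row with no domain annotation is an error —
#' never a silent retention — so tables assembled from sources without lineage
#' (e.g. Bracken alone) must have domains attached first.
#'
#' @param table Count tibble.
#' @param excluded_domains Character vector of domain names to drop.
#' @param excluded_taxids Integer vector of taxids whose rows are dropped.
#' @return The filtered count tibble, other rows untouched.
#' @export
filter_domains <- function(table,
                           excluded_domains = c("Archaea", "Viruses"),
                           excluded_taxids = 9606L) {
  assert_count_table(table)
  if (nrow(table) == 0) return(table)
  if (any(is.na(table$domain))) {
    bad <- table$taxid[is.na(table$domain)]
    abort(sprintf("taxa without domain annotation (taxid %s); cannot filter domains",
                  paste(head(bad, 5), collapse = ", ")))
  }
  table %>%
    filter(!.data$domain %in% excluded_domains,
           !.data$taxid %in% excluded_taxids)
}

#' Restrict a table to one taxonomic rank
#'
#' Keeps rows of the requested rank as-is. Counts are not summed across ranks:
#' the upstream classifier already assigns reads per rank, so a genus view is
#' simply the genus rows. Returns an empty table with a warning when the rank
#' is absent.
#'
#' @param table Count or relative-abundance tibble.
#' @param rank `"GENUS"` or `"SPECIES"` (case-insensitive).
#' @return Tibble containing only rows of that rank.
#' @export
keep_rank <- function(table, rank) {
  rank <- normalize_rank(rank)
  if (!rank %in% c("GENUS", "SPECIES")) {
    abort("rank views are defined for GENUS and SPECIES")
  }
  out <- filter(table, .data$rank == .env$rank)
  if (nrow(out) == 0) {
    warn(sprintf("no rows at rank %s; returning empty table", rank))
  }
  out
}

#' Convert counts to relative abundances
#'
#' Divides each sample column by its total. A sample with zero total reads is
#' left all-zero and recorded in the `zero_samples` attribute rather than
#' producing NaN.
#'
#' @param table Count tibble.
#' @return Tibble of the same shape with fractions; non-flagged columns sum
#'   to 1.
#' @export
to_relative <- function(table) {
  assert_count_table(table)
  smp <- sample_columns(table)
  zero <- character(0)
  out <- table
  for (s in smp) {
    tot <- sum(out[[s]])
    if (tot == 0) {
      zero <- c(zero, s)
    } else {
      out[[s]] <- out[[s]] / tot
    }
  }
  attr(out, "zero_samples") <- zero
  out
}

#' Mask the bait taxon (or genus) and renormalize
#'
#' Removes every row whose name equals `masked`, or whose genus (the first
#' word of the name) equals `masked`, then renormalizes each sample so the
#' remaining fractions sum to 1. Pairwise ratios among retained taxa are
#' preserved exactly. Masking at the genus level removes all species of the
#' bait genus, not just the bait species: spurious same-genus assignments
#' typically derive from the bait's own reads and would otherwise leak bait
#' signal into the partner table.
#'
#' A sample left empty by masking (the bait was 100% of it) becomes all-zero
#' and is added to the `zero_samples` attribute.
#'
#' @param table Relative-abundance tibble (output of [to_relative()]).
#' @param masked Taxon or genus name to remove (character, one or more).
#' @return Renormalized relative-abundance tibble without the masked rows.
#' @export
mask_taxa <- function(table, masked) {
  smp <- sample_columns(table)
  zero <- attr(table, "zero_samples") %||% character(0)
  hit <- table$name %in% masked | genus_of(table$name) %in% masked
  out <- table[!hit, , drop = FALSE]
  for (s in smp) {
    tot <- sum(out[[s]])
    if (tot == 0) {
      if (!s %in% zero) zero <- c(zero, s)
    } else {
      out[[s]] <- out[[s]] / tot
    }
  }
  attr(out, "zero_samples") <- zero
  out
}

#' Per-condition means and standard errors of relative abundance
#'
#' Arithmetic mean and standard error (sample SD / sqrt(n)) of each taxon's
#' fraction over the replicates of each requested condition. With a single
#' replicate the SE is defined as 0, with a warning.
#'
#' @param table Relative-abundance tibble.
#' @param metadata Sample metadata tibble.
#' @param conditions Conditions to summarise; default all conditions present
#'   in `metadata` that have at least one sample column in `table`.
#' @return Tibble with columns `name`, `taxid`, `rank`, `domain`, `condition`,
#'   `mean`, `se`, `n`, one row per taxon x condition.
#' @export
condition_means <- function(table, metadata, conditions = NULL) {
  assert_metadata(metadata)
  smp <- sample_columns(table)
  present <- as.character(metadata$condition[metadata$sample_id %in% smp])
  if (is.null(conditions)) conditions <- unique(present)
  missing <- setdiff(conditions, present)
  if (length(missing) > 0) {
    abort(sprintf("condition(s) %s absent from metadata/table",
                  paste(missing, collapse = ", ")))
  }
  long <- table %>%
    tidyr::pivot_longer(all_of(smp), names_to = "sample_id", values_to = "fraction") %>%
    inner_join(metadata, by = "sample_id") %>%
    mutate(condition = as.character(.data$condition)) %>%
    filter(.data$condition %in% .env$conditions)
  out <- long %>%
    group_by(across(all_of(c(TAXON_COLS, "condition")))) %>%
    summarise(mean = mean(.data$fraction),
              se = if (n() > 1) sd(.data$fraction) / sqrt(n()) else 0,
              n = n(),
              .groups = "drop") %>%
    arrange(match(.data$rank, RANK_LEVELS), .data$taxid,
            match(.data$condition, CONDITION_LEVELS))
  if (any(out$n == 1)) {
    warn("condition(s) with a single replicate: SE reported as 0")
  }
  out
}

#' Fold enrichment between two conditions
#'
#' The enrichment factor of a taxon is the ratio of its mean relative
#' abundance in a numerator condition to a denominator condition (the source
#' community, for partner calling). A positive numerator over a zero
#' denominator is flagged infinite and meets any threshold; 0/0 gives factor
#' 0 and fails. The default threshold of 100 encodes the "at least 100-fold
#' enrichment over the source suspension" rule used to nominate trustworthy
#' partner genera.
#'
#' @param means Output of [condition_means()] containing both conditions.
#' @param numerator,denominator Condition labels.
#' @param threshold Fold-change a taxon must reach (default 100).
#' @return Tibble with columns `name`, `taxid`, `rank`, `numerator_mean`,
#'   `denominator_mean`, `factor`, `infinite`, `meets_threshold`.
#' @export
fold_enrichment <- function(means, numerator, denominator, threshold = 100) {
  need <- c(numerator, denominator)
  if (!all(need %in% means$condition)) {
    abort(sprintf("conditions %s not all present in `means`",
                  paste(need, collapse = ", ")))
  }
  num <- filter(means, .data$condition == numerator)
  den <- filter(means, .data$condition == denominator)
  joined <- inner_join(
    select(num, all_of(c("name", "taxid", "rank")), numerator_mean = "mean"),
    select(den, all_of(c("taxid", "rank")), denominator_mean = "mean"),
    by = c("taxid", "rank")
  )
  if (nrow(joined) != nrow(num) || nrow(joined) != nrow(den)) {
    abort("numerator and denominator summaries cover different taxa")
  }
  ef <- enrichment_factor(joined$numerator_mean, joined$denominator_mean, threshold)
  dplyr::bind_cols(joined, ef)
}

#' Vectorized enrichment-factor arithmetic
#'
#' @param mean_num,mean_den Mean relative abundances (same length).
#' @param threshold Fold-change threshold.
#' @return Tibble with columns `factor`, `infinite`, `meets_threshold`.
#' @export
enrichment_factor <- function(mean_num, mean_den, threshold = 100) {
  if (length(mean_num) != length(mean_den)) {
    abort("mean_num and mean_den must have the same length")
  }
  infinite <- mean_den == 0 & mean_num > 0
  fct <- ifelse(mean_den == 0, 0, mean_num / mean_den)
  tibble(factor = fct,
         infinite = infinite,
         meets_threshold = infinite | fct >= threshold)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
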