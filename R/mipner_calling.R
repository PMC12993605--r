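# Tiered MiPner calling: the decision procedure that separates putative
# microbial partners of the bait from applicator-stick binders and
# non-candidates, at species and genus level.
#
# The species-level rule, applied to the bait-masked relative-abundance table:
#   1. rank taxa by mean masked fraction across the MiPner replicates and keep
#      the top n (default 100);
#   2. any raw read in any Binder replicate disqualifies a candidate
#      (UNASSIGNABLE_BINDER) -- absence in the binder control is defined on
#      raw read counts, the only scale on which zero is well-defined;
#   3. otherwise the candidate is a putative partner, high tier if its masked
#      fraction exceeds the tier threshold (default 1%) in at least one MiPner
#      sample (strictly greater), low tier if it is merely nonzero.
# Taxa outside the top n, or never seen in a MiPner sample, are NOT_CANDIDATE.

#' Classification settings for partner calling
#'
#' @param bait_genus Genus of the bait organism; every row of this genus is
#'   expected to be masked out of the relative table before calling.
#' @param bait_species Full bait species name.
#' @param high_tier_threshold Masked relative abundance a taxon must exceed
#'   (strictly) in at least one MiPner sample to be a high-tier putative
#'   partner. Fraction in (0, 1); default 0.01.
#' @param top_n_species How many of the most abundant MiPner taxa are
#'   considered candidates (default 100).
#' @param enrichment_threshold Fold enrichment over the soil source regarded
#'   as strong (default 100).
#' @return A validated list of class `mipner_config`.
#' @export
mipner_config <- function(bait_genus = "Serratia",
                          bait_species = "Serratia marcescens",
                          high_tier_threshold = 0.01,
                          top_n_species = 100L,
                          enrichment_threshold = 100) {
  errs <- character(0)
  if (!is.character(bait_genus) || length(bait_genus) != 1 || !nzchar(bait_genus))
    errs <- c(errs, "bait_genus must be a non-empty string")
  if (!is.character(bait_species) || length(bait_species) != 1 || !nzchar(bait_species))
    errs <- c(errs, "bait_species must be a non-empty string")
  if (!is.numeric(high_tier_threshold) || length(high_tier_threshold) != 1 ||
      is.na(high_tier_threshold) ||
      high_tier_threshold <= 0 || high_tier_threshold >= 1)
    errs <- c(errs, "high_tier_threshold must lie strictly between 0 and 1")
  if (!is.numeric(top_n_species) || length(top_n_species) != 1 ||
      is.na(top_n_species) || top_n_species < 1)
    errs <- c(errs, "top_n_species must be a positive integer")
  if (!is.numeric(enrichment_threshold) || length(enrichment_threshold) != 1 ||
      is.na(enrichment_threshold) || enrichment_threshold <= 0)
    errs <- c(errs, "enrichment_threshold must be positive")
  if (length(errs) > 0) abort(paste(errs, collapse = "; "))
  structure(list(bait_genus = bait_genus,
                 bait_species = bait_species,
                 high_tier_threshold = high_tier_threshold,
                 top_n_species = as.integer(top_n_species),
                 enrichment_threshold = enrichment_threshold),
            class = "mipner_config")
}

MIPNER_STATUS <- c("PUTATIVE_HIGH", "PUTATIVE_LOW",
                   "UNASSIGNABLE_BINDER", "NOT_CANDIDATE")

# Per-taxon mean/max fractions over the MiPner replicates, in ranking order:
# mean descending, ties by max descending, then taxid ascending.
mipner_ranking <- function(masked_rel, metadata) {
  mip <- condition_samples(metadata, "MIPNER")
  mip <- intersect(mip, sample_columns(masked_rel))
  if (length(mip) == 0) abort("no MIPNER samples in table")
  m <- as.matrix(masked_rel[mip])
  tibble(name = masked_rel$name,
         taxid = masked_rel$taxid,
         rank = masked_rel$rank,
         mean_mipner_fraction = rowMeans(m),
         max_mipner_fraction = apply(m, 1, max)) %>%
    arrange(desc(.data$mean_mipner_fraction),
            desc(.data$max_mipner_fraction),
            .data$taxid)
}

#' Rank candidate taxa by abundance across the MiPner samples
#'
#' Orders taxa of a bait-masked relative table by their mean fraction over the
#' MiPner replicates (ties broken by maximum fraction, then ascending taxid)
#' and returns the top `n` with a nonzero fraction, or all nonzero taxa when
#' fewer than `n` exist.
#'
#' @param masked_rel Bait-masked relative-abundance tibble (species rank).
#' @param metadata Sample metadata tibble.
#' @param n Number of candidates to keep (default 100).
#' @return Tibble of the ranked candidates with columns `name`, `taxid`,
#'   `rank`, `mean_mipner_fraction`, `max_mipner_fraction`.
#' @export
rank_candidate_species <- function(masked_rel, metadata, n = 100) {
  assert_metadata(metadata)
  ranked <- mipner_ranking(masked_rel, metadata)
  ranked %>%
    filter(.data$mean_mipner_fraction > 0 | .data$max_mipner_fraction > 0) %>%
    slice_head(n = n)
}

#' Call putative partners, binders and non-candidates at species level
#'
#' Applies the tiered presence/absence rule (see the package vignette) to the
#' top-`n` taxa of the bait-masked MiPner table. Every taxon of the input
#' receives exactly one status. Each call carries its evidence: MiPner
#' mean/max masked fractions, total raw Binder reads, fold enrichment of the
#' masked mean over the soil source, and a contaminant flag set when the taxon
#' has zero raw reads in every soil-source replicate (possible environmental
#' contamination; reported as a caveat, never a demotion).
#'
#' @param masked_rel Species-rank, bait-masked relative-abundance tibble
#'   covering all samples.
#' @param counts Species-rank raw count tibble over the same samples (used for
#'   the zero-read Binder and soil-source rules).
#' @param metadata Sample metadata tibble; must contain MIPNER and BINDER
#'   samples.
#' @param config A [mipner_config()].
#' @return A tibble of class `mipner_calls`, one row per taxon in
#'   `masked_rel`, with columns `name`, `taxid`, `rank`, `status`,
#'   `mean_mipner_fraction`, `max_mipner_fraction`, `binder_read_total`,
#'   `soil_read_total`, `enrichment_factor`, `enrichment_infinite`,
#'   `meets_enrichment`, `contaminant_flag`, `in_top_n`.
#' @export
call_species_mipners <- function(masked_rel, counts, metadata,
                                 config = mipner_config()) {
  assert_metadata(metadata)
  stopifnot(inherits(config, "mipner_config"))
  if (any(genus_of(masked_rel$name) == config$bait_genus |
          masked_rel$name == config$bait_species)) {
    abort(sprintf("bait genus '%s' still present in masked table; apply mask_taxa() first",
                  config$bait_genus))
  }
  for (cond in c("MIPNER", "BINDER", "SOIL_SOURCE")) condition_samples(metadata, cond)

  ranked <- mipner_ranking(masked_rel, metadata)
  candidates <- rank_candidate_species(masked_rel, metadata, config$top_n_species)

  binder_smp <- intersect(condition_samples(metadata, "BINDER"), sample_columns(counts))
  soil_smp <- intersect(condition_samples(metadata, "SOIL_SOURCE"), sample_columns(counts))
  if (length(binder_smp) == 0) abort("no BINDER samples in count table")
  if (length(soil_smp) == 0) abort("no SOIL_SOURCE samples in count table")
  reads <- tibble(
    taxid = counts$taxid,
    rank = counts$rank,
    binder_read_total = rowSums(as.matrix(counts[binder_smp])),
    soil_read_total = rowSums(as.matrix(counts[soil_smp]))
  )

  enr <- condition_means(masked_rel, metadata,
                         conditions = c("MIPNER", "SOIL_SOURCE")) %>%
    fold_enrichment("MIPNER", "SOIL_SOURCE", config$enrichment_threshold) %>%
    select(all_of(c("taxid", "rank")), enrichment_factor = "factor",
           enrichment_infinite = "infinite", meets_enrichment = "meets_threshold")

  calls <- ranked %>%
    mutate(in_top_n = .data$taxid %in% candidates$taxid) %>%
    left_join(reads, by = c("taxid", "rank")) %>%
    left_join(enr, by = c("taxid", "rank"))
  if (any(is.na(calls$binder_read_total))) {
    abort("count table does not cover every taxon of the masked table")
  }
  calls <- calls %>%
    mutate(
      status = case_when(
        !.data$in_top_n ~ "NOT_CANDIDATE",
        .data$binder_read_total > 0 ~ "UNASSIGNABLE_BINDER",
        .data$max_mipner_fraction > config$high_tier_threshold ~ "PUTATIVE_HIGH",
        .data$max_mipner_fraction > 0 ~ "PUTATIVE_LOW",
        TRUE ~ "NOT_CANDIDATE"
      ),
      status = factor(.data$status, levels = MIPNER_STATUS),
      contaminant_flag = .data$soil_read_total == 0
    ) %>%
    select(all_of(c("name", "taxid", "rank", "status",
                    "mean_mipner_fraction", "max_mipner_fraction",
                    "binder_read_total", "soil_read_total",
                    "enrichment_factor", "enrichment_infinite",
                    "meets_enrichment", "contaminant_flag", "in_top_n")))
  structure(calls, class = c("mipner_calls", class(tibble())),
            config = config)
}

#' Genus-level trust calls
#'
#' A genus is trusted as a partner candidate only if it has zero raw reads in
#' every Binder replicate (no stick affinity at all) and a nonzero mean masked
#' fraction across the MiPner samples. Fold enrichment over the soil source is
#' attached as supporting evidence.
#'
#' @param genus_rel Genus-rank, bait-masked relative-abundance tibble.
#' @param genus_counts Genus-rank raw count tibble over the same samples.
#' @param metadata Sample metadata tibble.
#' @param config A [mipner_config()].
#' @return A tibble of class `genus_trust` with columns `name`, `taxid`,
#'   `rank`, `trusted`, `binder_presence`, `mipner_mean`,
#'   `enrichment_factor`, `enrichment_infinite`, `meets_enrichment`.
#' @export
call_genus_trust <- function(genus_rel, genus_counts, metadata,
                             config = mipner_config()) {
  assert_metadata(metadata)
  stopifnot(inherits(config, "mipner_config"))
  if (any(genus_rel$name == config$bait_genus)) {
    abort(sprintf("bait genus '%s' still present in masked table; apply mask_taxa() first",
                  config$bait_genus))
  }
  for (cond in c("MIPNER", "BINDER", "SOIL_SOURCE")) condition_samples(metadata, cond)
  binder_smp <- intersect(condition_samples(metadata, "BINDER"),
                          sample_columns(genus_counts))
  if (length(binder_smp) == 0) abort("no BINDER samples in count table")

  ranked <- mipner_ranking(genus_rel, metadata)
  reads <- tibble(taxid = genus_counts$taxid, rank = genus_counts$rank,
                  binder_read_total = rowSums(as.matrix(genus_counts[binder_smp])))
  enr <- condition_means(genus_rel, metadata,
                         conditions = c("MIPNER", "SOIL_SOURCE")) %>%
    fold_enrichment("MIPNER", "SOIL_SOURCE", config$enrichment_threshold) %>%
    select(all_of(c("taxid", "rank")), enrichment_factor = "factor",
           enrichment_infinite = "infinite", meets_enrichment = "meets_threshold")

  out <- ranked %>%
    left_join(reads, by = c("taxid", "rank")) %>%
    left_join(enr, by = c("taxid", "rank")) %>%
    mutate(binder_presence = .data$binder_read_total > 0,
           mipner_mean = .data$mean_mipner_fraction,
           trusted = !.data$binder_presence & .data$mipner_mean > 0) %>%
    select(all_of(c("name", "taxid", "rank", "trusted", "binder_presence",
                    "mipner_mean", "enrichment_factor", "enrichment_infinite",
                    "meets_enrichment")))
  structure(out, class = c("genus_trust", class(tibble())), config = config)
}

#' Assemble the classification report
#'
#' Orders calls by status then mean MiPner fraction descending, and computes
#' the tier tally (how many taxa per status).
#'
#' @param calls A `mipner_calls` tibble.
#' @param trust_calls Optional `genus_trust` tibble, appended as a second
#'   section when writing to file.
#' @return A list of class `mipner_report` with elements `calls` (ordered
#'   tibble), `tier_counts` (named integer vector over all four statuses) and
#'   `trust_calls`.
#' @export
classification_report <- function(calls, trust_calls = NULL) {
  ordered <- calls %>%
    arrange(match(.data$status, MIPNER_STATUS),
            desc(.data$mean_mipner_fraction), .data$taxid)
  counts <- table(factor(calls$status, levels = MIPNER_STATUS))
  structure(list(calls = as_tibble(ordered),
                 tier_counts = setNames(as.integer(counts), MIPNER_STATUS),
                 trust_calls = trust_calls),
            class = "mipner_report")
}

#' Write a classification report to TSV
#'
#' One row per taxon, ordered by status then mean fraction descending, with a
#' `#`-prefixed footer giving the tier counts.
#'
#' @param report Output of [classification_report()] (a bare `mipner_calls`
#'   tibble is also accepted).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_classification_report <- function(report, path) {
  if (inherits(report, "mipner_calls")) report <- classification_report(report)
  stopifnot(inherits(report, "mipner_report"))
  body <- report$calls %>% mutate(status = as.character(.data$status))
  readr::write_tsv(body, path, progress = FALSE)
  footer <- sprintf("# %s\t%d", names(report$tier_counts), report$tier_counts)
  cat(footer, file = path, sep = "\n", append = TRUE)
  invisible(path)
}

#' @export
print.mipner_config <- function(x, ...) {
  cat("Partner-calling configuration\n")
  cat(sprintf("  bait: %s (genus %s)\n", x$bait_species, x$bait_genus))
  cat(sprintf("  high tier: masked fraction > %g in >=1 MiPner sample\n",
              x$high_tier_threshold))
  cat(sprintf("  candidates: top %d taxa by mean MiPner fraction\n",
              x$top_n_species))
  cat(sprintf("  strong enrichment: >= %g-fold over soil source\n",
              x$enrichment_threshold))
  invisible(x)
}

#' Tidy and summarise partner calls
#'
#' `tidy()` returns the calls as a plain tibble; `glance()` returns a one-row
#' summary with the tier counts and the configuration thresholds used.
#'
#' @param x A `mipner_calls` tibble.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mipner_calls <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' @rdname tidy.mipner_calls
#' @export
glance.mipner_calls <- function(x, ...) {
  cfg <- attr(x, "config")
  counts <- table(factor(x$status, levels = MIPNER_STATUS))
  high_tier <- sum(x$status %in% c("PUTATIVE_HIGH", "UNASSIGNABLE_BINDER") &
                     x$max_mipner_fraction > cfg$high_tier_threshold)
  tibble(n_taxa = nrow(x),
         n_high_tier = high_tier,
         n_putative_high = as.integer(counts[["PUTATIVE_HIGH"]]),
         n_putative_low = as.integer(counts[["PUTATIVE_LOW"]]),
         n_unassignable_binder = as.integer(counts[["UNASSIGNABLE_BINDER"]]),
         n_not_candidate = as.integer(counts[["NOT_CANDIDATE"]]),
         n_contaminant_flagged = sum(x$contaminant_flag &
                                       x$status %in% c("PUTATIVE_HIGH", "PUTATIVE_LOW")),
         high_tier_threshold = cfg$high_tier_threshold,
         top_n_species = cfg$top_n_species)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
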