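# End-to-end orchestration: ingest -> filter -> rank views -> relative ->
# mask -> diversity -> classify -> reports, with a validated run config and
# deterministic, provenance-stamped outputs.

#' Validate a pipeline run configuration
#'
#' Accepts a YAML file path or a named list. All validation errors are
#' collected and reported together, not first-failure. Classification fields
#' share defaults with [mipner_config()]; filtering fields with
#' [filter_domains()].
#'
#' Recognised fields: `counts` (combined count-table TSV) or `kraken_reports`
#' (named map sample_id -> report path), `metadata` (TSV path, required),
#' `out_dir` (required), `bait_genus`, `bait_species`, `high_tier_threshold`,
#' `top_n_species`, `enrichment_threshold`, `excluded_domains`,
#' `excluded_taxids`.
#'
#' @param config Path to a YAML file, or a named list.
#' @return Validated config list of class `mipner_run_config`.
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a YAML file path or a named list")
  defaults <- list(bait_genus = "Serratia",
                   bait_species = "Serratia marcescens",
                   high_tier_threshold = 0.01,
                   top_n_species = 100L,
                   enrichment_threshold = 100,
                   excluded_domains = c("Archaea", "Viruses"),
                   excluded_taxids = 9606L)
  known <- c(names(defaults), "counts", "kraken_reports", "metadata", "out_dir")
  errs <- character(0)
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    errs <- c(errs, sprintf("unknown field(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, config[intersect(names(config), known)])
  if (is.null(cfg$counts) && is.null(cfg$kraken_reports)) {
    errs <- c(errs, "one of `counts` or `kraken_reports` is required")
  }
  if (!is.null(cfg$counts) && !file.exists(cfg$counts)) {
    errs <- c(errs, sprintf("counts file not found: %s", cfg$counts))
  }
  if (!is.null(cfg$kraken_reports)) {
    if (is.null(names(cfg$kraken_reports)) || any(!nzchar(names(cfg$kraken_reports)))) {
      errs <- c(errs, "kraken_reports must be a named map sample_id -> path")
    } else {
      miss <- !vapply(cfg$kraken_reports, file.exists, logical(1))
      if (any(miss)) {
        errs <- c(errs, sprintf("kraken report(s) not found: %s",
                                paste(unlist(cfg$kraken_reports[miss]), collapse = ", ")))
      }
    }
  }
  if (is.null(cfg$metadata)) {
    errs <- c(errs, "`metadata` is required")
  } else if (!file.exists(cfg$metadata)) {
    errs <- c(errs, sprintf("metadata file not found: %s", cfg$metadata))
  }
  if (is.null(cfg$out_dir)) errs <- c(errs, "`out_dir` is required")
  if (!is.numeric(cfg$high_tier_threshold) ||
      cfg$high_tier_threshold <= 0 || cfg$high_tier_threshold >= 1) {
    errs <- c(errs, "high_tier_threshold must lie strictly between 0 and 1")
  }
  if (!is.numeric(cfg$top_n_species) || cfg$top_n_species < 1) {
    errs <- c(errs, "top_n_species must be a positive integer")
  }
  if (length(errs) > 0) {
    abort(paste0("invalid run config:\n", paste("-", errs, collapse = "\n")))
  }
  structure(cfg, class = "mipner_run_config")
}

write_tsv_with_provenance <- function(x, path, stamp) {
  cat(stamp, "\n", sep = "", file = path)
  readr::write_tsv(x, path, progress = FALSE, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in fixed order — parse/merge (if raw reports are
#' given), domain filtering, genus/species rank views, relative abundance,
#' bait masking, diversity summaries and group tests, shared-taxa regions,
#' partner calling — and writes every result table into `out_dir`. Outputs are
#' deterministic: rerunning on the same inputs and config is byte-identical.
#' Each output starts with a `#` provenance line (package version and config
#' hash).
#'
#' Written files (per rank where that rank is present): `combined_counts.tsv`,
#' `diversity.tsv`, `anova.tsv`, `tukey.tsv`, `upset_regions.tsv`,
#' `mipner_calls.tsv` (species), `genus_trust.tsv` (genus),
#' `condition_means.tsv`.
#'
#' @param config A run config (list, YAML path, or [validate_run_config()]
#'   output).
#' @return Invisibly, a named list with the in-memory results (`counts`,
#'   `metadata`, `diversity`, `anova`, `tukey`, `regions`, `calls`,
#'   `trust`, `files`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "mipner_run_config")) config <- validate_run_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  metadata <- stage("metadata", read_sample_metadata(config$metadata))
  counts <- stage("ingest", {
    if (!is.null(config$counts)) {
      read_count_table(config$counts)
    } else {
      tables <- purrr::imap(config$kraken_reports,
                            function(p, sid) read_kraken_report(p, sid))
      merge_count_tables(unname(tables))
    }
  })
  counts <- stage("domain filter",
                  filter_domains(counts, config$excluded_domains,
                                 config$excluded_taxids))

  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  stamp_cfg <- unclass(config)
  stamp <- sprintf("# mipnr %s | config %s",
                   as.character(utils::packageVersion("mipnr")),
                   rlang::hash(stamp_cfg))
  files <- character(0)
  emit <- function(x, fname) {
    path <- file.path(config$out_dir, fname)
    write_tsv_with_provenance(x, path, stamp)
    files[[fname]] <<- path
  }
  emit(counts[c(TAXON_COLS, sample_columns(counts))], "combined_counts.tsv")

  cls_cfg <- mipner_config(bait_genus = config$bait_genus,
                           bait_species = config$bait_species,
                           high_tier_threshold = config$high_tier_threshold,
                           top_n_species = config$top_n_species,
                           enrichment_threshold = config$enrichment_threshold)

  div_all <- list(); anova_all <- list(); tukey_all <- list()
  region_all <- list(); means_all <- list()
  calls <- NULL; trust <- NULL

  for (rk in c("GENUS", "SPECIES")) {
    view <- suppressWarnings(keep_rank(counts, rk))
    if (nrow(view) == 0) next
    div <- stage(paste("diversity", rk), alpha_diversity(view))
    div_all[[rk]] <- div
    has_bias_design <- all(c("SOIL_SOURCE", "SOIL_CULTURE", "MIXNER_A", "MIXNER_B") %in%
                             as.character(metadata$condition))
    if (has_bias_design) {
      for (resp in c("richness", "simpson")) {
        bt <- stage(paste("anova", rk, resp), culture_bias_test(div, metadata, resp))
        anova_all[[paste(rk, resp)]] <- mutate(glance(bt), rank = rk, response = resp)
        tukey_all[[paste(rk, resp)]] <- mutate(tidy(bt), rank = rk, response = resp)
      }
    }
    st <- stage(paste("shared taxa", rk), shared_taxa(view, metadata))
    region_all[[rk]] <- mutate(st$regions, rank = rk)

    rel <- to_relative(view)
    masked <- mask_taxa(rel, config$bait_genus)
    means_all[[rk]] <- condition_means(masked, metadata)
    if (rk == "SPECIES" &&
        all(c("MIPNER", "BINDER", "SOIL_SOURCE") %in% as.character(metadata$condition))) {
      calls <- stage("species calling",
                     call_species_mipners(masked, view, metadata, cls_cfg))
      rep_path <- file.path(config$out_dir, "mipner_calls.tsv")
      write_classification_report(classification_report(calls), rep_path)
      files[["mipner_calls.tsv"]] <- rep_path
    }
    if (rk == "GENUS" &&
        all(c("MIPNER", "BINDER", "SOIL_SOURCE") %in% as.character(metadata$condition))) {
      trust <- stage("genus trust",
                     call_genus_trust(masked, view, metadata, cls_cfg))
      emit(as_tibble(as.data.frame(trust)), "genus_trust.tsv")
    }
  }
  if (length(div_all) > 0) emit(bind_rows(div_all), "diversity.tsv")
  if (length(anova_all) > 0) emit(bind_rows(anova_all), "anova.tsv")
  if (length(tukey_all) > 0) emit(bind_rows(tukey_all), "tukey.tsv")
  if (length(region_all) > 0) emit(bind_rows(region_all), "upset_regions.tsv")
  if (length(means_all) > 0) emit(bind_rows(means_all), "condition_means.tsv")

  invisible(list(counts = counts, metadata = metadata,
                 diversity = if (length(div_all)) bind_rows(div_all) else NULL,
                 anova = if (length(anova_all)) bind_rows(anova_all) else NULL,
                 tukey = if (length(tukey_all)) bind_rows(tukey_all) else NULL,
                 regions = if (length(region_all)) bind_rows(region_all) else NULL,
                 calls = calls, trust = trust, files = files))
}
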