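# Dirichlet-multinomial generator for complete synthetic bait-capture
# experiments: all six conditions plus planted per-taxon ground truth, so the
# whole pipeline is testable without any sequencing data.
#
# Generative model (one draw of `depth` reads per sample, multinomial):
#   base soil composition  ~ Dirichlet(base_concentration) over the community
#                            taxa; the bait has base fraction 0 (it is not a
#                            soil resident);
#   SOIL_CULTURE           zero out non-culturable taxa, multiply survivors by
#                            a per-taxon lognormal growth factor (drawn once:
#                            growth on a plate is a property of the taxon),
#                            renormalize;
#   MIXNER_A / MIXNER_B    culture composition scaled to (1 - bait fraction),
#                            bait added at two different dosages;
#   BINDER                 culture composition with planted stick binders
#                            up-weighted by binder_capture_weight, no bait;
#   MIPNER                 culture composition with planted partners
#                            up-weighted by mipner_capture_weight (binders
#                            carried over only if binder_carryover), bait
#                            added at bait_fraction_mipner.
#
# Planted roles: binders are the taxa that dominate the plate (largest culture
# fractions — the same organisms that take over the bait-free culture are the
# ones that coat the applicator); planted partners are drawn from the rare
# tail (base fraction below the 25th percentile) among culturable taxa whose
# culture carriage lies in mipner_carriage_band, i.e. rare enough to stay at
# zero reads in the Binder control at the simulated depth yet recoverable
# once boosted by bait capture.

#' Configuration of a synthetic bait-capture experiment
#'
#' Defaults emulate the observed structure of the real experiment: a diverse
#' soil community of hundreds of taxa with a heavy rare tail
#' (`base_concentration` 0.3), a culture bottleneck keeping ~20% of taxa, a
#' bait spiked at 60-80% of reads wherever it was added, a handful of
#' stick-binding taxa dominating the Binder control, and rare soil taxa
#' strongly enriched only in the bait-capture samples.
#'
#' @param n_taxa Community size including the bait (default 800).
#' @param n_replicates Replicates per condition (default 3).
#' @param depth Reads per sample (default 1e6); every sample sums to this
#'   exactly.
#' @param base_concentration Dirichlet concentration of the soil composition
#'   (default 0.3; smaller means a heavier rare tail).
#' @param culturable_fraction Probability a community taxon grows on the plate
#'   (default 0.2).
#' @param growth_sdlog SD (log scale) of the per-taxon lognormal plate growth
#'   factor (default 2; large, so a few genera dominate cultures as observed).
#' @param bait_fraction_mipner Bait fraction of reads in MIPNER samples
#'   (default 0.7).
#' @param bait_fraction_mixner_a,bait_fraction_mixner_b Bait fractions of the
#'   two co-culture dosages (defaults 0.75 and 0.65).
#' @param n_planted_binders Number of planted stick binders (default 5).
#' @param binder_capture_weight Multiplicative stick-binding advantage in the
#'   BINDER condition (default 500).
#' @param n_planted_mipners Number of planted true partners (default 8).
#' @param mipner_capture_weight Multiplicative bait-binding advantage in the
#'   MIPNER condition (default 500).
#' @param mipner_carriage_band Culture-fraction band from which planted
#'   partners are preferentially drawn (default `c(1e-6, 1e-5)`).
#' @param binder_carryover Should planted binders keep their stick advantage
#'   in the MIPNER condition (default `FALSE`)?
#' @param seed Integer seed; required, all randomness flows from it.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_taxa = 800L,
                             n_replicates = 3L,
                             depth = 1e6,
                             base_concentration = 0.3,
                             culturable_fraction = 0.2,
                             growth_sdlog = 2,
                             bait_fraction_mipner = 0.7,
                             bait_fraction_mixner_a = 0.75,
                             bait_fraction_mixner_b = 0.65,
                             n_planted_binders = 5L,
                             binder_capture_weight = 500,
                             n_planted_mipners = 8L,
                             mipner_capture_weight = 500,
                             mipner_carriage_band = c(1e-6, 1e-5),
                             binder_carryover = FALSE,
                             seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("an explicit integer seed is required")
  }
  errs <- character(0)
  if (n_taxa < 10) errs <- c(errs, "n_taxa must be >= 10")
  if (n_replicates < 1) errs <- c(errs, "n_replicates must be >= 1")
  if (depth < 1) errs <- c(errs, "depth must be >= 1")
  if (base_concentration <= 0) errs <- c(errs, "base_concentration must be positive")
  for (p in c(culturable_fraction, bait_fraction_mipner,
              bait_fraction_mixner_a, bait_fraction_mixner_b)) {
    if (p < 0 || p > 1) errs <- c(errs, "fractions must lie in [0, 1]")
  }
  if (n_planted_binders + n_planted_mipners + 1 > n_taxa) {
    errs <- c(errs, "planted role counts exceed n_taxa")
  }
  if (length(errs) > 0) abort(paste(unique(errs), collapse = "; "))
  structure(list(n_taxa = as.integer(n_taxa),
                 n_replicates = as.integer(n_replicates),
                 depth = depth,
                 base_concentration = base_concentration,
                 culturable_fraction = culturable_fraction,
                 growth_sdlog = growth_sdlog,
                 bait_fraction_mipner = bait_fraction_mipner,
                 bait_fraction_mixner_a = bait_fraction_mixner_a,
                 bait_fraction_mixner_b = bait_fraction_mixner_b,
                 n_planted_binders = as.integer(n_planted_binders),
                 binder_capture_weight = binder_capture_weight,
                 n_planted_mipners = as.integer(n_planted_mipners),
                 mipner_capture_weight = mipner_capture_weight,
                 mipner_carriage_band = mipner_carriage_band,
                 binder_carryover = isTRUE(binder_carryover),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Simulate a complete bait-capture experiment
#'
#' Draws one synthetic experiment (six conditions, `n_replicates` samples
#' each) under the generative model described in [synthetic_config()].
#' Deterministic given the config seed; the caller's RNG state is untouched.
#'
#' @param config A [synthetic_config()].
#' @return List of class `mipner_simulation` with elements `counts`
#'   (species-rank count tibble, one column per sample), `metadata` (sample
#'   metadata tibble) and `truth` (per-taxon tibble: `taxid`, `name`, `role`
#'   in BAIT / PLANTED_BINDER / PLANTED_MIPNER / BACKGROUND, `culturable`,
#'   `base_fraction`, `growth_factor`).
#' @export
simulate_mipner <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)

  n <- cfg$n_taxa
  bait <- 1L
  # base soil composition; the bait is not a soil resident
  a <- rgamma(n - 1, cfg$base_concentration)
  base <- c(0, a / sum(a))
  culturable <- c(TRUE, runif(n - 1) < cfg$culturable_fraction)
  growth <- ifelse(culturable, rlnorm(n, 0, cfg$growth_sdlog), 0)
  fcult <- base * growth
  fcult <- fcult / sum(fcult)

  # planted binders: the dominant plate growers (excluding the bait)
  ord <- order(fcult, decreasing = TRUE)
  binders <- setdiff(ord, bait)[seq_len(cfg$n_planted_binders)]

  # planted partners: rare tail, culturable, detectable carriage
  q25 <- stats::quantile(base[-bait], 0.25)
  band <- cfg$mipner_carriage_band
  pool <- setdiff(which(culturable & base < q25 & fcult > 0), c(bait, binders))
  in_band <- pool[fcult[pool] >= band[1] & fcult[pool] <= band[2]]
  if (length(in_band) >= cfg$n_planted_mipners) {
    mipners <- sample(in_band, cfg$n_planted_mipners)
  } else {
    # small communities may not populate the preferred carriage band; fall
    # back to the culturable taxa nearest the band (rare tail first)
    target <- sqrt(prod(band))
    wider <- setdiff(which(culturable & fcult > 0), c(bait, binders))
    by_dist <- wider[order(!(wider %in% pool),
                           abs(log(fcult[wider]) - log(target)))]
    mipners <- head(unique(c(in_band, by_dist)), cfg$n_planted_mipners)
  }
  if (length(mipners) < cfg$n_planted_mipners) {
    abort("too few culturable taxa to plant the requested partners")
  }

  add_bait <- function(p, frac) {
    p <- p * (1 - frac)
    p[bait] <- p[bait] + frac
    p
  }
  w_bind <- rep(1, n); w_bind[binders] <- cfg$binder_capture_weight
  p_bind <- fcult * w_bind
  p_bind <- p_bind / sum(p_bind)
  w_mip <- rep(1, n); w_mip[mipners] <- cfg$mipner_capture_weight
  if (cfg$binder_carryover) w_mip[binders] <- w_mip[binders] * cfg$binder_capture_weight
  p_mip <- fcult * w_mip
  p_mip <- add_bait(p_mip / sum(p_mip), cfg$bait_fraction_mipner)

  profiles <- list(
    SOIL_SOURCE = base,
    SOIL_CULTURE = fcult,
    MIXNER_A = add_bait(fcult, cfg$bait_fraction_mixner_a),
    MIXNER_B = add_bait(fcult, cfg$bait_fraction_mixner_b),
    BINDER = p_bind,
    MIPNER = p_mip
  )

  names_vec <- c("Serratia marcescens",
                 sprintf("taxon_%04d sp.", seq_len(n - 1) + 1L))
  counts <- tibble(name = names_vec,
                   taxid = seq_len(n),
                   rank = "SPECIES",
                   domain = "Bacteria")
  meta <- list()
  for (cond in CONDITION_LEVELS) {
    for (r in seq_len(cfg$n_replicates)) {
      sid <- sprintf("%s_%d", cond, r)
      counts[[sid]] <- as.numeric(rmultinom(1, cfg$depth, profiles[[cond]])[, 1])
      meta[[sid]] <- tibble(sample_id = sid, condition = cond, replicate = r)
    }
  }
  metadata <- bind_rows(meta) %>%
    mutate(condition = factor(.data$condition, levels = CONDITION_LEVELS),
           replicate = as.integer(.data$replicate))

  role <- rep("BACKGROUND", n)
  role[bait] <- "BAIT"
  role[binders] <- "PLANTED_BINDER"
  role[mipners] <- "PLANTED_MIPNER"
  truth <- tibble(taxid = seq_len(n),
                  name = names_vec,
                  role = role,
                  culturable = culturable,
                  base_fraction = base,
                  growth_factor = growth)

  structure(list(counts = counts, metadata = metadata, truth = truth,
                 config = cfg),
            class = "mipner_simulation")
}

#' @export
print.mipner_simulation <- function(x, ...) {
  cat(sprintf("Synthetic bait-capture experiment: %d taxa x %d samples (seed %d)\n",
              nrow(x$counts), nrow(x$metadata), x$config$seed))
  cat(sprintf("  planted: %d binders, %d partners; depth %g reads/sample\n",
              x$config$n_planted_binders, x$config$n_planted_mipners,
              x$config$depth))
  invisible(x)
}

#' Write a simulated experiment as plain-text fixture files
#'
#' Emits `counts.tsv` (combined count table), `metadata.tsv` and `truth.tsv`
#' into a directory; reading them back reproduces the simulated experiment
#' exactly.
#'
#' @param sim A [simulate_mipner()] result.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_fixture <- function(sim, dir) {
  stopifnot(inherits(sim, "mipner_simulation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_count_table(sim$counts, paths[["counts"]])
  write_sample_metadata(sim$metadata, paths[["metadata"]])
  readr::write_tsv(sim$truth, paths[["truth"]], progress = FALSE)
  invisible(paths)
}

#' Score partner calls against planted truth
#'
#' @param calls A `mipner_calls` tibble from [call_species_mipners()].
#' @param truth The `truth` tibble of a [simulate_mipner()] result.
#' @return One-row tibble: `n_planted_mipners`, `n_recovered` (planted
#'   partners called putative, either tier), `recall`, `n_planted_binders`,
#'   `binders_called_putative`, `binders_unassignable`.
#' @export
evaluate_recovery <- function(calls, truth) {
  joined <- inner_join(as_tibble(as.data.frame(calls)),
                       select(truth, all_of(c("taxid", "role"))), by = "taxid")
  putative <- joined$status %in% c("PUTATIVE_HIGH", "PUTATIVE_LOW")
  is_mip <- joined$role == "PLANTED_MIPNER"
  is_bind <- joined$role == "PLANTED_BINDER"
  tibble(n_planted_mipners = sum(is_mip),
         n_recovered = sum(is_mip & putative),
         recall = sum(is_mip & putative) / sum(is_mip),
         n_planted_binders = sum(is_bind),
         binders_called_putative = sum(is_bind & putative),
         binders_unassignable = sum(is_bind & joined$status == "UNASSIGNABLE_BINDER"))
}
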