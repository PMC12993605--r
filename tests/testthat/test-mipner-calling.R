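# The tiered partner-calling decision procedure.

# Build masked relative + raw counts + calls for a community matrix over the
# slim three-condition metadata (3 MiPner, 3 Binder, 3 Soil Source samples).
call_on <- function(m, config = mipner_config(), meta = slim_metadata()) {
  counts <- make_counts(m, sample_ids = meta$sample_id)
  rel <- to_relative(counts)
  calls <- call_species_mipners(rel, counts, meta, config)
  calls
}

test_that("configuration validation reports every problem at once", {
  expect_error(mipner_config(high_tier_threshold = 1.5, top_n_species = 0),
               "high_tier_threshold.*top_n_species")
  expect_error(mipner_config(bait_genus = ""), "bait_genus")
  expect_s3_class(mipner_config(), "mipner_config")
})

test_that("candidates are ranked by mean, then max, then taxid", {
  meta <- slim_metadata()
  m <- rbind(c(0.5, 0.5, 0.5), c(0.3, 0.3, 0.3), c(0.2, 0.2, 0.2))
  tab <- make_counts(cbind(m, matrix(0, 3, 6)), sample_ids = meta$sample_id)
  top2 <- rank_candidate_species(tab, meta, n = 2)
  expect_equal(top2$taxid, c(1L, 2L))

  # equal means, max fractions 6 vs 2: the larger-max taxon ranks first even
  # though its taxid sorts later (exact integer arithmetic keeps means tied)
  tie <- make_counts(cbind(rbind(c(2, 2, 2), c(6, 0, 0)),
                           matrix(0, 2, 6)),
                     taxids = c(1, 2), sample_ids = meta$sample_id)
  ranked <- rank_candidate_species(tie, meta, n = 2)
  expect_equal(ranked$taxid, c(2L, 1L))
})

test_that("candidate ranking agrees with an independent sort oracle", {
  set.seed(31)
  meta <- slim_metadata()
  frac <- matrix(rgamma(200 * 3, 0.2), nrow = 200)
  frac[sample(length(frac), 200)] <- 0
  frac <- sweep(frac, 2, colSums(frac), "/")
  tab <- make_counts(cbind(frac, matrix(0, 200, 6)), sample_ids = meta$sample_id)
  got <- rank_candidate_species(tab, meta, n = 100)
  mn <- rowMeans(frac); mx <- apply(frac, 1, max)
  ord <- order(-mn, -mx, seq_len(200))
  ord <- ord[mn[ord] > 0][1:100]
  expect_equal(got$taxid, as.integer(ord))
})

test_that("statuses follow the tier rules, with a strict high-tier boundary", {
  base <- matrix(0, nrow = 5, ncol = 9)
  base[1, 1:3] <- c(200, 0, 0)      # 2% of MiPner sample 1, no binder reads
  base[2, 1:3] <- c(50, 0, 0)       # 0.5% max, no binder reads
  base[3, 1:3] <- c(3000, 2800, 3000); base[3, 4] <- 12  # strong but stick-bound
  base[4, 1:3] <- c(100, 100, 100); base[4, 1:3] <- 100  # exactly 1% everywhere
  base[5, 4:6] <- 5                 # binder only, never in MiPner
  filler <- matrix(0, nrow = 1, ncol = 9)
  filler[1, 1:3] <- c(6650, 7100, 6900)  # brings MiPner samples to 10000 reads
  m <- rbind(base, filler)
  calls <- call_on(m)
  expect_status(calls, 1, "PUTATIVE_HIGH")
  expect_status(calls, 2, "PUTATIVE_LOW")
  expect_status(calls, 3, "UNASSIGNABLE_BINDER")
  expect_status(calls, 4, "PUTATIVE_LOW")   # exactly at the threshold is low tier
  expect_status(calls, 5, "NOT_CANDIDATE")
  expect_equal(calls$binder_read_total[calls$taxid == 3], 12)
})

test_that("calling refuses unmasked bait and missing control conditions", {
  meta <- slim_metadata()
  tab <- make_counts(matrix(1, 2, 9), names = c("Serratia marcescens", "Alpha a"),
                     sample_ids = meta$sample_id)
  expect_error(call_species_mipners(to_relative(tab), tab, meta),
               "bait genus")
  nob <- meta[meta$condition != "BINDER", ]
  clean <- make_counts(matrix(1, 2, 6), sample_ids = nob$sample_id)
  expect_error(call_species_mipners(to_relative(clean), clean, nob), "BINDER")
})

test_that("calls agree with a literal transcription of the tier rules", {
  meta <- slim_metadata()
  cfg <- mipner_config(top_n_species = 3)
  # exhaustive enumeration: one community taxon plus a constant companion,
  # all 3^6 patterns of {0, 1, 50} across the six informative samples
  pats <- expand.grid(rep(list(c(0, 1, 50)), 6))
  for (i in seq_len(nrow(pats))) {
    m <- rbind(as.numeric(pats[i, ]), rep(20, 6))
    m <- cbind(m, matrix(c(5, 5, 5, 5, 5, 5), nrow = 2, ncol = 3))
    colnames(m) <- NULL
    counts <- make_counts(m, sample_ids = meta$sample_id)
    got <- call_species_mipners(to_relative(counts), counts, meta, cfg)
    want <- oracle_call_species(counts, meta, top_n = 3)
    expect_equal(as.character(got$status[order(got$taxid)]),
                 want$status[order(want$taxid)])
  }
})

test_that("calls match the oracle on random multi-taxon tables", {
  meta <- slim_metadata()
  cfg <- mipner_config(top_n_species = 4)
  set.seed(17)
  for (i in 1:150) {
    counts <- random_counts(6, meta)
    if (all(colSums(as.matrix(counts[meta$sample_id[1:3]])) == 0)) next
    got <- call_species_mipners(to_relative(counts), counts, meta, cfg)
    want <- oracle_call_species(counts, meta, top_n = 4)
    expect_equal(as.character(got$status[order(got$taxid)]),
                 want$status[order(want$taxid)])
  }
})

test_that("every taxon receives exactly one status", {
  set.seed(23)
  meta <- slim_metadata()
  counts <- random_counts(12, meta, alphabet = c(0, 0, 1, 5, 50))
  calls <- call_species_mipners(to_relative(counts), counts, meta,
                                mipner_config(top_n_species = 5))
  expect_equal(nrow(calls), 12)
  expect_false(any(is.na(calls$status)))
  expect_equal(sort(calls$taxid), 1:12)
})

test_that("adding Binder reads only ever moves a taxon toward unassignable", {
  set.seed(29)
  meta <- slim_metadata()
  rank_of <- c(PUTATIVE_HIGH = 1, PUTATIVE_LOW = 1, NOT_CANDIDATE = 2,
               UNASSIGNABLE_BINDER = 3)
  for (i in 1:25) {
    counts <- random_counts(5, meta)
    if (all(colSums(as.matrix(counts[meta$sample_id[1:3]])) == 0)) next
    before <- call_species_mipners(to_relative(counts), counts, meta)
    bumped <- counts
    victim <- sample(5, 1)
    bumped[[meta$sample_id[4]]][victim] <- bumped[[meta$sample_id[4]]][victim] + 7
    after <- call_species_mipners(to_relative(bumped), bumped, meta)
    b <- as.character(before$status[before$taxid == victim])
    a <- as.character(after$status[after$taxid == victim])
    expect_gte(rank_of[[a]], min(rank_of[[b]], 3))
    if (b %in% c("PUTATIVE_HIGH", "PUTATIVE_LOW")) {
      expect_equal(a, "UNASSIGNABLE_BINDER")
    }
  }
})

test_that("calls are invariant to permuting samples within a condition", {
  set.seed(37)
  meta <- slim_metadata()
  counts <- random_counts(8, meta, alphabet = c(0, 1, 5, 50))
  perm_meta <- meta
  perm <- c(3, 1, 2, 6, 4, 5, 9, 7, 8)  # rotate replicates within conditions
  perm_meta$sample_id <- meta$sample_id[perm]
  perm_meta$replicate <- meta$replicate
  calls <- call_species_mipners(to_relative(counts), counts, meta)
  calls_p <- call_species_mipners(to_relative(counts), counts, perm_meta)
  expect_equal(calls[order(calls$taxid), ], calls_p[order(calls_p$taxid), ])
})

test_that("contaminant flag marks taxa absent from every soil-source replicate", {
  meta <- slim_metadata()
  m <- matrix(0, 3, 9)
  m[1, 1:3] <- c(300, 200, 100); m[1, 7:9] <- 5   # in soil
  m[2, 1:3] <- c(100, 50, 10)                     # never in soil: contaminant
  m[3, 1:3] <- c(9600, 9750, 9890); m[3, 7:9] <- 100  # filler, also in soil
  calls <- call_on(m)
  expect_false(calls$contaminant_flag[calls$taxid == 1])
  expect_true(calls$contaminant_flag[calls$taxid == 2])
  # the flag never demotes: taxon 2 is still putative
  expect_true(as.character(calls$status[calls$taxid == 2]) %in%
                c("PUTATIVE_HIGH", "PUTATIVE_LOW"))
  # enrichment over soil source is infinite for soil-absent taxa
  expect_true(calls$enrichment_infinite[calls$taxid == 2])
})

test_that("genus trust requires total binder absence plus MiPner presence", {
  meta <- slim_metadata()
  m <- rbind(c(2720, 2700, 2750, 0, 0, 0, 26, 25, 27),    # trusted, ~100x enriched
             c(5000, 5100, 4900, 3, 0, 0, 500, 480, 520), # stick binder
             c(0, 0, 0, 0, 0, 0, 100, 90, 110),           # absent from MiPner
             c(2280, 2200, 2350, 9997, 10000, 10000, 9374, 9405, 9343))
  counts <- make_counts(m, rank = "GENUS",
                        names = c("Sphingobium", "Pseudomonas", "Quietus", "Filler"),
                        sample_ids = meta$sample_id)
  trust <- call_genus_trust(to_relative(counts), counts, meta)
  get <- function(g) trust[trust$name == g, ]
  expect_true(get("Sphingobium")$trusted)
  expect_true(get("Sphingobium")$meets_enrichment)
  expect_false(get("Pseudomonas")$trusted)
  expect_true(get("Pseudomonas")$binder_presence)
  expect_false(get("Quietus")$trusted)  # no evidence anywhere
  expect_false(get("Quietus")$binder_presence)
})

test_that("classification reports order calls and tally tiers correctly", {
  set.seed(41)
  meta <- slim_metadata()
  counts <- random_counts(10, meta, alphabet = c(0, 1, 5, 50))
  calls <- call_species_mipners(to_relative(counts), counts, meta,
                                mipner_config(top_n_species = 6))
  rep_ <- classification_report(calls)
  tally <- table(factor(calls$status,
                        levels = c("PUTATIVE_HIGH", "PUTATIVE_LOW",
                                   "UNASSIGNABLE_BINDER", "NOT_CANDIDATE")))
  expect_equal(unname(rep_$tier_counts), as.integer(tally))
  expect_equal(sum(rep_$tier_counts), 10)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_classification_report(rep_, path)
  lines <- readLines(path)
  expect_equal(sum(startsWith(lines, "#")), 4)      # one footer line per status
  expect_equal(length(lines), 1 + 10 + 4)           # header + rows + footer

  empty <- classification_report(calls[0, ])
  expect_equal(unname(empty$tier_counts), rep(0L, 4))
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_classification_report(empty, p2)
  expect_equal(length(readLines(p2)), 1 + 0 + 4)

  g <- glance(calls)
  expect_equal(g$n_putative_high + g$n_putative_low + g$n_unassignable_binder +
                 g$n_not_candidate, 10L)
})
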