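# Filtering, rank views, relative abundance, bait masking, condition means
# and fold enrichment.

test_that("domain filtering removes excluded domains and the human subtree", {
  tab <- make_counts(matrix(c(10, 5, 2, 3), ncol = 1),
                     names = c("Alpha a", "Virus v", "Archaeon x", "Homo sapiens"),
                     domain = c("Bacteria", "Viruses", "Archaea", "Eukaryota"),
                     taxids = c(1, 2, 3, 9606))
  out <- filter_domains(tab)
  expect_equal(out$name, "Alpha a")
  expect_equal(out$S1, 10)

  bacteria <- make_counts(matrix(1:3, ncol = 1))
  expect_equal(filter_domains(bacteria), bacteria)      # identity
  expect_equal(filter_domains(out), out)                # idempotent
})

test_that("domain filtering matches a set-comprehension oracle on random taxa", {
  set.seed(11)
  doms <- sample(c("Bacteria", "Archaea", "Viruses", "Eukaryota"), 20, replace = TRUE)
  tab <- make_counts(matrix(sample(0:9, 20, replace = TRUE), ncol = 1),
                     domain = doms)
  out <- filter_domains(tab, excluded_domains = c("Archaea", "Viruses"),
                        excluded_taxids = integer(0))
  keep <- vapply(seq_len(20), function(i) !doms[i] %in% c("Archaea", "Viruses"),
                 logical(1))
  expect_equal(sort(out$taxid), sort(tab$taxid[keep]))
})

test_that("domain filtering never silently retains unannotated taxa", {
  tab <- make_counts(matrix(1:2, ncol = 1), domain = c("Bacteria", NA))
  expect_error(filter_domains(tab), "without domain annotation")
})

test_that("rank views keep only rows of the requested rank, unsummed", {
  tab <- make_counts(matrix(c(60, 40, 25), ncol = 1),
                     rank = c("GENUS", "SPECIES", "SPECIES"))
  g <- keep_rank(tab, "genus")
  expect_equal(g$rank, "GENUS")
  expect_equal(g$S1, 60)
  s <- keep_rank(tab, "SPECIES")
  expect_equal(nrow(s), 2)
  expect_equal(keep_rank(s, "species"), s)  # idempotent

  expect_warning(empty <- keep_rank(s, "genus"), "no rows")
  expect_equal(nrow(empty), 0)

  set.seed(3)
  ranks <- sample(c("GENUS", "SPECIES"), 10, replace = TRUE)
  mixed <- make_counts(matrix(1:10, ncol = 1), rank = ranks)
  expect_equal(nrow(keep_rank(mixed, "species")), sum(ranks == "SPECIES"))
})

test_that("relative abundances divide by column totals, flagging empty samples", {
  tab <- make_counts(cbind(c(5, 5), c(0, 0)))
  rel <- to_relative(tab)
  expect_equal(rel$S1, c(0.5, 0.5))
  expect_equal(rel$S2, c(0, 0))
  expect_equal(attr(rel, "zero_samples"), "S2")

  four <- to_relative(make_counts(matrix(c(3, 5, 2, 10), ncol = 1)))
  expect_equal(four$S1, c(3, 5, 2, 10) / 20)
})

test_that("relative columns sum to one within 1e-9 on random tables", {
  set.seed(21)
  for (i in 1:20) {
    tab <- make_counts(matrix(sample(0:1000, 24, replace = TRUE), nrow = 6))
    rel <- to_relative(tab)
    for (s in sample_columns(rel)) {
      expect_equal(sum(rel[[s]]), 1, tolerance = 1e-9)
    }
  }
})

test_that("bait masking renormalizes and preserves retained-taxa ratios", {
  tab <- make_counts(matrix(c(0.5, 0.25, 0.25), ncol = 1),
                     names = c("Serratia marcescens", "Alpha a", "Beta b"))
  masked <- mask_taxa(tab, "Serratia")
  expect_equal(masked$S1, c(0.5, 0.5))
  expect_equal(nrow(masked), 2)

  nobait <- make_counts(matrix(c(0.6, 0.4), ncol = 1),
                        names = c("Alpha a", "Beta b"))
  expect_equal(mask_taxa(nobait, "Serratia")$S1, nobait$S1)

  # genus masking removes every species of the genus
  multi <- make_counts(matrix(c(0.3, 0.2, 0.5), ncol = 1),
                       names = c("Serratia marcescens", "Serratia ficaria", "Alpha a"))
  expect_equal(mask_taxa(multi, "Serratia")$name, "Alpha a")

  # a sample that was 100% bait becomes a flagged all-zero column
  pure <- make_counts(matrix(c(1, 0), ncol = 1),
                      names = c("Serratia marcescens", "Alpha a"))
  m <- mask_taxa(pure, "Serratia")
  expect_equal(m$S1, 0)
  expect_equal(attr(m, "zero_samples"), "S1")
})

test_that("masking preserves pairwise ratios to 1e-12 and is idempotent", {
  set.seed(5)
  fr <- rgamma(8, 1)
  fr <- fr / sum(fr) * 0.6
  tab <- make_counts(matrix(c(0.4, fr), ncol = 1),
                     names = c("Serratia marcescens",
                               sprintf("taxon_%02d sp.", 1:8)),
                     taxids = 1:9)
  masked <- mask_taxa(tab, "Serratia")
  pre <- fr / fr[1]
  post <- masked$S1 / masked$S1[1]
  expect_equal(post, pre, tolerance = 1e-12)
  expect_equal(mask_taxa(masked, "Serratia"), masked)
})

test_that("condition means and standard errors follow the n-replicate formulas", {
  meta <- slim_metadata()
  tab <- make_counts(matrix(c(0.1, 0.2, 0.3, rep(0.5, 6)), nrow = 1),
                     sample_ids = meta$sample_id)
  cm <- condition_means(tab, meta, "MIPNER")
  expect_equal(cm$mean, 0.2)
  expect_equal(cm$se, 0.1 / sqrt(3), tolerance = 1e-6)
  expect_equal(cm$n, 3L)

  # identical replicates: zero SE
  flat <- condition_means(tab, meta, "BINDER")
  expect_equal(flat$se, 0)

  one_meta <- slim_metadata(n_mipner = 1)
  one <- make_counts(matrix(c(0.4, rep(0.1, 6)), nrow = 1),
                     sample_ids = one_meta$sample_id)
  expect_warning(cm1 <- condition_means(one, one_meta, "MIPNER"), "single replicate")
  expect_equal(cm1$mean, 0.4)
  expect_equal(cm1$se, 0)

  expect_error(condition_means(tab, meta, "MIXNER_A"), "absent")
})

test_that("enrichment factors implement the zero-denominator policy", {
  # division of the published Sphingobium means: 27.2% MiPner over 0.26% soil
  ef <- enrichment_factor(0.272, 0.0026)
  expect_equal(ef$factor, 104.6, tolerance = 1e-3)
  expect_true(ef$meets_threshold)
  expect_false(ef$infinite)

  expect_true(enrichment_factor(0.1, 0)$infinite)
  expect_true(enrichment_factor(0.1, 0)$meets_threshold)

  both0 <- enrichment_factor(0, 0)
  expect_equal(both0$factor, 0)
  expect_false(both0$meets_threshold)

  flat <- enrichment_factor(0.01, 0.01)
  expect_equal(flat$factor, 1)
  expect_false(flat$meets_threshold)
})

test_that("reciprocal enrichment factors multiply to one for positive means", {
  set.seed(9)
  a <- runif(10, 0.01, 0.5)
  b <- runif(10, 0.01, 0.5)
  expect_equal(enrichment_factor(a, b)$factor * enrichment_factor(b, a)$factor,
               rep(1, 10), tolerance = 1e-12)
})

test_that("abundance operations are invariant to row and column permutation", {
  set.seed(13)
  meta <- slim_metadata()
  tab <- make_counts(matrix(sample(0:99, 5 * 9, replace = TRUE), nrow = 5),
                     sample_ids = meta$sample_id)
  prow <- sample(5)
  pcol <- sample(sample_columns(tab))
  shuffled <- tab[prow, c(names(tab)[1:4], pcol)]

  rel <- to_relative(tab)
  rel_sh <- to_relative(shuffled)
  expect_equal(rel_sh[order(prow), names(rel)], rel, ignore_attr = TRUE)

  cm <- condition_means(tab, meta, "MIPNER")
  cm_sh <- condition_means(shuffled, meta, "MIPNER")
  expect_equal(cm_sh, cm)  # output order is normalized
})
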