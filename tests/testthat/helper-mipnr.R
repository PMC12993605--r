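# Fixture builders and independent oracles shared across the suite.

# Build a count tibble from a taxon x sample matrix.
make_counts <- function(counts, names = NULL, rank = "SPECIES",
                        domain = "Bacteria", taxids = NULL,
                        sample_ids = NULL) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  if (is.null(taxids)) taxids <- seq_len(n)
  if (is.null(names)) names <- sprintf("taxon_%03d sp.", taxids)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%d", seq_len(ncol(counts)))
  out <- tibble::tibble(name = names, taxid = as.integer(taxids),
                        rank = rep_len(rank, n), domain = rep_len(domain, n))
  for (j in seq_along(sample_ids)) out[[sample_ids[j]]] <- as.numeric(counts[, j])
  out
}

# Metadata covering all six conditions with n_rep replicates each; sample ids
# are "<CONDITION>_<rep>".
full_metadata <- function(n_rep = 3) {
  conds <- mipner_conditions()
  tibble::tibble(
    sample_id = as.vector(t(outer(conds, seq_len(n_rep), paste, sep = "_"))),
    condition = factor(rep(conds, each = n_rep), levels = conds),
    replicate = rep(seq_len(n_rep), times = length(conds))
  )
}

# One sample per condition except the given ones.
slim_metadata <- function(n_mipner = 3, n_binder = 3, n_soil = 3) {
  tibble::tibble(
    sample_id = c(sprintf("MIPNER_%d", seq_len(n_mipner)),
                  sprintf("BINDER_%d", seq_len(n_binder)),
                  sprintf("SOIL_SOURCE_%d", seq_len(n_soil))),
    condition = factor(rep(c("MIPNER", "BINDER", "SOIL_SOURCE"),
                           c(n_mipner, n_binder, n_soil)),
                       levels = mipner_conditions()),
    replicate = c(seq_len(n_mipner), seq_len(n_binder), seq_len(n_soil))
  )
}

write_lines_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Literal transcription of the tiered species-calling rules, written in base R
# loops, independent of the package implementation. Takes the raw community
# count table (no bait rows), computes per-sample masked fractions, ranks by
# mean (ties: max, then taxid), keeps the top n nonzero, and assigns statuses:
# any Binder read -> UNASSIGNABLE_BINDER; max MiPner fraction strictly above
# the tier threshold -> PUTATIVE_HIGH; nonzero -> PUTATIVE_LOW; otherwise
# NOT_CANDIDATE.
oracle_call_species <- function(counts, metadata, top_n = 100, threshold = 0.01) {
  smp <- setdiff(names(counts), c("name", "taxid", "rank", "domain"))
  mip <- metadata$sample_id[metadata$condition == "MIPNER"]
  bind <- metadata$sample_id[metadata$condition == "BINDER"]
  m <- as.matrix(counts[intersect(smp, mip)])
  frac <- m
  for (j in seq_len(ncol(m))) {
    tot <- sum(m[, j])
    frac[, j] <- if (tot == 0) 0 else m[, j] / tot
  }
  mn <- rowMeans(frac)
  mx <- apply(frac, 1, max)
  ord <- order(-mn, -mx, counts$taxid)
  ord <- ord[mn[ord] > 0 | mx[ord] > 0]
  top <- ord[seq_len(min(top_n, length(ord)))]
  binder_reads <- rowSums(as.matrix(counts[intersect(smp, bind)]))
  status <- rep("NOT_CANDIDATE", nrow(counts))
  for (i in top) {
    if (binder_reads[i] > 0) {
      status[i] <- "UNASSIGNABLE_BINDER"
    } else if (mx[i] > threshold) {
      status[i] <- "PUTATIVE_HIGH"
    } else if (mx[i] > 0) {
      status[i] <- "PUTATIVE_LOW"
    }
  }
  data.frame(taxid = counts$taxid, status = status)
}

# Random small community count table over the six-condition metadata, with
# counts drawn from a fixed alphabet.
random_counts <- function(n_taxa, metadata, alphabet = c(0, 1, 50)) {
  m <- matrix(sample(alphabet, n_taxa * nrow(metadata), replace = TRUE),
              nrow = n_taxa)
  make_counts(m, sample_ids = metadata$sample_id)
}

expect_status <- function(calls, taxid, status) {
  expect_equal(as.character(calls$status[calls$taxid == taxid]), status)
}
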