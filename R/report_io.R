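# Reading and writing the taxonomic count-table formats the pipeline consumes.
#
# All readers return the same tabular shape: a tibble with the taxon key
# columns (name, taxid, rank, domain) followed by one integer count column per
# sample. Sample metadata lives in its own tibble (sample_id, condition,
# replicate), never inferred from sample names.

RANK_CODE_MAP <- c(D = "DOMAIN", P = "PHYLUM", C = "CLASS", O = "ORDER",
                   F = "FAMILY", G = "GENUS", S = "SPECIES")

#' Parse a Kraken-style 6-column classifier report
#'
#' Reads the standard tab-delimited report dialect (percent, clade reads,
#' direct reads, rank code, taxid, indented name) into a one-sample count
#' table. Direct-read counts (column 3) are used as the taxon count, never the
#' clade-cumulative column, because rank aggregation happens explicitly
#' downstream; using clade counts would double-count reads when both genus and
#' species rows are present.
#'
#' Rank codes map `D` to `DOMAIN`, `G` to `GENUS`, `S` to `SPECIES` (and
#' likewise `P`/`C`/`O`/`F`); sub-rank codes (`G1`, `S2`, `K`, ...) map to
#' `OTHER`. Each row inherits the domain of the most recent `D` row, so the
#' table can be domain-filtered later. Rows above domain level (`U`
#' unclassified, `R`/`R1` root and cellular organisms) are not taxa in the
#' output; they are counted in the `skipped` attribute (rows and line numbers)
#' so no line is dropped silently.
#'
#' @param path Path to the report file.
#' @param sample_id Name for the single count column.
#' @return A count tibble with one sample column, with attribute `skipped`
#'   (tibble of line numbers and reasons for rows not emitted as taxa).
#' @export
read_kraken_report <- function(path, sample_id) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort(sprintf("empty report file: %s", path))

  fields <- strsplit(lines, "\t", fixed = TRUE)
  out <- vector("list", length(lines))
  skipped <- list()
  current_domain <- NA_character_
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) != 6) {
      abort(sprintf("%s: line %d has %d columns, expected 6", path, i, length(f)))
    }
    direct <- suppressWarnings(as.numeric(f[3]))
    taxid <- suppressWarnings(as.integer(f[5]))
    if (is.na(direct) || direct != floor(direct) || direct < 0) {
      abort(sprintf("%s: line %d has non-integer count '%s'", path, i, f[3]))
    }
    code <- trimws(f[4])
    name <- sub("^\\s+", "", f[6])
    if (code %in% c("U", "R", "R1", "R2")) {
      skipped[[length(skipped) + 1]] <- tibble(line = i, name = name, reason = "above domain rank")
      next
    }
    if (is.na(taxid) || taxid <= 0) {
      abort(sprintf("%s: line %d has invalid taxid '%s'", path, i, f[5]))
    }
    rank <- if (code %in% names(RANK_CODE_MAP)) RANK_CODE_MAP[[code]] else "OTHER"
    if (rank == "DOMAIN") current_domain <- name
    out[[i]] <- tibble(name = name, taxid = taxid, rank = rank,
                       domain = current_domain, count = direct)
  }
  rows <- bind_rows(out)
  if (nrow(rows) == 0) {
    rows <- tibble(name = character(), taxid = integer(),
                   rank = character(), domain = character(), count = numeric())
  }
  if (anyDuplicated(rows[c("taxid", "rank")]) > 0) {
    abort(sprintf("%s: duplicate (taxid, rank) rows", path))
  }
  names(rows)[names(rows) == "count"] <- sample_id
  res <- order_taxa(rows)
  attr(res, "skipped") <- bind_rows(skipped)
  res
}

#' Parse a Bracken abundance file
#'
#' Reads the tab-delimited re-estimated abundance format (columns `name`,
#' `taxonomy_id`, `taxonomy_lvl`, `kraken_assigned_reads`, `added_reads`,
#' `new_est_reads`, `fraction_total_reads`). The `new_est_reads` column
#' becomes the count; the fraction column is ignored because relative
#' abundances are recomputed downstream after filtering and masking.
#'
#' Bracken files carry no lineage, so `domain` is `NA`; attach domains before
#' [filter_domains()] (e.g. by merging with a classifier report) or filter at
#' the classifier-report stage.
#'
#' @param path Path to the abundance file (header required, one rank per file).
#' @param sample_id Name for the single count column.
#' @param rank Taxonomic rank of the file, `"GENUS"` or `"SPECIES"`
#'   (case-insensitive).
#' @return A count tibble with one sample column.
#' @export
read_bracken <- function(path, sample_id, rank) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  rank <- normalize_rank(rank)
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(df) == 0) abort(sprintf("empty abundance file: %s", path))
  if (!"new_est_reads" %in% names(df)) {
    abort(sprintf("%s: missing required column 'new_est_reads'", path))
  }
  need <- c("name", "taxonomy_id")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")))
  }
  counts <- df$new_est_reads
  if (!is.numeric(counts) || any(is.na(counts)) || any(counts < 0)) {
    abort(sprintf("%s: new_est_reads must be non-negative numbers", path))
  }
  if (anyDuplicated(df$taxonomy_id) > 0) {
    dup <- df$taxonomy_id[duplicated(df$taxonomy_id)][1]
    abort(sprintf("%s: duplicate taxid %s", path, dup))
  }
  out <- tibble(name = as.character(df$name),
                taxid = as.integer(df$taxonomy_id),
                rank = rank,
                domain = NA_character_)
  out[[sample_id]] <- as.numeric(counts)
  order_taxa(out)
}

#' Merge per-sample count tables into one combined table
#'
#' Takes the union of taxon rows across tables; a taxon absent from a sample
#' gets count 0. Column order follows input order; row order is normalized to
#' (rank, taxid) ascending so merged output is deterministic regardless of the
#' order rows arrived in. Per-sample totals are conserved.
#'
#' @param tables A list of count tibbles, each with distinct sample columns.
#' @return One combined count tibble.
#' @export
merge_count_tables <- function(tables) {
  if (!is.list(tables) || length(tables) == 0) abort("need at least one table")
  if (is.data.frame(tables)) tables <- list(tables)
  purrr::walk(tables, assert_count_table)
  all_samples <- unlist(lapply(tables, sample_columns))
  if (anyDuplicated(all_samples) > 0) {
    abort(sprintf("duplicate sample_id across tables: %s",
                  paste(unique(all_samples[duplicated(all_samples)]), collapse = ", ")))
  }
  merged <- purrr::reduce(tables, function(a, b) {
    full_join(a, b, by = TAXON_COLS)
  })
  # a taxon key may appear with domain known in one table and NA in another;
  # full_join keeps them as distinct rows only if domain differs, which is the
  # conservative behaviour: reconcile identical (taxid, rank) with one NA domain
  merged <- reconcile_domains(merged)
  merged <- merged %>%
    mutate(across(all_of(setdiff(names(merged), TAXON_COLS)), ~ tidyr::replace_na(.x, 0)))
  assert_count_table(merged)
  order_taxa(merged)
}

# After a full join on the taxon key, the same (taxid, rank) can appear twice
# when one source knows the domain and another does not (e.g. classifier report
# vs Bracken). Collapse such rows, requiring a consistent name and at most one
# non-NA domain; counts for a sample come from exactly one source table, so a
# na.rm sum recovers them.
reconcile_domains <- function(x) {
  if (anyDuplicated(paste(x$taxid, x$rank)) == 0) return(x)
  smp <- sample_columns(x)
  out <- x %>%
    group_by(.data$taxid, .data$rank) %>%
    summarise(
      name = {
        nm <- unique(.data$name)
        if (length(nm) > 1) abort(sprintf(
          "conflicting names for taxid %d: %s", .data$taxid[1],
          paste(nm, collapse = " / ")))
        nm
      },
      domain = {
        d <- unique(.data$domain[!is.na(.data$domain)])
        if (length(d) > 1) abort(sprintf(
          "conflicting domains for taxid %d: %s", .data$taxid[1],
          paste(d, collapse = " / ")))
        if (length(d) == 0) NA_character_ else d
      },
      across(all_of(smp), ~ if (all(is.na(.x))) NA_real_ else sum(.x, na.rm = TRUE)),
      .groups = "drop"
    )
  out[c(TAXON_COLS, smp)]
}

#' Read and write the combined count-table TSV
#'
#' The combined layout is strict: UTF-8 TSV with header
#' `name  taxid  rank  domain  <sample...>`, no index column. Sample columns
#' must be non-negative and integer-valued; any other column is rejected by
#' name. `write_count_table()` followed by `read_count_table()` is the
#' identity, and rewriting a freshly read table reproduces the file byte for
#' byte.
#'
#' @param path File path.
#' @return `read_count_table()` returns the count tibble;
#'   `write_count_table()` returns `path` invisibly.
#' @export
read_count_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = readr::cols(.default = readr::col_guess()))
  miss <- setdiff(TAXON_COLS, names(df))
  if (length(miss) > 0) {
    abort(sprintf("%s: missing column(s) %s", path, paste(miss, collapse = ", ")))
  }
  if (!identical(names(df)[1:4], TAXON_COLS)) {
    abort(sprintf("%s: first four columns must be %s", path,
                  paste(TAXON_COLS, collapse = ", ")))
  }
  df <- as_tibble(df)
  if (nrow(df) > 0) {
    df$taxid <- as.integer(df$taxid)
    df$rank <- normalize_rank(df$rank)
    df$domain <- as.character(df$domain)
    for (s in sample_columns(df)) {
      v <- df[[s]]
      if (!is.numeric(v) || any(is.na(v)) || any(v < 0) || any(v != floor(v))) {
        abort(sprintf("%s: column '%s' is not a non-negative integer count column",
                      path, s))
      }
      df[[s]] <- as.numeric(v)
    }
    assert_count_table(df)
  } else {
    df$taxid <- integer(0); df$name <- character(0)
    df$rank <- character(0); df$domain <- character(0)
    for (s in sample_columns(df)) df[[s]] <- numeric(0)
  }
  df
}

#' @param table Count tibble to write.
#' @rdname read_count_table
#' @export
write_count_table <- function(table, path) {
  if (nrow(table) > 0) assert_count_table(table)
  out <- table[c(TAXON_COLS, sample_columns(table))]
  # counts are whole numbers; write them as integers so the TSV never uses
  # scientific notation
  for (s in sample_columns(out)) {
    if (all(out[[s]] == floor(out[[s]])) && all(out[[s]] <= .Machine$integer.max)) {
      out[[s]] <- as.integer(out[[s]])
    }
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and write the sample metadata TSV
#'
#' Columns `sample_id`, `condition`, `replicate`. Conditions must come from
#' [mipner_conditions()]; an unknown condition string is an error that lists
#' the valid labels. The sample-to-condition mapping is always explicit in
#' this file, never inferred from sample names.
#'
#' @param path File path.
#' @return `read_sample_metadata()` returns a tibble with columns `sample_id`
#'   (character), `condition` (factor over [mipner_conditions()]),
#'   `replicate` (integer).
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) abort(sprintf("metadata file not found: %s", path))
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_metadata(df)
  tibble(sample_id = as.character(df$sample_id),
         condition = factor(as.character(df$condition), levels = CONDITION_LEVELS),
         replicate = as.integer(df$replicate))
}

#' @param metadata Metadata tibble to write.
#' @rdname read_sample_metadata
#' @export
write_sample_metadata <- function(metadata, path) {
  assert_metadata(metadata)
  out <- tibble(sample_id = as.character(metadata$sample_id),
                condition = as.character(metadata$condition),
                replicate = as.integer(metadata$replicate))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
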