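#' Read BLAST tabular output (outfmt 6)
#'
#' Reads the standard 12-column tabular dialect, with an optional 13th
#' `qcovs` column. When no coverage column is present, query coverage is
#' computed as `alignment length / query length * 100` via [hit_coverage()]
#' if query lengths are supplied.
#'
#' @param path Path to a tab-separated BLAST result.
#' @param qcovs Logical; `TRUE` if the file carries a 13th query-coverage
#'   column.
#' @return A tibble with the standard columns (`qseqid`, `sseqid`, `pident`,
#'   `length`, `mismatch`, `gapopen`, `qstart`, `qend`, `sstart`, `send`,
#'   `evalue`, `bitscore`, and `qcovs` when present).
#' @export
read_blast_tab <- function(path, qcovs = FALSE) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (qcovs) cols <- c(cols, "qcovs")
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = cols, stringsAsFactors = FALSE)
  as_tibble(df)
}

#' Query coverage of BLAST hits
#'
#' Coverage of the query by a hit, as a percentage. By default computed per
#' row as `alignment length / query length * 100`; with
#' `union = TRUE`, overlapping alignment intervals of the same query/subject
#' pair are merged first (union-of-intervals coverage), which avoids
#' double-counting multi-domain hits.
#'
#' @param hits Tibble with `qseqid`, `qstart`, `qend`, `length`.
#' @param query_lengths Named numeric vector of query lengths (residues).
#' @param union Merge overlapping intervals per query/subject pair.
#' @return `hits` with a `qcovs` column added (or overwritten).
#' @export
hit_coverage <- function(hits, query_lengths, union = FALSE) {
  qlen <- unname(query_lengths[hits$qseqid])
  if (any(is.na(qlen))) {
    abort("Missing query length for some hits.",
          class = "chromatophore_input_error")
  }
  if (!union) {
    hits$qcovs <- 100 * hits$length / qlen
    return(hits)
  }
  cov <- hits |>
    dplyr::group_by(.data$qseqid, .data$sseqid) |>
    dplyr::summarise(covered = union_length(.data$qstart, .data$qend),
                     .groups = "drop")
  hits <- dplyr::left_join(hits, cov, by = c("qseqid", "sseqid"))
  hits$qcovs <- 100 * hits$covered / qlen
  dplyr::select(hits, -"covered")
}

union_length <- function(starts, ends) {
  lo <- pmin(starts, ends); hi <- pmax(starts, ends)
  ord <- order(lo)
  lo <- lo[ord]; hi <- hi[ord]
  total <- 0; cur_lo <- lo[1]; cur_hi <- hi[1]
  for (i in seq_along(lo)[-1]) {
    if (lo[i] <= cur_hi + 1) {
      cur_hi <- max(cur_hi, hi[i])
    } else {
      total <- total + (cur_hi - cur_lo + 1)
      cur_lo <- lo[i]; cur_hi <- hi[i]
    }
  }
  total + (cur_hi - cur_lo + 1)
}

#' Filter search-engine protein identifications
#'
#' Acceptance rule for protein identification tables: keep an entry iff
#' protein score >= 22 AND discriminant score >= 0.0 AND best peptide
#' expectation value <= 0.01. All three boundaries are inclusive; the
#' thresholds are configurable.
#'
#' @param entries Tibble with columns `protein_score`, `discriminant_score`,
#'   `expectation_value` (plus any id columns, which pass through).
#' @param min_score,min_discriminant,max_expectation Threshold values.
#' @return The accepted rows, order preserved.
#' @export
filter_identifications <- function(entries, min_score = 22,
                                   min_discriminant = 0.0,
                                   max_expectation = 0.01) {
  need <- c("protein_score", "discriminant_score", "expectation_value")
  missing <- setdiff(need, names(entries))
  if (length(missing) > 0L) {
    abort(sprintf("Missing identification column(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "chromatophore_input_error")
  }
  keep <- entries$protein_score >= min_score &
    entries$discriminant_score >= min_discriminant &
    entries$expectation_value <= max_expectation
  entries[keep, ]
}

#' Filter annotation hits by e-value
#'
#' @param hits Tibble with an `evalue` column.
#' @param threshold Keep hits with `evalue <= threshold` (default `1e-10`,
#'   the annotation acceptance cutoff). Order is preserved.
#' @return The kept rows.
#' @export
filter_hits_by_evalue <- function(hits, threshold = 1e-10) {
  if (any(hits$evalue < 0)) {
    abort("Negative e-value encountered.",
          class = "chromatophore_input_error")
  }
  hits[hits$evalue <= threshold, ]
}

#' S-crystallin classification rule
#'
#' An identified polypeptide is called S-crystallin (rather than a
#' glutathione S-transferase, its structural homolog) iff its hit against
#' the S-crystallin reference has strictly more than 90% query coverage AND
#' strictly more than 60% identity. Both comparisons are strict.
#'
#' @param coverage Query coverage percentage(s), 0-100.
#' @param identity Percent identity(ies), 0-100.
#' @return Logical vector.
#' @examples
#' classify_s_crystallin(coverage = 95, identity = 65)  # TRUE
#' classify_s_crystallin(coverage = 90, identity = 60)  # FALSE (boundary)
#' @export
classify_s_crystallin <- function(coverage, identity) {
  coverage > 90 & identity > 60
}

#' Best hit per query
#'
#' Selects one hit per query: lowest e-value wins; ties broken by higher
#' bitscore, then lexicographically smallest subject id. Queries with no
#' hits are simply absent from the output.
#'
#' @param hits Tibble with `qseqid`, `sseqid`, `evalue`, `bitscore`.
#' @return One row per distinct query.
#' @export
best_hit <- function(hits) {
  hits |>
    dplyr::group_by(.data$qseqid) |>
    dplyr::arrange(.data$evalue, dplyr::desc(.data$bitscore), .data$sseqid,
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
}
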