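#' Per-sample loading factors from spectral-count column totals
#'
#' Under the assumption that the total amount of protein per sample is
#' similar, the ratio of column totals estimates the relative protein
#' loading. The factor of the reference sample is 1; dividing each column by
#' its factor makes columns directly comparable.
#'
#' @param counts Tibble of spectral counts: first column protein ids (or a
#'   column named `protein`), remaining numeric columns one per sample.
#' @param reference Sample label, or `"min-total"` (default) to use the
#'   sample with the smallest column total, which yields factors >= 1.
#' @return A tibble with columns `sample`, `total`, `factor` and attribute
#'   `reference`.
#' @examples
#' tab <- tibble::tibble(protein = c("p1", "p2"),
#'                       yellow = c(400, 600), red = c(1100, 1100),
#'                       brown = c(900, 900))
#' loading_factors(tab, reference = "yellow")  # 1, 2.2, 1.8
#' @export
loading_factors <- function(counts, reference = "min-total") {
  counts <- validate_count_table(counts)
  samples <- setdiff(names(counts), "protein")
  totals <- vapply(counts[samples], sum, numeric(1))
  if (identical(reference, "min-total")) {
    reference <- samples[which.min(totals)]
  }
  if (!reference %in% samples) {
    abort(sprintf("Unknown reference sample '%s'.", reference),
          class = "chromatophore_input_error")
  }
  if (totals[[reference]] <= 0) {
    abort(sprintf("Reference sample '%s' has zero total count.", reference),
          class = "chromatophore_input_error")
  }
  out <- tibble(sample = samples, total = unname(totals),
                factor = unname(totals / totals[[reference]]))
  attr(out, "reference") <- reference
  out
}

validate_count_table <- function(counts) {
  counts <- as_tibble(counts)
  if (!"protein" %in% names(counts)) names(counts)[1] <- "protein"
  samples <- setdiff(names(counts), "protein")
  if (length(samples) == 0L) {
    abort("Count table has no sample columns.",
          class = "chromatophore_input_error")
  }
  num <- vapply(counts[samples], is.numeric, logical(1))
  if (!all(num)) {
    abort(sprintf("Non-numeric sample column(s): %s.",
                  paste(samples[!num], collapse = ", ")),
          class = "chromatophore_input_error")
  }
  if (any(vapply(counts[samples], function(x) any(x < 0 | is.na(x)),
                 logical(1)))) {
    abort("Counts must be non-negative and non-missing.",
          class = "chromatophore_input_error")
  }
  counts
}

#' Divide spectral counts by per-sample loading factors
#'
#' @param counts Count tibble (see [loading_factors()]).
#' @param factors Output of [loading_factors()], or a named numeric vector
#'   of factors keyed by sample.
#' @return A tibble of the same shape with each sample column divided by its
#'   factor; the reference column (factor 1) is unchanged.
#' @export
normalize_loading <- function(counts, factors) {
  counts <- validate_count_table(counts)
  if (is.data.frame(factors)) {
    f <- setNames(factors$factor, factors$sample)
  } else {
    f <- factors
  }
  samples <- setdiff(names(counts), "protein")
  missing <- setdiff(samples, names(f))
  if (length(missing) > 0L) {
    abort(sprintf("No loading factor for sample(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "chromatophore_input_error")
  }
  for (s in samples) counts[[s]] <- counts[[s]] / f[[s]]
  counts
}

#' Peptide-scaled abundance index
#'
#' Scales a (loading-normalized) spectral count by the protein's expected
#' tryptic peptide yield: `count / k_p * k_bar`, where `k_p` is the
#' protein's expected peptide count and `k_bar` the mean yield over the
#' protein set (65.5 for the published chromatophore proteome).
#'
#' @param count Non-negative numeric count(s).
#' @param k_p Expected peptide count(s), integer >= 1.
#' @param k_bar Mean expected peptide count over the dataset, > 0.
#' @return Numeric abundance index, same length as `count`.
#' @examples
#' abundance_index(10, k_p = 20, k_bar = 65.5)  # 32.75
#' @export
abundance_index <- function(count, k_p, k_bar) {
  if (any(k_p < 1)) {
    abort("k_p must be >= 1 (every protein yields at least one expected peptide).",
          class = "chromatophore_input_error")
  }
  stopifnot(k_bar > 0)
  count / k_p * k_bar
}

#' Full abundance-index pipeline
#'
#' Composes loading-factor estimation, loading normalization and peptide
#' scaling into the per-protein, per-sample abundance index ("normalized
#' peptide count"). Returns a long tibble carrying the raw count, the
#' loading-normalized count, the expected peptide count `k_p`, the float
#' index and its nearest-integer view (rounding half away from zero, as the
#' published integer counts imply).
#'
#' @param counts Count tibble (first column protein id, one numeric column
#'   per sample).
#' @param proteins Protein tibble with `id` and `sequence` covering every
#'   protein in `counts`.
#' @param params [digest_params()] used for the expected-peptide counts.
#' @param reference Passed to [loading_factors()].
#' @param normalize_loading If `FALSE`, skip loading normalization
#'   (granule/pigment-sample mode, where loading is deliberately not
#'   normalized).
#' @param k_bar Scaling constant; default recomputes
#'   [mean_expected_peptides()] over `proteins`.
#' @return A long tibble: `protein`, `sample`, `count`, `normalized`, `k_p`,
#'   `index`, `index_int`. Attributes `loading` (the factor table, or NULL)
#'   and `k_bar`.
#' @export
abundance_table <- function(counts, proteins, params = digest_params(),
                            reference = "min-total",
                            normalize_loading = TRUE,
                            k_bar = NULL) {
  counts <- validate_count_table(counts)
  missing <- setdiff(counts$protein, proteins$id)
  if (length(missing) > 0L) {
    abort(sprintf("No sequence for protein(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "chromatophore_input_error")
  }
  digest <- digest_proteome(proteins, params)
  if (is.null(k_bar)) k_bar <- mean(digest$expected_peptides)

  loading <- NULL
  norm <- counts
  if (normalize_loading) {
    loading <- loading_factors(counts, reference)
    norm <- normalize_loading(counts, loading)
  }

  long_raw <- tidyr::pivot_longer(counts, -"protein",
                                  names_to = "sample", values_to = "count")
  long_norm <- tidyr::pivot_longer(norm, -"protein",
                                   names_to = "sample",
                                   values_to = "normalized")
  out <- dplyr::left_join(long_raw, long_norm,
                          by = c("protein", "sample"))
  out <- dplyr::left_join(
    out, dplyr::select(digest, protein = "id", k_p = "expected_peptides"),
    by = "protein")
  out$index <- abundance_index(out$normalized, out$k_p, k_bar)
  out$index_int <- round_half_away(out$index)
  attr(out, "loading") <- loading
  attr(out, "k_bar") <- k_bar
  out
}

#' Per-sample functional-category percentages
#'
#' @param abundance Long abundance tibble from [abundance_table()] (any
#'   tibble with `protein`, `sample` and a value column works).
#' @param categories Tibble mapping `protein` to `category`; proteins absent
#'   from the map are assigned `"uncharacterized"`.
#' @param value Name of the column to aggregate (default `"index"`).
#' @return A tibble `sample`, `category`, `value`, `percent`; percentages
#'   within each sample sum to 100.
#' @export
category_percentages <- function(abundance, categories, value = "index") {
  stopifnot(all(c("protein", "sample", value) %in% names(abundance)),
            all(c("protein", "category") %in% names(categories)))
  if (anyDuplicated(categories$protein) > 0L) {
    abort("Each protein must map to exactly one category.",
          class = "chromatophore_input_error")
  }
  df <- dplyr::left_join(abundance, categories, by = "protein")
  df$category[is.na(df$category)] <- "uncharacterized"
  out <- df |>
    dplyr::group_by(.data$sample, .data$category) |>
    dplyr::summarise(value = sum(.data[[value]]), .groups = "drop_last") |>
    dplyr::mutate(percent = 100 * .data$value / sum(.data$value)) |>
    dplyr::ungroup()
  if (any(!is.finite(out$percent))) {
    abort("A sample has zero total; percentages are undefined.",
          class = "chromatophore_input_error")
  }
  out
}

#' Contaminant rules for protein record filtering
#'
#' Default rules remove skin-surface bacterial ribosomal proteins and
#' sample-preparation enzymes (trypsin, collagenase, papain) by
#' case-insensitive description match.
#'
#' @param keywords Character vector of case-insensitive fixed keywords
#'   matched against descriptions.
#' @param patterns Character vector of case-insensitive regular expressions.
#' @param blocklist Character vector of protein ids removed outright.
#' @return A list of class `contaminant_rules`.
#' @export
contaminant_rules <- function(keywords = c("ribosomal protein", "trypsin",
                                           "collagenase", "papain"),
                              patterns = character(),
                              blocklist = character()) {
  for (p in patterns) {
    ok <- tryCatch({grepl(p, ""); TRUE},
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) {
      abort(sprintf("Malformed contaminant regex: '%s'.", p),
            class = "chromatophore_config_error")
    }
  }
  structure(list(keywords = keywords, patterns = patterns,
                 blocklist = blocklist),
            class = "contaminant_rules")
}

#' Partition protein records into kept and contaminant sets
#'
#' @param records Tibble with columns `id` and `description`.
#' @param rules A [contaminant_rules()] object; empty rules keep everything.
#' @return A list with tibbles `kept` and `removed`; `removed` gains a
#'   `matched_rule` column naming the first rule that fired. The two parts
#'   partition the input exactly.
#' @export
contaminant_filter <- function(records, rules = contaminant_rules()) {
  stopifnot(all(c("id", "description") %in% names(records)))
  records <- as_tibble(records)
  matched <- rep(NA_character_, nrow(records))
  for (kw in rules$keywords) {
    hit <- is.na(matched) &
      grepl(kw, records$description, ignore.case = TRUE, fixed = FALSE)
    matched[hit] <- paste0("keyword: ", kw)
  }
  for (p in rules$patterns) {
    hit <- is.na(matched) & grepl(p, records$description, ignore.case = TRUE)
    matched[hit] <- paste0("pattern: ", p)
  }
  hit <- is.na(matched) & records$id %in% rules$blocklist
  matched[hit] <- "blocklist"

  removed <- records[!is.na(matched), ]
  removed$matched_rule <- matched[!is.na(matched)]
  list(kept = records[is.na(matched), ], removed = removed)
}
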