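#' Digestion parameters for in-silico trypsin cleavage
#'
#' Trypsin cleaves C-terminal to lysine (K) or arginine (R); with the
#' proline rule on, cleavage is suppressed when the next residue is proline
#' (P). Defaults are 0 missed cleavages, proline rule on, and no length or
#' mass filtering, so the expected-peptide count is the plain count of
#' fully-cleaved fragments.
#'
#' @param missed_cleavages Integer >= 0; peptides spanning up to this many
#'   internal cleavage sites are also emitted.
#' @param proline_rule Logical; suppress cleavage before proline.
#' @param min_length Integer >= 1; peptides shorter than this (residues) are
#'   filtered out.
#' @param mass_window Optional numeric `c(low, high)` window (Da) on the
#'   monoisotopic peptide mass; `NULL` disables mass filtering. Unknown `X`
#'   residues contribute zero mass and trigger a notice when the window is
#'   active.
#' @return A list of class `digest_params`.
#' @export
digest_params <- function(missed_cleavages = 0L, proline_rule = TRUE,
                          min_length = 1L, mass_window = NULL) {
  stopifnot(missed_cleavages >= 0, min_length >= 1,
            isTRUE(proline_rule) || isFALSE(proline_rule))
  if (!is.null(mass_window)) {
    if (length(mass_window) != 2L || !(mass_window[1] < mass_window[2])) {
      abort("mass_window must be c(low, high) with low < high.",
            class = "chromatophore_input_error")
    }
  }
  structure(list(missed_cleavages = as.integer(missed_cleavages),
                 proline_rule = proline_rule,
                 min_length = as.integer(min_length),
                 mass_window = mass_window),
            class = "digest_params")
}

# Fully-cleaved tryptic fragments of one sequence (character vector).
cleave_fragments <- function(chars, proline_rule = TRUE) {
  n <- length(chars)
  is_kr <- chars %in% c("K", "R")
  cut_after <- is_kr
  if (proline_rule && n > 1L) {
    next_is_p <- c(chars[-1] == "P", FALSE)
    cut_after <- cut_after & !next_is_p
  }
  cut_after[n] <- FALSE  # terminal K/R: cleavage at C-terminus is a no-op
  ends <- c(which(cut_after), n)
  starts <- c(1L, ends[-length(ends)] + 1L)
  vapply(seq_along(starts),
         function(i) paste(chars[starts[i]:ends[i]], collapse = ""),
         character(1))
}

monoisotopic_mass <- function(peptide) {
  chars <- strsplit(peptide, "", fixed = TRUE)[[1]]
  sum(AA_MONO_MASS[chars]) + WATER_MONO
}

#' Enumerate tryptic peptides of a protein
#'
#' Cleaves the sequence C-terminal to K/R (suppressed before P when the
#' proline rule is on) and emits every run of up to `missed_cleavages + 1`
#' adjacent fully-cleaved fragments. With 0 missed cleavages and no filters
#' the peptides concatenate back to the input sequence exactly.
#'
#' @param sequence Uppercase amino-acid string (20-letter alphabet plus X).
#' @param params A [digest_params()] object.
#' @param id Identifier used in error messages.
#' @param keep_all If `TRUE`, peptides failing the length/mass filters are
#'   retained with `kept = FALSE` instead of being dropped.
#' @return A tibble with columns `peptide`, `start`, `end`, `missed`
#'   (cleavage sites spanned), `mass` (monoisotopic, Da) and, when
#'   `keep_all = TRUE`, a logical `kept`.
#' @examples
#' tryptic_peptides("MKTAYR")           # MK | TAYR
#' tryptic_peptides("AKPGR")            # proline suppresses the K cleavage
#' tryptic_peptides("MKTAYR", digest_params(missed_cleavages = 1))
#' @export
tryptic_peptides <- function(sequence, params = digest_params(),
                             id = "<protein>", keep_all = FALSE) {
  chars <- check_sequence(sequence, id)
  frags <- cleave_fragments(chars, params$proline_rule)
  flen <- nchar(frags)
  fend <- cumsum(flen)
  fstart <- fend - flen + 1L
  nf <- length(frags)

  rows <- list()
  for (j in 0:params$missed_cleavages) {
    if (nf - j < 1L) break
    for (i in seq_len(nf - j)) {
      rows[[length(rows) + 1L]] <- list(
        peptide = paste(frags[i:(i + j)], collapse = ""),
        start = fstart[i], end = fend[i + j], missed = j
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out$mass <- vapply(out$peptide, monoisotopic_mass, numeric(1),
                     USE.NAMES = FALSE)

  kept <- nchar(out$peptide) >= params$min_length
  if (!is.null(params$mass_window)) {
    if (any(grepl("X", out$peptide, fixed = TRUE))) {
      inform(sprintf(
        "Protein '%s': X residues contribute zero mass under the active mass window.",
        id))
    }
    kept <- kept & out$mass >= params$mass_window[1] &
      out$mass <= params$mass_window[2]
  }
  out$kept <- kept
  out <- as_tibble(out)
  if (keep_all) out else dplyr::select(out[out$kept, ], -"kept")
}

#' Expected number of tryptic peptides for one protein
#'
#' The size-normalization denominator of the protein abundance index: the
#' number of peptides a protein is expected to produce under in-silico
#' trypsin digestion (after any active filters).
#'
#' @inheritParams tryptic_peptides
#' @return Integer count (>= 1 when no filters are active).
#' @export
expected_peptide_count <- function(sequence, params = digest_params(),
                                   id = "<protein>") {
  nrow(tryptic_peptides(sequence, params, id = id))
}

#' Digest a whole proteome
#'
#' @param proteins Tibble with columns `id` and `sequence` (as returned by
#'   [read_proteins()] or [make_proteome()]).
#' @param params A [digest_params()] object.
#' @return A tibble with `id`, `length` (residues) and `expected_peptides`.
#' @export
digest_proteome <- function(proteins, params = digest_params()) {
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  if (nrow(proteins) == 0L) {
    abort("Empty protein set.", class = "chromatophore_input_error")
  }
  tibble(
    id = proteins$id,
    length = nchar(proteins$sequence),
    expected_peptides = purrr::map2_int(
      proteins$sequence, proteins$id,
      function(s, i) expected_peptide_count(s, params, id = i)
    )
  )
}

#' Mean expected peptide yield over a protein set
#'
#' The scaling constant of the abundance index (the published chromatophore
#' set of 469 entries averages 65.5 expected peptides per protein).
#'
#' @inheritParams digest_proteome
#' @return The arithmetic mean of [expected_peptide_count()] over the set.
#' @export
mean_expected_peptides <- function(proteins, params = digest_params()) {
  mean(digest_proteome(proteins, params)$expected_peptides)
}
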