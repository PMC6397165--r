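# Internal helpers shared across modules.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

# Monoisotopic residue masses (Da); X contributes zero mass by design.
AA_MONO_MASS <- c(
  A = 71.03711, C = 103.00919, D = 115.02694, E = 129.04259, F = 147.06841,
  G = 57.02146, H = 137.05891, I = 113.08406, K = 128.09496, L = 113.08406,
  M = 131.04049, N = 114.04293, P = 97.05276, Q = 128.05858, R = 156.10111,
  S = 87.03203, T = 101.04768, V = 99.06841, W = 186.07931, Y = 163.06333,
  X = 0
)
WATER_MONO <- 18.010565

check_sequence <- function(sequence, id = "<protein>") {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L) {
    abort(sprintf("Protein '%s' has an empty or invalid sequence.", id),
          class = "chromatophore_input_error")
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% AA_ALPHABET)
  if (length(bad) > 0L) {
    abort(sprintf(
      "Protein '%s': illegal character '%s' at position %d.",
      id, chars[bad[1]], bad[1]
    ), class = "chromatophore_input_error")
  }
  invisible(chars)
}

#' Derive a reproducible sub-seed from a global seed
#'
#' Generators in this package draw from independent substreams keyed by a
#' label, so fixing one global seed makes every module independently
#' reproducible. Kept below 2^31 to stay within R's integer range.
#'
#' @param seed Integer global seed.
#' @param label Character stream label, e.g. `"proteome"`.
#' @return An integer seed.
#' @export
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.double(seed) * 48271 + h) %% 2147483647)
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
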