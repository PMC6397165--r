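# Independent brute-force oracles, deliberately written differently from
# the package implementation (character-by-character loops, exhaustive
# scans) so agreement is meaningful.

# Brute-force tryptic digest: walk the sequence residue by residue,
# collecting fully-cleaved fragments, then concatenate all runs of up to
# m + 1 fragments.
oracle_digest <- function(sequence, missed = 0, proline = TRUE) {
  chars <- strsplit(sequence, "")[[1]]
  frags <- character(0)
  cur <- ""
  for (i in seq_along(chars)) {
    cur <- paste0(cur, chars[i])
    cleave <- chars[i] %in% c("K", "R") && i < length(chars)
    if (cleave && proline && chars[i + 1] == "P") cleave <- FALSE
    if (cleave) {
      frags <- c(frags, cur)
      cur <- ""
    }
  }
  if (nchar(cur) > 0) frags <- c(frags, cur)
  out <- character(0)
  for (j in 0:missed) {
    if (length(frags) - j < 1) break
    for (i in seq_len(length(frags) - j)) {
      out <- c(out, paste(frags[i:(i + j)], collapse = ""))
    }
  }
  out
}

random_sequence <- function(len, p_kr = 0.15, p_p = 0.08) {
  letters20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  probs <- rep((1 - p_kr - p_p) / 17, 20)
  names(probs) <- letters20
  probs[c("K", "R")] <- p_kr / 2
  probs["P"] <- p_p
  paste(sample(letters20, len, replace = TRUE, prob = probs), collapse = "")
}

# Quarter-wave stack reflectance at the design wavelength, normal
# incidence: each quarter-wave layer transforms the admittance Y -> n^2/Y,
# applied from the substrate up.
oracle_quarter_wave_R <- function(n0, n_h, n_l, n_sub, n_pairs) {
  Y <- n_sub
  for (i in seq_len(n_pairs)) {
    Y <- n_l^2 / Y   # L layer (adjacent to substrate)
    Y <- n_h^2 / Y   # H layer
  }
  ((n0 - Y) / (n0 + Y))^2
}

# Exhaustive best-hit scan per query.
oracle_best_hits <- function(hits) {
  out <- NULL
  for (q in unique(hits$qseqid)) {
    sub <- hits[hits$qseqid == q, ]
    best <- sub[1, ]
    for (i in seq_len(nrow(sub))[-1]) {
      cand <- sub[i, ]
      better <- cand$evalue < best$evalue ||
        (cand$evalue == best$evalue && cand$bitscore > best$bitscore) ||
        (cand$evalue == best$evalue && cand$bitscore == best$bitscore &&
           cand$sseqid < best$sseqid)
      if (better) best <- cand
    }
    out <- rbind(out, best)
  }
  out
}

# Direct Lorentzian sum evaluation used as the broadening oracle.
oracle_lorentzian <- function(wavelengths, lines, strengths, fwhm) {
  g2 <- (fwhm / 2)^2
  sapply(wavelengths, function(w) {
    sum(strengths * g2 / ((w - lines)^2 + g2))
  })
}
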