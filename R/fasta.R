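#' Read protein sequences from a FASTA file
#'
#' Reads a (possibly line-wrapped) amino-acid FASTA file into a tibble with
#' one row per record. The record id is the first whitespace-delimited token
#' of the header; the remainder is kept as the description.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `description`, `sequence`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 omega-crystallin", "MKTAYR"), fa)
#' read_proteins(fa)
#' @export
read_proteins <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) {
    abort("No FASTA records found.", class = "chromatophore_input_error")
  }
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  tibble(id = ids, description = desc,
         sequence = unname(toupper(as.character(aa))))
}

#' Write a protein tibble to FASTA
#'
#' @param proteins Tibble with columns `id`, `sequence` and optionally
#'   `description`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_proteins <- function(proteins, path) {
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  hdr <- proteins$id
  if ("description" %in% names(proteins)) {
    has_desc <- !is.na(proteins$description) & nzchar(proteins$description)
    hdr[has_desc] <- paste(proteins$id[has_desc], proteins$description[has_desc])
  }
  aa <- Biostrings::AAStringSet(setNames(proteins$sequence, hdr))
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}
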