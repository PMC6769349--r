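#' Translate an open reading frame to protein
#'
#' Standard genetic code. The CDS must be a whole number of codons ending in
#' a stop; the terminal stop is dropped, so a valid ORF of `L` bp yields a
#' protein of `L/3 - 1` residues (e.g. 513 bp -> 170 aa, 1,656 bp -> 551 aa).
#' Internal stop codons are an error. A non-ATG start is tolerated with a
#' warning by default because genome annotations can truncate 5' ends;
#' `strict_start = "error"` forbids it.
#'
#' @param cds A dna [seq_record()] with unambiguous A/C/G/T residues.
#' @param strict_start One of `"warn"`, `"error"`, `"silent"`.
#' @return A protein [seq_record()] carrying the same id.
#' @examples
#' translate_orf(seq_record("m", "ATGTAA", "dna"))  # -> "M"
#' @export
translate_orf <- function(cds, strict_start = c("warn", "error", "silent")) {
  strict_start <- match.arg(strict_start)
  stopifnot(inherits(cds, "seq_record"), cds$alphabet == "dna")
  s <- cds$residues
  n <- nchar(s)
  if (n %% 3L != 0L)
    stop("CDS '", cds$id, "' length ", n, " is not divisible by 3",
         call. = FALSE)
  if (grepl("[^ACGT]", s))
    stop("CDS '", cds$id, "' contains ambiguous nucleotides", call. = FALSE)
  codons <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
  if (codons[[1]] != "ATG") {
    msg <- paste0("CDS '", cds$id, "' does not start with ATG")
    if (strict_start == "error") stop(msg, call. = FALSE)
    if (strict_start == "warn") warning(msg, call. = FALSE)
  }
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  k <- length(aa)
  if (aa[[k]] != "*")
    stop("CDS '", cds$id, "' does not end with a stop codon", call. = FALSE)
  internal <- which(aa[-k] == "*")
  if (length(internal))
    stop("CDS '", cds$id, "' has an internal stop codon at codon ",
         internal[[1]], call. = FALSE)
  seq_record(cds$id, paste(aa[-k], collapse = ""), "protein",
             cds$description)
}

#' Reverse-complement a DNA string
#' @param s DNA string (IUPAC codes supported).
#' @return Reverse-complemented string.
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
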