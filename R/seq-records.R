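#' Sequence records
#'
#' A `seq_record` is the universal currency of the pipeline: an identified
#' nucleotide or protein sequence with an optional free-text description.
#' Residues are stored uppercased; the declared alphabet is validated against
#' the IUPAC codes (ambiguity codes allowed for DNA).
#'
#' @param id Non-empty identifier token.
#' @param residues Non-empty residue string.
#' @param alphabet `"dna"` or `"protein"`.
#' @param description Free-text description (may be empty).
#' @return An object of class `seq_record` with fields `id`, `description`,
#'   `residues` and `alphabet`.
#' @examples
#' seq_record("g1", "ATGAAATAA", "dna")
#' @export
seq_record <- function(id, residues, alphabet = c("dna", "protein"),
                       description = "") {
  alphabet <- match.arg(alphabet)
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("sequence id must be a non-empty string", call. = FALSE)
  residues <- toupper(gsub("[[:space:]]", "", residues))
  if (!nzchar(residues))
    stop("sequence '", id, "' has no residues", call. = FALSE)
  allowed <- if (alphabet == "dna") .iupac_dna else .amino_letters_ext
  bad <- setdiff(strsplit(residues, "")[[1]], allowed)
  if (length(bad))
    stop("sequence '", id, "' contains characters outside the ", alphabet,
         " alphabet: ", paste(unique(bad), collapse = ", "), call. = FALSE)
  structure(list(id = id, description = description,
                 residues = residues, alphabet = alphabet),
            class = "seq_record")
}

# 15-letter nucleotide ambiguity alphabet plus gap
.iupac_dna <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                "B", "D", "H", "V", "N")
.amino_letters <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
                    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
.amino_letters_ext <- c(.amino_letters, "X", "B", "Z", "U", "*")

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record %s> %s, %d %s\n", x$alphabet, x$id,
              nchar(x$residues),
              if (x$alphabet == "dna") "bp" else "aa"))
  invisible(x)
}

#' @export
length.seq_record <- function(x) nchar(x$residues)

#' Read a FASTA file into a list of sequence records
#'
#' One record per header, order preserved, residues uppercased and stripped
#' of whitespace. Duplicate identifiers (first whitespace-delimited token of
#' the header) are an error.
#'
#' @param path Path to a plain-text FASTA file.
#' @param alphabet `"dna"` or `"protein"`; validated per record.
#' @return Named list of [seq_record()] objects (names = ids).
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "ACGT"), f)
#' read_fasta(f, "dna")
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || !startsWith(lines[[1]], ">"))
    stop("not FASTA-formatted (empty file or missing '>' header): ", path,
         call. = FALSE)
  hdr <- grepl("^>", lines)
  grp <- cumsum(hdr)
  recs <- lapply(split(lines, grp), function(block) {
    header <- sub("^>", "", block[[1]])
    id <- strsplit(trimws(header), "[[:space:]]+")[[1]][1]
    desc <- trimws(sub("^[^[:space:]]+", "", trimws(header)))
    seq_record(id, paste(block[-1], collapse = ""), alphabet, desc)
  })
  ids <- vapply(recs, `[[`, "", "id")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  names(recs) <- ids
  recs
}

#' Write sequence records to FASTA
#'
#' @param records List of [seq_record()] objects.
#' @param path Output path.
#' @param width Line-wrap width (residues per line).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    header <- if (nzchar(r$description)) paste(r$id, r$description) else r$id
    writeLines(paste0(">", header), con)
    n <- nchar(r$residues)
    starts <- seq(1L, n, by = width)
    writeLines(substring(r$residues, starts, pmin(starts + width - 1L, n)),
               con)
  }
  invisible(path)
}

#' Extract residue strings from a record list
#' @param records List of [seq_record()] objects.
#' @return Named character vector of residue strings.
#' @export
record_strings <- function(records) {
  vapply(records, `[[`, "", "residues")
}
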