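#' Gene models
#'
#' A `gene_model` records a gene's scaffold placement and exon structure in
#' 1-based inclusive coordinates (the convention used for genomic location
#' columns such as "1047802-1052107 (-stand)"). Minus-strand models keep
#' their exon intervals in forward-scaffold coordinates; sequence extraction
#' is responsible for reverse-complementing.
#'
#' @param gene_id Gene identifier token.
#' @param scaffold Scaffold/chromosome token.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix or data.frame of (start, end), 1-based
#'   inclusive, sorted ascending and non-overlapping.
#' @param orf_length ORF length in bp (stop codon included).
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, scaffold, strand, exons, orf_length) {
  exons <- as.matrix(exons)
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  if (any(exons[, "start"] > exons[, "end"]))
    stop("gene '", gene_id, "': exon start > end", call. = FALSE)
  if (is.unsorted(exons[, "start"], strictly = TRUE) && nrow(exons) > 1L)
    stop("gene '", gene_id, "': exons not sorted ascending", call. = FALSE)
  if (nrow(exons) > 1L &&
      any(exons[-1L, "start"] <= exons[-nrow(exons), "end"]))
    stop("gene '", gene_id, "': overlapping exons", call. = FALSE)
  if (!strand %in% c("+", "-"))
    stop("gene '", gene_id, "': strand must be '+' or '-'", call. = FALSE)
  orf_length <- as.integer(orf_length)
  if (sum(exons[, "end"] - exons[, "start"] + 1L) < orf_length)
    stop("gene '", gene_id, "': exon lengths sum below orf_length",
         call. = FALSE)
  structure(list(gene_id = gene_id, scaffold = scaffold, strand = strand,
                 exons = exons, orf_length = orf_length),
            class = "gene_model")
}

#' Read gene models from a tab-separated table
#'
#' Expected columns: `gene_id`, `scaffold`, `strand`, `exons`, `orf_length`,
#' where `exons` encodes 1-based inclusive intervals as
#' `"start1-end1;start2-end2;..."`. Lines starting with `#` are comments.
#'
#' @param path Path to the TSV file.
#' @return Named list of [gene_model()] objects.
#' @export
read_gene_models <- function(path) {
  tab <- read_tsv(path)
  need <- c("gene_id", "scaffold", "strand", "exons", "orf_length")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("gene-model table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  models <- lapply(seq_len(nrow(tab)), function(i) {
    iv <- strsplit(tab$exons[i], ";", fixed = TRUE)[[1]]
    parts <- do.call(rbind, strsplit(iv, "-", fixed = TRUE))
    exons <- cbind(start = as.integer(parts[, 1]),
                   end = as.integer(parts[, 2]))
    gene_model(tab$gene_id[i], tab$scaffold[i], tab$strand[i], exons,
               tab$orf_length[i])
  })
  names(models) <- tab$gene_id
  models
}

#' Summarize a gene's exon/intron structure
#'
#' @param model A [gene_model()].
#' @return Data frame row with `gene_id`, `n_exons`, `n_introns`
#'   (= `n_exons - 1`) and `cds_length` (= `orf_length`).
#' @examples
#' m <- gene_model("g", "scf1", "+", rbind(c(1, 300), c(500, 900)), 600)
#' gene_structure_summary(m)
#' @export
gene_structure_summary <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  data.frame(gene_id = model$gene_id,
             n_exons = nrow(model$exons),
             n_introns = nrow(model$exons) - 1L,
             cds_length = model$orf_length,
             stringsAsFactors = FALSE)
}

#' Convert 1-based inclusive intervals to 0-based half-open form and back
#'
#' Internal arithmetic that needs half-open intervals converts at this
#' boundary; the two converters are exact inverses.
#'
#' @param iv Two-column integer matrix of intervals.
#' @return Converted two-column matrix.
#' @keywords internal
#' @export
to_half_open <- function(iv) {
  cbind(start = iv[, 1] - 1L, end = iv[, 2])
}

#' @rdname to_half_open
#' @export
to_one_based <- function(iv) {
  cbind(start = iv[, 1] + 1L, end = iv[, 2])
}
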