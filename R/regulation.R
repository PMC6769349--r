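# Promoter cis-element census and expression analytics: IUPAC motif
# scanning, qRT-PCR relative expression with significance stars, and
# correlation-based hierarchical clustering of abundance matrices.

#' Load a cis-element motif dictionary
#'
#' TSV columns: `name`, `iupac`, `category` (development/hormone/stress),
#' `subcategory`. The bundled dictionary covers the classic plant promoter
#' elements (MeJA-response CGTCA/TGACG, GA-response GARE/P-box, ABA-response
#' ABRE/motif IIb/CE1, endosperm Skn-1/GCN4, stress ARE/GC/Box-W1/WUN, ...)
#' as published consensus strings.
#'
#' @param path TSV path; defaults to the bundled dictionary.
#' @return Data frame of motif definitions.
#' @export
load_motif_dictionary <- function(path = system.file("extdata",
                                                     "motif_dictionary.tsv",
                                                     package = "grfevol")) {
  tab <- read_tsv(path)
  if (anyDuplicated(tab$name))
    stop("duplicate motif name(s) in dictionary", call. = FALSE)
  bad <- grepl(paste0("[^", paste(.iupac_dna, collapse = ""), "]"),
               tab$iupac)
  if (any(bad))
    stop("motif(s) outside the IUPAC alphabet: ",
         paste(tab$name[bad], collapse = ", "), call. = FALSE)
  tab
}

#' Scan a promoter for cis-element motifs
#'
#' Every position where a motif's IUPAC pattern matches is reported,
#' overlaps included, on the forward strand of the given sequence only.
#'
#' @param promoter A dna [seq_record()] (unambiguous A/C/G/T residues),
#'   conventionally the 2,000 bp upstream of the translational start.
#' @param motifs Motif dictionary data frame ([load_motif_dictionary()]).
#' @return Data frame of hits: `gene_id`, `motif`, `start` (1-based),
#'   `matched`.
#' @export
scan_promoter <- function(promoter, motifs = load_motif_dictionary()) {
  stopifnot(inherits(promoter, "seq_record"))
  if (promoter$alphabet != "dna" || grepl("[^ACGT]", promoter$residues))
    stop("promoter '", promoter$id,
         "' must be unambiguous nucleotide sequence", call. = FALSE)
  subject <- Biostrings::DNAString(promoter$residues)
  rows <- lapply(seq_len(nrow(motifs)), function(i) {
    m <- Biostrings::matchPattern(motifs$iupac[i], subject,
                                  fixed = "subject")
    if (!length(m)) return(NULL)
    data.frame(gene_id = promoter$id, motif = motifs$name[i],
               start = Biostrings::start(m),
               matched = as.character(m), stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(gene_id = character(), motif = character(),
                      start = integer(), matched = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$motif, out$start), , drop = FALSE]
}

#' Census of motif hits by motif, gene and category
#'
#' @param hits Hit table from [scan_promoter()] (possibly row-bound over
#'   genes).
#' @param motifs Motif dictionary used for the scan.
#' @return List: `per_motif` (motif, category, count, category_total,
#'   share), `per_gene` (gene x motif count matrix), `per_category`
#'   (category totals).
#' @export
category_summary <- function(hits, motifs = load_motif_dictionary()) {
  counts <- stats::setNames(integer(nrow(motifs)), motifs$name)
  if (nrow(hits)) {
    tab <- table(hits$motif)
    counts[names(tab)] <- as.integer(tab)
  }
  per_motif <- data.frame(motif = motifs$name, category = motifs$category,
                          subcategory = motifs$subcategory,
                          count = as.integer(counts),
                          stringsAsFactors = FALSE)
  cat_tot <- tapply(per_motif$count, per_motif$category, sum)
  per_motif$category_total <- as.integer(cat_tot[per_motif$category])
  per_motif$share <- ifelse(per_motif$category_total > 0,
                            per_motif$count / per_motif$category_total, 0)
  genes <- unique(hits$gene_id)
  per_gene <- matrix(0L, length(genes), nrow(motifs),
                     dimnames = list(genes, motifs$name))
  if (nrow(hits))
    for (g in genes) {
      tab <- table(hits$motif[hits$gene_id == g])
      per_gene[g, names(tab)] <- as.integer(tab)
    }
  list(per_motif = per_motif, per_gene = per_gene,
       per_category = cat_tot)
}

.check_ct <- function(ct) {
  need <- c("gene", "time_point", "replicate", "ct_target", "ct_reference")
  missing <- setdiff(need, names(ct))
  if (length(missing))
    stop("Ct table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!"condition" %in% names(ct)) ct$condition <- "treatment"
  if (anyNA(ct$ct_reference))
    stop("reference-gene Ct missing for some records", call. = FALSE)
  ct
}

#' Relative expression by the 2^-ddCt method
#'
#' Per replicate, `dCt = ct_target - ct_reference`; per (gene, condition,
#' time point), `ddCt = mean dCt(t) - mean dCt(control)` and
#' `fold = 2^-ddCt`. The control time point has fold 1 by construction.
#'
#' @param ct Ct table: columns `gene`, (`condition`), `time_point`,
#'   `replicate`, `ct_target`, `ct_reference`.
#' @param control_time Control (calibrator) time point, present for every
#'   gene/condition.
#' @return Data frame: `gene`, `condition`, `time_point`, `fold_change`.
#' @export
relative_expression <- function(ct, control_time = 0) {
  ct <- .check_ct(ct)
  ct$dct <- ct$ct_target - ct$ct_reference
  rows <- list()
  for (key in split(ct, list(ct$gene, ct$condition), drop = TRUE)) {
    ctrl <- key$dct[key$time_point == control_time]
    if (!length(ctrl))
      stop("no control time point ", control_time, " for gene '",
           key$gene[1], "'", call. = FALSE)
    for (tp in unique(key$time_point)) {
      ddct <- mean(key$dct[key$time_point == tp]) - mean(ctrl)
      rows[[length(rows) + 1L]] <-
        data.frame(gene = key$gene[1], condition = key$condition[1],
                   time_point = tp,
                   fold_change = if (tp == control_time) 1 else 2^(-ddct),
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$gene, out$condition, out$time_point), , drop = FALSE]
}

#' Significance of expression changes versus the control time point
#'
#' Two-sided Welch (unequal-variance) t-test on the replicate dCt values of
#' each time point against the control; stars follow the convention
#' `"**"` for p < 0.01, `"*"` for p < 0.05, `""` otherwise. Cells with
#' fewer than 2 replicates get `NA` p-values and are flagged.
#'
#' @inheritParams relative_expression
#' @return Data frame: `gene`, `condition`, `time_point`, `p_value`,
#'   `stars`, `flagged`.
#' @export
significance <- function(ct, control_time = 0) {
  ct <- .check_ct(ct)
  ct$dct <- ct$ct_target - ct$ct_reference
  rows <- list()
  for (key in split(ct, list(ct$gene, ct$condition), drop = TRUE)) {
    ctrl <- key$dct[key$time_point == control_time]
    for (tp in setdiff(unique(key$time_point), control_time)) {
      grp <- key$dct[key$time_point == tp]
      p <- if (length(grp) < 2L || length(ctrl) < 2L) NA_real_
           else if (stats::sd(grp) == 0 && stats::sd(ctrl) == 0)
             if (isTRUE(all.equal(mean(grp), mean(ctrl)))) 1 else 0
           else stats::t.test(grp, ctrl, var.equal = FALSE)$p.value
      rows[[length(rows) + 1L]] <-
        data.frame(gene = key$gene[1], condition = key$condition[1],
                   time_point = tp, p_value = p,
                   stars = if (is.na(p)) "" else if (p < 0.01) "**"
                           else if (p < 0.05) "*" else "",
                   flagged = is.na(p), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$gene, out$condition, out$time_point), , drop = FALSE]
}

# Deterministic leaf ordering: at every merge, the subcluster that formed
# at the lower height comes first; ties break to the smaller leaf label.
.order_leaves <- function(h, labels) {
  info <- function(k) {
    if (k < 0) list(order = -k, height = 0, label = labels[-k])
    else {
      l <- info(h$merge[k, 1]); r <- info(h$merge[k, 2])
      first_l <- l$height < r$height ||
        (l$height == r$height && l$label < r$label)
      list(order = if (first_l) c(l$order, r$order) else c(r$order, l$order),
           height = h$height[k], label = min(l$label, r$label))
    }
  }
  info(nrow(h$merge))$order
}

#' Hierarchical clustering of an expression matrix
#'
#' Genes (rows) are clustered with distance `1 - Pearson correlation`
#' across samples and average linkage by default; rows are sorted by label
#' before clustering and leaves are ordered tighter-cluster-first, so the
#' result is invariant to input row order. Constant rows (undefined
#' correlation) are flagged and placed last, outside the dendrogram.
#'
#' @param mat Numeric matrix, genes x samples, rownames required,
#'   >= 2 genes and >= 2 samples, no missing values.
#' @param method Agglomeration method for [stats::hclust()].
#' @param distance `"correlation"` (1 - Pearson) or `"euclidean"`.
#' @return List: `order` (gene labels, flagged genes last), `hclust` (the
#'   clustering of the non-constant rows), `flagged` (constant-row labels),
#'   `merge_heights`.
#' @export
cluster_expression <- function(mat, method = "average",
                               distance = c("correlation", "euclidean")) {
  distance <- match.arg(distance)
  stopifnot(is.matrix(mat), nrow(mat) >= 2L, ncol(mat) >= 2L,
            !is.null(rownames(mat)))
  if (anyNA(mat)) stop("matrix has missing values", call. = FALSE)
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  const <- apply(mat, 1, stats::sd) == 0
  flagged <- rownames(mat)[const & distance == "correlation"]
  work <- mat[setdiff(rownames(mat), flagged), , drop = FALSE]
  if (nrow(work) < 2L)
    stop("fewer than 2 non-constant rows to cluster", call. = FALSE)
  d <- if (distance == "correlation")
    stats::as.dist(1 - stats::cor(t(work))) else stats::dist(work)
  h <- stats::hclust(d, method = method)
  ord <- rownames(work)[.order_leaves(h, rownames(work))]
  list(order = c(ord, flagged), hclust = h, flagged = flagged,
       merge_heights = h$height)
}
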