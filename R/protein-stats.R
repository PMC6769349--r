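# Physicochemical characterization: molecular weight from average residue
# masses, isoelectric point from a Henderson-Hasselbalch net-charge model.
# Both tables ship as editable data files (aa_masses.tsv, aa_pka.tsv).

.water_mass <- 18.01524

aa_mass_table <- function() {
  if (is.null(.grfevol_cache$aa_mass)) {
    tab <- read_tsv(system.file("extdata", "aa_masses.tsv",
                                package = "grfevol"))
    .grfevol_cache$aa_mass <- stats::setNames(tab$mass, tab$residue)
  }
  .grfevol_cache$aa_mass
}

aa_pka_table <- function() {
  if (is.null(.grfevol_cache$aa_pka)) {
    .grfevol_cache$aa_pka <- read_tsv(system.file("extdata", "aa_pka.tsv",
                                                  package = "grfevol"))
  }
  .grfevol_cache$aa_pka
}

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch model: each basic group contributes
#' `+1 / (1 + 10^(pH - pKa))`, each acidic group `-1 / (1 + 10^(pKa - pH))`;
#' the N- and C-termini count once each.
#'
#' @param residues Peptide string over the 20-letter alphabet.
#' @param ph pH value(s).
#' @return Net charge, vectorized over `ph`.
#' @export
peptide_charge <- function(residues, ph) {
  pka <- aa_pka_table()
  aa <- strsplit(toupper(residues), "")[[1]]
  counts <- c(NTERM = 1, CTERM = 1, table(aa)[intersect(unique(aa),
                                                        pka$group)])
  q <- numeric(length(ph))
  for (g in names(counts)) {
    i <- match(g, pka$group)
    q <- q + counts[[g]] * if (pka$sign[i] > 0)
      1 / (1 + 10^(ph - pka$pka[i])) else -1 / (1 + 10^(pka$pka[i] - ph))
  }
  q
}

#' Molecular weight, isoelectric point and length of a protein
#'
#' MW is the sum of average residue masses plus one water. pI is found by
#' bisection on the monotone net-charge curve to `tol` pH units; at the
#' returned pI the absolute net charge is below 1e-4 for any peptide with
#' both termini.
#'
#' @param protein A protein [seq_record()] with unambiguous residues.
#' @param tol Bisection tolerance in pH units.
#' @return Data frame row: `id`, `length` (aa), `mol_wt` (Da), `pi`.
#' @examples
#' p <- seq_record("pep", "ACDEFGHIKLMNPQRSTVWY", "protein")
#' physicochemical_stats(p)
#' @export
physicochemical_stats <- function(protein, tol = 1e-6) {
  stopifnot(inherits(protein, "seq_record"))
  if (protein$alphabet != "protein")
    stop("physicochemical_stats expects a protein record", call. = FALSE)
  aa <- strsplit(protein$residues, "")[[1]]
  bad <- setdiff(aa, .amino_letters)
  if (length(bad))
    stop("protein '", protein$id, "' has residues outside the 20-letter ",
         "alphabet: ", paste(unique(bad), collapse = ", "), call. = FALSE)
  masses <- aa_mass_table()
  mw <- sum(masses[aa]) + .water_mass
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (peptide_charge(protein$residues, mid) > 0) lo <- mid else hi <- mid
  }
  data.frame(id = protein$id, length = length(aa), mol_wt = mw,
             pi = (lo + hi) / 2, stringsAsFactors = FALSE)
}

#' Characterize a whole family (Table-1-style report)
#'
#' Per-gene protein length, MW, pI and (when gene models are supplied) exon
#' and intron counts, plus recomputed column means. Means are always
#' recomputed from per-gene values rather than copied from any published
#' summary, and the report carries them under `mean_mol_wt`/`mean_pi`.
#'
#' @param proteins Named list of protein [seq_record()]s.
#' @param models Optional named list of [gene_model()]s (ids matching).
#' @return List with `table` (one row per gene) and `means`.
#' @export
family_table <- function(proteins, models = NULL) {
  rows <- do.call(rbind, lapply(proteins, physicochemical_stats))
  rownames(rows) <- NULL
  if (!is.null(models)) {
    gs <- do.call(rbind, lapply(models, gene_structure_summary))
    rows <- merge(rows, gs, by.x = "id", by.y = "gene_id", all.x = TRUE,
                  sort = FALSE)
  }
  log_stage("family_scan", nrow(rows), " proteins characterized")
  list(table = rows,
       means = c(mol_wt = mean(rows$mol_wt), pi = mean(rows$pi),
                 length = mean(rows$length)))
}
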