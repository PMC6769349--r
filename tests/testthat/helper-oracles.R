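# Independent brute-force oracles used to freeze expected values. These
# deliberately share no code with the package implementation.

STOPS <- c("TAA", "TAG", "TGA")
BASES <- c("A", "C", "G", "T")
CODE <- Biostrings::GENETIC_CODE
SENSE <- setdiff(names(CODE), STOPS)

# --- NG86 site counting: enumerate all 9 single-base mutants explicitly ---
oracle_sites <- function(codon) {
  syn <- 0
  for (pos in 1:3) {
    muts <- character(0)
    for (b in BASES) {
      if (b == substr(codon, pos, pos)) next
      m <- codon
      substr(m, pos, pos) <- b
      muts <- c(muts, m)
    }
    legal <- muts[!muts %in% STOPS]
    syn <- syn + sum(CODE[legal] == CODE[[codon]]) / length(legal)
  }
  c(syn = syn, nonsyn = 3 - syn)
}

# --- NG86 difference counting: explicit pathway enumeration -------------
perms_of <- function(v) {
  if (length(v) <= 1) return(matrix(v, nrow = 1))
  out <- NULL
  for (i in seq_along(v)) {
    sub <- perms_of(v[-i])
    out <- rbind(out, cbind(v[i], sub))
  }
  out
}

oracle_diffs <- function(ca, cb) {
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  if (!length(pos)) return(c(syn = 0, nonsyn = 0))
  paths <- perms_of(pos)
  syn_tot <- 0; nonsyn_tot <- 0; legal_n <- 0
  for (r in seq_len(nrow(paths))) {
    cur <- ca; syn <- 0; nonsyn <- 0; ok <- TRUE
    for (p in paths[r, ]) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (nxt %in% STOPS) { ok <- FALSE; break }
      if (CODE[[nxt]] == CODE[[cur]]) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    if (ok) {
      syn_tot <- syn_tot + syn; nonsyn_tot <- nonsyn_tot + nonsyn
      legal_n <- legal_n + 1
    }
  }
  if (!legal_n) return(c(syn = NA_real_, nonsyn = NA_real_))
  c(syn = syn_tot / legal_n, nonsyn = nonsyn_tot / legal_n)
}

# Ka/Ks of a gap-free codon alignment composed purely from the oracles.
oracle_kaks <- function(codons_a, codons_b) {
  S <- 0; N <- 0; Sd <- 0; Nd <- 0
  for (i in seq_along(codons_a)) {
    d <- oracle_diffs(codons_a[i], codons_b[i])
    if (anyNA(d)) next
    sa <- oracle_sites(codons_a[i]); sb <- oracle_sites(codons_b[i])
    S <- S + (sa[["syn"]] + sb[["syn"]]) / 2
    N <- N + (sa[["nonsyn"]] + sb[["nonsyn"]]) / 2
    Sd <- Sd + d[["syn"]]; Nd <- Nd + d[["nonsyn"]]
  }
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(ka = jc(Nd / N), ks = jc(Sd / S), s_sites = S, n_sites = N,
       sd = Sd, nd = Nd)
}

# --- affine-gap local alignment score by exhaustive recursion -----------
# Score of the best local alignment: max over all substring pairs of the
# best global alignment score, never below 0. A gap run of length L costs
# gap_open + L * gap_extend. Exponential; inputs must stay tiny (<= 6 bp).
oracle_local_score <- function(a, b, match = 2, mismatch = -3,
                               gap_open = -5, gap_extend = -2) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  glob_score <- function(sa, sb) {
    # best global score of sa vs sb; state: 0 fresh, 1 gap-in-a, 2 gap-in-b
    memo <- new.env(parent = emptyenv())
    rec <- function(i, j, state) {
      key <- paste(i, j, state)
      got <- memo[[key]]
      if (!is.null(got)) return(got)
      out <- rec_raw(i, j, state)
      memo[[key]] <- out
      out
    }
    rec_raw <- function(i, j, state) {
      if (i > length(sa) && j > length(sb)) return(0)
      best <- -Inf
      if (i <= length(sa) && j <= length(sb))
        best <- max(best, (if (sa[i] == sb[j]) match else mismatch) +
                            rec(i + 1, j + 1, 0))
      if (j <= length(sb))  # consume b against a gap in a
        best <- max(best, (if (state == 1) 0 else gap_open) + gap_extend +
                            rec(i, j + 1, 1))
      if (i <= length(sa))  # consume a against a gap in b
        best <- max(best, (if (state == 2) 0 else gap_open) + gap_extend +
                            rec(i + 1, j, 2))
      best
    }
    rec(1, 1, 0)
  }
  best <- 0
  for (i1 in seq_along(ca)) for (i2 in i1:length(ca))
    for (j1 in seq_along(cb)) for (j2 in j1:length(cb))
      best <- max(best, glob_score(ca[i1:i2], cb[j1:j2]))
  best
}

# --- isoelectric point by fine-grid scan of the net-charge curve --------
oracle_pi_grid <- function(residues, step = 1e-4) {
  grid <- seq(0, 14, by = step)
  q <- peptide_charge(residues, grid)
  grid[which.min(abs(q))]
}

# --- adjusted Rand index for planted-cluster recovery -------------------
adjusted_rand <- function(x, y) {
  tab <- table(x, y)
  comb2 <- function(n) n * (n - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_i * sum_j / comb2(n)
  (sum_ij - expected) / ((sum_i + sum_j) / 2 - expected)
}

# random protein record over a restricted alphabet (to control plantings)
random_protein <- function(id, n, exclude = character(0)) {
  ab <- setdiff(c("A", "R", "N", "D", "C", "E", "G", "H", "I", "L", "K",
                  "M", "F", "P", "S", "T", "V", "Y"), exclude)
  seq_record(id, paste(sample(ab, n, replace = TRUE), collapse = ""),
             "protein")
}

random_dna <- function(id, n) {
  seq_record(id, paste(sample(BASES, n, replace = TRUE), collapse = ""),
             "dna")
}

# bare Robinson-Foulds distance (ape attaches names/attrs inconsistently)
rf_dist <- function(t1, t2) as.numeric(ape::dist.topo(t1, t2))
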