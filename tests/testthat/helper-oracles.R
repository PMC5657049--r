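# Independent oracles, deliberately written with different algorithms/data
# structures than the package internals they check.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# ---- exhaustive Viterbi oracle -------------------------------------------
# Enumerates every legal state path: enter at any match state (log2(1/L)),
# walk M/I/D transitions (M and I consume one residue, D is silent), exit
# free after any match state. Returns the maximum log2-odds score over all
# paths, or -Inf if none.
oracle_viterbi <- function(hmm, peptide) {
  L <- hmm$L
  lbg <- log2(hmm$background)
  mlo <- sweep(log2(hmm$match_emissions), 2, lbg)
  ilo <- sweep(log2(hmm$insert_emissions), 2, lbg)
  ltr <- log2(hmm$transitions)
  ch <- strsplit(peptide, "")[[1]]
  n <- length(ch)
  elo <- function(tab, k, c) {
    if (c == "X") return(0)
    j <- match(c, AA)
    if (is.na(j)) return(-Inf)
    tab[k, j]
  }
  best <- -Inf
  # walk(type, node, pos, score): `pos` = index of next residue to consume
  walk <- function(type, k, pos, sc) {
    if (!is.finite(sc)) return()
    if (type == "M") best <<- max(best, sc)  # free exit after a match
    # M_k -> M_{k+1}, I_k, D_{k+1}; I_k -> M_{k+1}, I_k; D_k -> M_{k+1}, D_{k+1}
    if (type == "M" || type == "I") {
      tnames <- if (type == "M") c("MM", "MI", "MD") else c("IM", "II")
      if (pos <= n && k < L)
        walk("M", k + 1, pos + 1,
             sc + ltr[k, tnames[1]] + elo(mlo, k + 1, ch[pos]))
      if (pos <= n)
        walk("I", k, pos + 1, sc + ltr[k, tnames[2]] + elo(ilo, k, ch[pos]))
      if (type == "M" && k < L)
        walk("D", k + 1, pos, sc + ltr[k, "MD"])
    } else {
      if (pos <= n && k < L)
        walk("M", k + 1, pos + 1,
             sc + ltr[k, "DM"] + elo(mlo, k + 1, ch[pos]))
      if (k < L)
        walk("D", k + 1, pos, sc + ltr[k, "DD"])
    }
  }
  entry <- log2(1 / L)
  for (i0 in seq_len(n))
    for (k0 in seq_len(L))
      walk("M", k0, i0 + 1, entry + elo(mlo, k0, ch[i0]))
  best
}

# Random small HMM over a reduced-alphabet emission profile (mass mostly on
# `letters_used`), with random normalized transition bundles.
random_tiny_hmm <- function(L, letters_used = c("A", "C", "D", "E"),
                            family_id = "TOY") {
  rdir <- function(n) { x <- rexp(n); x / sum(x) }
  me <- matrix(1e-4, L, 20, dimnames = list(NULL, AA))
  ie <- matrix(1e-4, L, 20, dimnames = list(NULL, AA))
  j <- match(letters_used, AA)
  for (k in seq_len(L)) {
    me[k, j] <- rdir(length(j))
    ie[k, j] <- rdir(length(j))
  }
  me <- me / rowSums(me)
  ie <- ie / rowSums(ie)
  tr <- matrix(0, L, 7,
               dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II",
                                       "DM", "DD")))
  for (k in seq_len(L)) {
    tr[k, c("MM", "MI", "MD")] <- rdir(3)
    tr[k, c("IM", "II")] <- rdir(2)
    tr[k, c("DM", "DD")] <- rdir(2)
  }
  shortpair:::new_profile_hmm(family_id, me, ie, tr, rep(1 / 20, 20),
                              seq_len(L))
}

random_peptide <- function(n, letters_used = c("A", "C", "D", "E")) {
  paste(sample(letters_used, n, replace = TRUE), collapse = "")
}

# ---- plain-arithmetic posterior oracle -----------------------------------
# Direct, non-log evaluation of w = e^{s1/T} e^{s2/T} P(f), normalized.
oracle_posteriors <- function(s1, s2, pf, T) {
  w <- exp(s1 / T) * exp(s2 / T) * pf
  w / sum(w)
}

# ---- histogram oracle -----------------------------------------------------
# Smoothed histogram built with a different code path (explicit loop).
oracle_histogram <- function(lengths, smoothing) {
  bins <- min(lengths):max(lengths)
  cnt <- vapply(bins, function(b) sum(lengths == b), numeric(1))
  p <- numeric(length(bins))
  for (i in seq_along(bins))
    p[i] <- (cnt[i] + smoothing / length(bins)) /
      (length(lengths) + smoothing)
  names(p) <- bins
  p
}

# ---- independent codon-table translation oracle ---------------------------
CODONS <- within(expand.grid(a = c("T", "C", "A", "G"),
                             b = c("T", "C", "A", "G"),
                             c = c("T", "C", "A", "G"),
                             stringsAsFactors = FALSE),
                 codon <- paste0(a, b, c))
AA_BY_CODON <- local({
  # standard code, written out independently of the package's table
  x <- c(TTT = "F", TTC = "F", TTA = "L", TTG = "L",
         CTT = "L", CTC = "L", CTA = "L", CTG = "L",
         ATT = "I", ATC = "I", ATA = "I", ATG = "M",
         GTT = "V", GTC = "V", GTA = "V", GTG = "V",
         TCT = "S", TCC = "S", TCA = "S", TCG = "S",
         CCT = "P", CCC = "P", CCA = "P", CCG = "P",
         ACT = "T", ACC = "T", ACA = "T", ACG = "T",
         GCT = "A", GCC = "A", GCA = "A", GCG = "A",
         TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
         CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
         AAT = "N", AAC = "N", AAA = "K", AAG = "K",
         GAT = "D", GAC = "D", GAA = "E", GAG = "E",
         TGT = "C", TGC = "C", TGA = "*", TGG = "W",
         CGT = "R", CGC = "R", CGA = "R", CGG = "R",
         AGT = "S", AGC = "S", AGA = "R", AGG = "R",
         GGT = "G", GGC = "G", GGA = "G", GGG = "G")
  x
})

oracle_translate <- function(seq, frame) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ch <- strsplit(toupper(seq), "")[[1]]
  if (frame < 0) ch <- rev(unname(comp[ch]))
  off <- abs(frame) - 1
  ch <- ch[(off + 1):length(ch)]
  n <- length(ch) %/% 3
  if (n == 0) return("")
  paste(vapply(seq_len(n), function(i)
    unname(AA_BY_CODON[paste(ch[(3 * i - 2):(3 * i)], collapse = "")]),
    character(1)), collapse = "")
}
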