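# Six-frame conceptual translation under the standard genetic code.
# Implemented over a cached codon lookup table rather than per-read calls
# into heavyweight sequence classes: the scanner translates every read six
# times, so this is on the hot path.

.translate_env <- new.env(parent = emptyenv())

# IUPAC nucleotide resolutions.
IUPAC_NT <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
                 M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
                 S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
                 V = c("A", "C", "G"), H = c("A", "C", "T"),
                 D = c("A", "G", "T"), B = c("C", "G", "T"),
                 N = c("A", "C", "G", "T"))

codon_table <- function() {
  tab <- get0("codon_tab", envir = .translate_env)
  if (is.null(tab)) {
    tab <- as.character(Biostrings::GENETIC_CODE)
    names(tab) <- names(Biostrings::GENETIC_CODE)
    assign("codon_tab", tab, envir = .translate_env)
  }
  tab
}

# Translate one codon, resolving IUPAC ambiguity codes: if every resolution
# agrees on a residue (or stop) return it, otherwise 'X'. Resolved codons
# are cached.
translate_codon <- function(codon) {
  tab <- codon_table()
  aa <- tab[codon]
  if (!is.na(aa)) return(unname(aa))
  cache <- get0("fuzzy", envir = .translate_env)
  if (is.null(cache)) {
    cache <- new.env(parent = emptyenv())
    assign("fuzzy", cache, envir = .translate_env)
  }
  hit <- get0(codon, envir = cache)
  if (!is.null(hit)) return(hit)
  nts <- lapply(strsplit(codon, "")[[1]], function(ch)
    IUPAC_NT[[ch]] %||% character(0))
  aa <- if (any(!lengths(nts))) "X" else {
    combos <- do.call(paste0, expand.grid(nts, stringsAsFactors = FALSE))
    res <- unique(unname(tab[combos]))
    if (length(res) == 1L) res else "X"
  }
  assign(codon, aa, envir = cache)
  aa
}

translate_nt <- function(seq) {
  n <- nchar(seq) %/% 3L
  if (n == 0L) return("")
  codons <- substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  tab <- codon_table()
  aa <- unname(tab[codons])
  miss <- which(is.na(aa))
  for (i in miss) aa[i] <- translate_codon(codons[i])
  paste(aa, collapse = "")
}

COMP_FROM <- "ACGTUMRWSYKVHDBNacgtumrwsykvhdbn"
COMP_TO   <- "TGCAAKYWSRMBDHVNtgcaakywsrmbdhvn"

#' Reverse-complement a nucleotide string
#'
#' @param seq A single nucleotide string (IUPAC codes allowed).
#' @return The reverse complement, as a character string.
#' @export
reverse_complement <- function(seq) {
  paste(rev(strsplit(chartr(COMP_FROM, COMP_TO, seq), "")[[1]]),
        collapse = "")
}

#' Translate a read in all six frames
#'
#' Produces the three forward-frame and three reverse-frame conceptual
#' translations of a nucleotide sequence under the standard genetic code.
#' Reverse frames are read off the reverse complement. Stop codons are kept
#' as `'*'` (the aligner treats them as zero-probability emissions, so an
#' alignment can never cross a stop); codons containing IUPAC ambiguity
#' codes translate to `'X'` unless every resolution agrees on one residue.
#'
#' @param seq A single nucleotide string (IUPAC codes allowed), length >= 3.
#' @param read_id,end Optional identifiers carried through to the result.
#'
#' @return A data.frame with one row per frame and columns `read_id`, `end`,
#'   `frame` (one of `+1,+2,+3,-1,-2,-3`), `peptide` and `nt_offset` (0-based
#'   offset of the frame start on the strand being read).
#' @export
#' @examples
#' six_frame_translate("ATGGCCAAA")
six_frame_translate <- function(seq, read_id = NA_character_,
                                end = NA_integer_) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) < 3L)
    stop("sequence shorter than one codon: ", nchar(seq), " nt")
  seq <- toupper(seq)
  rc <- reverse_complement(seq)
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  peps <- character(6)
  offs <- integer(6)
  for (j in seq_along(frames)) {
    f <- frames[j]
    off <- abs(f) - 1L
    s <- if (f > 0) seq else rc
    peps[j] <- translate_nt(substr(s, off + 1L, nchar(s)))
    offs[j] <- off
  }
  data.frame(read_id = read_id, end = end,
             frame = frames, peptide = peps, nt_offset = offs,
             stringsAsFactors = FALSE)
}
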