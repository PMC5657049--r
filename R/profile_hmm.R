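# Profile HMM construction, local Viterbi alignment in bits, and Gumbel
# E-value statistics. This is a minimal Plan7-like aligner: match/insert/
# delete states per node, uniform local entry over match states, free exit
# after any match, scores reported as log2 likelihood ratios against an
# i.i.d. background null.

new_profile_hmm <- function(family_id, match_emissions, insert_emissions,
                            transitions, background, map_to_column,
                            gumbel_mu = NULL, gumbel_lambda = NULL,
                            msa = NULL, background_default = FALSE) {
  L <- nrow(match_emissions)
  stopifnot(L >= 1L, ncol(match_emissions) == 20L,
            all(dim(insert_emissions) == c(L, 20L)),
            all(dim(transitions) == c(L, 7L)),
            length(background) == 20L, length(map_to_column) == L)
  if (any(abs(rowSums(match_emissions) - 1) > 1e-6) ||
      any(abs(rowSums(insert_emissions) - 1) > 1e-6))
    stop("emission rows do not sum to 1")
  if (is.unsorted(map_to_column, strictly = TRUE))
    stop("map_to_column must be strictly increasing")
  structure(list(family_id = family_id, L = L,
                 match_emissions = match_emissions,
                 insert_emissions = insert_emissions,
                 transitions = transitions,
                 background = setNames(as.numeric(background), AA_ALPHABET),
                 map_to_column = as.integer(map_to_column),
                 gumbel_mu = gumbel_mu, gumbel_lambda = gumbel_lambda,
                 msa = msa, background_default = background_default),
            class = "ProfileHMM")
}

#' @export
print.ProfileHMM <- function(x, ...) {
  cat("ProfileHMM", x$family_id, "- L =", x$L,
      if (!is.null(x$gumbel_mu))
        sprintf("(Gumbel mu = %.2f, lambda = %.3f)", x$gumbel_mu,
                x$gumbel_lambda)
      else "(uncalibrated)", "\n")
  invisible(x)
}

is_gap <- function(ch) ch == "-" | ch == "."

msa_char_matrix <- function(msa) {
  do.call(rbind, strsplit(msa$seqs, ""))
}

#' Build a profile HMM from a seed alignment
#'
#' Match columns are those designated by the `#=GC RF` annotation when
#' present, otherwise columns whose gap fraction is below 0.5. Match and
#' insert emissions are Laplace-smoothed counts (+1 per residue); node
#' transition bundles are counted from the observed per-row state paths and
#' smoothed the same way. `map_to_column` records the 1-based MSA column of
#' each match state, which later anchors model coordinates back onto each
#' seed sequence.
#'
#' @param msa A `SeedAlignment`.
#' @param exclude_ids Optional seed identifiers to drop before training
#'   (e.g. to hold out the genes a benchmark's reads were drawn from).
#' @param background Background residue distribution (default uniform).
#' @return A `ProfileHMM`; the training alignment rides along in `$msa` for
#'   fragment-length coordinate conversion.
#' @export
build_from_msa <- function(msa, exclude_ids = NULL,
                           background = rep(1 / 20, 20)) {
  stopifnot(inherits(msa, "SeedAlignment"))
  keep <- !(msa$ids %in% exclude_ids)
  if (!any(keep)) stop("all seed rows excluded for family ", msa$family_id)
  msa <- new_seed_alignment(msa$family_id, msa$ids[keep], msa$seqs[keep],
                            rf = msa$rf)
  m <- toupper(msa_char_matrix(msa))
  gap <- is_gap(m)
  if (!is.null(msa$rf)) {
    rfc <- strsplit(msa$rf, "")[[1]]
    match_cols <- which(!is_gap(rfc) & rfc != "~")
  } else {
    match_cols <- which(colMeans(gap) < 0.5)
  }
  if (!length(match_cols))
    stop("no match columns in family ", msa$family_id)
  L <- length(match_cols)
  n <- nrow(m)
  bg <- background / sum(background)

  count_col <- function(chars) {
    tab <- table(factor(chars[chars %in% AA_ALPHABET], levels = AA_ALPHABET))
    as.numeric(tab)
  }
  me <- matrix(0, L, 20, dimnames = list(NULL, AA_ALPHABET))
  for (k in seq_len(L)) {
    cnt <- count_col(m[, match_cols[k]])
    me[k, ] <- (cnt + 1) / (sum(cnt) + 20)
  }
  # Insert emissions for node k: residues in insert columns between match
  # column k and k+1, pooled; Laplace-smoothed (an empty block reduces to
  # the uniform background under the +1 smoothing).
  ie <- matrix(0, L, 20, dimnames = list(NULL, AA_ALPHABET))
  for (k in seq_len(L)) {
    lo_c <- match_cols[k] + 1L
    hi_c <- if (k < L) match_cols[k + 1L] - 1L else msa$n_columns
    cnt <- if (hi_c >= lo_c)
      count_col(as.vector(m[, lo_c:hi_c, drop = FALSE]))
    else numeric(20)
    ie[k, ] <- (cnt + 1) / (sum(cnt) + 20)
  }

  # Transition counts from each row's observed state path over nodes 1..L.
  tc <- matrix(0, L, 7, dimnames = list(NULL, TRANS_NAMES))
  is_match_col <- logical(msa$n_columns)
  is_match_col[match_cols] <- TRUE
  node_of_col <- cumsum(is_match_col)  # node index at/before each column
  for (r in seq_len(n)) {
    prev_type <- NULL
    prev_node <- 0L
    for (cc in seq_len(msa$n_columns)) {
      if (is_match_col[cc]) {
        type <- if (gap[r, cc]) "D" else "M"
        node <- node_of_col[cc]
      } else if (!gap[r, cc]) {
        type <- "I"
        node <- node_of_col[cc]
      } else next
      if (!is.null(prev_type) && prev_node >= 1L) {
        j <- match(paste0(prev_type, type), TRANS_NAMES)
        if (!is.na(j) && prev_node <= L)
          tc[prev_node, j] <- tc[prev_node, j] + 1
      }
      prev_type <- type
      prev_node <- node
    }
  }
  tr <- matrix(0, L, 7, dimnames = list(NULL, TRANS_NAMES))
  for (k in seq_len(L)) {
    mb <- tc[k, c("MM", "MI", "MD")] + 1
    ib <- tc[k, c("IM", "II")] + 1
    db <- tc[k, c("DM", "DD")] + 1
    tr[k, c("MM", "MI", "MD")] <- mb / sum(mb)
    tr[k, c("IM", "II")] <- ib / sum(ib)
    tr[k, c("DM", "DD")] <- db / sum(db)
  }

  new_profile_hmm(msa$family_id, me, ie, tr, bg, match_cols, msa = msa)
}

# Encode a peptide for the C++ DP: 0..19 residue index, -1 = 'X'
# (background, log-odds 0), -2 = '*' or any other symbol (probability 0).
encode_peptide <- function(peptide) {
  ch <- strsplit(toupper(peptide), "")[[1]]
  idx <- match(ch, AA_ALPHABET)
  out <- ifelse(is.na(idx), ifelse(ch %in% c("X", "B", "Z", "J", "U", "O"),
                                   -1L, -2L), idx - 1L)
  as.integer(out)
}

hmm_log_odds <- function(hmm) {
  lbg <- log2(hmm$background)
  list(mlo = sweep(log2(hmm$match_emissions), 2, lbg),
       ilo = sweep(log2(hmm$insert_emissions), 2, lbg),
       ltr = log2(hmm$transitions),
       entry = log2(1 / hmm$L))
}

#' Locally align a peptide to a profile HMM by Viterbi
#'
#' Best local alignment (uniform entry over match states, free exit after
#' any match) in bits: the log2 likelihood ratio of the Viterbi path against
#' an i.i.d. background null over the aligned residues. `'*'` emits with
#' probability zero, so alignments never cross a stop codon; `'X'` emits the
#' background (log-odds zero).
#'
#' @param hmm A `ProfileHMM`.
#' @param peptide Amino-acid string (may contain `'*'` / `'X'`).
#' @param min_score Alignments scoring at or below this many bits return
#'   `NULL` (default 0).
#' @return A one-row hit data.frame (`family_id`, `model_start`,
#'   `model_end`, `seq_start`, `seq_end`, `score`, `evalue = NA`), or `NULL`
#'   when no alignment beats `min_score`.
#' @export
viterbi_align <- function(hmm, peptide, min_score = 0) {
  stopifnot(inherits(hmm, "ProfileHMM"), nzchar(peptide))
  lo <- hmm_log_odds(hmm)
  res <- viterbi_local_c(lo$mlo, lo$ilo, lo$ltr, encode_peptide(peptide),
                         lo$entry)
  if (!is.finite(res$score) || res$score <= min_score) return(NULL)
  data.frame(read_id = NA_character_, end = NA_integer_, frame = NA_integer_,
             family_id = hmm$family_id,
             model_start = res$model_start, model_end = res$model_end,
             seq_start = res$seq_start, seq_end = res$seq_end,
             score = res$score, evalue = NA_real_, stringsAsFactors = FALSE)
}

# Raw local Viterbi score (bits), with no reporting floor; -Inf when no
# finite-scoring path exists. Used by calibration.
viterbi_score <- function(hmm, peptide, lo = NULL) {
  lo <- lo %||% hmm_log_odds(hmm)
  viterbi_local_c(lo$mlo, lo$ilo, lo$ltr, encode_peptide(peptide),
                  lo$entry)$score
}

#' Gumbel E-value for a bit score
#'
#' \eqn{E = Z \exp(-\lambda (s - \mu))}, clipped to \eqn{[0, Z]}: the
#' expected number of alignments at or above score `s` in `database_size`
#' independent comparisons under the null, using the model's Gumbel tail.
#'
#' @param hmm A `ProfileHMM` with Gumbel parameters (from a `.hmm` STATS
#'   line or [calibrate_gumbel()]).
#' @param score Bit score(s).
#' @param database_size Number of comparisons (Z).
#' @return E-value(s), in `[0, database_size]`.
#' @export
evalue <- function(hmm, score, database_size) {
  if (is.null(hmm$gumbel_mu) || is.null(hmm$gumbel_lambda))
    stop("model ", hmm$family_id, " has no Gumbel parameters; ",
         "run calibrate_gumbel() or supply a .hmm with a STATS line")
  pmin(pmax(database_size *
              exp(-hmm$gumbel_lambda * (score - hmm$gumbel_mu)), 0),
       database_size)
}

# Maximum-likelihood Gumbel (max) fit: location mu, rate lambda = 1/beta.
# The scale MLE solves beta = mean(x) - sum(x e^{-x/beta}) / sum(e^{-x/beta});
# solved by uniroot on that fixed-point equation.
fit_gumbel <- function(x) {
  if (length(x) < 10L || stats::sd(x) < 1e-9)
    stop("degenerate score distribution; cannot fit Gumbel")
  xbar <- mean(x)
  g <- function(beta) {
    w <- exp(-(x - max(x)) / beta)  # stabilised weights
    beta - xbar + sum(x * w) / sum(w)
  }
  lo <- stats::sd(x) / 10
  hi <- stats::sd(x) * 10
  beta <- stats::uniroot(g, c(lo, hi), tol = 1e-10, extendInt = "yes")$root
  mu <- -beta * log(mean(exp(-(x - xbar) / beta))) + xbar
  c(mu = mu, lambda = 1 / beta)
}

#' Calibrate Gumbel E-value parameters by simulation
#'
#' Fits a Gumbel distribution by maximum likelihood to the local Viterbi
#' scores of `n_random` i.i.d. background-sampled peptides, giving the
#' model's null score statistics. Deterministic for a given seed.
#'
#' @param hmm A `ProfileHMM`.
#' @param n_random Number of random peptides (>= 200).
#' @param seed Integer RNG seed.
#' @param peptide_length Length of the random peptides; default 25, the
#'   protein-space length of a 76-bp read.
#' @return The `ProfileHMM` with `gumbel_mu` / `gumbel_lambda` filled in.
#' @export
calibrate_gumbel <- function(hmm, n_random = 500L, seed = 1L,
                             peptide_length = 25L) {
  stopifnot(inherits(hmm, "ProfileHMM"))
  if (n_random < 200L)
    stop("n_random must be >= 200 for a stable Gumbel fit, got ", n_random)
  scores <- with_seed(seed, {
    lo <- hmm_log_odds(hmm)
    vapply(seq_len(n_random), function(i) {
      pep <- paste(sample(AA_ALPHABET, peptide_length, replace = TRUE,
                          prob = hmm$background), collapse = "")
      viterbi_score(hmm, pep, lo = lo)
    }, numeric(1))
  })
  fit <- fit_gumbel(scores[is.finite(scores)])
  hmm$gumbel_mu <- unname(fit["mu"])
  hmm$gumbel_lambda <- unname(fit["lambda"])
  hmm
}

# Run `code` under a private RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  }, add = TRUE)
  set.seed(seed)
  code
}
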