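# Posterior ranking of candidate (alignment-pair, family) assignments.
# For one read pair, each candidate family with alignments on both ends
# gets an unnormalised weight
#
#     w = exp(s1 / T) * exp(s2 / T) * Pr(f)
#
# where s1, s2 are the two bit scores, Pr(f) the fragment-length
# probability, and T a scaling factor. Posteriors are the weights
# normalised over the read pair's whole candidate set, computed in log
# space. With the default T = 1/ln 2, exp(s/T) = 2^s: a bit score enters
# as the model-vs-null likelihood ratio it encodes.

#' Scoring configuration
#'
#' @param T Scaling factor applied to bit scores; default `1/log(2)` so that
#'   `exp(s/T) = 2^s`.
#' @param tau Retention fraction for [filter_by_tau()]; default 0.40.
#' @return A `ScoringConfig` list.
#' @export
scoring_config <- function(T = 1 / log(2), tau = 0.40) {
  stopifnot(T > 0, tau > 0, tau <= 1)
  structure(list(T = T, tau = tau), class = "ScoringConfig")
}

#' Assign posterior probabilities to one read pair's candidates
#'
#' @param candidates A data.frame with one row per candidate family for a
#'   single read pair; required columns `score1`, `score2` (bits) and
#'   `fragment_length` (amino acids).
#' @param dist A `FragmentLengthDistribution`.
#' @param cfg A `ScoringConfig`.
#' @return `candidates` with columns `fragment_prob` and `posterior` added;
#'   posteriors sum to 1 over the set.
#' @export
score_candidates <- function(candidates, dist, cfg = scoring_config()) {
  if (!nrow(candidates)) stop("empty candidate set")
  stopifnot(all(c("score1", "score2", "fragment_length") %in%
                  names(candidates)),
            all(is.finite(candidates$score1)),
            all(is.finite(candidates$score2)))
  pf <- fragment_probability(dist, candidates$fragment_length)
  if (all(pf == 0))
    stop("all fragment probabilities are zero; build the distribution ",
         "with smoothing > 0")
  logw <- (candidates$score1 + candidates$score2) / cfg$T + log(pf)
  m <- max(logw)
  w <- exp(logw - m)
  candidates$fragment_prob <- pf
  candidates$posterior <- w / sum(w)
  candidates
}

#' Retain candidates above the p_max * tau threshold
#'
#' Keeps every candidate whose posterior is at least `tau` times the
#' maximum posterior of the set (non-strict, so the rule is stable under
#' ties and the argmax is always retained). Output is sorted by posterior
#' descending, ties broken lexicographically by family id, then by the end-1
#' model start when present.
#'
#' @param candidates Scored candidates (see [score_candidates()]).
#' @param tau Retention fraction in (0, 1].
#' @return The retained subset, sorted.
#' @export
filter_by_tau <- function(candidates, tau = 0.40) {
  if (!nrow(candidates)) stop("empty candidate set")
  stopifnot("posterior" %in% names(candidates), tau > 0, tau <= 1)
  keep <- candidates$posterior >= max(candidates$posterior) * tau
  out <- candidates[keep, , drop = FALSE]
  fam <- if ("family_id" %in% names(out)) out$family_id
         else rep("", nrow(out))
  ms <- if ("model_start1" %in% names(out)) out$model_start1
        else rep(0L, nrow(out))
  out[order(-out$posterior, fam, ms), , drop = FALSE]
}
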