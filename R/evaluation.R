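# Per-read-pair evaluation metrics for family assignment, plus the
# domain-abundance distance. For a pair sequenced from family set TP and
# predicted set C over a universe U:
#
#   sensitivity = |TP n C| / |TP|
#   FP rate     = |C - TP| / |U - TP|
#   PPV         = |TP n C| / |C|
#   F-score     = 2 * sensitivity * PPV / (sensitivity + PPV)

#' Per-pair sensitivity
#'
#' @param TP Character vector of true family ids (non-empty).
#' @param C Character vector of predicted family ids.
#' @return `|TP n C| / |TP|`.
#' @export
pair_sensitivity <- function(TP, C) {
  TP <- unique(TP)
  if (!length(TP)) stop("sensitivity undefined for empty truth set")
  length(intersect(TP, C)) / length(TP)
}

#' Per-pair false-positive rate
#'
#' @param TP True family ids.
#' @param C Predicted family ids.
#' @param U The family universe; the true-negative set is `U - TP`.
#' @return `|C - TP| / |U - TP|`.
#' @export
pair_fp_rate <- function(TP, C, U) {
  TP <- unique(TP)
  TN <- setdiff(unique(U), TP)
  if (!length(TN))
    stop("FP rate undefined: universe contains no true negatives")
  length(setdiff(unique(C), TP)) / length(TN)
}

#' Per-pair F-score and positive predictive value
#'
#' @param TP True family ids.
#' @param C Predicted family ids.
#' @return `c(f_score, ppv)`; both 0 when `C` is disjoint from `TP`
#'   (PPV is 0 for empty `C` by the same convention).
#' @export
f_score_ppv <- function(TP, C) {
  TP <- unique(TP)
  C <- unique(C)
  ppv <- if (!length(C)) 0 else length(intersect(TP, C)) / length(C)
  sens <- if (!length(TP)) 0 else length(intersect(TP, C)) / length(TP)
  f <- if (sens + ppv == 0) 0 else 2 * sens * ppv / (sens + ppv)
  c(f_score = f, ppv = ppv)
}

#' Averaged metrics over a dataset, with a threshold sweep
#'
#' Computes the unweighted per-pair mean of sensitivity, FP rate, F-score
#' and PPV, and optionally re-evaluates across a threshold grid to trace a
#' ROC-style curve: a `tau` grid (posterior mode, candidates filtered at
#' each retention fraction) or an `evalue` grid (baseline mode, hits
#' filtered at each cutoff).
#'
#' @param truth Named list: per read id, the character vector of true
#'   family ids. Pairs with empty truth are excluded from averaging and
#'   counted in `n_excluded`.
#' @param predictions Named list: per read id, either a character vector of
#'   predicted family ids, or a data.frame with `family_id` plus
#'   `posterior` / `evalue` columns for sweeping.
#' @param universe Character vector of all family ids.
#' @param sweep One of `"none"`, `"tau"`, `"evalue"`.
#' @param grid Threshold grid; defaults to `seq(0.1, 0.7, 0.1)` for tau
#'   (the 10--70\% retention sweep) and `10^(3:-5)` for E-values.
#' @return A list with `mean` (named vector), `per_pair` (data.frame),
#'   `n_excluded`, and `sweep` (data.frame of means per threshold, or
#'   `NULL`).
#' @export
dataset_metrics <- function(truth, predictions, universe,
                            sweep = c("none", "tau", "evalue"),
                            grid = NULL) {
  sweep <- match.arg(sweep)
  ids <- names(truth)
  evaluable <- ids[vapply(truth, function(tp) length(tp) > 0, logical(1))]
  if (!length(evaluable)) stop("no evaluable pairs (all truth sets empty)")

  pred_set <- function(p, thr = NULL) {
    if (is.data.frame(p)) {
      if (!nrow(p)) return(character(0))
      if (is.null(thr)) return(unique(p$family_id))
      if (sweep == "tau")
        unique(p$family_id[p$posterior >= max(p$posterior) * thr])
      else unique(p$family_id[p$evalue <= thr])
    } else unique(p)
  }
  eval_at <- function(thr = NULL) {
    per <- t(vapply(evaluable, function(rid) {
      tp <- unique(truth[[rid]])
      C <- pred_set(predictions[[rid]] %||% character(0), thr)
      fp <- f_score_ppv(tp, C)
      c(sensitivity = pair_sensitivity(tp, C),
        fp_rate = pair_fp_rate(tp, C, universe),
        f_score = unname(fp["f_score"]), ppv = unname(fp["ppv"]))
    }, numeric(4)))
    per
  }
  per <- eval_at(NULL)
  out <- list(mean = colMeans(per),
              per_pair = data.frame(read_id = evaluable, per,
                                    row.names = NULL,
                                    stringsAsFactors = FALSE),
              n_excluded = length(ids) - length(evaluable),
              sweep = NULL)
  if (sweep != "none") {
    grid <- grid %||% if (sweep == "tau") seq(0.1, 0.7, by = 0.1)
                      else 10^seq(3, -5, by = -1)
    sw <- t(vapply(grid, function(thr) colMeans(eval_at(thr)), numeric(4)))
    out$sweep <- data.frame(threshold = grid, sw, row.names = NULL)
  }
  out
}

#' Domain abundance distance
#'
#' Per-family absolute difference between the number of read pairs a tool
#' assigned to the family and the number in the ground truth; families
#' absent from one side count as zero. Smaller mean distance means the
#' predicted domain abundance profile is closer to the truth.
#'
#' @param predicted,truth Named numeric vectors (or two-column data.frames
#'   `family_id`, `read_pair_count`) of per-family read-pair counts.
#' @return A list with `per_family` (data.frame `family_id`, `predicted`,
#'   `truth`, `distance`) and `mean_distance`.
#' @export
abundance_distance <- function(predicted, truth) {
  as_counts <- function(x) {
    if (is.data.frame(x)) setNames(x$read_pair_count, x$family_id)
    else x
  }
  p <- as_counts(predicted)
  t <- as_counts(truth)
  fams <- sort(union(names(p), names(t)))
  pv <- ifelse(fams %in% names(p), p[fams], 0)
  tv <- ifelse(fams %in% names(t), t[fams], 0)
  pv[is.na(pv)] <- 0
  tv[is.na(tv)] <- 0
  per <- data.frame(family_id = fams, predicted = as.numeric(pv),
                    truth = as.numeric(tv),
                    distance = abs(as.numeric(pv) - as.numeric(tv)),
                    row.names = NULL, stringsAsFactors = FALSE)
  list(per_family = per, mean_distance = mean(per$distance))
}

#' Read a truth table written by the simulator
#'
#' @param path TSV with columns `read_id`, `family_id` (comma-separated for
#'   multi-family truth), and optionally `true_fragment_aa`.
#' @return Named list of character vectors, per read id.
#' @export
read_truth_tsv <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
  setNames(strsplit(tab$family_id, ","), tab$read_id)
}
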