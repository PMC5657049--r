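# Orchestration of the three-step paired-end homology search:
#   step 1  scan every end (six-frame translations) against every family,
#           keeping best-frame hits under an E-value cutoff;
#   step 2  for pairs with a single aligned end, rescue the missing mate by
#           full Viterbi against only the anchor's families, admitting any
#           positive-bit-score alignment;
#   step 3  score every (pair, family) candidate with the fragment-length
#           posterior and keep those within tau of the pair's maximum.
# The fragment-length distribution is estimated between steps 1 and 2 from
# pairs uniquely aligned to one family.

#' Run configuration
#'
#' @param evalue_cutoff Step-1 reporting threshold (default 10).
#' @param tau Posterior retention fraction (default 0.40).
#' @param T Bit-score scaling factor (default `1/log(2)`).
#' @param smoothing Fragment-histogram pseudo-count weight (default 1).
#' @param frag_min_bp,frag_max_bp Optional nucleotide fragment bounds (for
#'   example a library's 198 and 801 bp); divided by 3 they clip outlier
#'   fragment-length estimates before the histogram is built.
#' @param seed Integer seed for every stochastic step (Gumbel calibration).
#' @param calibrate_n Random peptides per model for E-value calibration.
#' @return A `RunConfig` list.
#' @export
run_config <- function(evalue_cutoff = 10, tau = 0.40, T = 1 / log(2),
                       smoothing = 1, frag_min_bp = NULL,
                       frag_max_bp = NULL, seed = 1L, calibrate_n = 500L) {
  stopifnot(evalue_cutoff > 0)
  structure(list(evalue_cutoff = evalue_cutoff, tau = tau, T = T,
                 smoothing = smoothing, frag_min_bp = frag_min_bp,
                 frag_max_bp = frag_max_bp, seed = as.integer(seed),
                 calibrate_n = as.integer(calibrate_n)),
            class = "RunConfig")
}

fragment_clip <- function(cfg) {
  if (is.null(cfg$frag_min_bp) || is.null(cfg$frag_max_bp)) return(NULL)
  c(floor(cfg$frag_min_bp / 3), ceiling(cfg$frag_max_bp / 3))
}

# Ensure every model carries Gumbel parameters; models lacking a STATS line
# are calibrated by simulation, each under a seed derived from cfg$seed and
# its position so the run is reproducible model-by-model.
prepare_models <- function(hmms, cfg) {
  if (inherits(hmms, "ProfileHMM")) hmms <- list(hmms)
  hmms <- lapply(seq_along(hmms), function(j) {
    h <- hmms[[j]]
    if (inherits(h, "SeedAlignment")) h <- build_from_msa(h)
    if (is.null(h$gumbel_mu))
      h <- calibrate_gumbel(h, n_random = cfg$calibrate_n,
                            seed = (cfg$seed + 7919L * j) %% .Machine$integer.max)
    h
  })
  names(hmms) <- vapply(hmms, `[[`, character(1), "family_id")
  if (anyDuplicated(names(hmms)))
    stop("duplicate family ids among models")
  hmms
}

# Best-frame hit per family for one translated end. `peps` is the data.frame
# from six_frame_translate(); `los` the precomputed log-odds per model.
scan_one_end <- function(peps, hmms, los, enc) {
  lapply(seq_along(hmms), function(j) {
    lo <- los[[j]]
    best <- NULL
    best_f <- NA_integer_
    for (f in seq_len(nrow(peps))) {
      if (!length(enc[[f]])) next
      r <- viterbi_local_c(lo$mlo, lo$ilo, lo$ltr, enc[[f]], lo$entry)
      if (is.finite(r$score) && (is.null(best) || r$score > best$score)) {
        best <- r
        best_f <- peps$frame[f]
      }
    }
    if (is.null(best)) return(NULL)
    list(res = best, frame = best_f, family = j)
  })
}

hit_row <- function(read_id, end, frame, family_id, res, score, ev,
                    provenance) {
  data.frame(read_id = read_id, end = end, frame = frame,
             family_id = family_id,
             model_start = res$model_start, model_end = res$model_end,
             seq_start = res$seq_start, seq_end = res$seq_end,
             score = score, evalue = ev, provenance = provenance,
             stringsAsFactors = FALSE)
}

#' Step 1: scan every read end against every family
#'
#' Translates each end in six frames and aligns each frame to every model;
#' per end and family only the best-scoring frame is kept (the frames are
#' mutually exclusive hypotheses), and a hit is reported iff its score is
#' positive and its E-value is at most `cfg$evalue_cutoff`. Following the
#' usual profile-search convention, the E-value search size is the number
#' of targets scanned per model: six frame translations of every read end
#' (`12 x n_pairs`).
#'
#' @param pairs Read-pair data.frame (see [read_paired_reads()]).
#' @param hmms List of `ProfileHMM` (or `SeedAlignment`, built on the fly).
#' @param cfg A `RunConfig`.
#' @param domtblout Optional path to a HMMER `--domtblout` table from an
#'   external per-end scan; when given the internal scan is skipped and the
#'   same score/E-value gate is applied to the imported hits.
#' @return Hit data.frame with `provenance = "step1"`.
#' @export
step1_scan <- function(pairs, hmms, cfg = run_config(), domtblout = NULL) {
  if (!is.null(domtblout)) {
    h <- parse_domtblout(domtblout)
    h <- h[h$read_id %in% pairs$id & h$score > 0 &
             h$evalue <= cfg$evalue_cutoff, , drop = FALSE]
    h$provenance <- "step1"
    rownames(h) <- NULL
    return(h)
  }
  if (!length(hmms)) stop("step1_scan: no models supplied")
  hmms <- prepare_models(hmms, cfg)
  los <- lapply(hmms, hmm_log_odds)
  Z <- 6 * 2 * nrow(pairs)  # targets searched per model: six frames of every end
  out <- vector("list", 2L * nrow(pairs))
  ii <- 0L
  for (i in seq_len(nrow(pairs))) {
    for (e in 1:2) {
      seq <- pairs[[paste0("end", e)]][i]
      peps <- six_frame_translate(seq, pairs$id[i], e)
      enc <- lapply(peps$peptide, encode_peptide)
      found <- scan_one_end(peps, hmms, los, enc)
      rows <- lapply(found, function(b) {
        if (is.null(b) || b$res$score <= 0) return(NULL)
        ev <- evalue(hmms[[b$family]], b$res$score, Z)
        if (ev > cfg$evalue_cutoff) return(NULL)
        hit_row(pairs$id[i], e, b$frame, names(hmms)[b$family], b$res,
                b$res$score, ev, "step1")
      })
      rows <- rows[!vapply(rows, is.null, logical(1))]
      if (length(rows)) {
        ii <- ii + 1L
        out[[ii]] <- do.call(rbind, rows)
      }
    }
  }
  if (ii == 0L) return(cbind(empty_hits(), provenance = character(0)))
  do.call(rbind, out[seq_len(ii)])
}

#' Step 2: rescue the missing mate of one-end pairs
#'
#' For every pair with hits on exactly one end, the other end's six frames
#' are aligned by full Viterbi against only the families already hit by the
#' aligned mate. Any positive-bit-score alignment is admitted -- no E-value
#' gate -- mirroring a filters-off maximum-sensitivity search; specificity
#' is deferred to the posterior ranking. Rescue never touches pairs with
#' zero step-1 hits and never searches a family outside the anchor's list.
#'
#' @param pairs Read-pair data.frame.
#' @param hits Step-1 hit data.frame.
#' @param hmms Models as in [step1_scan()].
#' @param cfg A `RunConfig`.
#' @return `hits` with rescued rows (`provenance = "rescued"`) appended.
#' @export
step2_rescue <- function(pairs, hits, hmms, cfg = run_config()) {
  hmms <- prepare_models(hmms, cfg)
  los <- lapply(hmms, hmm_log_odds)
  Z <- 6 * 2 * nrow(pairs)  # targets searched per model: six frames of every end
  ends_seen <- tapply(hits$end, hits$read_id, function(e) length(unique(e)))
  one_end <- names(ends_seen)[ends_seen == 1L]
  new_rows <- list()
  for (rid in one_end) {
    h <- hits[hits$read_id == rid, , drop = FALSE]
    missing_end <- if (all(h$end == 1L)) 2L else 1L
    fams <- unique(h$family_id)
    i <- match(rid, pairs$id)
    if (is.na(i)) next
    seq <- pairs[[paste0("end", missing_end)]][i]
    peps <- six_frame_translate(seq, rid, missing_end)
    enc <- lapply(peps$peptide, encode_peptide)
    for (fam in fams) {
      j <- match(fam, names(hmms))
      lo <- los[[j]]
      best <- NULL
      best_f <- NA_integer_
      for (f in seq_len(nrow(peps))) {
        if (!length(enc[[f]])) next
        r <- viterbi_local_c(lo$mlo, lo$ilo, lo$ltr, enc[[f]], lo$entry)
        if (is.finite(r$score) && (is.null(best) || r$score > best$score)) {
          best <- r
          best_f <- peps$frame[f]
        }
      }
      if (!is.null(best) && best$score > 0) {
        ev <- evalue(hmms[[j]], best$score, Z)
        new_rows[[length(new_rows) + 1L]] <-
          hit_row(rid, missing_end, best_f, fam, best, best$score, ev,
                  "rescued")
      }
    }
  }
  if (length(new_rows)) hits <- rbind(hits, do.call(rbind, new_rows))
  rownames(hits) <- NULL
  hits
}

# Best hit per (end, family) for one pair's hit rows.
best_per_family <- function(h) {
  key <- paste(h$end, h$family_id)
  keep <- unlist(lapply(split(seq_len(nrow(h)), key), function(ix)
    ix[which.max(h$score[ix])]), use.names = FALSE)
  h[sort(keep), , drop = FALSE]
}

candidate_fragment_length <- function(hmm, h1, h2) {
  if (!is.null(hmm$msa))
    estimate_fragment_length(hmm$msa, hmm$map_to_column, h1, h2)
  else  # no seed alignment available: outer span in model coordinates
    max(h1$model_end, h2$model_end) - min(h1$model_start, h2$model_start) + 1L
}

#' Step 3: posterior ranking and case classification
#'
#' Builds one candidate per family with hits on both ends of a pair (best
#' hit per end per family), estimates each candidate's fragment length
#' through the family's seed alignment, scores the set with the
#' fragment-length posterior and retains candidates within `tau` of the
#' maximum. Pairs are classified: case 2 when at least one candidate is
#' retained, case 1 when only one end has hits (or the ends share no
#' family), case 3 when nothing aligned.
#'
#' @param pairs Read-pair data.frame.
#' @param hits Hit data.frame after rescue.
#' @param dist A `FragmentLengthDistribution`.
#' @param hmms Models as in [step1_scan()].
#' @param cfg A `RunConfig`.
#' @return A list of `PairResult`s (one per input pair, input order): each
#'   has `read_id`, `case`, and `retained` (a data.frame of scored
#'   candidates for case 2, of single-end hits for case 1, empty for
#'   case 3).
#' @export
step3_rank <- function(pairs, hits, dist, hmms, cfg = run_config()) {
  if (is.null(dist)) stop("step3_rank: missing fragment-length distribution")
  hmms <- prepare_models(hmms, cfg)
  scfg <- scoring_config(T = cfg$T, tau = cfg$tau)
  idx <- split(seq_len(nrow(hits)), hits$read_id)
  lapply(seq_len(nrow(pairs)), function(i) {
    rid <- pairs$id[i]
    h <- hits[idx[[rid]] %||% integer(0), , drop = FALSE]
    if (!nrow(h))
      return(structure(list(read_id = rid, case = 3L,
                            retained = empty_candidates()),
                       class = "PairResult"))
    h <- best_per_family(h)
    fams <- intersect(h$family_id[h$end == 1L], h$family_id[h$end == 2L])
    if (!length(fams)) {
      ret <- h[order(h$evalue, h$family_id), , drop = FALSE]
      return(structure(list(read_id = rid, case = 1L, retained = ret),
                       class = "PairResult"))
    }
    cand <- do.call(rbind, lapply(fams, function(fam) {
      h1 <- h[h$end == 1L & h$family_id == fam, , drop = FALSE]
      h2 <- h[h$end == 2L & h$family_id == fam, , drop = FALSE]
      fl <- candidate_fragment_length(hmms[[fam]], h1, h2)
      data.frame(read_id = rid, family_id = fam,
                 score1 = h1$score, score2 = h2$score,
                 model_start1 = h1$model_start, model_end1 = h1$model_end,
                 model_start2 = h2$model_start, model_end2 = h2$model_end,
                 provenance1 = h1$provenance, provenance2 = h2$provenance,
                 fragment_length = fl, stringsAsFactors = FALSE)
    }))
    cand <- score_candidates(cand, dist, scfg)
    ret <- filter_by_tau(cand, scfg$tau)
    structure(list(read_id = rid, case = 2L, retained = ret),
              class = "PairResult")
  })
}

empty_candidates <- function() {
  data.frame(read_id = character(0), family_id = character(0),
             score1 = numeric(0), score2 = numeric(0),
             model_start1 = integer(0), model_end1 = integer(0),
             model_start2 = integer(0), model_end2 = integer(0),
             provenance1 = character(0), provenance2 = character(0),
             fragment_length = integer(0), fragment_prob = numeric(0),
             posterior = numeric(0), stringsAsFactors = FALSE)
}

#' @export
print.PairResult <- function(x, ...) {
  cat("PairResult", x$read_id, "- case", x$case, "-",
      nrow(x$retained), "retained\n")
  invisible(x)
}

#' Run the full paired-end homology search
#'
#' Executes the three steps in order: step-1 scan, fragment-length
#' distribution from uniquely aligned step-1 pairs, mate rescue, posterior
#' ranking. Because rescue only ever adds alignments, the post-rescue
#' case-2 fraction is at least the step-1-only case-2 fraction.
#'
#' @param pairs Read-pair data.frame, or path(s): `run_short_pair(reads1,
#'   reads2, ...)` style input goes through [read_paired_reads()] first.
#' @param hmms List of `ProfileHMM` or `SeedAlignment` objects.
#' @param cfg A `RunConfig`.
#' @param dist Optional user-supplied `FragmentLengthDistribution`
#'   (e.g. from [read_fragdist_tsv()]); when `NULL` it is estimated.
#' @param domtblout Optional external per-end scan to use in place of the
#'   internal step-1 scan (see [step1_scan()]).
#' @param out_prefix Optional path prefix; when given,
#'   `<prefix>.pairs.tsv`, `<prefix>.abundance.tsv` and
#'   `<prefix>.fragdist.tsv` are written.
#' @return A list with `results` (list of `PairResult`), `hits`, `dist`,
#'   `summary` (case counts and percentages at step 1 and after rescue),
#'   `pairs_table` and `abundance` (the two output tables).
#' @export
run_short_pair <- function(pairs, hmms, cfg = run_config(), dist = NULL,
                           domtblout = NULL, out_prefix = NULL) {
  if (is.character(pairs))
    pairs <- if (length(pairs) == 2L) read_paired_reads(pairs[1], pairs[2])
             else read_paired_reads(pairs)
  if (!nrow(pairs)) {
    warning("no input read pairs; empty result")
    empty <- list(results = list(), hits = empty_hits(), dist = dist,
                  summary = summarize_cases(list(), 0L, NULL),
                  pairs_table = empty_pairs_table(),
                  abundance = data.frame(family_id = character(0),
                                         read_pair_count = integer(0)))
    if (!is.null(out_prefix)) write_outputs(empty, out_prefix)
    return(empty)
  }
  hmms <- prepare_models(hmms, cfg)
  hits1 <- step1_scan(pairs, hmms, cfg, domtblout = domtblout)
  if (is.null(dist)) {
    uniq <- collect_unique_pairs(hits1)
    lens <- vapply(seq_len(nrow(uniq)), function(k) {
      fam <- uniq$family_id[k]
      candidate_fragment_length(hmms[[fam]],
                                hits1[uniq$row1[k], , drop = FALSE],
                                hits1[uniq$row2[k], , drop = FALSE])
    }, numeric(1))
    if (!length(lens))
      stop("no uniquely aligned pairs to estimate the fragment-length ",
           "distribution from; supply one via `dist`")
    dist <- build_distribution(lens, smoothing = cfg$smoothing,
                               clip = fragment_clip(cfg))
  }
  hits <- step2_rescue(pairs, hits1, hmms, cfg)
  results <- step3_rank(pairs, hits, dist, hmms, cfg)
  res <- list(results = results, hits = hits, dist = dist,
              summary = summarize_cases(results, nrow(pairs), hits1),
              pairs_table = pairs_table(results),
              abundance = abundance_table(results))
  if (!is.null(out_prefix)) write_outputs(res, out_prefix)
  res
}

# Case counts/percentages after ranking, plus the step-1-only baseline
# (computed from which ends had step-1 hits).
summarize_cases <- function(results, n_pairs, hits1) {
  cases <- vapply(results, `[[`, integer(1), "case")
  tab <- function(x) {
    out <- c(`1` = sum(x == 1L), `2` = sum(x == 2L), `3` = sum(x == 3L))
    out
  }
  final <- tab(cases)
  s1 <- c(`1` = NA_integer_, `2` = NA_integer_, `3` = NA_integer_)
  if (!is.null(hits1) && n_pairs > 0) {
    ends <- tapply(hits1$end, hits1$read_id, function(e) length(unique(e)))
    n2 <- sum(ends == 2L)
    n1 <- sum(ends == 1L)
    s1 <- c(`1` = n1, `2` = n2, `3` = n_pairs - n1 - n2)
  }
  list(n_pairs = n_pairs,
       step1_counts = s1,
       step1_pct = if (n_pairs > 0) 100 * s1 / n_pairs else s1 * NA_real_,
       final_counts = final,
       final_pct = if (n_pairs > 0) 100 * final / n_pairs else
         final * NA_real_)
}

empty_pairs_table <- function() {
  data.frame(read_id = character(0), case = integer(0),
             family_id = character(0), end1_score_bits = numeric(0),
             end2_score_bits = numeric(0), end1_model_span = character(0),
             end2_model_span = character(0), fragment_len_aa = integer(0),
             posterior = numeric(0), provenance = character(0),
             stringsAsFactors = FALSE)
}

# Flatten PairResults into the long pairs.tsv table (one row per retained
# assignment; one NA row for case-3 pairs).
pairs_table <- function(results) {
  rows <- lapply(results, function(pr) {
    if (pr$case == 2L) {
      r <- pr$retained
      data.frame(read_id = pr$read_id, case = 2L, family_id = r$family_id,
                 end1_score_bits = r$score1, end2_score_bits = r$score2,
                 end1_model_span = paste0(r$model_start1, "-", r$model_end1),
                 end2_model_span = paste0(r$model_start2, "-", r$model_end2),
                 fragment_len_aa = r$fragment_length,
                 posterior = r$posterior,
                 provenance = paste0(r$provenance1, "+", r$provenance2),
                 stringsAsFactors = FALSE)
    } else if (pr$case == 1L) {
      r <- pr$retained
      span <- paste0(r$model_start, "-", r$model_end)
      data.frame(read_id = pr$read_id, case = 1L, family_id = r$family_id,
                 end1_score_bits = ifelse(r$end == 1L, r$score, NA_real_),
                 end2_score_bits = ifelse(r$end == 2L, r$score, NA_real_),
                 end1_model_span = ifelse(r$end == 1L, span, NA_character_),
                 end2_model_span = ifelse(r$end == 2L, span, NA_character_),
                 fragment_len_aa = NA_integer_, posterior = NA_real_,
                 provenance = r$provenance, stringsAsFactors = FALSE)
    } else {
      data.frame(read_id = pr$read_id, case = 3L, family_id = NA_character_,
                 end1_score_bits = NA_real_, end2_score_bits = NA_real_,
                 end1_model_span = NA_character_,
                 end2_model_span = NA_character_,
                 fragment_len_aa = NA_integer_, posterior = NA_real_,
                 provenance = NA_character_, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, c(list(empty_pairs_table()), rows))
  rownames(out) <- NULL
  out
}

# Family abundance: number of read pairs whose retained case-2 candidate
# set contains the family.
abundance_table <- function(results) {
  fams <- unlist(lapply(results, function(pr)
    if (pr$case == 2L) unique(pr$retained$family_id) else character(0)))
  if (!length(fams))
    return(data.frame(family_id = character(0),
                      read_pair_count = integer(0),
                      stringsAsFactors = FALSE))
  tab <- table(fams)
  data.frame(family_id = names(tab),
             read_pair_count = as.integer(tab),
             stringsAsFactors = FALSE)[order(names(tab)), , drop = FALSE]
}

write_outputs <- function(res, out_prefix) {
  fmt <- function(df) {
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], function(x)
      ifelse(is.na(x), NA_character_, sprintf("%.6g", x)))
    df
  }
  write.table(fmt(res$pairs_table), paste0(out_prefix, ".pairs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  write.table(res$abundance, paste0(out_prefix, ".abundance.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$dist))
    write_fragdist_tsv(res$dist, paste0(out_prefix, ".fragdist.tsv"))
  invisible(out_prefix)
}
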