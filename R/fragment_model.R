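# Reference-free fragment-length distribution. Paired model-coordinate
# alignments are pushed through the seed MSA onto each seed sequence; the
# per-seed outer spans are averaged into one fragment-length estimate per
# uniquely aligned pair, and the pooled estimates form a smoothed histogram
# used by the posterior.

#' Convert a model-coordinate span to a seed-sequence span
#'
#' Model positions are mapped to MSA columns through `map_to_column`, then to
#' residue positions on one seed row by counting that row's non-gap
#' characters up to and including the column (1-based inclusive). When the
#' row is gapped at both terminal columns no residue anchors the span and
#' `NULL` is returned.
#'
#' @param msa A `SeedAlignment`.
#' @param map_to_column Integer vector mapping model positions to 1-based
#'   MSA columns (from the family's `ProfileHMM`).
#' @param seed_row Row index into `msa`.
#' @param model_start,model_end 1-based inclusive model coordinates.
#' @return `c(seed_start, seed_end)` or `NULL` when unanchored.
#' @export
model_span_to_seed_span <- function(msa, map_to_column, seed_row,
                                    model_start, model_end) {
  stopifnot(inherits(msa, "SeedAlignment"),
            model_start >= 1, model_start <= model_end,
            model_end <= length(map_to_column))
  if (seed_row < 1 || seed_row > length(msa$seqs))
    stop("seed_row ", seed_row, " out of range (", length(msa$seqs),
         " rows)")
  ch <- strsplit(msa$seqs[seed_row], "")[[1]]
  res <- !is_gap(ch)
  cum <- cumsum(res)
  c1 <- map_to_column[model_start]
  c2 <- map_to_column[model_end]
  if (!res[c1] && !res[c2]) return(NULL)
  s1 <- max(1L, cum[c1])
  s2 <- max(1L, cum[c2])
  c(seed_start = s1, seed_end = s2)
}

#' Estimate the fragment length implied by a pair of alignments
#'
#' Takes the outer model-coordinate span of the two hits (minimum start to
#' maximum end), converts it onto every seed sequence of the family's
#' alignment, and averages the per-seed span lengths (end - start + 1),
#' rounding half up to the nearest integer. The result is the pair's
#' aligned footprint on the family, in amino acids -- the protein-space
#' fragment (insert) size.
#'
#' @param msa A `SeedAlignment`.
#' @param map_to_column Model-to-column map of the family's profile HMM.
#' @param hit1,hit2 One-row hit data.frames on the same family.
#' @return Integer fragment length (amino acids).
#' @export
estimate_fragment_length <- function(msa, map_to_column, hit1, hit2) {
  if (!identical(hit1$family_id, hit2$family_id))
    stop("hits are on different families: ", hit1$family_id, " vs ",
         hit2$family_id)
  m1 <- min(hit1$model_start, hit2$model_start)
  m2 <- max(hit1$model_end, hit2$model_end)
  spans <- lapply(seq_along(msa$seqs), function(r)
    model_span_to_seed_span(msa, map_to_column, r, m1, m2))
  lens <- vapply(spans[!vapply(spans, is.null, logical(1))],
                 function(s) s[2] - s[1] + 1, numeric(1))
  if (!length(lens))
    stop("no seed sequence anchors the span [", m1, ", ", m2,
         "] in family ", hit1$family_id)
  as.integer(floor(mean(lens) + 0.5))
}

#' Build a smoothed fragment-length distribution
#'
#' A 1-amino-acid-resolution histogram over `[min(lengths), max(lengths)]`.
#' Each bin receives `smoothing / n_bins` pseudo-mass before normalisation,
#' so no length inside the support -- and via the `floor`, no length at all
#' -- ever has probability zero when `smoothing > 0`, which the posterior's
#' product form requires.
#'
#' @param lengths Integer fragment lengths (amino acids), at least one.
#' @param smoothing Total pseudo-count weight spread across the support
#'   bins (default 1).
#' @param clip Optional `c(min, max)` (amino acids); lengths outside are
#'   dropped as outliers before building.
#' @return A `FragmentLengthDistribution`: list with `probs` (named numeric
#'   over the support), `support_min`, `support_max`, `floor` (probability
#'   returned for unseen lengths), `n_observations`.
#' @export
build_distribution <- function(lengths, smoothing = 1, clip = NULL) {
  stopifnot(smoothing >= 0)
  lengths <- as.integer(lengths)
  if (!is.null(clip))
    lengths <- lengths[lengths >= clip[1] & lengths <= clip[2]]
  if (!length(lengths))
    stop("no fragment lengths to build a distribution from",
         if (!is.null(clip)) " (all clipped as outliers)" else "")
  smin <- min(lengths)
  smax <- max(lengths)
  bins <- smin:smax
  counts <- tabulate(lengths - smin + 1L, nbins = length(bins))
  pseudo <- smoothing / length(bins)
  probs <- (counts + pseudo) / (length(lengths) + smoothing)
  names(probs) <- bins
  structure(list(probs = probs, support_min = smin, support_max = smax,
                 floor = pseudo / (length(lengths) + smoothing),
                 n_observations = length(lengths)),
            class = "FragmentLengthDistribution")
}

#' @export
print.FragmentLengthDistribution <- function(x, ...) {
  cat("FragmentLengthDistribution on [", x$support_min, ",", x$support_max,
      "] aa from", x$n_observations, "pairs (floor",
      signif(x$floor, 3), ")\n")
  invisible(x)
}

#' Probability of a fragment length
#'
#' Lookup into the smoothed histogram; lengths outside the support return
#' the smoothing floor (the mass of an empty bin), never zero when the
#' distribution was built with `smoothing > 0`.
#'
#' @param dist A `FragmentLengthDistribution`.
#' @param length_aa Fragment length(s), amino acids.
#' @return Probability vector.
#' @export
fragment_probability <- function(dist, length_aa) {
  stopifnot(inherits(dist, "FragmentLengthDistribution"))
  p <- unname(dist$probs[as.character(as.integer(length_aa))])
  p[is.na(p)] <- dist$floor
  p
}

#' Select read pairs uniquely aligned to one family
#'
#' From a per-end hit table, keeps exactly those read pairs where end 1 and
#' end 2 each hit exactly one family and it is the same family. These are
#' the pairs whose alignments are trusted for reference-free fragment-size
#' estimation.
#'
#' @param hits A hit data.frame (columns as in [parse_domtblout()]).
#' @return A data.frame with one row per retained pair: `read_id`,
#'   `family_id`, plus the row indices `row1`, `row2` of the two hits in
#'   `hits`.
#' @export
collect_unique_pairs <- function(hits) {
  out <- data.frame(read_id = character(0), family_id = character(0),
                    row1 = integer(0), row2 = integer(0),
                    stringsAsFactors = FALSE)
  if (!nrow(hits)) return(out)
  idx <- split(seq_len(nrow(hits)), hits$read_id)
  rows <- lapply(idx, function(h) {
    h1 <- h[hits$end[h] == 1L]
    h2 <- h[hits$end[h] == 2L]
    if (!length(h1) || !length(h2)) return(NULL)
    f1 <- unique(hits$family_id[h1])
    f2 <- unique(hits$family_id[h2])
    if (length(f1) != 1L || length(f2) != 1L || f1 != f2) return(NULL)
    c(h1[which.max(hits$score[h1])], h2[which.max(hits$score[h2])])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(out)
  r1 <- vapply(rows, `[`, integer(1), 1L)
  r2 <- vapply(rows, `[`, integer(1), 2L)
  out <- data.frame(read_id = hits$read_id[r1],
                    family_id = hits$family_id[r1],
                    row1 = r1, row2 = r2, stringsAsFactors = FALSE)
  # restore first-occurrence order of the hit table
  out[order(r1), , drop = FALSE]
}

#' Write / read a fragment-length distribution as TSV
#'
#' Two columns: `length_aa`, `probability`. The floor is stored as a
#' comment header so a round trip preserves lookups outside the support.
#'
#' @param dist A `FragmentLengthDistribution`.
#' @param path Output (input) path.
#' @return `path` invisibly; for the reader, the distribution.
#' @export
write_fragdist_tsv <- function(dist, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# floor\t%.17g", dist$floor),
               sprintf("# n_observations\t%d", dist$n_observations),
               "length_aa\tprobability"), con)
  write.table(data.frame(length_aa = as.integer(names(dist$probs)),
                         probability = unname(dist$probs)),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_fragdist_tsv
#' @export
read_fragdist_tsv <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  get_meta <- function(key, default) {
    hit <- grep(paste0("^# ", key, "\t"), meta, value = TRUE)
    if (length(hit)) as.numeric(sub(".*\t", "", hit[1])) else default
  }
  tab <- read.table(text = lines[!startsWith(lines, "#")], sep = "\t",
                    header = TRUE)
  probs <- setNames(tab$probability, tab$length_aa)
  structure(list(probs = probs,
                 support_min = min(tab$length_aa),
                 support_max = max(tab$length_aa),
                 floor = get_meta("floor", min(probs)),
                 n_observations = as.integer(get_meta("n_observations",
                                                      NA_real_))),
            class = "FragmentLengthDistribution")
}
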