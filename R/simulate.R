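# Synthetic benchmark generator: homologous protein families with
# controllable divergence and indels, a held-out member gene per family,
# and paired-end reads sequenced inward (FR) from the two ends of fragments
# drawn from a truncated normal length distribution. Substitutions are
# uniform over the 19 alternative residues, which keeps expectations (mean
# pairwise identity, fragment-length moments) in closed form for testing.

#' Describe a simulation scenario
#'
#' Defaults emulate a short-read paired-end library: 76-bp reads and
#' fragments of 198--801 bp (66--267 amino acids, drawn here from a
#' truncated normal with mean 150 aa and sd 15).
#'
#' @param n_families Number of protein families.
#' @param seeds_per_family Seed sequences per family alignment.
#' @param family_length Family (ancestor) length in amino acids.
#' @param divergence Per-site substitution probability seed vs ancestor.
#' @param indel_rate Per-site probability of a deletion in a seed row, and
#'   of an insertion column after a site (per row).
#' @param member_divergence Divergence of the held-out member gene.
#' @param fragment_mean_aa,fragment_sd_aa,fragment_min_aa,fragment_max_aa
#'   Truncated-normal fragment length distribution, in amino acids.
#' @param read_length_nt Read length in nucleotides.
#' @param n_pairs Number of read pairs.
#' @param error_rate Per-base sequencing substitution probability.
#' @param mate_divergence_rate Fraction of pairs whose end-2 source region
#'   is additionally diverged (emulates a mate falling on a poorly
#'   conserved stretch); 0 disables.
#' @param mate_divergence Per-site substitution probability applied to
#'   those end-2 regions.
#' @param rng_seed Integer seed; the whole simulation is deterministic
#'   given it.
#' @return A `SimScenario` list.
#' @export
simulate_scenario <- function(n_families = 5L, seeds_per_family = 10L,
                              family_length = 300L, divergence = 0.3,
                              indel_rate = 0.02, member_divergence = 0.1,
                              fragment_mean_aa = 150, fragment_sd_aa = 15,
                              fragment_min_aa = 66, fragment_max_aa = 267,
                              read_length_nt = 76L, n_pairs = 1000L,
                              error_rate = 0.005,
                              mate_divergence_rate = 0,
                              mate_divergence = 0, rng_seed = 1L) {
  sc <- list(n_families = as.integer(n_families),
             seeds_per_family = as.integer(seeds_per_family),
             family_length = as.integer(family_length),
             divergence = divergence, indel_rate = indel_rate,
             member_divergence = member_divergence,
             fragment_mean_aa = fragment_mean_aa,
             fragment_sd_aa = fragment_sd_aa,
             fragment_min_aa = as.integer(fragment_min_aa),
             fragment_max_aa = as.integer(fragment_max_aa),
             read_length_nt = as.integer(read_length_nt),
             n_pairs = as.integer(n_pairs), error_rate = error_rate,
             mate_divergence_rate = mate_divergence_rate,
             mate_divergence = mate_divergence,
             rng_seed = as.integer(rng_seed))
  rates <- c(sc$divergence, sc$indel_rate, sc$member_divergence,
             sc$error_rate, sc$mate_divergence_rate, sc$mate_divergence)
  stopifnot(all(rates >= 0), all(rates <= 1),
            sc$fragment_min_aa * 3 >= sc$read_length_nt,
            sc$family_length >= sc$fragment_max_aa,
             sc$fragment_min_aa <= sc$fragment_max_aa)
  structure(sc, class = "SimScenario")
}

# Uniform substitution over the 19 alternative residues at rate p.
mutate_protein <- function(aa, p) {
  hit <- runif(length(aa)) < p
  if (any(hit))
    aa[hit] <- vapply(aa[hit], function(x)
      sample(setdiff(AA_ALPHABET, x), 1L), character(1))
  aa
}

# Codons of the standard genetic code per amino acid (stops excluded).
codons_for <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

# Back-translate a protein with uniform synonymous codon choice.
back_translate <- function(aa, codon_table = codons_for()) {
  paste(vapply(aa, function(x) {
    cs <- codon_table[[x]]
    cs[sample.int(length(cs), 1L)]
  }, character(1)), collapse = "")
}

#' Simulate one protein family and its held-out member gene
#'
#' An ancestor is sampled uniformly from the amino-acid alphabet; each seed
#' derives from it by i.i.d. substitutions at `divergence` plus deletions
#' (gaps in that row) and private insertion columns at `indel_rate`. The
#' held-out member derives from the ancestor at `member_divergence`, never
#' appears among the seeds, and is back-translated with uniform synonymous
#' codon usage.
#'
#' @param scenario A `SimScenario`.
#' @param family_id Family identifier.
#' @param seed Integer seed (defaults to the scenario's).
#' @return List with `msa` (a `SeedAlignment`), `member_aa`, `member_nt`.
#' @export
simulate_family <- function(scenario, family_id = "FAM1",
                            seed = scenario$rng_seed) {
  stopifnot(inherits(scenario, "SimScenario"))
  with_seed(seed, {
    Lf <- scenario$family_length
    anc <- sample(AA_ALPHABET, Lf, replace = TRUE)
    n <- scenario$seeds_per_family
    rows <- vector("list", n)
    ins_after <- vector("list", n)   # per seed: private insertions after site
    for (r in seq_len(n)) {
      aa <- mutate_protein(anc, scenario$divergence)
      del <- runif(Lf) < scenario$indel_rate
      aa[del] <- "-"
      rows[[r]] <- aa
      nins <- rbinom(Lf + 1L, 1L, scenario$indel_rate)
      ins_after[[r]] <- nins  # 0/1 private insert after position k-1
    }
    # Assemble the MSA: ancestor sites are shared columns; each private
    # insertion becomes a column gapped in every other row.
    cols <- vector("list", 0L)
    for (k in 0:Lf) {
      for (r in seq_len(n)) {
        if (ins_after[[r]][k + 1L] == 1L) {
          col <- rep("-", n)
          col[r] <- sample(AA_ALPHABET, 1L)
          cols[[length(cols) + 1L]] <- col
        }
      }
      if (k < Lf)
        cols[[length(cols) + 1L]] <- vapply(rows, `[`, character(1), k + 1L)
    }
    mat <- do.call(cbind, cols)
    seqs <- apply(mat, 1L, paste, collapse = "")
    msa <- new_seed_alignment(family_id,
                              sprintf("%s_seed%02d", family_id, seq_len(n)),
                              seqs)
    member <- mutate_protein(anc, scenario$member_divergence)
    list(msa = msa, member_aa = paste(member, collapse = ""),
         member_nt = back_translate(member))
  })
}

rtruncnorm_int <- function(n, mean, sd, lo, hi) {
  out <- integer(0)
  while (length(out) < n) {
    x <- as.integer(round(rnorm(2L * (n - length(out)) + 10L, mean, sd)))
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

mutate_dna <- function(nt, p) {
  hit <- runif(length(nt)) < p
  if (any(hit))
    nt[hit] <- vapply(nt[hit], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1L), character(1))
  nt
}

#' Simulate paired-end reads from a member gene
#'
#' Fragment lengths are drawn (in amino acids) from the scenario's
#' truncated normal and placed uniformly on the gene; end 1 is the first
#' `read_length_nt` bases of the fragment and end 2 the reverse complement
#' of the last `read_length_nt` bases (FR orientation). Sequencing
#' substitution errors are applied per base at `error_rate`. When the
#' scenario's `mate_divergence_rate` is positive, that fraction of pairs
#' has the protein sequence under the end-2 read additionally mutated at
#' `mate_divergence` before sequencing, emulating a mate on a poorly
#' conserved stretch; such pairs are flagged in the truth table.
#'
#' @param scenario A `SimScenario`.
#' @param gene_nt Nucleotide gene sequence (back-translated member).
#' @param family_id Truth label for the pairs.
#' @param n_pairs Number of pairs (defaults to the scenario's).
#' @param seed Integer seed.
#' @param id_prefix Read id prefix.
#' @return List with `pairs` (read-pair data.frame) and `truth`
#'   (data.frame `read_id`, `family_id`, `true_fragment_aa`,
#'   `mate_diverged`).
#' @export
simulate_pairs <- function(scenario, gene_nt, family_id = "FAM1",
                           n_pairs = scenario$n_pairs,
                           seed = scenario$rng_seed + 1L,
                           id_prefix = family_id) {
  stopifnot(inherits(scenario, "SimScenario"))
  glen <- nchar(gene_nt)
  if (glen < 3L * scenario$fragment_max_aa)
    stop("gene (", glen, " nt) shorter than the maximum fragment (",
         3L * scenario$fragment_max_aa, " nt)")
  rl <- scenario$read_length_nt
  with_seed(seed, {
    gene <- strsplit(gene_nt, "")[[1]]
    flen_aa <- rtruncnorm_int(n_pairs, scenario$fragment_mean_aa,
                              scenario$fragment_sd_aa,
                              scenario$fragment_min_aa,
                              scenario$fragment_max_aa)
    diverged <- runif(n_pairs) < scenario$mate_divergence_rate
    ids <- sprintf("%s_p%06d", id_prefix, seq_len(n_pairs))
    end1 <- character(n_pairs)
    end2 <- character(n_pairs)
    ct <- codons_for()
    for (i in seq_len(n_pairs)) {
      fnt <- 3L * flen_aa[i]
      start <- sample.int(glen - fnt + 1L, 1L)
      frag <- gene[start:(start + fnt - 1L)]
      if (diverged[i]) {
        # mutate, at the protein level, the gene-frame codons fully covered
        # by the end-2 read window, then re-encode them in place
        g_lo <- start + fnt - rl
        g_hi <- start + fnt - 1L
        ci_min <- ceiling((g_lo + 2L) / 3)
        ci_max <- g_hi %/% 3L
        if (ci_max >= ci_min) {
          cod_idx <- ci_min:ci_max
          aa_win <- vapply(cod_idx, function(ci) {
            codon <- paste(gene[(3L * ci - 2L):(3L * ci)], collapse = "")
            as.character(Biostrings::GENETIC_CODE[[codon]])
          }, character(1))
          aa_mut <- mutate_protein(aa_win, scenario$mate_divergence)
          for (jj in which(aa_mut != aa_win)) {
            ci <- cod_idx[jj]
            cs <- ct[[aa_mut[jj]]]
            pos <- (3L * ci - 2L):(3L * ci) - start + 1L
            frag[pos] <- strsplit(cs[sample.int(length(cs), 1L)], "")[[1]]
          }
        }
      }
      r1 <- mutate_dna(frag[1:rl], scenario$error_rate)
      r2 <- mutate_dna(frag[(fnt - rl + 1L):fnt], scenario$error_rate)
      end1[i] <- paste(r1, collapse = "")
      end2[i] <- reverse_complement(paste(r2, collapse = ""))
    }
    list(pairs = data.frame(id = ids, end1 = end1, end2 = end2,
                            qual1 = NA_character_, qual2 = NA_character_,
                            stringsAsFactors = FALSE),
         truth = data.frame(read_id = ids, family_id = family_id,
                            true_fragment_aa = flen_aa,
                            mate_diverged = diverged,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a complete multi-family benchmark dataset
#'
#' Runs [simulate_family()] and [simulate_pairs()] for every family,
#' splitting `n_pairs` evenly, and pools reads and truth. Per-family seeds
#' are derived deterministically from the scenario seed.
#'
#' @param scenario A `SimScenario`.
#' @return List with `msas` (named list of `SeedAlignment`), `members`
#'   (named list of `member_aa` / `member_nt`), `pairs`, `truth`.
#' @export
simulate_dataset <- function(scenario) {
  stopifnot(inherits(scenario, "SimScenario"))
  nf <- scenario$n_families
  per <- diff(round(seq(0, scenario$n_pairs, length.out = nf + 1L)))
  msas <- list()
  members <- list()
  pairs <- list()
  truth <- list()
  for (j in seq_len(nf)) {
    fid <- sprintf("FAM%02d", j)
    fam <- simulate_family(scenario, fid,
                           seed = (scenario$rng_seed + 104729L * j) %%
                             .Machine$integer.max)
    sim <- simulate_pairs(scenario, fam$member_nt, fid,
                          n_pairs = per[j],
                          seed = (scenario$rng_seed + 130363L * j) %%
                            .Machine$integer.max)
    msas[[fid]] <- fam$msa
    members[[fid]] <- fam[c("member_aa", "member_nt")]
    pairs[[j]] <- sim$pairs
    truth[[j]] <- sim$truth
  }
  list(msas = msas, members = members,
       pairs = do.call(rbind, pairs), truth = do.call(rbind, truth))
}

#' Write a simulated dataset to disk
#'
#' Writes `reads_1.fastq`, `reads_2.fastq`, one Stockholm file per family
#' under `families/`, `truth.tsv`, and (when a scenario is supplied and
#' jsonlite is available) a `scenario.json` echo of the parameters.
#'
#' @param dataset Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @param scenario Optional `SimScenario` to echo as JSON.
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(dataset, dir, scenario = NULL) {
  dir.create(file.path(dir, "families"), recursive = TRUE,
             showWarnings = FALSE)
  write_paired_fastq(dataset$pairs, file.path(dir, "reads_1.fastq"),
                     file.path(dir, "reads_2.fastq"))
  for (fid in names(dataset$msas))
    write_stockholm(dataset$msas[[fid]],
                    file.path(dir, "families", paste0(fid, ".sto")))
  write.table(dataset$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(scenario) && requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(unclass(scenario), file.path(dir, "scenario.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
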