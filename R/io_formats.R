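# Readers and writers for the standard formats the tool touches: paired
# FASTA/FASTQ reads, Stockholm seed alignments, HMMER3 ASCII profiles and
# --domtblout tables. No science in this file.

#' Read paired-end reads from FASTA or FASTQ
#'
#' Reads two files (one per end) or a single interleaved file, auto-detecting
#' FASTA vs FASTQ from the first record character. Mate tags are stripped
#' from identifiers before pairing: both the classic `/1`, `/2` suffixes and
#' Casava-style ` 1:...`, ` 2:...` space-delimited tags are recognised,
#' detected per file.
#'
#' @param path1 Path to the first (or interleaved) read file.
#' @param path2 Optional path to the second read file; when `NULL`, `path1`
#'   is treated as interleaved (end1 record immediately followed by its
#'   end2 record).
#'
#' @return A data.frame of read pairs with columns `id`, `end1`, `end2`,
#'   `qual1`, `qual2` (qualities `NA` for FASTA), in the order of the first
#'   file.
#' @export
read_paired_reads <- function(path1, path2 = NULL) {
  r1 <- read_seq_file(path1)
  if (is.null(path2)) {
    n <- nrow(r1)
    if (n %% 2L != 0L)
      stop("interleaved file has an odd number of records: ", path1)
    odd <- seq(1L, n, by = 2L)
    even <- odd + 1L
    id1 <- strip_mate_tag(r1$id[odd])
    id2 <- strip_mate_tag(r1$id[even])
    bad <- which(id1 != id2)
    if (length(bad))
      stop("interleaved records not paired by id: ", r1$id[odd[bad[1]]],
           " followed by ", r1$id[even[bad[1]]])
    out <- data.frame(id = id1, end1 = r1$seq[odd], end2 = r1$seq[even],
                      qual1 = r1$qual[odd], qual2 = r1$qual[even],
                      stringsAsFactors = FALSE)
  } else {
    r2 <- read_seq_file(path2)
    if (attr(r1, "format") != attr(r2, "format"))
      stop("mixed formats: ", path1, " is ", attr(r1, "format"), " but ",
           path2, " is ", attr(r2, "format"))
    id1 <- strip_mate_tag(r1$id)
    id2 <- strip_mate_tag(r2$id)
    pos <- match(id1, id2)
    if (anyNA(pos)) {
      orphans <- id1[is.na(pos)]
      stop("read(s) without a mate in ", path2, ": ",
           paste(head(orphans, 5L), collapse = ", "))
    }
    extra <- setdiff(id2, id1)
    if (length(extra))
      stop("read(s) without a mate in ", path1, ": ",
           paste(head(extra, 5L), collapse = ", "))
    out <- data.frame(id = id1, end1 = r1$seq, end2 = r2$seq[pos],
                      qual1 = r1$qual, qual2 = r2$qual[pos],
                      stringsAsFactors = FALSE)
  }
  if (anyDuplicated(out$id))
    stop("duplicate read pair id: ", out$id[anyDuplicated(out$id)])
  ok <- grepl("^[ACGTUMRWSYKVHDBNacgtumrwsykvhdbn]+$", out$end1) &
        grepl("^[ACGTUMRWSYKVHDBNacgtumrwsykvhdbn]+$", out$end2)
  if (!all(ok))
    stop("non-IUPAC nucleotide characters in read(s): ",
         paste(head(out$id[!ok], 5L), collapse = ", "))
  rownames(out) <- NULL
  out
}

# Low-level single-file reader; returns data.frame(id, seq, qual) plus a
# "format" attribute, via Biostrings.
read_seq_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- substr(readLines(path, n = 1L), 1L, 1L)
  if (identical(first, "@")) {
    # readQualityScaledDNAStringSet warns about dropping metadata columns
    # it never uses; silence just that
    x <- withCallingHandlers(
      Biostrings::readQualityScaledDNAStringSet(path),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    out <- data.frame(id = names(x), seq = as.character(x),
                      qual = as.character(Biostrings::quality(x)),
                      stringsAsFactors = FALSE)
    fmt <- "fastq"
  } else if (identical(first, ">")) {
    x <- Biostrings::readBStringSet(path)
    out <- data.frame(id = names(x), seq = as.character(x),
                      qual = NA_character_, stringsAsFactors = FALSE)
    fmt <- "fasta"
  } else {
    stop("cannot detect FASTA/FASTQ format of ", path,
         " (first character ", dQuote(first), ")")
  }
  rownames(out) <- NULL
  attr(out, "format") <- fmt
  out
}

# Strip /1, /2 suffixes or Casava " 1:...", " 2:..." tags from read names.
# The dialect is detected per identifier vector (per file).
strip_mate_tag <- function(ids) {
  if (all(grepl("/[12]$", ids))) return(sub("/[12]$", "", ids))
  if (all(grepl(" [12](:|$)", ids))) return(sub(" [12](:.*)?$", "", ids))
  ids
}

#' Read a Stockholm 1.0 seed alignment
#'
#' Parses a single-alignment Stockholm file (aligned FASTA is accepted as a
#' fallback). The `#=GC RF` reference annotation line, when present, is
#' retained so model building can use curated match columns. Gap characters
#' `-` and `.` are both treated as gaps downstream.
#'
#' @param path Path to the alignment file.
#' @param family_id Family identifier; default is the `#=GF ID` field when
#'   present, else the file base name.
#'
#' @return A `SeedAlignment`: list with `family_id`, `ids`, `seqs` (aligned
#'   strings, equal length), `n_columns`, and `rf` (the RF string or `NULL`).
#' @export
read_stockholm <- function(path, family_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop("empty alignment file: ", path)
  if (startsWith(lines[1], ">")) {
    x <- Biostrings::readBStringSet(path)
    return(new_seed_alignment(
      family_id %||% sub("\\.[^.]*$", "", basename(path)),
      names(x), as.character(x), rf = NULL))
  }
  if (!grepl("^# STOCKHOLM 1\\.0", lines[1]))
    stop("not a Stockholm 1.0 file (missing header): ", path)
  ids <- character(0)
  seqs <- list()
  rf <- ""
  gf_id <- NULL
  for (ln in lines[-1]) {
    if (grepl("^//", ln)) break
    if (!nzchar(trimws(ln))) next
    if (grepl("^#=GF +ID +", ln)) {
      gf_id <- sub("^#=GF +ID +", "", ln)
      next
    }
    if (grepl("^#=GC +RF +", ln)) {
      rf <- paste0(rf, sub("^#=GC +RF +", "", ln))
      next
    }
    if (startsWith(ln, "#")) next
    parts <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    if (length(parts) != 2L)
      stop("malformed Stockholm sequence line: ", ln)
    i <- match(parts[1], ids)
    if (is.na(i)) {
      ids <- c(ids, parts[1])
      seqs[[length(ids)]] <- parts[2]
    } else {
      seqs[[i]] <- paste0(seqs[[i]], parts[2])  # multi-block alignment
    }
  }
  if (!length(ids)) stop("empty alignment: ", path)
  new_seed_alignment(family_id %||% gf_id %||%
                       sub("\\.[^.]*$", "", basename(path)),
                     ids, unlist(seqs),
                     rf = if (nzchar(rf)) rf else NULL)
}

new_seed_alignment <- function(family_id, ids, seqs, rf = NULL) {
  nc <- unique(nchar(seqs))
  if (length(nc) != 1L)
    stop("ragged alignment rows (widths ", paste(nc, collapse = ", "),
         ") in family ", family_id)
  if (!is.null(rf) && nchar(rf) != nc)
    stop("RF annotation width ", nchar(rf), " != alignment width ", nc)
  structure(list(family_id = family_id, ids = ids, seqs = unname(seqs),
                 n_columns = nc, rf = rf),
            class = "SeedAlignment")
}

#' @export
print.SeedAlignment <- function(x, ...) {
  cat("SeedAlignment", x$family_id, "-", length(x$ids), "rows x",
      x$n_columns, "columns",
      if (!is.null(x$rf)) "(RF annotated)" else "", "\n")
  invisible(x)
}

#' Write a Stockholm 1.0 seed alignment
#'
#' @param msa A `SeedAlignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stockholm <- function(msa, path) {
  stopifnot(inherits(msa, "SeedAlignment"))
  w <- max(nchar(msa$ids), if (!is.null(msa$rf)) nchar("#=GC RF") else 0L)
  lines <- c("# STOCKHOLM 1.0",
             paste("#=GF ID", msa$family_id),
             sprintf("%-*s %s", w, msa$ids, msa$seqs))
  if (!is.null(msa$rf))
    lines <- c(lines, sprintf("%-*s %s", w, "#=GC RF", msa$rf))
  writeLines(c(lines, "//"), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a HMMER3 ASCII profile HMM
#'
#' Parses a `HMMER3/f` format ASCII `.hmm` file into the package's
#' `ProfileHMM` representation, converting the file's negative-log
#' probabilities back to probabilities. The `MAP` column annotation and the
#' `STATS LOCAL VITERBI` Gumbel parameters are captured when present; when
#' the `COMPO` line is absent the background defaults to uniform and
#' `background_default = TRUE` is recorded.
#'
#' @param path Path to the `.hmm` file (first model only).
#' @return A `ProfileHMM` object (see [build_from_msa()]).
#' @export
read_hmmer3_hmm <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (!grepl("^HMMER3/f", lines[1]))
    stop("unsupported profile format (expected HMMER3/f): ",
         strsplit(lines[1], " ")[[1]][1])
  from_nl <- function(tok) {
    v <- ifelse(tok == "*", Inf, suppressWarnings(as.numeric(tok)))
    if (anyNA(v)) stop("unparseable score field in ", path)
    exp(-v)
  }
  name <- NULL; L <- NULL; mu <- NULL; lambda <- NULL
  bg <- NULL; has_map <- FALSE
  i <- 2L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    tok <- strsplit(ln, "[[:space:]]+")[[1]]
    if (tok[1] == "NAME") name <- tok[2]
    if (tok[1] == "LENG") L <- as.integer(tok[2])
    if (tok[1] == "MAP") has_map <- toupper(tok[2]) == "YES"
    if (tok[1] == "STATS" && tok[2] == "LOCAL" && tok[3] == "VITERBI") {
      mu <- as.numeric(tok[4]); lambda <- as.numeric(tok[5])
    }
    if (tok[1] == "HMM") break
    i <- i + 1L
  }
  if (is.null(L)) stop("no LENG line in ", path)
  i <- i + 2L  # skip the two header lines of the model section
  tok <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
  if (tok[1] == "COMPO") {
    bg <- from_nl(tok[2:21])
    i <- i + 1L
  }
  background_default <- is.null(bg)
  if (background_default) bg <- rep(1 / 20, 20)
  bg <- bg / sum(bg)
  # node 0: insert-0 emissions + begin transitions (both unused by the
  # local-alignment model here; skipped)
  i <- i + 2L
  me <- matrix(0, L, 20, dimnames = list(NULL, AA_ALPHABET))
  ie <- matrix(0, L, 20, dimnames = list(NULL, AA_ALPHABET))
  tr <- matrix(0, L, 7, dimnames = list(NULL, TRANS_NAMES))
  map <- integer(L)
  for (k in seq_len(L)) {
    t1 <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (as.integer(t1[1]) != k) stop("node numbering off at node ", k)
    me[k, ] <- from_nl(t1[2:21])
    map[k] <- if (has_map && length(t1) >= 22 && t1[22] != "-")
      as.integer(t1[22]) else k
    t2 <- strsplit(trimws(lines[i + 1L]), "[[:space:]]+")[[1]]
    ie[k, ] <- from_nl(t2[1:20])
    t3 <- strsplit(trimws(lines[i + 2L]), "[[:space:]]+")[[1]]
    tr[k, ] <- from_nl(t3[1:7])
    i <- i + 3L
  }
  if (any(!is.finite(me)) || any(me < 0) || any(!is.finite(ie)))
    stop("invalid probabilities after conversion in ", path)
  me <- me / rowSums(me)
  ie <- ie / rowSums(ie)
  new_profile_hmm(name %||% basename(path), me, ie, tr, bg, map,
                  gumbel_mu = mu, gumbel_lambda = lambda,
                  background_default = background_default)
}

#' Write a profile HMM in HMMER3/f ASCII format
#'
#' @param hmm A `ProfileHMM`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hmmer3_hmm <- function(hmm, path) {
  stopifnot(inherits(hmm, "ProfileHMM"))
  nl <- function(p) ifelse(p <= 0, "*", sprintf("%.5f", -log(p)))
  con <- file(path, "w")
  on.exit(close(con))
  wr <- function(...) writeLines(paste0(...), con)
  wr("HMMER3/f [shortpair]")
  wr("NAME  ", hmm$family_id)
  wr("LENG  ", hmm$L)
  wr("ALPH  amino")
  wr("MAP   yes")
  if (!is.null(hmm$gumbel_mu))
    wr(sprintf("STATS LOCAL VITERBI  %.4f  %.5f",
               hmm$gumbel_mu, hmm$gumbel_lambda))
  wr("HMM          ", paste(sprintf("%8s", AA_ALPHABET), collapse = " "))
  wr("            ", paste(sprintf("%8s", TRANS_NAMES), collapse = " "))
  wr("  COMPO   ", paste(nl(hmm$background), collapse = "  "))
  # node-0 insert emissions (background) and begin transitions (uniform-ish
  # placeholders; the local aligner does not use them)
  wr("          ", paste(nl(hmm$background), collapse = "  "))
  wr("          ", paste(nl(rep(1 / 7, 7)), collapse = "  "))
  for (k in seq_len(hmm$L)) {
    wr(sprintf("%7d   ", k),
       paste(nl(hmm$match_emissions[k, ]), collapse = "  "),
       sprintf("  %6d", hmm$map_to_column[k]))
    wr("          ", paste(nl(hmm$insert_emissions[k, ]), collapse = "  "))
    wr("          ", paste(nl(hmm$transitions[k, ]), collapse = "  "))
  }
  wr("//")
  invisible(path)
}

#' Parse a HMMER3 --domtblout domain table
#'
#' Maps each domain line of a per-domain hits table to a `DomainHit` row,
#' taking model coordinates from the "hmm coord" from/to columns (1-based
#' inclusive, HMMER's convention), the per-domain bit score, and the
#' independent E-value.
#'
#' @param path Path to the whitespace-delimited table; lines starting with
#'   `#` are skipped.
#' @return A data.frame of hits with columns `read_id`, `end`, `frame`,
#'   `family_id`, `model_start`, `model_end`, `seq_start`, `seq_end`,
#'   `score`, `evalue`. The mate tag on the target name, when present,
#'   populates `end`; `frame` is `NA` (unknown to HMMER's table).
#' @export
parse_domtblout <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(trimws(lines))
  rows <- lapply(which(keep), function(i) {
    tok <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(tok) < 21L)
      stop("short domtblout line ", i, " (", length(tok), " fields)")
    tname <- tok[1]
    end <- if (grepl("/1$", tname)) 1L else if (grepl("/2$", tname)) 2L
           else NA_integer_
    data.frame(read_id = strip_mate_tag(tname), end = end,
               frame = NA_integer_, family_id = tok[4],
               model_start = as.integer(tok[16]),
               model_end = as.integer(tok[17]),
               seq_start = as.integer(tok[18]),
               seq_end = as.integer(tok[19]),
               score = as.numeric(tok[14]), evalue = as.numeric(tok[13]),
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) return(empty_hits())
  do.call(rbind, rows)
}

# The canonical empty hit table; every stage returns/accepts this shape.
empty_hits <- function() {
  data.frame(read_id = character(0), end = integer(0), frame = integer(0),
             family_id = character(0), model_start = integer(0),
             model_end = integer(0), seq_start = integer(0),
             seq_end = integer(0), score = numeric(0), evalue = numeric(0),
             stringsAsFactors = FALSE)
}

#' Write paired FASTQ files
#'
#' @param pairs A read-pair data.frame as returned by [read_paired_reads()]
#'   or [simulate_pairs()].
#' @param path1,path2 Output paths for end 1 and end 2.
#' @return `c(path1, path2)`, invisibly.
#' @export
write_paired_fastq <- function(pairs, path1, path2) {
  q1 <- ifelse(is.na(pairs$qual1), strrep("I", nchar(pairs$end1)), pairs$qual1)
  q2 <- ifelse(is.na(pairs$qual2), strrep("I", nchar(pairs$end2)), pairs$qual2)
  writeLines(as.vector(rbind(paste0("@", pairs$id, "/1"), pairs$end1,
                             "+", q1)), path1)
  writeLines(as.vector(rbind(paste0("@", pairs$id, "/2"), pairs$end2,
                             "+", q2)), path2)
  invisible(c(path1, path2))
}
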