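#' Trim 3' adapters from small-RNA reads
#'
#' The leftmost occurrence of an adapter prefix of at least
#' `cfg$adapter_seed_len` nt (default 7), with at most `cfg$adapter_mm`
#' mismatches, truncates the read at that position. Reads with no
#' detectable adapter are kept whole; reads whose trimmed insert is
#' shorter than `cfg$min_read_len` get an NA (removal) verdict.
#'
#' @param seqs character vector of read sequences (RNA alphabet).
#' @param adapter the 3' adapter sequence (>= 7 nt, same alphabet).
#' @param cfg a [milr_config()].
#' @return character vector: trimmed sequence, or NA for removed reads.
#' @export
trim_adapter <- function(seqs, adapter, cfg = milr_config()) {
  adapter <- normalize_alphabet(adapter, "rna")
  if (nchar(adapter) < 7L) stop("adapter must be at least 7 nt")
  seed_len <- cfg$adapter_seed_len
  seed <- utf8ToInt(substr(adapter, 1L, seed_len))
  vapply(seqs, function(s) {
    v <- utf8ToInt(s)
    n <- length(v)
    cut <- NA_integer_
    if (n >= seed_len) {
      for (p in 0:(n - seed_len)) {
        mm <- sum(v[(p + 1):(p + seed_len)] != seed)
        if (mm <= cfg$adapter_mm) { cut <- p; break }
      }
    }
    if (is.na(cut)) return(s)                      # no adapter: keep whole
    if (cut < cfg$min_read_len) return(NA_character_)  # too short after trim
    substr(s, 1L, cut)
  }, character(1), USE.NAMES = FALSE)
}

#' Quality-filter reads
#'
#' A read is dropped when its mean Phred score falls below
#' `cfg$min_mean_q` or when it contains an N. Reads without quality
#' strings default to keep (FASTA input).
#'
#' @param seqs character vector of read sequences.
#' @param qual character vector of Phred+33 quality strings (NA allowed).
#' @param cfg a [milr_config()].
#' @return logical keep vector.
#' @export
quality_filter <- function(seqs, qual = NULL, cfg = milr_config()) {
  keep <- !grepl("N", seqs, fixed = TRUE)
  if (!is.null(qual)) {
    meanq <- vapply(seq_along(qual), function(i) {
      if (is.na(qual[i])) return(Inf)
      mean(utf8ToInt(qual[i]) - 33L)
    }, numeric(1))
    keep <- keep & meanq >= cfg$min_mean_q
  }
  keep
}

#' Run the full small-RNA preprocessing for one library
#'
#' Adapter trimming, quality filtering, then length filtering to
#' `[min_read_len, max_read_len]`.
#'
#' @param records a sequence table from [read_fastq()] or [read_fasta()].
#' @param adapter 3' adapter sequence.
#' @param cfg a [milr_config()].
#' @return character vector of clean read sequences (one entry per
#'   surviving read; multiplicities preserved).
#' @export
preprocess_library <- function(records, adapter, cfg = milr_config()) {
  n0 <- nrow(records)
  keep <- quality_filter(records$seq, records$qual, cfg)
  seqs <- records$seq[keep]
  trimmed <- trim_adapter(seqs, adapter, cfg)
  trimmed <- trimmed[!is.na(trimmed)]
  len <- nchar(trimmed)
  out <- trimmed[len >= cfg$min_read_len & len <= cfg$max_read_len]
  stage_log("preprocess", n0, length(out))
  out
}

#' Collapse clean reads into grouped sRNAs with per-library counts
#'
#' One row per distinct sequence with its exact multiplicity in each
#' library and the derived library-of-origin class: `M` (mycelium only),
#' `F` (fruiting body only) or `B` (both). Rows are sorted by total count
#' descending, ties broken lexicographically by sequence.
#'
#' @param reads_MY,reads_FB character vectors of clean read sequences.
#' @return data.frame of class `grouped_srna` with columns `sequence`,
#'   `count_MY`, `count_FB`, `lib`.
#' @examples
#' group_reads(c("ACGU", "ACGU", "GGGC"), "ACGU")
#' @export
group_reads <- function(reads_MY, reads_FB) {
  all_seq <- sort(unique(c(reads_MY, reads_FB)))
  if (!length(all_seq)) {
    out <- data.frame(sequence = character(), count_MY = integer(),
                      count_FB = integer(), lib = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("grouped_srna", "data.frame")
    return(out)
  }
  cm <- tabulate(match(reads_MY, all_seq), nbins = length(all_seq))
  cf <- tabulate(match(reads_FB, all_seq), nbins = length(all_seq))
  out <- data.frame(sequence = all_seq, count_MY = cm, count_FB = cf,
                    stringsAsFactors = FALSE)
  out$lib <- ifelse(out$count_FB == 0L, "M",
                    ifelse(out$count_MY == 0L, "F", "B"))
  ord <- order(-(out$count_MY + out$count_FB), out$sequence)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("grouped_srna", "data.frame")
  out
}

#' Sequence length histogram and 5' nucleotide frequency
#'
#' @param seqs character vector of sequences.
#' @return `length_histogram`: named integer vector (length -> count),
#'   sorted by length. `five_prime_freq`: named integer vector over
#'   A, C, G, U.
#' @export
length_histogram <- function(seqs) {
  if (!length(seqs)) return(setNames(integer(0), character(0)))
  tab <- table(nchar(seqs))
  setNames(as.integer(tab), names(tab))
}

#' @rdname length_histogram
#' @export
five_prime_freq <- function(seqs) {
  if (!length(seqs)) return(setNames(integer(0), character(0)))
  first <- substr(seqs, 1L, 1L)
  bases <- c("A", "C", "G", "U")
  vapply(bases, function(b) sum(first == b), integer(1))
}

#' Modal value of a length histogram
#'
#' @param hist output of [length_histogram()].
#' @return the most frequent length (smallest on ties), or NA if empty.
#' @export
modal_length <- function(hist) {
  if (!length(hist)) return(NA_integer_)
  as.integer(names(hist)[which.max(hist)])
}
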