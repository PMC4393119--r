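#' Locate a precursor on genome scaffolds by exact match
#'
#' Searches the precursor (as DNA, U -> T) and its reverse complement over
#' all scaffolds. A unique hit yields a stranded placement; with multiple
#' exact hits the first by (scaffold id, position, + before -) is
#' returned with `multi_hit = TRUE`.
#'
#' @param precursor precursor sequence (RNA or DNA).
#' @param scaffolds sequence table of genome scaffolds ([read_fasta()]
#'   with `moltype = "dna"`) or a named character vector.
#' @param precursor_id id recorded in the result.
#' @return one-row data.frame (`precursor_id`, `scaffold`, `start`
#'   0-based, `strand`, `multi_hit`), or NULL when the precursor is
#'   absent.
#' @export
place_on_genome <- function(precursor, scaffolds, precursor_id = "precursor") {
  if (is.data.frame(scaffolds)) {
    scaffolds <- setNames(scaffolds$seq, scaffolds$id)
  }
  fwd <- chartr("U", "T", toupper(precursor))
  rev <- revcomp(fwd)
  hits <- list()
  for (sc in sort(names(scaffolds))) {
    s <- scaffolds[[sc]]
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") fwd else rev
      m <- gregexpr(pat, s, fixed = TRUE)[[1]]
      if (m[1] == -1L) next
      for (p in as.integer(m)) {
        hits[[length(hits) + 1L]] <- data.frame(
          precursor_id = precursor_id, scaffold = sc, start = p - 1L,
          strand = strand, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) return(NULL)
  hits <- do.call(rbind, hits)
  hits <- hits[order(hits$scaffold, hits$start, hits$strand), , drop = FALSE]
  out <- hits[1L, , drop = FALSE]
  out$multi_hit <- nrow(hits) > 1L
  rownames(out) <- NULL
  out
}

#' Classify the genomic context of a placement
#'
#' Precedence: exon overlap on the opposite strand -> `exon_antisense`;
#' exon overlap on the same strand -> `exon_sense`; otherwise intron
#' overlap on any strand -> `intron`; otherwise `intergenic`. Overlap
#' means at least one shared base (0-based half-open intervals).
#'
#' @param placement one-row data.frame from [place_on_genome()] plus an
#'   `end` column, or a list with `scaffold`, `start`, `end`, `strand`.
#' @param genes a `gene_models` data.frame from [read_gff3()].
#' @return one of `"intergenic"`, `"intron"`, `"exon_antisense"`,
#'   `"exon_sense"`.
#' @export
classify_context <- function(placement, genes) {
  st <- placement$start
  en <- placement$end
  overlaps <- function(a1, a2, b1, b2) a1 < b2 & b1 < a2
  if (nrow(genes)) {
    ex <- genes[overlaps(st, en, genes$start, genes$end), , drop = FALSE]
    ex <- ex[ex$scaffold == placement$scaffold, , drop = FALSE]
    if (nrow(ex)) {
      return(if (any(ex$strand != placement$strand)) "exon_antisense"
             else "exon_sense")
    }
    introns <- gene_introns(genes)
    int <- introns[introns$scaffold == placement$scaffold &
                     overlaps(st, en, introns$start, introns$end), ,
                   drop = FALSE]
    if (nrow(int)) return("intron")
  }
  "intergenic"
}

#' Place and classify a set of precursors
#'
#' @param precursors named character vector (precursor id -> sequence).
#' @param scaffolds genome scaffolds as in [place_on_genome()].
#' @param genes a `gene_models` data.frame.
#' @return data.frame with one row per placed precursor: `precursor_id`,
#'   `scaffold`, `start`, `end`, `strand`, `multi_hit`, `context`.
#' @export
genome_context <- function(precursors, scaffolds, genes) {
  rows <- list()
  for (id in names(precursors)) {
    pl <- place_on_genome(precursors[[id]], scaffolds, precursor_id = id)
    if (is.null(pl)) next
    pl$end <- pl$start + nchar(precursors[[id]])
    pl$context <- classify_context(pl, genes)
    rows[[length(rows) + 1L]] <- pl
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(precursor_id = character(), scaffold = character(),
               start = integer(), strand = character(),
               multi_hit = logical(), end = integer(), context = character(),
               stringsAsFactors = FALSE)
  stage_log("genome_context", length(precursors), nrow(out))
  out
}

#' Estimate genome size from the k-mer multiplicity spectrum
#'
#' Counts all k-mers of the reads, builds the multiplicity histogram,
#' finds the primary peak depth d (multiplicities 1-2, the error
#' shoulder, are ignored; the histogram is smoothed with a 5-wide running
#' mean before the peak is taken, which stabilizes the mode at desk
#' scale), and returns `total_kmer_count / d`.
#'
#' @param reads sequence table ([read_fasta()]/[read_fastq()]) or a
#'   character vector of read sequences.
#' @param k odd k-mer size in 11..31.
#' @return estimated genome size in bp.
#' @export
kmer_genome_size <- function(reads, k = 17L) {
  if (is.data.frame(reads)) reads <- reads$seq
  if (!length(reads)) stop("empty read set")
  if (k %% 2L == 0L || k < 11L || k > 31L) stop("k must be odd and in 11..31")
  kmers <- unlist(lapply(reads, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1L), k:n)
  }), use.names = FALSE)
  if (!length(kmers)) stop("reads shorter than k")
  mult <- table(table(kmers))
  depth <- as.integer(names(mult))
  cnt <- as.numeric(mult)
  keep <- depth >= 3L
  if (!any(keep)) stop("no k-mer peak above the error shoulder")
  depth <- depth[keep]; cnt <- cnt[keep]
  # smooth over a dense grid so absent depths count as zero
  grid <- seq(min(depth), max(depth))
  dense <- setNames(numeric(length(grid)), grid)
  dense[as.character(depth)] <- cnt
  sm <- stats::filter(dense, rep(1 / 5, 5), sides = 2)
  sm[is.na(sm)] <- dense[is.na(sm)]
  d <- grid[which.max(sm)]
  length(kmers) / d
}
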