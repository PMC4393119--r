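#' Read a FASTA file into a sequence table
#'
#' Sequences are uppercased and normalized to the requested molecule type
#' (`T` to `U` for RNA, `U` to `T` for DNA). Input order is preserved.
#'
#' @param path path to a FASTA file.
#' @param moltype `"rna"` or `"dna"`; the internal alphabet to normalize to.
#' @return a data.frame with columns `id`, `seq`, `qual` (NA for FASTA) and
#'   attribute `moltype`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "ACGT"), fa)
#' read_fasta(fa, moltype = "rna")$seq  # "ACGU"
#' @export
read_fasta <- function(path, moltype = c("rna", "dna")) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) stop("malformed FASTA in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  ids <- names(set)
  seqs <- as.character(set)
  new_seq_records(ids, seqs, qual = NULL, moltype = moltype, path = path)
}

#' Read a FASTQ file (Phred+33) into a sequence table
#'
#' @inheritParams read_fasta
#' @return as [read_fasta()], with `qual` holding the Phred+33 quality
#'   string of each read. Use [phred_scores()] to decode.
#' @export
read_fastq <- function(path, moltype = c("rna", "dna")) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L) {
    return(new_seq_records(character(), character(), character(), moltype, path))
  }
  if (length(lines) %% 4L != 0L) {
    stop("truncated FASTQ (line count not a multiple of 4): ", path)
  }
  idx <- seq(1L, length(lines), by = 4L)
  hdr <- lines[idx]
  if (any(substr(hdr, 1L, 1L) != "@")) {
    stop("malformed FASTQ header at line ", idx[which(substr(hdr, 1, 1) != "@")[1]])
  }
  ids <- sub("\\s.*$", "", substring(hdr, 2L))
  seqs <- lines[idx + 1L]
  qual <- lines[idx + 3L]
  bad <- nchar(qual) != nchar(seqs)
  if (any(bad)) {
    stop("sequence/quality length mismatch for read '", ids[which(bad)[1]], "'")
  }
  new_seq_records(ids, seqs, qual, moltype, path)
}

new_seq_records <- function(ids, seqs, qual, moltype, path = "<memory>") {
  if (length(ids) && anyDuplicated(ids)) {
    stop("duplicate sequence id '", ids[duplicated(ids)][1], "' in ", path)
  }
  if (length(seqs) && any(!nzchar(seqs))) {
    stop("empty sequence for id '", ids[!nzchar(seqs)][1], "' in ", path)
  }
  seqs <- normalize_alphabet(seqs, moltype)
  df <- data.frame(id = as.character(ids), seq = seqs,
                   qual = if (is.null(qual)) rep(NA_character_, length(ids))
                          else as.character(qual),
                   stringsAsFactors = FALSE)
  attr(df, "moltype") <- moltype
  df
}

normalize_alphabet <- function(seqs, moltype) {
  seqs <- toupper(seqs)
  seqs <- if (moltype == "rna") chartr("T", "U", seqs) else chartr("U", "T", seqs)
  ok <- grepl("^[ACGUTN]*$", seqs)
  if (any(!ok)) stop("non-nucleotide characters in sequence: ",
                     substr(seqs[!ok][1], 1, 40))
  seqs
}

#' Decode Phred+33 quality strings to integer scores
#'
#' @param qual character vector of quality strings.
#' @return list of integer vectors (NULL for NA entries).
#' @export
phred_scores <- function(qual) {
  lapply(qual, function(q) {
    if (is.na(q)) NULL else utf8ToInt(q) - 33L
  })
}

#' Write sequence tables back to FASTA / FASTQ
#'
#' @param records a sequence table as returned by [read_fasta()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fasta <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(records)) {
    writeLines(paste0(">", records$id, "\n", records$seq), con, sep = "\n")
  }
  invisible(path)
}

#' @rdname write_fasta
#' @export
write_fastq <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(records)) {
    qual <- ifelse(is.na(records$qual),
                   vapply(nchar(records$seq),
                          function(n) strrep("I", n), character(1)),
                   records$qual)
    writeLines(paste0("@", records$id, "\n", records$seq, "\n+\n", qual),
               con, sep = "\n")
  }
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/exon features (1-based inclusive coordinates on file),
#' resolves each exon to its parent gene through the mRNA layer, and
#' returns exon intervals in the package's internal 0-based half-open
#' convention.
#'
#' @param path path to a GFF3 file.
#' @return a data.frame of class `gene_models` with one row per exon:
#'   columns `gene_id`, `scaffold`, `strand`, `start`, `end` (0-based
#'   half-open), sorted by gene then start.
#' @seealso [gene_introns()], [classify_context()]
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readLines(path)
  body <- raw[!grepl("^#", raw) & nzchar(trimws(raw))]
  empty <- empty_gene_models()
  if (length(body) == 0L) return(empty)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("malformed GFF3 in ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  ids <- if ("ID" %in% names(md)) as.character(md$ID) else rep(NA_character_, length(gr))
  parents <- if ("Parent" %in% names(md)) {
    vapply(md$Parent, function(p) if (length(p)) as.character(p)[1] else NA_character_,
           character(1))
  } else rep(NA_character_, length(gr))

  # map mRNA id -> gene id; exons may point at either layer
  tx <- type %in% c("mRNA", "transcript")
  tx_parent <- setNames(parents[tx], ids[tx])
  gene_ids <- ids[type == "gene"]

  ex <- which(type == "exon")
  if (length(ex) == 0L) return(empty)
  resolve <- function(p) {
    if (is.na(p)) return(NA_character_)
    if (p %in% gene_ids) return(p)
    if (p %in% names(tx_parent)) return(tx_parent[[p]])
    NA_character_
  }
  gid <- vapply(parents[ex], resolve, character(1))
  if (any(is.na(gid))) {
    stop("exon without resolvable gene parent (Parent=",
         parents[ex][is.na(gid)][1], ")")
  }
  df <- data.frame(
    gene_id = gid,
    scaffold = as.character(GenomicRanges::seqnames(gr[ex])),
    strand = as.character(GenomicRanges::strand(gr[ex])),
    start = GenomicRanges::start(gr[ex]) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr[ex]),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$gene_id, df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("gene_models", "data.frame")
  df
}

empty_gene_models <- function() {
  df <- data.frame(gene_id = character(), scaffold = character(),
                   strand = character(), start = integer(), end = integer(),
                   stringsAsFactors = FALSE)
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Write gene models to GFF3 (1-based inclusive on file)
#'
#' Emits gene, mRNA and exon features so that [read_gff3()] round-trips.
#'
#' @param models a `gene_models` data.frame.
#' @param path output path.
#' @export
write_gff3 <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in unique(models$gene_id)) {
    ex <- models[models$gene_id == g, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    sc <- ex$scaffold[1]; strand <- ex$strand[1]
    g1 <- min(ex$start) + 1L; g2 <- max(ex$end)
    tid <- paste0(g, ".t1")
    writeLines(c(
      sprintf("%s\tmilrseek\tgene\t%d\t%d\t.\t%s\t.\tID=%s", sc, g1, g2, strand, g),
      sprintf("%s\tmilrseek\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              sc, g1, g2, strand, tid, g),
      sprintf("%s\tmilrseek\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
              sc, ex$start + 1L, ex$end, strand, tid, seq_len(nrow(ex)), tid)
    ), con)
  }
  invisible(path)
}

#' Derive intron intervals from gene models
#'
#' Introns are exactly the gaps between consecutive exons of a gene.
#'
#' @param models a `gene_models` data.frame.
#' @return data.frame with columns `gene_id`, `scaffold`, `strand`,
#'   `start`, `end` (0-based half-open), one row per intron.
#' @export
gene_introns <- function(models) {
  out <- lapply(unique(models$gene_id), function(g) {
    ex <- models[models$gene_id == g, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) < 2L) return(NULL)
    data.frame(gene_id = g, scaffold = ex$scaffold[1], strand = ex$strand[1],
               start = ex$end[-nrow(ex)], end = ex$start[-1L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), scaffold = character(),
                      strand = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Reverse complement of a nucleotide string
#'
#' Alphabet-aware: RNA input returns RNA, DNA returns DNA.
#'
#' @param x character vector of sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  rc <- function(s) {
    is_rna <- grepl("U", s, fixed = TRUE) || !grepl("T", s, fixed = TRUE)
    comp <- if (is_rna) chartr("ACGUN", "UGCAN", s) else chartr("ACGTN", "TGCAN", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }
  vapply(x, rc, character(1), USE.NAMES = FALSE)
}

#' Structured one-line stage log
#'
#' @param stage stage name.
#' @param n_in,n_out input/output item counts.
#' @param extra optional named list appended as key=value pairs.
#' @keywords internal
stage_log <- function(stage, n_in, n_out, extra = NULL) {
  msg <- sprintf("[%s] in=%d out=%d", stage, n_in, n_out)
  if (length(extra)) {
    msg <- paste(msg, paste(names(extra), unlist(extra), sep = "=", collapse = " "))
  }
  message(msg)
  invisible(msg)
}
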