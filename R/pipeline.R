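#' Load the bundled A. cinnamomea milRNA candidate catalog
#'
#' The package ships the published catalog of 63 predicted novel milRNA
#' candidates of *Antrodia cinnamomea* (accessions `aci-milR-*`, with
#' library class `M`/`F`/`B`, source contig, mature sequence and read
#' count) and the 4 conserved miRNA records, as plain TSV under
#' `inst/extdata`. They are used as a reference data set for the
#' candidate data model and its summaries.
#'
#' @return data.frame with columns `lib`, `accession`, `contig_id`,
#'   `sequence`, `reads` (conserved catalog: `lib`, `mir_name`,
#'   `sequence`, `reads`).
#' @export
load_milr_catalog <- function() {
  path <- system.file("extdata", "aci_milR_catalog.tsv", package = "milrseek")
  x <- read.delim(path, stringsAsFactors = FALSE)
  validate_catalog(x, id_col = "accession")
  x
}

#' @rdname load_milr_catalog
#' @export
load_conserved_catalog <- function() {
  path <- system.file("extdata", "aci_conserved_miRNA.tsv",
                      package = "milrseek")
  x <- read.delim(path, stringsAsFactors = FALSE)
  validate_catalog(x, id_col = "mir_name")
  x
}

validate_catalog <- function(x, id_col) {
  stopifnot(all(c("lib", id_col, "sequence", "reads") %in% names(x)))
  if (!all(x$lib %in% c("M", "F", "B"))) stop("invalid library class")
  if (!all(grepl("^[ACGU]+$", x$sequence))) stop("non-RNA catalog sequence")
  if (anyDuplicated(x[[id_col]])) stop("duplicate catalog id")
  if (!all(x$reads >= 1L)) stop("catalog read counts must be >= 1")
  invisible(x)
}

#' Render a folded precursor with its candidate reads marked
#'
#' Emits the sequence line, the dot-bracket line, and one marker line per
#' candidate: `=` under milR intervals (uppercase role marker `M` at the
#' 5' end) and `-` under milR* intervals (`*` marker).
#'
#' @param folded a `folded_contig`.
#' @param candidates candidate rows (from [call_candidates()]) placed on
#'   this precursor.
#' @return character vector of aligned lines (equal width).
#' @export
render_precursor <- function(folded, candidates = NULL) {
  n <- nchar(folded$seq)
  lines <- c(folded$seq, folded$dotbracket)
  if (!is.null(candidates) && nrow(candidates)) {
    for (k in seq_len(nrow(candidates))) {
      mk <- rep(" ", n)
      a <- candidates$start[k] + 1L
      b <- min(n, candidates$start[k] + nchar(candidates$sequence[k]))
      fill <- if (candidates$role[k] == "milR") "=" else "-"
      mk[a:b] <- fill
      mk[a] <- if (candidates$role[k] == "milR") "M" else "*"
      lines <- c(lines, paste(mk, collapse = ""))
    }
  }
  lines
}

read_truth <- function(path) {
  hdr <- readLines(path, n = 1L)
  meta <- list()
  if (startsWith(hdr, "#")) {
    kv <- strsplit(trimws(sub("^#", "", hdr)), "\\s+")[[1]]
    for (item in kv) {
      p <- strsplit(item, "=", fixed = TRUE)[[1]]
      meta[[p[1]]] <- p[2]
    }
  }
  loci <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  list(loci = loci, meta = meta)
}

#' Run the whole pipeline end to end
#'
#' Executes the stages in dependency order: simulate (optional) ->
#' preprocess -> fold -> discover -> deg -> targets -> context -> report.
#' All thresholds come from one [milr_config()]; rerunning with an
#' identical config and inputs reproduces identical outputs. Any missing
#' input for a requested stage raises a usage error before anything runs.
#'
#' @param out_dir directory for stage outputs (created if needed).
#' @param cfg a [milr_config()]; `cfg$seed` drives the simulation.
#' @param inputs named list/vector of input files (`srna_MY`, `srna_FB`,
#'   `contigs`, `adapter` (sequence, not a file), optional `unigenes`,
#'   `counts`, `mature_ref`, `genome`, `genes`). Ignored when
#'   `simulate = TRUE`.
#' @param simulate generate inputs with [simulate_study()] first.
#' @param truth_args arguments passed on to [synthetic_truth()] when
#'   simulating (seed defaults to `cfg$seed`).
#' @return a `milr_report` (list) with per-stage counts and summaries;
#'   stage tables are written under `out_dir` as TSV.
#' @export
run_all <- function(out_dir, cfg = milr_config(), inputs = NULL,
                    simulate = is.null(inputs), truth_args = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (simulate) {
    truth_args$seed <- truth_args$seed %||% cfg$seed
    truth <- do.call(synthetic_truth, truth_args)
    sim <- simulate_study(truth, file.path(out_dir, "sim"))
    inputs <- as.list(sim$files)
    inputs$adapter <- truth$adapter
  } else {
    req <- c("srna_MY", "srna_FB", "contigs", "adapter")
    miss <- setdiff(req, names(inputs))
    if (length(miss)) {
      stop("missing required input(s): ", paste(miss, collapse = ", "))
    }
    for (nm in setdiff(names(inputs), "adapter")) {
      if (!file.exists(inputs[[nm]])) {
        stop("input file for stage '", nm, "' not found: ", inputs[[nm]])
      }
    }
  }

  # preprocess ---------------------------------------------------------
  reads_MY <- read_fastq(inputs$srna_MY, moltype = "rna")
  reads_FB <- read_fastq(inputs$srna_FB, moltype = "rna")
  clean_MY <- preprocess_library(reads_MY, inputs$adapter, cfg)
  clean_FB <- preprocess_library(reads_FB, inputs$adapter, cfg)
  grouped <- group_reads(clean_MY, clean_FB)
  write.table(grouped, file.path(out_dir, "grouped_srna.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # fold ---------------------------------------------------------------
  contigs <- read_fasta(inputs$contigs, moltype = "rna")
  folded <- fold_contigs(contigs, cfg)
  folded_tab <- data.frame(
    contig_id = names(folded),
    sequence = vapply(folded, `[[`, character(1), "seq"),
    dotbracket = vapply(folded, `[[`, character(1), "dotbracket"),
    score = vapply(folded, `[[`, numeric(1), "score"))
  write.table(folded_tab, file.path(out_dir, "folded.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # discover -----------------------------------------------------------
  placements <- map_reads(grouped, folded, cfg)
  precursors <- find_precursor_candidates(placements, folded)
  called <- call_candidates(precursors, placements, folded, cfg)
  write.table(called$candidates, file.path(out_dir, "candidates.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(called$precursors, file.path(out_dir, "precursors.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  conserved <- NULL
  if (!is.null(inputs$mature_ref)) {
    mature <- read_fasta(inputs$mature_ref, moltype = "rna")
    conserved <- annotate_conserved(grouped, mature, folded, cfg,
                                    placements = placements)
    write.table(conserved, file.path(out_dir, "conserved.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  # deg ----------------------------------------------------------------
  expression <- NULL
  if (!is.null(inputs$counts)) {
    counts <- read.delim(inputs$counts, stringsAsFactors = FALSE)
    expression <- classify_deg(counts, cfg)
    write.table(expression, file.path(out_dir, "expression.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  # targets ------------------------------------------------------------
  kept_hits <- NULL
  milr_only <- called$candidates[called$candidates$role == "milR", ,
                                 drop = FALSE]
  if (!is.null(inputs$unigenes) && !is.null(expression) && nrow(milr_only)) {
    unigenes <- read_fasta(inputs$unigenes, moltype = "rna")
    hits <- scan_targets(milr_only, unigenes, cfg)
    lc <- setNames(milr_only$lib_class, milr_only$accession)
    kept_hits <- cross_filter(hits, expression, lc)
    write.table(kept_hits, file.path(out_dir, "targets.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  # genomic context ----------------------------------------------------
  contexts <- NULL
  if (!is.null(inputs$genome)) {
    if (is.null(inputs$genes)) stop("genome given without gene models")
    scaffolds <- read_fasta(inputs$genome, moltype = "dna")
    genes <- read_gff3(inputs$genes)
    regions <- precursor_regions(called$candidates, folded)
    contexts <- genome_context(regions, scaffolds, genes)
    write.table(contexts, file.path(out_dir, "context.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  report <- build_report(reads_MY, reads_FB, clean_MY, clean_FB, grouped,
                         folded, called, conserved, expression, kept_hits,
                         contexts, cfg)
  writeLines(format(report), file.path(out_dir, "report.txt"))
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the duplex-spanning region of each called precursor
#'
#' The minimal contig interval covering all candidate reads of a
#' precursor; used for mapping precursors back to the genome.
#'
#' @param candidates the candidates table from [call_candidates()].
#' @param folded a `folded_set`.
#' @return named character vector (precursor id -> region sequence).
#' @export
precursor_regions <- function(candidates, folded) {
  out <- character(0)
  for (pid in unique(candidates$precursor_id)) {
    rows <- candidates[candidates$precursor_id == pid, , drop = FALSE]
    a <- min(rows$start)
    b <- max(rows$start + nchar(rows$sequence))
    out[[pid]] <- substr(folded[[pid]]$seq, a + 1L, b)
  }
  out
}

build_report <- function(reads_MY, reads_FB, clean_MY, clean_FB, grouped,
                         folded, called, conserved, expression, kept_hits,
                         contexts, cfg) {
  cand <- called$candidates
  milr <- cand[cand$role == "milR", , drop = FALSE]
  cls <- function(x) vapply(c("M", "F", "B"),
                            function(l) sum(x == l), integer(1))
  rep <- list(
    raw_reads = c(MY = nrow(reads_MY), FB = nrow(reads_FB)),
    clean_reads = c(MY = length(clean_MY), FB = length(clean_FB)),
    grouped_srnas = nrow(grouped),
    folded_contigs = length(folded),
    candidates_total = nrow(cand),
    candidates_by_class = cls(cand$lib_class),
    milr_by_class = cls(milr$lib_class),
    precursor_count = length(unique(cand$precursor_id)),
    precursors_by_class = cls(called$precursors$lib_class),
    candidate_length_hist = length_histogram(cand$sequence),
    candidate_5p_freq = five_prime_freq(cand$sequence),
    conserved_hits = if (is.null(conserved)) NA_integer_ else nrow(conserved),
    deg_class_counts = if (is.null(expression)) NULL else
      table(factor(expression$deg_class,
                   levels = c("up_MY", "up_FB", "MY_specific", "FB_specific",
                              "not_DE"))),
    retained_target_hits = if (is.null(kept_hits)) NA_integer_ else
      nrow(kept_hits),
    context_counts = if (is.null(contexts)) NULL else
      table(factor(contexts$context,
                   levels = c("intergenic", "intron", "exon_antisense",
                              "exon_sense"))),
    config_hash = substr(digest_config(cfg), 1, 12)
  )
  class(rep) <- "milr_report"
  rep
}

digest_config <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(v)
    paste(format(v, digits = 17), collapse = ","), character(1)),
    sep = "=", collapse = ";")
  # small deterministic hash (djb2) -- avoids a digest dependency
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' @export
format.milr_report <- function(x, ...) {
  fmt_vec <- function(v) paste(names(v), v, sep = "=", collapse = " ")
  c("milrseek run report",
    sprintf("  raw reads:            %s", fmt_vec(x$raw_reads)),
    sprintf("  clean reads:          %s", fmt_vec(x$clean_reads)),
    sprintf("  grouped sRNAs:        %d", x$grouped_srnas),
    sprintf("  folded contigs:       %d", x$folded_contigs),
    sprintf("  candidates (total):   %d", x$candidates_total),
    sprintf("  candidates by class:  %s", fmt_vec(x$candidates_by_class)),
    sprintf("  milR by class:        %s", fmt_vec(x$milr_by_class)),
    sprintf("  precursors:           %d", x$precursor_count),
    sprintf("  precursors by class:  %s", fmt_vec(x$precursors_by_class)),
    sprintf("  candidate length mode: %s",
            modal_length(x$candidate_length_hist)),
    sprintf("  candidate 5' freq:    %s", fmt_vec(x$candidate_5p_freq)),
    sprintf("  conserved hits:       %s", x$conserved_hits),
    if (!is.null(x$deg_class_counts))
      sprintf("  DEG classes:          %s", fmt_vec(c(x$deg_class_counts))),
    sprintf("  retained target hits: %s", x$retained_target_hits),
    if (!is.null(x$context_counts))
      sprintf("  genomic contexts:     %s", fmt_vec(c(x$context_counts))),
    sprintf("  config hash:          %s", x$config_hash))
}

#' @export
print.milr_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}
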