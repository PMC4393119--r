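#' Pipeline run configuration
#'
#' Collects every tunable threshold of the pipeline in one validated object.
#' All defaults are the pipeline's declared operating point; each can be
#' overridden here or (for the command-line interface) by a flag.
#'
#' @param mismatch_max maximum mismatches when remapping an sRNA onto a
#'   folded contig ("fewer than 4" = 3). Integer >= 0.
#' @param min_read_len,max_read_len retained sRNA length bounds in nt.
#' @param fdr_threshold Benjamini-Hochberg FDR cutoff for differential
#'   expression calls.
#' @param fc_up,fc_down fold-change (FB/MY RPKM ratio) bounds for the up_FB
#'   and up_MY classes. `fc_down` defaults to `1/fc_up`.
#' @param expectation_max maximum target-prediction expectation penalty.
#' @param min_loop minimum hairpin loop length in nt (RNAfold convention).
#' @param stem_overlap_frac fraction of a read's paired bases that must lie
#'   on a single stem for the read to count as stem-located.
#' @param conserved_mm_max maximum mismatches for a conserved miRNA hit.
#' @param min_mean_q minimum mean Phred quality for a read to be kept.
#' @param adapter_seed_len minimum adapter prefix length that triggers a
#'   trim (nt).
#' @param adapter_mm mismatches tolerated in the adapter seed match.
#' @param min_specific minimum own-library read count for a
#'   library-specific expression call.
#' @param min_paired_frac minimum fraction of a read's bases that must be
#'   base-paired for the read to be considered stem-located at all (guards
#'   against loop-only placements).
#' @param duplex_overlap_frac fraction of one read's base-pair partners
#'   that must fall inside the other read's (slightly extended) interval
#'   for the two reads to be called a duplex.
#' @param stem_gap_max maximal bulge/internal-loop size (nt per side)
#'   merged into a single stem.
#' @param locus_5p_tol reads on the same arm whose 5' ends lie within this
#'   many nt are grouped as one locus family.
#' @param target_w_mismatch,target_w_wobble,target_w_gap per-position
#'   penalties of the target expectation score.
#' @param target_seed_mult multiplier applied to penalties at milRNA
#'   positions `target_seed_range` (counted from the 5' end, 1-based).
#' @param target_seed_range integer positions receiving the multiplier.
#' @param target_central_range positions whose imperfections switch the
#'   inhibition call from Cleavage to Translation.
#' @param target_gap_max maximum total gaps in a target alignment.
#' @param fold_window,fold_step window/step (nt) used to fold contigs
#'   longer than `fold_max_len` in overlapping pieces.
#' @param fold_max_len contig length above which windowed folding is used.
#' @param seed integer RNG seed recorded with the run.
#'
#' @return an object of class `milr_config` (a validated named list).
#' @examples
#' cfg <- milr_config(mismatch_max = 2)
#' cfg$mismatch_max
#' @export
milr_config <- function(mismatch_max = 3L,
                        min_read_len = 18L,
                        max_read_len = 35L,
                        fdr_threshold = 0.05,
                        fc_up = 2.0,
                        fc_down = NULL,
                        expectation_max = 4.0,
                        min_loop = 3L,
                        stem_overlap_frac = 0.6,
                        conserved_mm_max = 2L,
                        min_mean_q = 20,
                        adapter_seed_len = 7L,
                        adapter_mm = 1L,
                        min_specific = 5L,
                        min_paired_frac = 0.5,
                        duplex_overlap_frac = 0.5,
                        stem_gap_max = 3L,
                        locus_5p_tol = 2L,
                        target_w_mismatch = 1.0,
                        target_w_wobble = 0.5,
                        target_w_gap = 2.0,
                        target_seed_mult = 2.0,
                        target_seed_range = 2:13,
                        target_central_range = 9:11,
                        target_gap_max = 2L,
                        fold_window = 700L,
                        fold_step = 350L,
                        fold_max_len = 2000L,
                        seed = 1L) {
  if (is.null(fc_down)) fc_down <- 1 / fc_up
  cfg <- list(
    mismatch_max = as.integer(mismatch_max),
    min_read_len = as.integer(min_read_len),
    max_read_len = as.integer(max_read_len),
    fdr_threshold = as.numeric(fdr_threshold),
    fc_up = as.numeric(fc_up),
    fc_down = as.numeric(fc_down),
    expectation_max = as.numeric(expectation_max),
    min_loop = as.integer(min_loop),
    stem_overlap_frac = as.numeric(stem_overlap_frac),
    conserved_mm_max = as.integer(conserved_mm_max),
    min_mean_q = as.numeric(min_mean_q),
    adapter_seed_len = as.integer(adapter_seed_len),
    adapter_mm = as.integer(adapter_mm),
    min_specific = as.integer(min_specific),
    min_paired_frac = as.numeric(min_paired_frac),
    duplex_overlap_frac = as.numeric(duplex_overlap_frac),
    stem_gap_max = as.integer(stem_gap_max),
    locus_5p_tol = as.integer(locus_5p_tol),
    target_w_mismatch = as.numeric(target_w_mismatch),
    target_w_wobble = as.numeric(target_w_wobble),
    target_w_gap = as.numeric(target_w_gap),
    target_seed_mult = as.numeric(target_seed_mult),
    target_seed_range = as.integer(target_seed_range),
    target_central_range = as.integer(target_central_range),
    target_gap_max = as.integer(target_gap_max),
    fold_window = as.integer(fold_window),
    fold_step = as.integer(fold_step),
    fold_max_len = as.integer(fold_max_len),
    seed = as.integer(seed)
  )
  class(cfg) <- "milr_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "milr_config"))
  if (cfg$mismatch_max < 0L) stop("mismatch_max must be >= 0")
  if (!(cfg$fdr_threshold > 0 && cfg$fdr_threshold < 1)) {
    stop("fdr_threshold must lie strictly between 0 and 1")
  }
  if (cfg$min_read_len < 1L || cfg$max_read_len < cfg$min_read_len) {
    stop("invalid read length bounds")
  }
  if (cfg$min_loop < 0L) stop("min_loop must be >= 0")
  if (cfg$fc_up <= 1 || cfg$fc_down >= 1 || cfg$fc_down <= 0) {
    stop("fold-change bounds must satisfy fc_down < 1 < fc_up")
  }
  if (cfg$expectation_max < 0) stop("expectation_max must be >= 0")
  invisible(cfg)
}

#' @export
print.milr_config <- function(x, ...) {
  cat("milrseek run configuration\n")
  scalars <- vapply(x, function(v) length(v) == 1L, logical(1))
  for (nm in names(x)[scalars]) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  for (nm in names(x)[!scalars]) {
    cat(sprintf("  %-20s %s\n", nm, paste(x[[nm]], collapse = ",")))
  }
  invisible(x)
}

#' Write / read a run configuration as a flat key:value file
#'
#' Thresholds serialize losslessly (`format(..., digits = 17)`); integer
#' vectors are comma-separated. `read_config()` round-trips the file back
#' into a validated [milr_config()].
#'
#' @param cfg a `milr_config` object.
#' @param path file path.
#' @return `read_config` returns a `milr_config`; `write_config` its path,
#'   invisibly.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  fmt <- function(v) {
    if (is.numeric(v) && !is.integer(v)) {
      paste(format(v, digits = 17, scientific = FALSE), collapse = ",")
    } else {
      paste(v, collapse = ",")
    }
  }
  lines <- vapply(names(cfg), function(nm) paste0(nm, ": ", fmt(cfg[[nm]])),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+):\\s*(.*)$", lines))
  bad <- vapply(kv, length, integer(1)) != 3L
  if (any(bad)) stop("malformed config line: ", lines[which(bad)[1]])
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- vapply(kv, `[`, character(1), 3L)
  args <- list()
  proto <- formals(milr_config)
  for (i in seq_along(keys)) {
    k <- keys[i]
    v <- strsplit(vals[i], ",", fixed = TRUE)[[1]]
    args[[k]] <- as.numeric(v)
  }
  do.call(milr_config, args)
}
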