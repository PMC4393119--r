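#' Build a hairpin precursor around a given milR sequence
#'
#' The precursor carries the milR on its 5' arm, a loop, and the
#' near-reverse-complement of the milR (the milR* arm) on the 3' arm.
#' `bulges` positions of the 3' arm (interior, never the terminal two on
#' either side) are substituted so that they can neither Watson-Crick nor
#' G:U pair with their milR partner, producing internal loops like those
#' of natural milRNA precursors. Folding the result with [fold_contigs()]
#' pairs at least 80% of the milR bases to the 3' arm as long as
#' `bulges <= 0.2 * nchar(milR)`.
#'
#' @param milR milR sequence (RNA, 18-30 nt).
#' @param loop_len loop length in nt (>= `cfg$min_loop`).
#' @param bulges number of mismatched positions designed into the 3' arm.
#' @param cfg a [milr_config()].
#' @return list: `precursor` (RNA string), `milR`, `milRstar` (the 3' arm
#'   as it appears 5'->3'), `milR_start`, `milRstar_start` (0-based
#'   offsets within the precursor).
#' @examples
#' set.seed(1)
#' hp <- make_hairpin("UGAGGUAGUAGGUUGUAUAGUU", loop_len = 6)
#' nchar(hp$precursor)  # 2 * 22 + 6
#' @export
make_hairpin <- function(milR, loop_len = 6L, bulges = 0L,
                         cfg = milr_config()) {
  milR <- normalize_alphabet(milR, "rna")
  L <- nchar(milR)
  if (L < 18L || L > 30L) stop("milR length must lie in 18..30 nt")
  if (loop_len < cfg$min_loop) {
    stop("loop_len must be at least min_loop (", cfg$min_loop, ")")
  }
  if (bulges > L - 4L) stop("too many bulges for this milR length")
  star <- revcomp(milR)
  if (bulges > 0L) {
    pos <- sample(3:(L - 2L), bulges)
    sv <- strsplit(star, "", fixed = TRUE)[[1]]
    mv <- strsplit(milR, "", fixed = TRUE)[[1]]
    for (p in pos) {
      partner <- mv[L - p + 1L]  # milR base this star position faces
      forbidden <- switch(partner,
                          A = c("U"), U = c("A", "G"),
                          G = c("C", "U"), C = c("G"))
      choices <- setdiff(c("A", "C", "G", "U"), c(forbidden, sv[p]))
      sv[p] <- sample(choices, 1L)
    }
    star <- paste(sv, collapse = "")
  }
  loop <- paste(sample(c("A", "C"), loop_len, replace = TRUE), collapse = "")
  list(precursor = paste0(milR, loop, star),
       milR = milR, milRstar = star,
       milR_start = 0L, milRstar_start = L + loop_len)
}

rand_seq <- function(n, probs = c(A = .25, C = .25, G = .25, U = .25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

#' Specify a synthetic milRNA study
#'
#' Draws the "truth" of a toy two-library study: planted hairpin loci with
#' per-library milR/milR* counts, their genomic contexts, a unigene panel
#' with planted differential expression, planted target pairings, and the
#' global nuisance parameters (3' adapter, per-base substitution error
#' rate, background-read fraction). Defaults emulate the biology the
#' pipeline is aimed at: milR lengths 20-26 nt peaking at 23, a 50%
#' 5'-uracil bias, library classes in roughly the published 13:46:4
#' M:F:B proportion (all three classes always represented), and
#' intergenic/intron/exon-antisense genomic contexts (all three always
#' represented).
#'
#' @param n_loci number of planted hairpin loci.
#' @param n_unigenes size of the unigene expression panel.
#' @param n_deg number of unigenes with planted differential expression
#'   (|log2 fold change| = 2).
#' @param n_targets number of planted milRNA -> unigene target sites.
#' @param error_rate per-base substitution probability in simulated reads.
#' @param background_frac fraction of each library made of uniform random
#'   background reads.
#' @param adapter 3' adapter sequence (19 nt default).
#' @param seed integer RNG seed; regenerating with the same seed gives
#'   byte-identical outputs.
#' @return an object of class `milr_truth`.
#' @export
synthetic_truth <- function(n_loci = 20L, n_unigenes = 40L, n_deg = 10L,
                            n_targets = 4L, error_rate = 0.01,
                            background_frac = 0.2,
                            adapter = "UGGAAUUCUCGGGUGCCAA", seed = 1L) {
  stopifnot(n_loci >= 3L, n_unigenes >= n_deg, n_deg >= n_targets)
  set.seed(seed)
  len_probs <- c(`20` = .05, `21` = .10, `22` = .18, `23` = .32,
                 `24` = .18, `25` = .10, `26` = .07)
  contexts <- c("intergenic", "intron", "exon_antisense")
  base_cls <- c("M", "F", "B")

  loci <- lapply(seq_len(n_loci), function(i) {
    L <- as.integer(sample(names(len_probs), 1L, prob = len_probs))
    first <- if (runif(1) < 0.5) "U" else sample(c("A", "C", "G"), 1L)
    milR <- paste0(first, rand_seq(L - 1L))
    hp <- make_hairpin(milR, loop_len = sample(4:8, 1L),
                       bulges = sample(0:2, 1L))
    cls <- if (i <= 3L) base_cls[i] else
      sample(base_cls, 1L, prob = c(13, 46, 4) / 63)
    ctx <- if (i <= 3L) contexts[i] else sample(contexts, 1L,
                                                prob = c(.7, .15, .15))
    tot <- max(10L, min(300L, round(stats::rlnorm(1, log(60), 0.8))))
    split_counts <- function(total, cls) {
      switch(cls,
             M = c(total, 0L),
             F = c(0L, total),
             B = { a <- max(1L, min(total - 1L,
                                    stats::rbinom(1, total, runif(1, .3, .7))))
                   c(a, total - a) })
    }
    mc <- split_counts(tot, cls)
    star_tot <- max(1L, round(tot * runif(1, 0.05, 0.4)))
    if (star_tot >= tot) star_tot <- tot - 1L
    sc <- split_counts(star_tot, cls)
    data.frame(
      precursor_id = sprintf("prec_%02d", i),
      contig_id = sprintf("contig_%02d", i),
      context = ctx, strand = sample(c("+", "-"), 1L, prob = c(.7, .3)),
      lib_class = cls,
      milR_seq = hp$milR, milRstar_seq = hp$milRstar,
      precursor_seq = hp$precursor,
      milR_count_MY = mc[1], milR_count_FB = mc[2],
      milRstar_count_MY = sc[1], milRstar_count_FB = sc[2],
      stringsAsFactors = FALSE
    )
  })
  loci <- do.call(rbind, loci)

  # unigene panel with planted DEG (|log2FC| = 2)
  log2fc <- numeric(n_unigenes)
  deg_idx <- seq_len(n_deg)
  log2fc[deg_idx] <- rep(c(2, -2), length.out = n_deg)  # + = up in FB
  unigenes <- data.frame(
    unigene_id = sprintf("unigene_%03d", seq_len(n_unigenes)),
    length_bp = sample(300:800, n_unigenes, replace = TRUE),
    log2fc = log2fc,
    base_mean = pmax(20, round(stats::rlnorm(n_unigenes, log(100), 0.6))),
    stringsAsFactors = FALSE
  )

  # planted target pairs: milRNA class opposed to target DEG direction
  targets <- NULL
  if (n_targets > 0L) {
    host_pool_up_fb <- which(log2fc > 0)
    host_pool_up_my <- which(log2fc < 0)
    rows <- list()
    li <- which(loci$lib_class != "B")[seq_len(n_targets)]
    for (k in seq_along(li)) {
      i <- li[k]
      pool <- if (loci$lib_class[i] == "M") host_pool_up_fb else host_pool_up_my
      host <- pool[1L + (k - 1L) %% length(pool)]
      rows[[k]] <- data.frame(precursor_id = loci$precursor_id[i],
                              milR_seq = loci$milR_seq[i],
                              unigene_id = unigenes$unigene_id[host],
                              stringsAsFactors = FALSE)
    }
    targets <- do.call(rbind, rows)
    targets <- targets[!duplicated(targets$unigene_id), , drop = FALSE]
  }

  structure(list(loci = loci, unigenes = unigenes, targets = targets,
                 adapter = normalize_alphabet(adapter, "rna"),
                 error_rate = error_rate, background_frac = background_frac,
                 seed = as.integer(seed)),
            class = "milr_truth")
}

mutate_reads <- function(reads, rate) {
  if (rate <= 0 || !length(reads)) return(reads)
  bases <- c("A", "C", "G", "T")
  vapply(reads, function(r) {
    n <- nchar(r)
    k <- stats::rbinom(1L, n, rate)
    if (k == 0L) return(r)
    pos <- sample.int(n, k)
    v <- strsplit(r, "", fixed = TRUE)[[1]]
    for (p in pos) v[p] <- sample(setdiff(bases, v[p]), 1L)
    paste(v, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Generate the files of a synthetic milRNA study
#'
#' Materializes a [synthetic_truth()] specification into a directory:
#' `genome.fa` (two scaffolds with the precursors planted in their stated
#' genomic contexts), `genes.gff3`, `contigs.fa` (transcript contigs
#' embedding the precursors), `unigenes.fa` + `counts.tsv` (expression
#' panel with planted fold changes and embedded target sites),
#' `srna_MY.fastq` / `srna_FB.fastq` (35-nt reads: insert + 3' adapter,
#' truncated, with substitution errors and uniform background reads),
#' `mature_ref.fa` (two planted milRs under reference names plus decoys;
#' all sequences synthetic), and `truth.tsv`. Regenerating with the same
#' truth yields byte-identical files.
#'
#' The `recoverable` flag in `truth.tsv` records whether the built-in
#' folder reproduces the designed duplex on the embedded contig (flank
#' sequence can occasionally distort a hairpin) -- downstream recovery is
#' asserted against recoverable loci only.
#'
#' @param truth a `milr_truth` object.
#' @param out_dir output directory (created if needed).
#' @return list with element `files` (named paths) and `truth` (the input
#'   truth with placement columns and the `recoverable` flag added).
#' @export
simulate_study <- function(truth, out_dir) {
  stopifnot(inherits(truth, "milr_truth"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(truth$seed + 7L)
  loci <- truth$loci
  if (anyDuplicated(loci$precursor_id) || anyDuplicated(loci$contig_id)) {
    stop("colliding ids in truth")
  }
  cfg <- milr_config()

  # --- transcript contigs: flank + precursor + flank ------------------
  flank5 <- vapply(seq_len(nrow(loci)), function(i)
    rand_seq(sample(20:35, 1L)), character(1))
  flank3 <- vapply(seq_len(nrow(loci)), function(i)
    rand_seq(sample(20:35, 1L)), character(1))
  contig_seq <- paste0(flank5, loci$precursor_seq, flank3)
  loci$contig_pos <- nchar(flank5)  # 0-based precursor offset in contig

  # --- genome: two scaffolds of per-locus blocks ----------------------
  half <- ceiling(nrow(loci) / 2)
  scaffold_of <- ifelse(seq_len(nrow(loci)) <= half, "scaf_1", "scaf_2")
  loci$scaffold <- scaffold_of
  loci$genome_pos <- NA_integer_
  genes <- list()
  scaf_seqs <- c(scaf_1 = "", scaf_2 = "")
  for (i in seq_len(nrow(loci))) {
    sc <- loci$scaffold[i]
    cur <- nchar(scaf_seqs[[sc]])
    prec_dna <- chartr("U", "T", loci$precursor_seq[i])
    if (loci$strand[i] == "-") prec_dna <- revcomp(prec_dna)
    ctx <- loci$context[i]
    spacer <- chartr("U", "T", rand_seq(sample(80:120, 1L)))
    block_start <- cur + nchar(spacer)
    gid <- sprintf("gene_%02d", i)
    if (ctx == "intergenic") {
      block <- paste0(spacer, prec_dna)
      loci$genome_pos[i] <- block_start
    } else if (ctx == "intron") {
      ex1 <- chartr("U", "T", rand_seq(60)); ex2 <- chartr("U", "T", rand_seq(60))
      pad <- chartr("U", "T", rand_seq(10))
      block <- paste0(spacer, ex1, pad, prec_dna, pad, ex2)
      p0 <- block_start + 60L + 10L
      loci$genome_pos[i] <- p0
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = gid, scaffold = sc, strand = loci$strand[i],
        start = c(block_start, p0 + nchar(prec_dna) + 10L),
        end = c(block_start + 60L, p0 + nchar(prec_dna) + 70L),
        stringsAsFactors = FALSE)
    } else {  # exon_antisense: single-exon gene on the opposite strand
      pad <- chartr("U", "T", rand_seq(10))
      block <- paste0(spacer, pad, prec_dna, pad)
      p0 <- block_start + 10L
      loci$genome_pos[i] <- p0
      gstrand <- if (loci$strand[i] == "+") "-" else "+"
      genes[[length(genes) + 1L]] <- data.frame(
        gene_id = gid, scaffold = sc, strand = gstrand,
        start = block_start, end = block_start + nchar(block) - nchar(spacer),
        stringsAsFactors = FALSE)
    }
    scaf_seqs[[sc]] <- paste0(scaf_seqs[[sc]], block)
  }
  scaf_seqs <- vapply(scaf_seqs, function(s)
    paste0(s, chartr("U", "T", rand_seq(100))), character(1))
  gene_models <- if (length(genes)) {
    g <- do.call(rbind, genes)
    class(g) <- c("gene_models", "data.frame")
    g
  } else empty_gene_models()
  if (any(loci$context == "intron") && !nrow(gene_models)) {
    stop("intron context requested but no gene models generated")
  }

  # --- unigene panel with embedded target sites -----------------------
  uni <- truth$unigenes
  uni_seq <- vapply(uni$length_bp, rand_seq, character(1))
  if (!is.null(truth$targets)) {
    tg <- truth$targets
    tg$site_start <- NA_integer_
    for (k in seq_len(nrow(tg))) {
      u <- match(tg$unigene_id[k], uni$unigene_id)
      site <- revcomp(tg$milR_seq[k])
      pos <- sample(50:(uni$length_bp[u] - nchar(site) - 50L), 1L)
      uni_seq[u] <- paste0(substr(uni_seq[u], 1L, pos),
                           site,
                           substr(uni_seq[u], pos + nchar(site) + 1L,
                                  uni$length_bp[u]))
      tg$site_start[k] <- pos
    }
    truth$targets <- tg
  }
  lib_size_factor <- 1.0  # equal sequencing depth in MY and FB
  uni$count_MY <- stats::rpois(nrow(uni), uni$base_mean)
  uni$count_FB <- stats::rpois(nrow(uni), uni$base_mean * 2^uni$log2fc *
                                 lib_size_factor)

  # --- sRNA reads -----------------------------------------------------
  adapter_dna <- chartr("U", "T", truth$adapter)
  make_lib <- function(lib) {
    milc <- loci[[paste0("milR_count_", lib)]]
    starc <- loci[[paste0("milRstar_count_", lib)]]
    inserts <- c(rep(chartr("U", "T", loci$milR_seq), milc),
                 rep(chartr("U", "T", loci$milRstar_seq), starc))
    n_planted <- length(inserts)
    n_bg <- if (truth$background_frac > 0)
      round(truth$background_frac / (1 - truth$background_frac) * n_planted)
    else 0L
    bg <- vapply(seq_len(n_bg), function(i)
      chartr("U", "T", rand_seq(sample(18:35, 1L))), character(1))
    reads <- substr(paste0(c(inserts, bg), adapter_dna), 1L, 35L)
    reads <- mutate_reads(reads, truth$error_rate)
    data.frame(id = sprintf("%s_read_%06d", lib, seq_along(reads)),
               seq = reads,
               qual = strrep("I", nchar(reads)),
               stringsAsFactors = FALSE)
  }
  lib_MY <- make_lib("MY")
  lib_FB <- make_lib("FB")

  # --- recoverability: does the built-in folder keep the duplex? ------
  folded <- fold_contigs(setNames(contig_seq, loci$contig_id), cfg)
  loci$recoverable <- vapply(seq_len(nrow(loci)), function(i) {
    fc <- folded[[loci$contig_id[i]]]
    p1 <- list(start = loci$contig_pos[i], sequence = loci$milR_seq[i])
    p2 <- list(start = loci$contig_pos[i] + nchar(loci$precursor_seq[i]) -
                 nchar(loci$milRstar_seq[i]),
               sequence = loci$milRstar_seq[i])
    ok <- same_stem_check(p1, p2, fc, cfg)$verdict ||
          same_stem_check(p2, p1, fc, cfg)$verdict
    tot_m <- loci$milR_count_MY[i] + loci$milR_count_FB[i]
    tot_s <- loci$milRstar_count_MY[i] + loci$milRstar_count_FB[i]
    # preprocessing fidelity: an adapter-like 7-mer inside the insert
    # would truncate its reads, so such loci are not recoverable
    trims_ok <- all(vapply(c(loci$milR_seq[i], loci$milRstar_seq[i]),
                           function(insert) {
      read <- substr(paste0(insert, truth$adapter), 1L, 35L)
      identical(trim_adapter(read, truth$adapter, cfg), insert)
    }, logical(1)))
    ok && tot_m > tot_s && trims_ok
  }, logical(1))

  # --- write everything -----------------------------------------------
  f <- function(x) file.path(out_dir, x)
  files <- c(genome = f("genome.fa"), genes = f("genes.gff3"),
             contigs = f("contigs.fa"), unigenes = f("unigenes.fa"),
             counts = f("counts.tsv"), srna_MY = f("srna_MY.fastq"),
             srna_FB = f("srna_FB.fastq"), mature_ref = f("mature_ref.fa"),
             truth = f("truth.tsv"))
  writeLines(paste0(">", names(scaf_seqs), "\n", scaf_seqs), files["genome"])
  write_gff3(gene_models, files["genes"])
  writeLines(paste0(">", loci$contig_id, "\n",
                    chartr("U", "T", contig_seq)), files["contigs"])
  writeLines(paste0(">", uni$unigene_id, "\n",
                    chartr("U", "T", uni_seq)), files["unigenes"])
  write.table(uni[, c("unigene_id", "length_bp", "count_MY", "count_FB")],
              files["counts"], sep = "\t", quote = FALSE, row.names = FALSE)
  write_fastq(lib_MY, files["srna_MY"])
  write_fastq(lib_FB, files["srna_FB"])

  # mature reference: two planted milRs under reference-style names + decoys
  ref_ids <- c("syn-miR-101", "syn-miR-202", "syn-miR-x1", "syn-miR-x2",
               "syn-miR-x3")
  ref_seqs <- c(chartr("U", "T", loci$milR_seq[1:2]),
                vapply(1:3, function(i) chartr("U", "T", rand_seq(22)),
                       character(1)))
  writeLines(paste0(">", ref_ids, "\n", ref_seqs), files["mature_ref"])

  tt <- loci[, c("precursor_id", "contig_id", "scaffold", "genome_pos",
                 "strand", "context", "milR_seq", "milRstar_seq",
                 "milR_count_MY", "milR_count_FB", "milRstar_count_MY",
                 "milRstar_count_FB", "contig_pos", "lib_class",
                 "recoverable")]
  meta <- sprintf("#adapter=%s error_rate=%g background_frac=%g seed=%d",
                  truth$adapter, truth$error_rate, truth$background_frac,
                  truth$seed)
  con <- file(files["truth"], "w")
  writeLines(meta, con)
  suppressWarnings(write.table(tt, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  close(con)

  truth$loci <- loci
  truth$conserved_ref <- data.frame(ref_id = ref_ids[1:2],
                                    milR_seq = loci$milR_seq[1:2],
                                    stringsAsFactors = FALSE)
  stage_log("simulate_study", nrow(loci),
            nrow(lib_MY) + nrow(lib_FB))
  list(files = files, truth = truth)
}
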