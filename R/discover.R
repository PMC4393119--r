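#' Map grouped sRNAs onto folded contigs
#'
#' Every ungapped, full-length placement of each sRNA with at most
#' `cfg$mismatch_max` mismatches is reported ("fewer than 4 mismatched
#' nucleotides" at the default of 3); all qualifying positions on all
#' contigs are emitted, no indels.
#'
#' @param grouped a `grouped_srna` table from [group_reads()].
#' @param folded a `folded_set` from [fold_contigs()].
#' @param cfg a [milr_config()].
#' @return data.frame of placements: `seq_idx` (row in `grouped`),
#'   `sequence`, `contig_id`, `start` (0-based), `mismatches`,
#'   `count_MY`, `count_FB`, `lib`.
#' @export
map_reads <- function(grouped, folded, cfg = milr_config()) {
  ids <- names(folded)
  seqs <- vapply(folded, `[[`, character(1), "seq")
  if (!nrow(grouped) || !length(folded)) {
    return(data.frame(seq_idx = integer(), sequence = character(),
                      contig_id = character(), start = integer(),
                      mismatches = integer(), count_MY = integer(),
                      count_FB = integer(), lib = character(),
                      stringsAsFactors = FALSE))
  }
  hits <- map_reads_cpp(grouped$sequence, unname(seqs), cfg$mismatch_max)
  out <- data.frame(
    seq_idx = hits$read,
    sequence = grouped$sequence[hits$read],
    contig_id = ids[hits$contig],
    start = hits$start,
    mismatches = hits$mismatches,
    count_MY = grouped$count_MY[hits$read],
    count_FB = grouped$count_FB[hits$read],
    lib = grouped$lib[hits$read],
    stringsAsFactors = FALSE
  )
  stage_log("map_reads", nrow(grouped), nrow(out))
  out
}

#' Keep contigs carrying at least two distinct sRNA sequences
#'
#' A folded contig (or window) survives as a precursor candidate iff two
#' or more distinct sRNA sequences place on it.
#'
#' @param placements output of [map_reads()].
#' @param folded a `folded_set`.
#' @return character vector of surviving contig ids, in `folded` order.
#' @export
find_precursor_candidates <- function(placements, folded) {
  n_distinct <- tapply(placements$sequence, placements$contig_id,
                       function(s) length(unique(s)))
  keep <- names(n_distinct)[n_distinct >= 2L]
  out <- names(folded)[names(folded) %in% keep]
  stage_log("precursor_candidates", length(folded), length(out))
  out
}

# Stem location of one placement: which stem carries it, on which arm.
# Returns list(located, stem, arm, paired_pos, frac_paired).
placement_stem_info <- function(start, len, folded, stems, cfg) {
  pos <- (start + 1L):(start + len)
  pos <- pos[pos <= length(folded$partner)]
  paired <- pos[!is.na(folded$partner[pos])]
  frac_paired <- length(paired) / len
  none <- list(located = FALSE, stem = NA_integer_, arm = NA_character_,
               paired_pos = paired, frac_paired = frac_paired)
  if (!length(paired) || frac_paired < cfg$min_paired_frac) return(none)
  pair_stem <- attr(stems, "pair_stem")
  sid <- pair_stem[paired]
  tab <- table(sid)
  best <- names(tab)[which.max(tab)]
  frac <- max(tab) / length(paired)
  if (frac < cfg$stem_overlap_frac) return(none)
  s <- as.integer(best)
  row <- stems[stems$stem == s, , drop = FALSE]
  on5 <- sum(paired > row$arm5_start & paired <= row$arm5_end)
  on3 <- sum(paired > row$arm3_start & paired <= row$arm3_end)
  arm <- if (on5 >= on3) "5p" else "3p"
  list(located = TRUE, stem = s, arm = arm, paired_pos = paired,
       frac_paired = frac_paired)
}

#' Test whether two placements form a duplex on the same stem
#'
#' True iff both reads are stem-located on the same stem (at least
#' `cfg$stem_overlap_frac` of each read's paired bases on that stem),
#' occupy opposite arms, and at least `cfg$duplex_overlap_frac` of the
#' first read's paired bases have partners inside the second read's
#' interval extended by 3 nt.
#'
#' @param p1,p2 lists or one-row data.frames with `start` and `sequence`.
#' @param folded a single `folded_contig` both placements refer to.
#' @param cfg a [milr_config()].
#' @return list with `verdict` (logical) and `stem` (index or NA).
#' @export
same_stem_check <- function(p1, p2, folded, cfg = milr_config()) {
  stems <- extract_stems(folded, cfg)
  i1 <- placement_stem_info(p1$start, nchar(p1$sequence), folded, stems, cfg)
  i2 <- placement_stem_info(p2$start, nchar(p2$sequence), folded, stems, cfg)
  duplex_check(i1, p1, i2, p2, folded, cfg)
}

# same_stem_check on precomputed placement_stem_info results
duplex_check <- function(i1, p1, i2, p2, folded, cfg) {
  fail <- list(verdict = FALSE, stem = NA_integer_)
  if (!i1$located || !i2$located) return(fail)
  if (i1$stem != i2$stem || i1$arm == i2$arm) return(fail)
  # duplex relation: partners of p1's paired bases fall inside p2 +- 3 nt
  lo <- p2$start + 1L - 3L
  hi <- p2$start + nchar(p2$sequence) + 3L
  partners <- folded$partner[i1$paired_pos]
  frac <- mean(partners >= lo & partners <= hi)
  if (frac < cfg$duplex_overlap_frac) return(fail)
  list(verdict = TRUE, stem = i1$stem)
}

#' Call milRNA candidates from stem-located duplexes
#'
#' For every surviving precursor, reads forming a same-stem opposite-arm
#' duplex are retained; in each duplex the read with the strictly larger
#' total count is the milR, the other the milR* (equal counts discard the
#' duplex). Reads on the same arm whose 5' ends lie within
#' `cfg$locus_5p_tol` nt are grouped into one locus family and numbered by
#' descending count. Accessions follow the `aci-milR-<locus><letter>-<k>`
#' scheme (letter omitted for single-family precursors, `-<k>` omitted for
#' single-variant families). Library class is `M`/`F`/`B` from the read's
#' own counts; a precursor's class is the union of its reads' classes.
#'
#' @param precursors contig ids from [find_precursor_candidates()].
#' @param placements output of [map_reads()].
#' @param folded a `folded_set`.
#' @param cfg a [milr_config()].
#' @param prefix accession prefix.
#' @return list with `candidates` and `precursors` data.frames.
#' @export
call_candidates <- function(precursors, placements, folded,
                            cfg = milr_config(), prefix = "aci-milR") {
  cand_rows <- list()
  prec_rows <- list()
  locus_n <- 0L
  for (cid in precursors) {
    fc <- folded[[cid]]
    stems <- extract_stems(fc, cfg)
    pl <- placements[placements$contig_id == cid, , drop = FALSE]
    if (nrow(pl) < 2L) next
    info <- lapply(seq_len(nrow(pl)), function(k) {
      placement_stem_info(pl$start[k], nchar(pl$sequence[k]), fc, stems, cfg)
    })
    located <- which(vapply(info, `[[`, logical(1), "located"))
    if (length(located) < 2L) next

    total <- pl$count_MY + pl$count_FB
    in_duplex <- rep(FALSE, nrow(pl))
    best_partner <- rep(NA_integer_, nrow(pl))
    for (a in located) {
      for (b in located) {
        if (a >= b) next
        if (pl$sequence[a] == pl$sequence[b]) next
        ok <- duplex_check(info[[a]], pl[a, ], info[[b]], pl[b, ], fc,
                           cfg)$verdict ||
              duplex_check(info[[b]], pl[b, ], info[[a]], pl[a, ], fc,
                           cfg)$verdict
        if (!ok) next
        if (total[a] == total[b]) next        # strict inequality required
        in_duplex[c(a, b)] <- TRUE
        if (is.na(best_partner[a]) || total[b] > total[best_partner[a]]) {
          best_partner[a] <- b
        }
        if (is.na(best_partner[b]) || total[a] > total[best_partner[b]]) {
          best_partner[b] <- a
        }
      }
    }
    # guide/passenger relative to the dominant duplex partner
    is_milR <- in_duplex & total > ifelse(is.na(best_partner), Inf,
                                          total[best_partner])
    sel <- which(in_duplex)
    if (!length(sel)) next

    locus_n <- locus_n + 1L
    arm <- vapply(info[sel], `[[`, character(1), "arm")
    df <- data.frame(
      idx = sel, arm = arm, start = pl$start[sel],
      sequence = pl$sequence[sel], total = total[sel],
      stringsAsFactors = FALSE
    )
    # locus families: same arm, 5' ends within tolerance (chained);
    # lettered along the precursor so the 5' family comes first
    df <- df[order(df$start, df$arm, -df$total, df$sequence), , drop = FALSE]
    fam <- integer(nrow(df))
    f <- 0L
    for (k in seq_len(nrow(df))) {
      if (k == 1L || df$arm[k] != df$arm[k - 1L] ||
          df$start[k] - df$start[k - 1L] > cfg$locus_5p_tol) {
        f <- f + 1L
      }
      fam[k] <- f
    }
    df$family <- fam
    n_fam <- max(fam)
    fam_letter <- if (n_fam == 1L) "" else letters[seq_len(n_fam)]
    acc <- character(nrow(df))
    for (fm in seq_len(n_fam)) {
      rows <- which(df$family == fm)
      rows <- rows[order(-df$total[rows], df$sequence[rows])]
      base <- paste0(prefix, "-", locus_n,
                     if (n_fam == 1L) "" else fam_letter[fm])
      acc[rows] <- if (length(rows) == 1L) base
                   else paste0(base, "-", seq_along(rows))
    }
    df$accession <- acc

    lib <- pl$lib[df$idx]
    role <- ifelse(is_milR[df$idx], "milR", "milRstar")
    cand_rows[[length(cand_rows) + 1L]] <- data.frame(
      accession = df$accession,
      precursor_id = cid,
      contig_id = fc$parent_id,
      arm = df$arm,
      role = role,
      sequence = df$sequence,
      start = df$start,
      mismatches = pl$mismatches[df$idx],
      count_MY = pl$count_MY[df$idx],
      count_FB = pl$count_FB[df$idx],
      lib_class = lib,
      stringsAsFactors = FALSE
    )
    prec_class <- if (length(unique(lib)) > 1L || any(lib == "B")) "B" else lib[1]
    prec_rows[[length(prec_rows) + 1L]] <- data.frame(
      precursor_id = cid, contig_id = fc$parent_id, lib_class = prec_class,
      n_candidates = nrow(df), stringsAsFactors = FALSE
    )
  }
  candidates <- if (length(cand_rows)) do.call(rbind, cand_rows) else
    data.frame(accession = character(), precursor_id = character(),
               contig_id = character(), arm = character(), role = character(),
               sequence = character(), start = integer(),
               mismatches = integer(), count_MY = integer(),
               count_FB = integer(), lib_class = character(),
               stringsAsFactors = FALSE)
  precs <- if (length(prec_rows)) do.call(rbind, prec_rows) else
    data.frame(precursor_id = character(), contig_id = character(),
               lib_class = character(), n_candidates = integer(),
               stringsAsFactors = FALSE)
  rownames(candidates) <- rownames(precs) <- NULL
  stage_log("call_candidates", length(precursors), nrow(candidates))
  list(candidates = candidates, precursors = precs)
}

#' Annotate grouped sRNAs against a mature miRNA reference
#'
#' A hit requires an ungapped alignment of the sRNA to a reference mature
#' miRNA covering at least 18 nt with at most `cfg$conserved_mm_max`
#' mismatches, and the sRNA must itself be stem-located on some folded
#' contig. Only stem-located hits are reported.
#'
#' @param grouped a `grouped_srna` table.
#' @param mature_ref sequence table of mature miRNAs (miRBase-style ids).
#' @param folded a `folded_set` used for the stem-location requirement.
#' @param cfg a [milr_config()].
#' @param placements optional precomputed [map_reads()] output.
#' @return data.frame: `sequence`, `ref_name`, `mismatches`, `overlap`,
#'   `count_MY`, `count_FB`, `lib`.
#' @export
annotate_conserved <- function(grouped, mature_ref, folded,
                               cfg = milr_config(), placements = NULL) {
  if (!nrow(mature_ref)) stop("mature reference is empty")
  if (is.null(placements)) placements <- map_reads(grouped, folded, cfg)
  stem_ok <- stem_located_sequences(placements, folded, cfg)

  min_ov <- 18L
  hits <- list()
  refs <- mature_ref$seq
  ref_int <- lapply(refs, utf8ToInt)
  for (i in seq_len(nrow(grouped))) {
    s <- grouped$sequence[i]
    if (!(s %in% stem_ok)) next
    sv <- utf8ToInt(s)
    ls <- length(sv)
    best_mm <- NA_integer_; best_ref <- NA_character_; best_ov <- 0L
    for (r in seq_along(refs)) {
      rv <- ref_int[[r]]
      lr <- length(rv)
      if (min(ls, lr) < min_ov) next
      for (off in (-(ls - min_ov)):(lr - min_ov)) {
        a <- max(1L, 1L - off); b <- min(ls, lr - off)
        ov <- b - a + 1L
        if (ov < min_ov) next
        mm <- sum(sv[a:b] != rv[(a + off):(b + off)])
        if (mm <= cfg$conserved_mm_max &&
            (is.na(best_mm) || mm < best_mm ||
             (mm == best_mm && ov > best_ov))) {
          best_mm <- mm; best_ref <- mature_ref$id[r]; best_ov <- ov
        }
      }
    }
    if (!is.na(best_mm)) {
      hits[[length(hits) + 1L]] <- data.frame(
        sequence = s, ref_name = best_ref, mismatches = best_mm,
        overlap = best_ov, count_MY = grouped$count_MY[i],
        count_FB = grouped$count_FB[i], lib = grouped$lib[i],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else
    data.frame(sequence = character(), ref_name = character(),
               mismatches = integer(), overlap = integer(),
               count_MY = integer(), count_FB = integer(), lib = character(),
               stringsAsFactors = FALSE)
  stage_log("annotate_conserved", nrow(grouped), nrow(out))
  out
}

# distinct sequences with at least one stem-located placement
stem_located_sequences <- function(placements, folded, cfg) {
  ok <- character(0)
  stem_cache <- list()
  for (k in seq_len(nrow(placements))) {
    s <- placements$sequence[k]
    if (s %in% ok) next
    cid <- placements$contig_id[k]
    if (is.null(stem_cache[[cid]])) {
      stem_cache[[cid]] <- extract_stems(folded[[cid]], cfg)
    }
    inf <- placement_stem_info(placements$start[k], nchar(s),
                               folded[[cid]], stem_cache[[cid]], cfg)
    if (inf$located) ok <- c(ok, s)
  }
  ok
}
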