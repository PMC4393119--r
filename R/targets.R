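#' Expectation score of a milRNA against one target site
#'
#' Plant-style (psRNATarget/miRU convention) complementarity penalty: the
#' site is aligned against the reverse complement of the milRNA with at
#' most `cfg$target_gap_max` gaps in total; each milRNA position
#' contributes 0 for a Watson-Crick match, `cfg$target_w_wobble` for a
#' G:U wobble, `cfg$target_w_mismatch` for a mismatch and
#' `cfg$target_w_gap` for a gap, multiplied by `cfg$target_seed_mult`
#' when the position (from the milRNA 5' end) lies in
#' `cfg$target_seed_range`. The minimal penalty over all such alignments
#' is returned. An unaligned site base is attributed to the milRNA
#' position of the adjacent (3'-ward) aligned base.
#'
#' @param milrna milRNA sequence (RNA, 18-30 nt).
#' @param site candidate target site (RNA, within `target_gap_max` nt of
#'   the milRNA length).
#' @param cfg a [milr_config()].
#' @return list: `expectation` (penalty), `alignment` data.frame with
#'   per-column `op` (`match`/`wobble`/`mismatch`/`gap`) and `milrna_pos`
#'   (1-based from the milRNA 5' end).
#' @examples
#' expectation_score("ACGUACGUACGUACGUACGUAC",
#'                   revcomp("ACGUACGUACGUACGUACGUAC"))$expectation  # 0
#' @export
expectation_score <- function(milrna, site, cfg = milr_config()) {
  milrna <- normalize_alphabet(milrna, "rna")
  site <- normalize_alphabet(site, "rna")
  n <- nchar(milrna)
  if (n < 18L || n > 30L) stop("milRNA length must lie in 18..30 nt")
  if (abs(nchar(site) - n) > 4L) stop("site length must lie within 4 nt of the milRNA")
  q <- revcomp(milrna)
  r <- expectation_dp_cpp(q, site, cfg$target_w_mismatch, cfg$target_w_wobble,
                          cfg$target_w_gap, cfg$target_seed_mult,
                          min(cfg$target_seed_range), max(cfg$target_seed_range),
                          cfg$target_gap_max)
  if (!is.finite(r$score)) {
    stop("site length incompatible with the gap cap (", cfg$target_gap_max, ")")
  }
  ops <- c("match", "wobble", "mismatch", "gap", "gap")[r$ops + 1L]
  list(expectation = r$score,
       alignment = data.frame(op = ops, milrna_pos = r$milpos,
                              stringsAsFactors = FALSE))
}

#' Scan unigenes for milRNA target sites
#'
#' Every window of each unigene is scored with [expectation_score()];
#' for each milRNA-unigene pair only the minimal-expectation site is
#' reported, and only when its expectation does not exceed
#' `cfg$expectation_max`. Inhibition is `Translation` when any
#' mismatch, wobble or gap falls at milRNA positions
#' `cfg$target_central_range` (default 9-11), else `Cleavage`.
#'
#' @param milrnas named character vector (accession -> milRNA sequence) or
#'   a candidates data.frame with `accession` and `sequence`.
#' @param unigenes sequence table of unigenes (RNA alphabet).
#' @param cfg a [milr_config()].
#' @return data.frame of class `target_hits`: `milrna_acc`, `target_id`,
#'   `expectation`, `align_start` (0-based), `align_len`, `inhibition`.
#' @export
scan_targets <- function(milrnas, unigenes, cfg = milr_config()) {
  if (is.data.frame(milrnas)) {
    milrnas <- setNames(milrnas$sequence, milrnas$accession)
  }
  milrnas <- milrnas[!duplicated(names(milrnas))]
  rows <- list()
  central <- cfg$target_central_range
  cache <- new.env(parent = emptyenv())  # identical sequences scan once
  for (acc in names(milrnas)) {
    m <- milrnas[[acc]]
    q <- revcomp(m)
    for (u in seq_len(nrow(unigenes))) {
      key <- paste0(m, "|", u)
      hit <- if (!is.null(cache[[key]])) cache[[key]] else
        target_scan_cpp(q, unigenes$seq[u], cfg$target_w_mismatch,
                             cfg$target_w_wobble, cfg$target_w_gap,
                             cfg$target_seed_mult,
                             min(cfg$target_seed_range),
                             max(cfg$target_seed_range),
                             cfg$target_gap_max, cfg$expectation_max)
      cache[[key]] <- hit
      if (!isTRUE(hit$found)) next
      imperfect <- hit$ops != 0L & hit$milpos %in% central
      rows[[length(rows) + 1L]] <- data.frame(
        milrna_acc = acc,
        target_id = unigenes$id[u],
        expectation = hit$score,
        align_start = hit$start,
        align_len = hit$len,
        inhibition = if (any(imperfect)) "Translation" else "Cleavage",
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(milrna_acc = character(), target_id = character(),
               expectation = numeric(), align_start = integer(),
               align_len = integer(), inhibition = character(),
               stringsAsFactors = FALSE)
  class(out) <- c("target_hits", "data.frame")
  stage_log("scan_targets", length(milrnas) * nrow(unigenes), nrow(out))
  out
}

#' Cross-filter target hits by expression direction
#'
#' Keeps a hit iff the milRNA's library of origin and the target's
#' differential-expression direction are opposed: an M-class milRNA must
#' hit a gene up in FB (`up_FB` or `FB_specific`), an F-class milRNA a
#' gene up in MY (`up_MY` or `MY_specific`); B-class milRNAs are kept
#' under either direction. Targets without a DEG call are dropped, as are
#' hits whose target id is absent from the expression table (with a
#' warning).
#'
#' @param hits a `target_hits` data.frame from [scan_targets()].
#' @param expression output of [classify_deg()].
#' @param lib_classes named character vector: milRNA accession -> class
#'   (`M`, `F` or `B`).
#' @return the filtered hits with added `deg_class`, `rpkm_MY`, `rpkm_FB`
#'   columns.
#' @export
cross_filter <- function(hits, expression, lib_classes) {
  if (!nrow(hits)) return(cbind(hits, deg_class = character(0),
                                rpkm_MY = numeric(0), rpkm_FB = numeric(0)))
  idx <- match(hits$target_id, expression$unigene_id)
  if (any(is.na(idx))) {
    warning("dropping ", sum(is.na(idx)),
            " hit(s) with targets absent from the expression table")
  }
  keep_known <- !is.na(idx)
  hits <- hits[keep_known, , drop = FALSE]
  idx <- idx[keep_known]
  hits$deg_class <- expression$deg_class[idx]
  hits$rpkm_MY <- expression$rpkm_MY[idx]
  hits$rpkm_FB <- expression$rpkm_FB[idx]
  lc <- lib_classes[hits$milrna_acc]
  up_fb <- hits$deg_class %in% c("up_FB", "FB_specific")
  up_my <- hits$deg_class %in% c("up_MY", "MY_specific")
  keep <- (lc == "M" & up_fb) | (lc == "F" & up_my) | (lc == "B" & (up_fb | up_my))
  out <- hits[keep & !is.na(keep), , drop = FALSE]
  rownames(out) <- NULL
  stage_log("cross_filter", length(keep), nrow(out))
  out
}
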