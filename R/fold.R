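#' Fold an RNA sequence with a weighted Nussinov dynamic program
#'
#' Predicts a nested (pseudoknot-free) secondary structure maximizing a
#' weighted base-pair sum (GC = 3, AU = 2, GU = 1) subject to a minimum
#' hairpin loop of `cfg$min_loop` nt. The traceback is deterministic
#' (pairing preferred over leaving a base unpaired, smallest partner index
#' on ties), so identical input always yields an identical dot-bracket.
#' This is a topology-oriented stand-in for a thermodynamic folder: the
#' downstream milRNA criteria depend only on stem membership, which both
#' kinds of folder provide. An external folder can be plugged in through
#' `backend`.
#'
#' Contigs longer than `cfg$fold_max_len` are folded in overlapping
#' windows of `cfg$fold_window` nt (step `cfg$fold_step`); each window is
#' returned as its own folded record with id `<contig>|w<start>`.
#'
#' @param contigs a sequence table from [read_fasta()] (RNA alphabet), or a
#'   named character vector of RNA sequences.
#' @param cfg a [milr_config()].
#' @param backend optional replacement folder: a `function(sequence)`
#'   returning a dot-bracket string of the same length.
#' @return a `folded_set`: a list of `folded_contig` records, each with
#'   `contig_id`, `seq`, `dotbracket`, `score`, `partner` (integer vector,
#'   1-based partner index or NA), and for windowed folds `offset` (0-based
#'   offset of the window in the parent contig) and `parent_id`.
#' @examples
#' f <- fold_contigs(c(h1 = "GGGGAAAACCCC"))[[1]]
#' f$dotbracket  # "((((....))))"
#' @export
fold_contigs <- function(contigs, cfg = milr_config(), backend = NULL) {
  if (is.data.frame(contigs)) {
    seqs <- setNames(contigs$seq, contigs$id)
  } else {
    seqs <- contigs
    if (is.null(names(seqs))) names(seqs) <- paste0("contig", seq_along(seqs))
  }
  out <- list()
  for (id in names(seqs)) {
    s <- seqs[[id]]
    if (!grepl("^[ACGUN]*$", s)) stop("non-RNA characters in contig ", id)
    if (nchar(s) <= cfg$fold_max_len) {
      out[[length(out) + 1L]] <- fold_one(id, s, 0L, id, cfg, backend)
    } else {
      starts <- seq(0L, max(0L, nchar(s) - cfg$fold_window), by = cfg$fold_step)
      # make sure the tail is covered
      last <- nchar(s) - cfg$fold_window
      if (starts[length(starts)] < last) starts <- c(starts, last)
      for (st in starts) {
        w <- substr(s, st + 1L, min(nchar(s), st + cfg$fold_window))
        out[[length(out) + 1L]] <-
          fold_one(paste0(id, "|w", st), w, as.integer(st), id, cfg, backend)
      }
    }
  }
  names(out) <- vapply(out, `[[`, character(1), "contig_id")
  class(out) <- "folded_set"
  out
}

fold_one <- function(id, s, offset, parent, cfg, backend) {
  if (is.null(backend)) {
    r <- nussinov_fold_cpp(s, cfg$min_loop)
    db <- r$dotbracket
    score <- r$score
    partner <- ifelse(r$partner < 0L, NA_integer_, r$partner + 1L)
  } else {
    db <- backend(s)
    if (nchar(db) != nchar(s)) stop("backend returned structure of wrong length")
    partner <- dotbracket_partner(db)
    score <- sum(!is.na(partner)) / 2
  }
  structure(list(contig_id = id, seq = s, dotbracket = db, score = score,
                 partner = partner, offset = offset, parent_id = parent),
            class = "folded_contig")
}

#' Parse a dot-bracket string into a partner map
#'
#' @param db dot-bracket string over `(`, `)`, `.`.
#' @return integer vector; `partner[i]` is the 1-based pairing partner of
#'   position i, or NA if unpaired.
#' @export
dotbracket_partner <- function(db) {
  ch <- strsplit(db, "", fixed = TRUE)[[1]]
  partner <- rep(NA_integer_, length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket")
  partner
}

#' Decompose a folded contig into stems
#'
#' A stem is a maximal run of nested base pairs, merged across bulges and
#' internal loops of at most `cfg$stem_gap_max` nt per side. Every base
#' pair belongs to exactly one stem.
#'
#' @param folded a `folded_contig` record from [fold_contigs()].
#' @param cfg a [milr_config()].
#' @return data.frame with one row per stem: `stem` (index), `arm5_start`,
#'   `arm5_end`, `arm3_start`, `arm3_end` (0-based half-open intervals) and
#'   `n_pairs`; plus attribute `pair_stem`, an integer vector mapping each
#'   paired 5' position (1-based) to its stem index.
#' @export
extract_stems <- function(folded, cfg = milr_config()) {
  partner <- folded$partner
  i5 <- which(!is.na(partner) & seq_along(partner) < partner)
  empty <- data.frame(stem = integer(), arm5_start = integer(),
                      arm5_end = integer(), arm3_start = integer(),
                      arm3_end = integer(), n_pairs = integer())
  if (!length(i5)) {
    attr(empty, "pair_stem") <- setNames(integer(0), character(0))
    return(empty)
  }
  i5 <- sort(i5)
  j5 <- partner[i5]
  stem_id <- integer(length(i5))
  cur <- 1L
  stem_id[1] <- 1L
  for (k in seq_along(i5)[-1]) {
    nested <- i5[k] > i5[k - 1] && j5[k] < j5[k - 1]
    small_gap <- (i5[k] - i5[k - 1] - 1L) <= cfg$stem_gap_max &&
                 (j5[k - 1] - j5[k] - 1L) <= cfg$stem_gap_max
    if (nested && small_gap) stem_id[k] <- cur
    else { cur <- cur + 1L; stem_id[k] <- cur }
  }
  rows <- lapply(seq_len(cur), function(s) {
    sel <- stem_id == s
    data.frame(stem = s,
               arm5_start = min(i5[sel]) - 1L, arm5_end = max(i5[sel]),
               arm3_start = min(j5[sel]) - 1L, arm3_end = max(j5[sel]),
               n_pairs = sum(sel))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$arm5_start), , drop = FALSE]
  out$stem <- seq_len(nrow(out))
  rownames(out) <- NULL
  # per-position stem membership (both arms), renumbered to match `out`
  reorder <- order(vapply(seq_len(cur), function(s) min(i5[stem_id == s]),
                          integer(1)))
  new_id <- match(stem_id, reorder)
  pair_stem <- rep(NA_integer_, length(partner))
  pair_stem[i5] <- new_id
  pair_stem[j5] <- new_id
  attr(out, "pair_stem") <- pair_stem
  out
}
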