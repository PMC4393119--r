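# Independent oracles used by the tests. These deliberately use brute
# force (explicit enumeration) rather than the package's dynamic programs.

oracle_pair_w <- function(a, b) {
  key <- paste0(a, b)
  if (key %in% c("GC", "CG")) return(3)
  if (key %in% c("AU", "UA")) return(2)
  if (key %in% c("GU", "UG")) return(1)
  0
}

# all nested structures on positions i..j as lists of pairs, min_loop
# enforced; returns the maximal weighted pair sum over all of them
oracle_fold_max <- function(seq, min_loop = 3) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  enum <- function(i, j) {
    # list of structures (each a list of c(i, k) pairs) on i..j
    if (i > j || j - i < min_loop + 1) return(list(list()))
    out <- lapply(enum(i + 1, j), identity)  # i unpaired
    for (k in (i + min_loop + 1):j) {
      if (oracle_pair_w(ch[i], ch[k]) == 0) next
      inner <- enum(i + 1, k - 1)
      outer <- if (k < j) enum(k + 1, j) else list(list())
      for (a in inner) for (b in outer) {
        out[[length(out) + 1L]] <- c(list(c(i, k)), a, b)
      }
    }
    out
  }
  structs <- enum(1, n)
  scores <- vapply(structs, function(st) {
    if (!length(st)) return(0)
    sum(vapply(st, function(p) oracle_pair_w(ch[p[1]], ch[p[2]]), numeric(1)))
  }, numeric(1))
  max(scores)
}

# naive per-position Hamming scan
oracle_map <- function(read, contig, mm_max) {
  L <- nchar(read)
  n <- nchar(contig)
  rv <- strsplit(read, "", fixed = TRUE)[[1]]
  cv <- strsplit(contig, "", fixed = TRUE)[[1]]
  hits <- list()
  if (n >= L) {
    for (p in 0:(n - L)) {
      mm <- sum(rv != cv[(p + 1):(p + L)])
      if (mm <= mm_max) hits[[length(hits) + 1L]] <- c(start = p, mm = mm)
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(), mm = integer()))
  }
  as.data.frame(do.call(rbind, hits))
}

# exhaustive enumeration of all global alignments of q vs y with at most
# gap_max gaps, scored with the package's stated convention
oracle_expectation <- function(milrna, site, cfg = milr_config()) {
  q <- strsplit(revcomp(milrna), "", fixed = TRUE)[[1]]
  y <- strsplit(site, "", fixed = TRUE)[[1]]
  n <- length(q); m <- length(y)
  seed <- cfg$target_seed_range
  wt <- function(qpos) {
    mp <- max(1L, n - qpos + 1L)
    if (mp %in% seed) cfg$target_seed_mult else 1
  }
  sub_cost <- function(i, j) {
    key <- paste0(q[i], y[j])
    base <- if (q[i] == y[j]) 0
    else if (key %in% c("CU", "AG")) cfg$target_w_wobble
    else cfg$target_w_mismatch
    base * wt(i)
  }
  # explicit enumeration (no memoization)
  rec <- function(i, j, g) {
    if (i > n && j > m) return(0)
    best <- Inf
    if (i <= n && j <= m) {
      best <- min(best, sub_cost(i, j) + rec(i + 1, j + 1, g))
    }
    if (g < cfg$target_gap_max) {
      if (i <= n) {
        best <- min(best, cfg$target_w_gap * wt(i) + rec(i + 1, j, g + 1))
      }
      if (j <= m) {
        nxt <- if (i <= n) i else n
        best <- min(best, cfg$target_w_gap * wt(nxt) + rec(i, j + 1, g + 1))
      }
    }
    best
  }
  rec(1, 1, 0)
}

rand_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

# run simulate -> preprocess -> fold -> discover on a synthetic study
run_discovery <- function(truth, dir) {
  sim <- simulate_study(truth, dir)
  cfg <- milr_config()
  my <- preprocess_library(read_fastq(sim$files["srna_MY"], "rna"),
                           truth$adapter, cfg)
  fb <- preprocess_library(read_fastq(sim$files["srna_FB"], "rna"),
                           truth$adapter, cfg)
  grouped <- group_reads(my, fb)
  folded <- fold_contigs(read_fasta(sim$files["contigs"], "rna"), cfg)
  placements <- map_reads(grouped, folded, cfg)
  precs <- find_precursor_candidates(placements, folded)
  called <- call_candidates(precs, placements, folded, cfg)
  list(sim = sim, grouped = grouped, folded = folded,
       placements = placements, called = called)
}

# fraction of recoverable planted loci recovered with exact roles/classes
recovery_fraction <- function(truth, dir) {
  res <- run_discovery(truth, dir)
  loci <- res$sim$truth$loci
  rec <- loci[loci$recoverable, , drop = FALSE]
  cand <- res$called$candidates
  ok <- vapply(seq_len(nrow(rec)), function(i) {
    hit <- cand[cand$sequence == rec$milR_seq[i] &
                  cand$contig_id == rec$contig_id[i], , drop = FALSE]
    star <- cand[cand$sequence == rec$milRstar_seq[i] &
                   cand$contig_id == rec$contig_id[i], , drop = FALSE]
    nrow(hit) >= 1 && all(hit$role == "milR") &&
      all(hit$lib_class == rec$lib_class[i]) &&
      (nrow(star) == 0 || all(star$role == "milRstar"))
  }, logical(1))
  c(n_recoverable = nrow(rec), fraction = mean(ok))
}
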