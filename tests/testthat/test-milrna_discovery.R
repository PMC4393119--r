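cfg <- milr_config()

make_grouped <- function(seqs, my, fb) {
  group_reads(rep(seqs, my), rep(seqs, fb))
}

test_that("read mapping reports all qualifying ungapped placements", {
  set.seed(4)
  contig <- rand_rna(80)
  read <- substr(contig, 11, 32)  # placement at 0-based start 10
  g <- make_grouped(read, 1, 0)
  folded <- fold_contigs(setNames(contig, "c1"), cfg)
  pm <- map_reads(g, folded, cfg)
  expect_true(any(pm$start == 10 & pm$mismatches == 0))

  # 3 mismatches placed, 4 not ("fewer than 4")
  mut <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    for (p in seq_len(k)) v[p] <- setdiff(c("A", "C", "G", "U"), v[p])[1]
    paste(v, collapse = "")
  }
  g3 <- make_grouped(mut(read, 3), 1, 0)
  expect_true(10 %in% map_reads(g3, folded, cfg)$start)
  g4 <- make_grouped(mut(read, 4), 1, 0)
  expect_false(10 %in% map_reads(g4, folded, cfg)$start)
})

test_that("mapping equals the naive Hamming-scan oracle", {
  set.seed(12)
  for (rep in 1:50) {
    contig <- rand_rna(sample(60:150, 1))
    read <- if (runif(1) < 0.5) {
      p <- sample(nchar(contig) - 25, 1)
      chartr("A", "G", substr(contig, p, p + sample(18:25, 1)))
    } else rand_rna(sample(18:25, 1))
    for (mm in c(0L, 1L, 3L)) {
      c_mm <- milr_config(mismatch_max = mm)
      g <- make_grouped(read, 1, 0)
      folded <- fold_contigs(setNames(contig, "c"), c_mm)
      got <- map_reads(g, folded, c_mm)
      want <- oracle_map(read, contig, mm)
      expect_equal(got$start, want$start)
      expect_equal(got$mismatches, want$mm)
    }
  }
})

test_that("placements are monotone in the mismatch allowance", {
  set.seed(13)
  contig <- rand_rna(200)
  seqs <- vapply(1:30, function(i) rand_rna(19), character(1))
  g <- make_grouped(seqs, rep(1, 30), rep(0, 30))
  counts <- vapply(0:3, function(mm) {
    cmm <- milr_config(mismatch_max = mm)
    nrow(map_reads(g, fold_contigs(setNames(contig, "c"), cmm), cmm))
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("precursor candidates need two distinct mapped sequences", {
  set.seed(14)
  contig <- rand_rna(90)
  s1 <- substr(contig, 5, 26)
  s2 <- substr(contig, 41, 62)
  folded <- fold_contigs(setNames(contig, "c"), cfg)
  both <- map_reads(make_grouped(c(s1, s2), c(1, 1), c(0, 0)), folded, cfg)
  expect_equal(find_precursor_candidates(both, folded), "c")
  # a single sequence, even high count / multiple offsets, is not enough
  solo <- map_reads(make_grouped(s1, 1000, 0), folded, cfg)
  expect_length(find_precursor_candidates(solo, folded), 0L)
  rep_contig <- paste0(contig, contig)  # s1 places twice: still one sequence
  folded2 <- fold_contigs(setNames(rep_contig, "c2"), cfg)
  multi <- map_reads(make_grouped(s1, 1, 0), folded2, cfg)
  expect_gte(nrow(multi), 2L)
  expect_length(find_precursor_candidates(multi, folded2), 0L)
})

test_that("same_stem_check accepts planted duplexes and rejects same-arm pairs", {
  set.seed(15)
  hp <- make_hairpin("UGAGGUAGUAGGUUGUAUAGUU", loop_len = 6, bulges = 1)
  fc <- fold_contigs(setNames(hp$precursor, "p"), cfg)[[1]]
  p_milR <- list(start = 0L, sequence = hp$milR)
  p_star <- list(start = hp$milRstar_start, sequence = hp$milRstar)
  expect_true(same_stem_check(p_milR, p_star, fc, cfg)$verdict)
  # two overlapping reads on the same (5') arm
  p_shift <- list(start = 2L, sequence = substr(hp$precursor, 3, 22))
  expect_false(same_stem_check(p_milR, p_shift, fc, cfg)$verdict)
  # reads on two different hairpins of one contig
  set.seed(16)
  hp2 <- make_hairpin("ACGGAUGCAGACCUGAAGCGAA", loop_len = 6)
  two <- paste0(hp$precursor, strrep("A", 10), hp2$precursor)
  fc2 <- fold_contigs(setNames(two, "q"), cfg)[[1]]
  off2 <- nchar(hp$precursor) + 10L
  pa <- list(start = 0L, sequence = hp$milR)
  pb <- list(start = off2, sequence = hp2$milR)
  expect_false(same_stem_check(pa, pb, fc2, cfg)$verdict)
})

test_that("candidate calling assigns roles by strict count dominance", {
  set.seed(17)
  hp <- make_hairpin("UGAGGUAGUAGGUUGUAUAGUU", loop_len = 6)
  contig <- paste0("ACCAC", hp$precursor, "GUGGA")
  folded <- fold_contigs(setNames(contig, "c"), cfg)
  g <- make_grouped(c(hp$milR, hp$milRstar), c(100, 5), c(0, 0))
  pm <- map_reads(g, folded, cfg)
  res <- call_candidates("c", pm, folded, cfg)
  expect_equal(nrow(res$candidates), 2L)
  milR_row <- res$candidates[res$candidates$role == "milR", ]
  expect_equal(milR_row$sequence, hp$milR)
  expect_equal(milR_row$count_MY, 100L)
  expect_equal(milR_row$lib_class, "M")
  expect_equal(res$precursors$lib_class, "M")
  # equal counts: duplex discarded entirely
  g_eq <- make_grouped(c(hp$milR, hp$milRstar), c(7, 7), c(0, 0))
  res_eq <- call_candidates("c", map_reads(g_eq, folded, cfg), folded, cfg)
  expect_equal(nrow(res_eq$candidates), 0L)
})

test_that("locus families group shifted variants with suffixed accessions", {
  set.seed(18)
  hp <- make_hairpin("UGAGGUAGUAGGUUGUAUAGUU", loop_len = 6)
  contig <- paste0("ACCAC", hp$precursor, "GUGGA")
  folded <- fold_contigs(setNames(contig, "c"), cfg)
  variant <- substr(contig, 7, 27)  # milR shifted by one
  g <- make_grouped(c(hp$milR, variant, hp$milRstar),
                    c(100, 40, 5), c(0, 0, 0))
  pm <- map_reads(g, folded, cfg)
  res <- call_candidates("c", pm, folded, cfg)
  cand <- res$candidates
  expect_equal(nrow(cand), 3L)
  fam5p <- cand[cand$arm == cand$arm[cand$sequence == hp$milR], ]
  # the two 5'-shifted variants share a family base and are numbered
  accs <- sort(cand$accession[cand$sequence %in% c(hp$milR, variant)])
  expect_match(accs, "^aci-milR-1a-[12]$", all = TRUE)
  expect_equal(cand$accession[cand$sequence == hp$milRstar], "aci-milR-1b")
})

test_that("planted-study discovery satisfies the class-partition invariant", {
  tr <- synthetic_truth(n_loci = 6, n_unigenes = 10, n_deg = 4,
                        n_targets = 2, error_rate = 0, background_frac = 0,
                        seed = 19)
  res <- run_discovery(tr, withr::local_tempdir())
  cand <- res$called$candidates
  expect_gt(nrow(cand), 0)
  expect_true(all(cand$lib_class %in% c("M", "F", "B")))
  cls <- table(factor(cand$lib_class, levels = c("M", "F", "B")))
  expect_equal(sum(cls), nrow(cand))
  # role antisymmetry: each precursor has at least one milR and the
  # planted milR/milR* pair is never both milR
  loci <- res$sim$truth$loci
  for (i in which(loci$recoverable)) {
    rows <- cand[cand$contig_id == loci$contig_id[i], ]
    roles <- rows$role[match(c(loci$milR_seq[i], loci$milRstar_seq[i]),
                             rows$sequence)]
    roles <- roles[!is.na(roles)]
    expect_lte(sum(roles == "milR"), 1L)
  }
})

test_that("conserved annotation requires identity, mismatch cap and stem location", {
  set.seed(20)
  hp <- make_hairpin("UGAGGUAGUAGGUUGUAUAGUU", loop_len = 12)
  contig <- paste0("ACCAC", hp$precursor, "GUGGA")
  folded <- fold_contigs(setNames(contig, "c"), cfg)
  loop_seq <- substr(hp$precursor, 18, 40)  # mostly unpaired loop
  g <- make_grouped(c(hp$milR, loop_seq), c(10, 10), c(1, 0))
  refs <- data.frame(id = c("ref-miR-1", "ref-miR-2"),
                     seq = c(hp$milR, loop_seq),
                     qual = NA, stringsAsFactors = FALSE)
  hits <- annotate_conserved(g, refs, folded, cfg)
  expect_true(hp$milR %in% hits$sequence)
  expect_equal(hits$mismatches[hits$sequence == hp$milR], 0L)
  # identical to a reference but sitting on the loop: not reported
  expect_false(loop_seq %in% hits$sequence)
  # mismatch cap: a read 3 away from every reference is not reported
  mut3 <- hp$milR
  substr(mut3, 2, 2) <- "C"; substr(mut3, 5, 5) <- "C"; substr(mut3, 9, 9) <- "A"
  g2 <- make_grouped(mut3, 10, 0)
  refs2 <- data.frame(id = "ref-miR-1", seq = hp$milR, qual = NA,
                      stringsAsFactors = FALSE)
  hits2 <- annotate_conserved(g2, refs2, folded, cfg)
  expect_false(mut3 %in% hits2$sequence)
  expect_error(annotate_conserved(g, refs[0, ], folded, cfg), "empty")
})
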