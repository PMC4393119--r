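cfg <- milr_config()

# a 22-nt milRNA without G at 20 / U at 5 issues is easiest built by hand
MIL <- "UGAGGUAGUAGGUUGUAUAGUU"

# site with controlled imperfections: start from the exact complement and
# edit the site base facing a chosen milRNA position
site_with <- function(milrna, pos, type = c("wobble", "mismatch")) {
  type <- match.arg(type)
  q <- strsplit(revcomp(milrna), "", fixed = TRUE)[[1]]
  n <- length(q)
  k <- n - pos + 1  # site index facing milRNA position `pos`
  y <- q
  if (type == "wobble") {
    # G:U wobble in q-space: (q, y) = (C, U) or (A, G)
    y[k] <- switch(q[k], C = "U", A = "G",
                   stop("milRNA position cannot wobble"))
  } else {
    y[k] <- setdiff(c("A", "C", "G", "U"),
                    c(q[k], switch(q[k], C = "U", A = "G", q[k])))[1]
  }
  paste(y, collapse = "")
}

test_that("an exact complementary site scores zero", {
  r <- expectation_score(MIL, revcomp(MIL), cfg)
  expect_equal(r$expectation, 0)
  expect_true(all(r$alignment$op == "match"))
  expect_equal(r$alignment$milrna_pos, rev(seq_len(nchar(MIL))))
})

test_that("positional weighting doubles penalties in positions 2-13", {
  # milRNA position 20 (G here) -> G:U wobble outside the seed: 0.5
  expect_equal(expectation_score(MIL, site_with(MIL, 20, "wobble"),
                                 cfg)$expectation, 0.5)
  # same wobble type at position 5 (G) -> inside the seed: 1.0
  expect_equal(expectation_score(MIL, site_with(MIL, 5, "wobble"),
                                 cfg)$expectation, 1.0)
  # mismatches: 1.0 outside, 2.0 inside
  expect_equal(expectation_score(MIL, site_with(MIL, 20, "mismatch"),
                                 cfg)$expectation, 1.0)
  expect_equal(expectation_score(MIL, site_with(MIL, 5, "mismatch"),
                                 cfg)$expectation, 2.0)
})

test_that("length bounds are enforced", {
  expect_error(expectation_score("ACGUACGU", "ACGUACGU"), "18..30")
  expect_error(expectation_score(MIL, rand_rna(30)), "within 4 nt")
})

test_that("banded minimum equals the exhaustive <=2-gap enumeration", {
  set.seed(40)
  for (rep in 1:30) {
    m <- rand_rna(sample(18:24, 1))
    site <- if (runif(1) < 0.5) {
      # perturbed complement (realistic near-sites)
      v <- strsplit(revcomp(m), "", fixed = TRUE)[[1]]
      for (k in sample(length(v), sample(0:4, 1))) {
        v[k] <- sample(c("A", "C", "G", "U"), 1)
      }
      if (runif(1) < 0.3) v <- v[-sample(length(v), 1)]  # induce a gap
      paste(v, collapse = "")
    } else rand_rna(nchar(m) + sample(-2:2, 1))
    got <- expectation_score(m, site, cfg)$expectation
    want <- oracle_expectation(m, site, cfg)
    expect_equal(got, want, info = paste(m, site))
  }
})

test_that("expectation is monotone under added mismatches", {
  set.seed(41)
  for (rep in 1:10) {
    m <- rand_rna(22)
    site <- revcomp(m)
    prev <- expectation_score(m, site, cfg)$expectation
    v <- strsplit(site, "", fixed = TRUE)[[1]]
    for (k in sample(22, 5)) {
      old <- v[k]
      v[k] <- sample(setdiff(c("A", "C", "G", "U"), old), 1)
      cur <- expectation_score(m, paste(v, collapse = ""), cfg)$expectation
      expect_gte(cur, prev - 1e-9)
      prev <- cur
    }
  }
})

test_that("scan reports best site, threshold subsets and inhibition mode", {
  set.seed(42)
  uni_bg <- rand_rna(400)
  site <- revcomp(MIL)
  uni <- paste0(substr(uni_bg, 1, 150), site, substr(uni_bg, 151, 400))
  unis <- data.frame(id = c("hit", "none"), seq = c(uni, rand_rna(400)),
                     qual = NA, stringsAsFactors = FALSE)
  hits <- scan_targets(c(mil = MIL), unis, cfg)
  expect_equal(hits$target_id, "hit")
  expect_equal(hits$expectation, 0)
  expect_equal(hits$align_start, 150L)
  expect_equal(hits$inhibition, "Cleavage")
  # single central (position 10) mismatch -> Translation
  uni10 <- paste0(substr(uni_bg, 1, 150), site_with(MIL, 10, "mismatch"),
                  substr(uni_bg, 151, 400))
  h10 <- scan_targets(c(mil = MIL),
                      data.frame(id = "u", seq = uni10, qual = NA), cfg)
  expect_equal(h10$inhibition, "Translation")
  # hits at expectation_max 3 are a subset of those at 4
  set.seed(43)
  unis2 <- data.frame(id = paste0("u", 1:20),
                      seq = vapply(1:20, function(i) {
                        v <- strsplit(revcomp(MIL), "")[[1]]
                        for (k in sample(22, sample(1:4, 1)))
                          v[k] <- sample(c("A", "C", "G", "U"), 1)
                        paste0(rand_rna(30), paste(v, collapse = ""),
                               rand_rna(30))
                      }, character(1)), qual = NA, stringsAsFactors = FALSE)
  h4 <- scan_targets(c(mil = MIL), unis2, cfg)
  h3 <- scan_targets(c(mil = MIL), unis2, milr_config(expectation_max = 3))
  expect_true(all(h3$target_id %in% h4$target_id))
  expect_true(all(h3$expectation <= 3))
})

test_that("cross_filter keeps only direction-opposed DEG targets", {
  hits <- data.frame(
    milrna_acc = c("m1", "m1", "f1", "f1", "b1", "x1"),
    target_id = c("g_upFB", "g_upMY", "g_upMY", "g_null", "g_upFB",
                  "g_missing"),
    expectation = 1, align_start = 0L, align_len = 22L,
    inhibition = "Cleavage", stringsAsFactors = FALSE)
  expression <- data.frame(
    unigene_id = c("g_upFB", "g_upMY", "g_null", "g_spec"),
    deg_class = c("up_FB", "up_MY", "not_DE", "FB_specific"),
    rpkm_MY = c(1, 50, 10, 0), rpkm_FB = c(40, 2, 10, 30),
    stringsAsFactors = FALSE)
  lc <- c(m1 = "M", f1 = "F", b1 = "B", x1 = "M")
  expect_warning(kept <- cross_filter(hits, expression, lc), "absent")
  expect_setequal(paste(kept$milrna_acc, kept$target_id),
                  c("m1 g_upFB", "f1 g_upMY", "b1 g_upFB"))
  expect_equal(kept$rpkm_FB[kept$milrna_acc == "m1"], 40)
})

test_that("planted target pairs survive cross-filtering exactly", {
  tr <- synthetic_truth(n_loci = 6, n_unigenes = 16, n_deg = 8,
                        n_targets = 3, error_rate = 0, background_frac = 0,
                        seed = 44)
  sim <- simulate_study(tr, withr::local_tempdir())
  unis <- read_fasta(sim$files[["unigenes"]], "rna")
  counts <- read.delim(sim$files[["counts"]], stringsAsFactors = FALSE)
  expression <- classify_deg(counts, cfg)
  tg <- sim$truth$targets
  loci <- sim$truth$loci
  mil <- setNames(loci$milR_seq, loci$precursor_id)
  lc <- setNames(loci$lib_class, loci$precursor_id)
  hits <- scan_targets(mil, unis, cfg)
  kept <- cross_filter(hits, expression, lc)
  planted_pairs <- paste(tg$precursor_id, tg$unigene_id)
  kept_pairs <- paste(kept$milrna_acc, kept$target_id)
  # every planted pair whose host gene got a DEG call is retained
  called <- expression$deg_class[match(tg$unigene_id,
                                       expression$unigene_id)] != "not_DE"
  expect_true(all(planted_pairs[called] %in% kept_pairs))
  # and nothing unplanted sneaks through
  expect_true(all(kept_pairs %in% planted_pairs))
})
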