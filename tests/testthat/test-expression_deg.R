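cfg <- milr_config()

test_that("rpkm follows its closed form and scaling law", {
  expect_equal(rpkm(0, 500, 1e6), 0)
  expect_equal(rpkm(10, 1000, 1e6), 10)
  set.seed(30)
  counts <- rpois(20, 50)
  lens <- sample(200:3000, 20)
  expect_equal(rpkm(counts, lens, 2e6), rpkm(counts, lens, 1e6) / 2)
  expect_error(rpkm(5, 0, 1e6), "gene_len_bp")
  expect_error(rpkm(5, 100, 0), "lib_total")
})

test_that("deg_test behaves at its anchor points", {
  expect_gt(deg_test(50, 50, 1e6, 1e6), 0.9)
  expect_lt(deg_test(100, 0, 1e6, 1e6), 1e-6)
  expect_equal(deg_test(0, 0, 1e6, 1e6), 1)
  expect_error(deg_test(1, 1, 0, 1e6), "totals")
})

test_that("the exact small-count branch matches binom.test", {
  # dual route: our summed-density two-sided p vs stats::binom.test
  for (x in 0:12) {
    ours <- deg_test(x, 12 - x, 1e6, 1e6)
    ref <- stats::binom.test(x, 12, 0.5)$p.value
    expect_equal(ours, ref, tolerance = 1e-9, info = paste("x =", x))
  }
  # unequal library totals shift the null proportion
  ours <- deg_test(10, 5, 2e6, 1e6)
  ref <- stats::binom.test(10, 15, 2 / 3)$p.value
  expect_equal(ours, ref, tolerance = 1e-9)
})

test_that("type-I error is calibrated under the null", {
  set.seed(31)
  n_genes <- 2000
  mu <- 100
  cm <- rpois(n_genes, mu)
  cf <- rpois(n_genes, mu)
  p <- deg_test(cm, cf, sum(cm), sum(cf))
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("bh_adjust reproduces hand-computed and reference values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(32)
  for (rep in 1:10) {
    p <- runif(sample(2:50, 1))
    expect_equal(bh_adjust(p), stats::p.adjust(p, "BH"))
  }
})

test_that("classification applies the FDR and fold-change gates", {
  counts <- data.frame(
    unigene_id = c("strong_FB", "weak_fc", "my_specific", "fb_low", "null1",
                   "null2"),
    length_bp = rep(1000L, 6),
    count_MY = c(50L, 400L, 40L, 0L, 200L, 200L),
    count_FB = c(450L, 600L, 0L, 3L, 200L, 205L),
    stringsAsFactors = FALSE)
  x <- classify_deg(counts, cfg, total_MY = 1e6, total_FB = 1e6)
  cls <- setNames(x$deg_class, x$unigene_id)
  expect_equal(cls[["strong_FB"]], "up_FB")     # FDR tiny, FC 9
  expect_equal(cls[["weak_fc"]], "not_DE")      # FC 1.5 below gate
  expect_equal(cls[["my_specific"]], "MY_specific")
  expect_equal(cls[["fb_low"]], "not_DE")       # 3 < min_specific
  expect_true(all(cls[c("null1", "null2")] == "not_DE"))
  # partition: every gene gets exactly one of the five classes
  expect_true(all(x$deg_class %in% c("up_MY", "up_FB", "MY_specific",
                                     "FB_specific", "not_DE")))
})

test_that("classes are scale-invariant and never flip direction", {
  set.seed(33)
  counts <- data.frame(unigene_id = paste0("u", 1:300),
                       length_bp = sample(300:3000, 300, TRUE),
                       count_MY = rpois(300, 80),
                       count_FB = rpois(300, 80), stringsAsFactors = FALSE)
  counts$count_FB[1:30] <- rpois(30, 320)  # planted up_FB
  x1 <- classify_deg(counts, cfg)
  counts10 <- counts
  counts10$count_MY <- counts$count_MY * 10L
  counts10$count_FB <- counts$count_FB * 10L
  x10 <- classify_deg(counts10, cfg)
  expect_equal(x1$fold_change, x10$fold_change)
  flipped <- (x1$deg_class == "up_MY" & x10$deg_class == "up_FB") |
             (x1$deg_class == "up_FB" & x10$deg_class == "up_MY")
  expect_false(any(flipped))
})

test_that("planted differential expression is recovered", {
  set.seed(34)
  n <- 1000
  planted <- 1:100
  mu <- rep(30, n)  # ~30 reads per gene
  lfc <- numeric(n)
  lfc[planted] <- rep(c(2, -2), 50)
  cm <- rpois(n, mu)
  cf <- rpois(n, mu * 2^lfc)
  counts <- data.frame(unigene_id = paste0("u", 1:n),
                       length_bp = 1000L, count_MY = cm, count_FB = cf,
                       stringsAsFactors = FALSE)
  x <- classify_deg(counts, cfg, total_MY = 1e6, total_FB = 1e6)
  called <- x$deg_class %in% c("up_MY", "up_FB", "MY_specific", "FB_specific")
  sens <- mean(called[planted])
  fp <- mean(called[-planted])
  expect_gte(sens, 0.80)
  expect_lte(fp, 0.01)
})
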