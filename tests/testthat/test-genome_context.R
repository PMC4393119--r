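test_that("exact placement finds planted precursors on either strand", {
  set.seed(50)
  prec <- rand_rna(60)
  prec_dna <- chartr("U", "T", prec)
  scaf <- paste0(paste(sample(c("A", "C", "G", "T"), 1000, TRUE),
                       collapse = ""))
  s_plus <- paste0(substr(scaf, 1, 200), prec_dna, substr(scaf, 201, 1000))
  scaffolds <- c(s1 = s_plus)
  pl <- place_on_genome(prec, scaffolds, "p1")
  expect_equal(pl$start, 200L)
  expect_equal(pl$strand, "+")
  expect_false(pl$multi_hit)
  # reverse-complemented precursor: same locus, flipped strand
  pl_rc <- place_on_genome(revcomp(prec), scaffolds, "p1")
  expect_equal(pl_rc$start, 200L)
  expect_equal(pl_rc$strand, "-")
  # absent sequence
  expect_null(place_on_genome(rand_rna(60), scaffolds))
  # multiple hits flag, first by position wins
  dup <- c(s1 = paste0(prec_dna, strrep("A", 50), prec_dna))
  pl_dup <- place_on_genome(prec, dup, "p1")
  expect_true(pl_dup$multi_hit)
  expect_equal(pl_dup$start, 0L)
})

empty_gm <- function() {
  g <- data.frame(gene_id = character(), scaffold = character(),
                  strand = character(), start = integer(), end = integer())
  class(g) <- c("gene_models", "data.frame")
  g
}

test_that("context classification follows the exon > intron precedence", {
  genes <- data.frame(gene_id = "g1", scaffold = "s1", strand = "+",
                      start = c(100L, 300L), end = c(200L, 400L),
                      stringsAsFactors = FALSE)
  class(genes) <- c("gene_models", "data.frame")
  plc <- function(st, en, strand = "+") {
    list(scaffold = "s1", start = st, end = en, strand = strand)
  }
  expect_equal(classify_context(plc(230, 280), genes), "intron")
  expect_equal(classify_context(plc(120, 160, "-"), genes), "exon_antisense")
  expect_equal(classify_context(plc(120, 160, "+"), genes), "exon_sense")
  expect_equal(classify_context(plc(500, 560), genes), "intergenic")
  expect_equal(classify_context(plc(10, 40), genes), "intergenic")
  # straddles the exon/intron boundary: exon wins
  expect_equal(classify_context(plc(190, 240, "-"), genes), "exon_antisense")
  expect_equal(classify_context(plc(5, 20), empty_gm()), "intergenic")
})

test_that("planted genomic contexts are recovered exactly", {
  tr <- synthetic_truth(error_rate = 0, background_frac = 0, seed = 51)
  sim <- simulate_study(tr, withr::local_tempdir())
  scaffolds <- read_fasta(sim$files[["genome"]], "dna")
  genes <- read_gff3(sim$files[["genes"]])
  loci <- sim$truth$loci
  prec <- setNames(loci$precursor_seq, loci$precursor_id)
  ctx <- genome_context(prec, scaffolds, genes)
  expect_equal(nrow(ctx), nrow(loci))
  idx <- match(ctx$precursor_id, loci$precursor_id)
  expect_equal(ctx$context, loci$context[idx])
  expect_equal(ctx$scaffold, loci$scaffold[idx])
  expect_equal(ctx$start, loci$genome_pos[idx])
  expect_equal(ctx$strand, loci$strand[idx])
  expect_setequal(unique(ctx$context),
                  c("intergenic", "intron", "exon_antisense"))
})

test_that("k-mer spectrum recovers a known genome size", {
  set.seed(52)
  genome <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
  read_len <- 100L
  n_reads <- round(50 * 10000 / read_len)  # 50x coverage
  starts <- sample(10000 - read_len + 1L, n_reads, replace = TRUE)
  reads <- substring(genome, starts, starts + read_len - 1L)
  est <- kmer_genome_size(reads, k = 17L)
  expect_lt(abs(est - 10000) / 10000, 0.05)
  # a collapsed duplication: two identical copies still estimate ~10 kb
  genome2 <- paste0(genome, genome)
  starts2 <- sample(20000 - read_len + 1L, 2 * n_reads, replace = TRUE)
  reads2 <- substring(genome2, starts2, starts2 + read_len - 1L)
  est2 <- kmer_genome_size(reads2, k = 17L)
  expect_lt(abs(est2 - 10000) / 10000, 0.06)
})

test_that("k-mer estimator rejects bad input", {
  expect_error(kmer_genome_size(character(0)), "empty read set")
  expect_error(kmer_genome_size("ACGTACGTACGTACGTACGT", k = 16L), "odd")
  expect_error(kmer_genome_size(c("ACGT"), k = 17L), "shorter than k")
})
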