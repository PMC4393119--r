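#' Reads per kilobase per million mapped reads
#'
#' `rpkm = count * 1e9 / (lib_total * gene_len_bp)`.
#'
#' @param count read count(s).
#' @param gene_len_bp gene length(s) in bp (> 0).
#' @param lib_total total mapped reads in the library (> 0).
#' @return numeric RPKM value(s).
#' @examples
#' rpkm(10, 1000, 1e6)  # 10
#' @export
rpkm <- function(count, gene_len_bp, lib_total) {
  if (any(gene_len_bp <= 0)) stop("gene_len_bp must be > 0")
  if (any(lib_total <= 0)) stop("lib_total must be > 0")
  count * 1e9 / (lib_total * gene_len_bp)
}

#' Two-sided test for equal read proportions between two libraries
#'
#' Under the null, a gene's reads split between the two libraries as a
#' binomial with p = lib_total_MY / (lib_total_MY + lib_total_FB)
#' (the DEGseq model class: binomial sampling of the per-gene log-ratio).
#' For genes with fewer than 30 total reads the exact binomial two-sided
#' p-value is used (summing outcome probabilities not exceeding the
#' observed one); otherwise the normal approximation.
#'
#' @param count_MY,count_FB per-gene counts (vectors).
#' @param total_MY,total_FB library totals.
#' @param exact_below total-count threshold under which the exact test is
#'   used.
#' @return numeric vector of two-sided p-values (1 for zero-count genes).
#' @export
deg_test <- function(count_MY, count_FB, total_MY, total_FB,
                     exact_below = 30L) {
  if (total_MY <= 0 || total_FB <= 0) stop("library totals must be > 0")
  n <- count_MY + count_FB
  p0 <- total_MY / (total_MY + total_FB)
  pv <- rep(1, length(n))
  exact <- n > 0 & n < exact_below
  if (any(exact)) {
    pv[exact] <- mapply(function(x, nn) {
      probs <- dbinom(0:nn, nn, p0)
      sum(probs[probs <= dbinom(x, nn, p0) * (1 + 1e-7)])
    }, count_MY[exact], n[exact])
  }
  appr <- n >= exact_below
  if (any(appr)) {
    z <- (count_MY[appr] - n[appr] * p0) / sqrt(n[appr] * p0 * (1 - p0))
    pv[appr] <- 2 * pnorm(-abs(z))
  }
  pmin(pv, 1)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up FDR adjustment with monotonicity enforcement;
#' order-preserving (the i-th output corresponds to the i-th input).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted values (FDR) in input order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  ord <- order(p, decreasing = TRUE)
  ro <- order(ord)
  adj <- pmin(1, cummin(m / (m:1) * p[ord]))[ro]
  adj
}

#' Build the expression table and classify differential expression
#'
#' Computes RPKM per library, the FB/MY fold change, the binomial p-value,
#' BH-adjusted FDR, and a five-way class: `up_MY` / `up_FB` (FDR below
#' `cfg$fdr_threshold` and fold change at or beyond `cfg$fc_down` /
#' `cfg$fc_up`), `MY_specific` / `FB_specific` (zero reads in the other
#' library, own count at least `cfg$min_specific`; exempted from the
#' ratio), else `not_DE`.
#'
#' @param counts data.frame with columns `unigene_id`, `length_bp`,
#'   `count_MY`, `count_FB`.
#' @param cfg a [milr_config()].
#' @param total_MY,total_FB library totals; default column sums.
#' @return the input with added columns `rpkm_MY`, `rpkm_FB`,
#'   `fold_change`, `p_value`, `fdr`, `deg_class`.
#' @export
classify_deg <- function(counts, cfg = milr_config(),
                         total_MY = sum(counts$count_MY),
                         total_FB = sum(counts$count_FB)) {
  stopifnot(all(c("unigene_id", "length_bp", "count_MY", "count_FB")
                %in% names(counts)))
  x <- counts
  x$rpkm_MY <- rpkm(x$count_MY, x$length_bp, total_MY)
  x$rpkm_FB <- rpkm(x$count_FB, x$length_bp, total_FB)
  x$fold_change <- ifelse(x$rpkm_MY > 0, x$rpkm_FB / x$rpkm_MY, NA_real_)
  x$p_value <- deg_test(x$count_MY, x$count_FB, total_MY, total_FB)
  x$fdr <- bh_adjust(x$p_value)

  cls <- rep("not_DE", nrow(x))
  cls[x$count_FB == 0L & x$count_MY >= cfg$min_specific] <- "MY_specific"
  cls[x$count_MY == 0L & x$count_FB >= cfg$min_specific] <- "FB_specific"
  free <- cls == "not_DE"
  sig <- free & !is.na(x$fold_change) & x$fdr < cfg$fdr_threshold
  cls[sig & x$fold_change >= cfg$fc_up] <- "up_FB"
  cls[sig & x$fold_change <= cfg$fc_down] <- "up_MY"
  x$deg_class <- cls
  stage_log("classify_deg", nrow(x), sum(cls != "not_DE"))
  x
}
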