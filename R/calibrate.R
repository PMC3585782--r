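#' Chance-run length for tract scanning
#'
#' Smallest integer run length `L` such that the expected genome-wide
#' number of chance runs of `L` consecutive homozygous calls,
#' `n_subjects * n_snps * p_hom^L`, falls below `alpha`. Under SNP
#' independence, a minimum tract length of `L` SNPs then has less than
#' `alpha` likelihood of arising by chance anywhere in the study.
#'
#' @param p_hom Genome-wide homozygosity rate in \[0, 1).
#' @param n_subjects,n_snps Study dimensions (positive).
#' @param alpha Tolerated chance likelihood (default 0.05).
#' @return Positive integer `L`.
#' @examples
#' chance_run_length(0.665, 1618, 514355)  # 58
#' @export
chance_run_length <- function(p_hom, n_subjects, n_snps, alpha = 0.05) {
  stopifnot(p_hom >= 0, p_hom < 1, n_subjects > 0, n_snps > 0, alpha > 0)
  if (p_hom == 0) return(1L)
  base <- log(n_subjects) + log(n_snps)
  lik <- function(L) base + L * log(p_hom)
  if (lik(1) < log(alpha)) return(1L)
  L <- ceiling((log(alpha) - base) / log(p_hom))
  # guard against floating-point edge: enforce lik(L) < alpha <= lik(L-1)
  while (lik(L) >= log(alpha)) L <- L + 1
  while (L > 1 && lik(L - 1) < log(alpha)) L <- L - 1
  as.integer(L)
}

#' LD-adjusted run length
#'
#' Deflates an independence-based run length by the fraction of separable
#' LD tag groups among all SNPs: `round(L / tag_fraction)` (half-up), so
#' the adjusted run keeps approximately the same effective degrees of
#' freedom as `L` independent SNPs.
#'
#' @param L Run length in SNPs.
#' @param tag_fraction Separable tag groups / total SNPs, in (0, 1].
#' @return Positive integer.
#' @examples
#' ld_adjusted_length(58, 0.63)  # 92
#' @export
ld_adjusted_length <- function(L, tag_fraction) {
  stopifnot(L >= 1, tag_fraction > 0, tag_fraction <= 1)
  as.integer(floor(L / tag_fraction + 0.5))
}

#' Empirical tract-length quantiles
#'
#' Linear-interpolation quantiles of the SNP lengths of a tract list;
#' used to pick an empirical scanning length range after a permissive
#' rescan (e.g. minimum length just above the local-LD haplotype-block
#' scale).
#'
#' @param tohs Tract tibble with an `n_snps` column (or a numeric vector
#'   of lengths).
#' @param probs Quantile probabilities.
#' @return Named numeric vector of quantiles.
#' @export
toh_length_quantiles <- function(tohs, probs = c(0.95, 0.999)) {
  lens <- if (is.data.frame(tohs)) tohs$n_snps else tohs
  if (!length(lens)) stop("no tracts supplied: quantiles undefined")
  stats::quantile(lens, probs, type = 7)
}
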