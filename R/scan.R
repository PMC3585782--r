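#' Tract-scanning parameters
#'
#' Constraints defining a qualifying tract of homozygosity (TOH). A run
#' qualifies either by SNP count (`min_snps`, the usual mode) or, when
#' `min_kb` is supplied, by physical length in kb together with a reduced
#' SNP-count floor (`min_snps_if_kb`). A bounded number of interior
#' heterozygous and missing calls is tolerated; both endpoints of a
#' reported run are always homozygous non-missing calls.
#'
#' @param min_snps Minimum number of SNPs in a run (default 100).
#' @param min_kb Optional minimum run length in kb; when set it replaces
#'   the SNP-count criterion (but `min_snps_if_kb` still applies).
#' @param min_snps_if_kb Minimum SNP count used together with `min_kb`
#'   (default 25).
#' @param max_het Maximum interior heterozygous calls per run (default 0).
#' @param max_missing Maximum interior missing calls per run (default 2).
#' @param max_gap_kb Optional maximum kb gap between adjacent SNPs inside a
#'   run (density guard; default off).
#' @return A list of class `toh_scan_params`.
#' @export
scan_params <- function(min_snps = 100L, min_kb = NULL, min_snps_if_kb = 25L,
                        max_het = 0L, max_missing = 2L, max_gap_kb = NULL) {
  stopifnot(min_snps >= 1, min_snps_if_kb >= 1, max_het >= 0, max_missing >= 0)
  if (!is.null(min_kb)) stopifnot(min_kb >= 0)
  if (!is.null(max_gap_kb)) stopifnot(max_gap_kb > 0)
  structure(list(min_snps = as.integer(min_snps), min_kb = min_kb,
                 min_snps_if_kb = as.integer(min_snps_if_kb),
                 max_het = as.integer(max_het),
                 max_missing = as.integer(max_missing),
                 max_gap_kb = max_gap_kb),
            class = "toh_scan_params")
}

# Maximal qualifying homozygous runs on one chromosome of one subject.
# codes: integer vector (2 hom, 1 het, 0 missing); pos_bp: positions.
# Returns a matrix with columns start, end (1-based local), n_het, n_missing.
# Two-pointer sweep: for each homozygous left endpoint i the furthest
# feasible window end jmax(i) is non-decreasing in i, so each run candidate
# is (i, last homozygous SNP <= jmax(i)); a candidate is maximal iff its end
# exceeds every earlier candidate's end (no earlier start reaches it).
find_hom_runs <- function(codes, pos_bp, max_het = 0L, max_missing = 0L,
                          max_gap_bp = Inf) {
  n <- length(codes)
  out <- matrix(integer(), 0L, 4L,
                dimnames = list(NULL, c("start", "end", "n_het", "n_missing")))
  if (n == 0L) return(out)
  het_c <- cumsum(codes == 1L)
  mis_c <- cumsum(codes == 0L)
  cnt <- function(cm, i, j) cm[j] - if (i > 1L) cm[i - 1L] else 0L
  gap_ok <- if (is.finite(max_gap_bp)) c(diff(pos_bp) <= max_gap_bp, FALSE)
            else rep(TRUE, n)
  last_hom <- cummax(ifelse(codes == 2L, seq_len(n), 0L))

  res <- vector("list", 0L)
  j <- 0L
  best_end <- 0L
  for (i in seq_len(n)) {
    if (codes[i] != 2L) next
    if (j < i) j <- i
    while (j < n && gap_ok[j] &&
           cnt(het_c, i, j + 1L) <= max_het &&
           cnt(mis_c, i, j + 1L) <= max_missing) {
      j <- j + 1L
    }
    r <- last_hom[j]
    if (r >= i && r > best_end) {
      res[[length(res) + 1L]] <- c(i, r, cnt(het_c, i, r), cnt(mis_c, i, r))
      best_end <- r
    }
  }
  if (length(res)) out <- rbind(out, do.call(rbind, res))
  out
}

run_qualifies <- function(n_snps, length_kb, params) {
  if (is.null(params$min_kb)) {
    n_snps >= params$min_snps
  } else {
    length_kb >= params$min_kb & n_snps >= params$min_snps_if_kb
  }
}

#' Scan all subjects for tracts of homozygosity
#'
#' Detects, for every subject and chromosome, the maximal runs of
#' consecutive homozygous genotype calls satisfying the constraints in
#' `params`. A run is maximal when it cannot be extended by one SNP in
#' either direction without violating a constraint; overlapping sub-runs
#' are never reported, and run endpoints are homozygous non-missing calls
#' (allowed heterozygous/missing calls are interior only).
#'
#' @param geno A `toh_genotypes` object from [read_ped_map()] or
#'   [simulate_toh_data()].
#' @param params A [scan_params()] object.
#' @return Tibble with one row per TOH: `toh_id`, `subject`, `chrom`,
#'   `start_idx`/`end_idx` (0-based inclusive SNP indices within the
#'   chromosome), `start_snp`/`end_snp`, `start_bp`/`end_bp`, `n_snps`,
#'   `n_het`, `n_missing`, `length_kb` (closed bp interval / 1000).
#'   Rows are ordered by subject (input order), chromosome (map order),
#'   then position.
#' @examples
#' spec <- sim_spec(n_subjects = 5, n_snps = 300, seed = 1)
#' sim <- simulate_toh_data(spec)
#' scan_toh(sim$geno, scan_params(min_snps = 50))
#' @export
scan_toh <- function(geno, params = scan_params()) {
  stopifnot(inherits(geno, "toh_genotypes"), inherits(params, "toh_scan_params"))
  codes <- genotype_codes(geno)
  map <- geno$map
  chroms <- unique(map$chrom)
  max_gap_bp <- if (is.null(params$max_gap_kb)) Inf else params$max_gap_kb * 1000
  subjects <- geno$subjects$iid

  acc <- list()
  for (ch in chroms) {
    sel <- which(map$chrom == ch)
    pos <- map$pos_bp[sel]
    ids <- map$snp_id[sel]
    for (s in seq_along(subjects)) {
      runs <- find_hom_runs(codes[s, sel], pos,
                            max_het = params$max_het,
                            max_missing = params$max_missing,
                            max_gap_bp = max_gap_bp)
      if (!nrow(runs)) next
      len_kb <- (pos[runs[, "end"]] - pos[runs[, "start"]] + 1) / 1000
      nsnp <- runs[, "end"] - runs[, "start"] + 1L
      keep <- run_qualifies(nsnp, len_kb, params)
      if (!any(keep)) next
      runs <- runs[keep, , drop = FALSE]
      st <- unname(runs[, "start"]); en <- unname(runs[, "end"])
      acc[[length(acc) + 1L]] <- tibble::tibble(
        subject = subjects[s],
        chrom = ch,
        start_idx = st - 1L,
        end_idx = en - 1L,
        start_snp = ids[st],
        end_snp = ids[en],
        start_bp = pos[st],
        end_bp = pos[en],
        n_snps = en - st + 1L,
        n_het = unname(runs[, "n_het"]),
        n_missing = unname(runs[, "n_missing"]),
        length_kb = (pos[en] - pos[st] + 1) / 1000
      )
    }
  }
  out <- if (length(acc)) dplyr::bind_rows(acc) else tibble::tibble(
    subject = character(), chrom = character(),
    start_idx = integer(), end_idx = integer(),
    start_snp = character(), end_snp = character(),
    start_bp = integer(), end_bp = integer(),
    n_snps = integer(), n_het = integer(), n_missing = integer(),
    length_kb = numeric())
  out <- dplyr::arrange(out,
                        match(.data$subject, subjects),
                        match(.data$chrom, chroms), .data$start_bp)
  dplyr::bind_cols(tibble::tibble(toh_id = seq_len(nrow(out))), out)
}

#' Genome-wide homozygosity rate
#'
#' Fraction of non-missing genotype calls that are homozygous -- the
#' marginal statistic used to calibrate the chance-run length
#' ([chance_run_length()]).
#'
#' @param geno A `toh_genotypes` object.
#' @return A number in \[0, 1\].
#' @export
homozygosity_rate <- function(geno) {
  codes <- genotype_codes(geno)
  nm <- sum(codes != 0L)
  if (nm == 0L) stop("homozygosity rate undefined: all calls are missing")
  sum(codes == 2L) / nm
}
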