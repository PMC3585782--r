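# Independent oracles and tiny fixture builders shared across the suite.

# Build a toh_genotypes object from a call-code matrix (2 hom, 1 het,
# 0 missing). Homozygous calls get allele "A" unless `alt_hom` marks
# cells that should be homozygous for "G" instead.
geno_from_codes <- function(codes, chrom = "1", pos_bp = NULL,
                            alt_hom = NULL) {
  n <- nrow(codes); p <- ncol(codes)
  if (length(chrom) == 1) chrom <- rep(chrom, p)
  if (is.null(pos_bp)) pos_bp <- as.integer(stats::ave(
    seq_len(p), factor(chrom, unique(chrom)), FUN = seq_along)) * 1000L
  a1 <- matrix("A", n, p); a2 <- matrix("A", n, p)
  a2[codes == 1L] <- "G"
  if (!is.null(alt_hom)) { a1[alt_hom] <- "G"; a2[alt_hom & codes == 2L] <- "G" }
  a1[codes == 0L] <- NA_character_; a2[codes == 0L] <- NA_character_
  subjects <- tibble::tibble(fid = sprintf("f%d", seq_len(n)),
                             iid = sprintf("s%d", seq_len(n)),
                             pat = rep("0", n), mat = rep("0", n),
                             sex = rep("1", n), phenotype = rep("0", n))
  map <- tibble::tibble(chrom = chrom, snp_id = sprintf("rs%d", seq_len(p)),
                        genetic_dist = 0, pos_bp = as.integer(pos_bp))
  map$chrom_idx <- tohkit:::chrom_local_index(map$chrom)
  tohkit:::new_toh_genotypes(a1, a2, subjects, map)
}

# Brute-force maximal-run scanner: O(n^2) feasibility over all windows
# reduced to non-extendable ones, then the length filter. Independent of
# the package's sweep implementation.
brute_scan <- function(codes, pos_bp, min_snps, max_het = 0L,
                       max_missing = 0L, max_gap_bp = Inf) {
  n <- length(codes)
  if (n == 0) return(matrix(integer(), 0, 2))
  het_c <- c(0L, cumsum(codes == 1L))
  mis_c <- c(0L, cumsum(codes == 0L))
  idx <- seq_len(n)
  het_w <- outer(idx, idx, function(i, j) het_c[j + 1L] - het_c[i])
  mis_w <- outer(idx, idx, function(i, j) mis_c[j + 1L] - mis_c[i])
  hom_i <- matrix(codes == 2L, n, n)
  hom_j <- matrix(codes == 2L, n, n, byrow = TRUE)
  feasible <- het_w <= max_het & mis_w <= max_missing & hom_i & hom_j &
    upper.tri(het_w, diag = TRUE)
  if (is.finite(max_gap_bp)) {
    gap_bad <- which(diff(pos_bp) > max_gap_bp)  # gap between g and g+1
    for (g in gap_bad) feasible[idx <= g, idx > g] <- FALSE
  }
  # a feasible window is maximal iff no feasible window extends it on
  # either side (monotone constraints make two-axis checks sufficient)
  reach_left <- apply(feasible, 2, function(col) cummax(col) > 0)
  left_ext <- rbind(FALSE, reach_left[-n, , drop = FALSE])
  reach_right <- t(apply(feasible, 1, function(row) rev(cummax(rev(row)) > 0)))
  right_ext <- cbind(reach_right[, -1, drop = FALSE], FALSE)
  maximal <- feasible & !right_ext & !left_ext
  w <- which(maximal, arr.ind = TRUE)
  w <- w[w[, 2] - w[, 1] + 1L >= min_snps, , drop = FALSE]
  w[order(w[, 1]), , drop = FALSE]
}

# Hypergeometric point probability of table (a, b, c, d) at fixed margins
log_hyper_prob <- function(a, m1, m2, k) {
  lchoose(m1, a) + lchoose(m2, k - a) - lchoose(m1 + m2, k)
}

# Two-sided Fisher p by the point-probability rule, via full enumeration
brute_fisher_p <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  lo <- max(0L, k - m2); hi <- min(k, m1)
  supp <- lo:hi
  lp <- log_hyper_prob(supp, m1, m2, k)
  p_obs <- lp[supp == a]
  sum(exp(lp[lp <= p_obs + 1e-7]))
}

# Conditional-MLE odds ratio: argmax of the noncentral hypergeometric
# likelihood, by bounded optimization on log(psi)
brute_cmle_or <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  lo <- max(0L, k - m2); hi <- min(k, m1)
  if (a == lo) return(0)
  if (a == hi) return(Inf)
  supp <- lo:hi
  lw <- lchoose(m1, supp) + lchoose(m2, k - supp)
  loglik <- function(lpsi) {
    t <- lw + supp * lpsi
    (lw[supp == a] + a * lpsi) - (max(t) + log(sum(exp(t - max(t)))))
  }
  opt <- stats::optimize(loglik, c(-15, 15), maximum = TRUE, tol = 1e-10)
  exp(opt$maximum)
}

# Normalized cut of a bipartition of similarity matrix S
ncut_value <- function(S, part) {
  other <- setdiff(seq_len(nrow(S)), part)
  cut <- sum(S[part, other])
  vol1 <- sum(S[part, ]); vol2 <- sum(S[other, ])
  cut / vol1 + cut / vol2
}

# Exhaustive minimum-normalized-cut bipartition (n <= ~15)
best_ncut <- function(S) {
  n <- nrow(S)
  best <- NULL; best_v <- Inf
  for (mask in 0:(2^(n - 1) - 2)) {  # member 1 always on side A
    part <- c(1L, which(bitwAnd(2^(0:(n - 2)), mask) > 0) + 1L)
    if (length(part) == n) next
    v <- ncut_value(S, part)
    if (v < best_v) { best_v <- v; best <- part }
  }
  list(part = best, value = best_v)
}

same_partition <- function(p1, p2, n) {
  s1 <- sort(p1[[1]]); s2 <- sort(p2[[1]])
  identical(s1, s2) || identical(s1, sort(setdiff(seq_len(n), s2)))
}

random_call_codes <- function(n, p_hom = 0.7, p_het = 0.25) {
  sample(c(2L, 1L, 0L), n, replace = TRUE,
         prob = c(p_hom, p_het, 1 - p_hom - p_het))
}
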