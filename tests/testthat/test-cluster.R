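span_tohs <- function(spans, subjects = NULL) {
  n <- nrow(spans)
  tibble::tibble(
    toh_id = seq_len(n),
    subject = subjects %||% sprintf("s%d", seq_len(n)),
    chrom = "1",
    start_idx = as.integer(spans[, 1]), end_idx = as.integer(spans[, 2]),
    start_snp = sprintf("rs%d", spans[, 1] + 1),
    end_snp = sprintf("rs%d", spans[, 2] + 1),
    start_bp = as.integer(spans[, 1] + 1) * 1000L,
    end_bp = as.integer(spans[, 2] + 1) * 1000L,
    n_snps = as.integer(spans[, 2] - spans[, 1] + 1))
}

test_that("positional similarity is min of mutual overlap fractions", {
  tohs <- span_tohs(matrix(c(0, 99,      # 100 SNPs
                             20, 219,    # 200 SNPs, overlap 80 with first
                             300, 399),  # disjoint
                           ncol = 2, byrow = TRUE))
  S <- positional_similarity(tohs)
  expect_equal(diag(S), rep(1, 3))
  expect_equal(S[1, 2], min(80 / 100, 80 / 200))  # 0.4
  expect_equal(S[1, 3], 0)
  expect_equal(S, t(S))
  # identical spans
  S2 <- positional_similarity(span_tohs(matrix(c(5, 50, 5, 50), 2, byrow = TRUE)))
  expect_equal(S2[1, 2], 1)
  # different chromosomes never overlap
  t2 <- span_tohs(matrix(c(0, 99, 0, 99), 2, byrow = TRUE))
  t2$chrom <- c("1", "2")
  expect_equal(positional_similarity(t2)[1, 2], 0)
  # geometric kernel alternative
  expect_equal(positional_similarity(tohs, kernel = "geometric")[1, 2],
               80^2 / (100 * 200))
})

test_that("allelic similarity counts matched homozygous alleles over the overlap and gates on gamma", {
  # two subjects, fully overlapping 100-SNP tracts; 10 SNPs with opposite
  # homozygous alleles in subject 2
  codes <- rbind(rep(2L, 100), rep(2L, 100))
  alt <- matrix(FALSE, 2, 100); alt[2, 1:10] <- TRUE
  g <- geno_from_codes(codes, alt_hom = alt)
  tohs <- scan_toh(g, scan_params(min_snps = 50, max_missing = 0))
  S <- allelic_similarity(tohs, g)
  expect_equal(S[1, 2], 0.9)

  # identical alleles -> 1
  g2 <- geno_from_codes(codes)
  tohs2 <- scan_toh(g2, scan_params(min_snps = 50, max_missing = 0))
  expect_equal(allelic_similarity(tohs2, g2)[1, 2], 1)

  # overlap fraction 0.4 < gamma 0.5 -> gated to 0 even if alleles match
  codes3 <- rbind(c(rep(2L, 100), rep(1L, 100)),
                  c(rep(1L, 60), rep(2L, 140)))
  g3 <- geno_from_codes(codes3)
  tohs3 <- scan_toh(g3, scan_params(min_snps = 30, max_missing = 0))
  expect_equal(nrow(tohs3), 2L)
  o <- min(tohs3$end_idx) - max(tohs3$start_idx) + 1
  frac <- min(o / tohs3$n_snps)
  expect_lt(frac, 0.5)
  expect_equal(allelic_similarity(tohs3, g3)[1, 2], 0)
  expect_gt(allelic_similarity(tohs3, g3, gamma = frac)[1, 2], 0)
})

test_that("allele-token order inside a call never changes allelic similarity", {
  set.seed(23)
  codes <- rbind(rep(2L, 80), rep(2L, 80))
  alt <- matrix(runif(160) < 0.4, 2, 80)
  g <- geno_from_codes(codes, alt_hom = alt)
  tohs <- scan_toh(g, scan_params(min_snps = 40, max_missing = 0))
  S1 <- allelic_similarity(tohs, g)
  swap <- matrix(runif(160) < 0.5, 2, 80)
  g2 <- g
  tmp <- g2$a1[swap]; g2$a1[swap] <- g2$a2[swap]; g2$a2[swap] <- tmp
  expect_equal(allelic_similarity(tohs, g2), S1)
})

test_that("spectral bisection separates disconnected blocks and minimizes the normalized cut", {
  # block-diagonal: exact connected components
  S <- matrix(0, 5, 5)
  S[1:3, 1:3] <- 1; S[4:5, 4:5] <- 1
  parts <- binary_spectral_split(S, seed = 3)
  expect_true(same_partition(parts, list(1:3, 4:5), 5))

  # well-separated 4-member instance agrees with exhaustive minimum ncut
  S4 <- rbind(c(1, .9, .1, .1), c(.9, 1, .1, .1),
              c(.1, .1, 1, .9), c(.1, .1, .9, 1))
  parts <- binary_spectral_split(S4, seed = 3)
  expect_true(same_partition(parts, list(1:2, 3:4), 4))
  expect_equal(sort(best_ncut(S4)$part), 1:2)

  # deterministic under seed, including the degenerate all-ones matrix
  S1s <- matrix(1, 4, 4)
  p1 <- binary_spectral_split(S1s, seed = 9)
  p2 <- binary_spectral_split(S1s, seed = 9)
  expect_identical(p1, p2)
  expect_true(all(lengths(p1) > 0))

  # zero-degree members split off as one side
  S0 <- diag(4); S0[1, 2] <- S0[2, 1] <- 0.8
  parts <- binary_spectral_split(S0, seed = 1)
  expect_true(same_partition(parts, list(3:4, 1:2), 4))
})

test_that("spectral split matches exhaustive minimum normalized cut on well-separated random instances", {
  set.seed(77)
  for (rep in 1:12) {
    n <- sample(6:12, 1)
    k <- sample(2:(n - 2), 1)
    S <- matrix(runif(n * n, 0, 0.15), n, n)
    S[1:k, 1:k] <- runif(k * k, 0.8, 1)
    S[(k + 1):n, (k + 1):n] <- runif((n - k)^2, 0.8, 1)
    S <- (S + t(S)) / 2; diag(S) <- 1
    parts <- binary_spectral_split(S, seed = rep)
    expect_true(same_partition(parts, list(best_ncut(S)$part, NULL), n))
  }
})

test_that("tree stop rules fire on size, similarity and depth; leaves partition the root", {
  tohs <- span_tohs(matrix(rep(c(0, 99), 4), ncol = 2, byrow = TRUE))
  S <- positional_similarity(tohs)
  tree <- build_cluster_tree(tohs, S, cluster_params(min_node_size = 5))
  expect_true(tree$root$leaf)  # 4 members < min_node_size

  tohs10 <- span_tohs(matrix(rep(c(0, 99), 10), ncol = 2, byrow = TRUE))
  S10 <- positional_similarity(tohs10)
  tree10 <- build_cluster_tree(tohs10, S10, cluster_params(threshold = 0.75))
  expect_true(tree10$root$leaf)  # all similarities 1 > 0.75

  # forced depth-0 leaf
  set.seed(3)
  spans <- cbind(0:9 * 30, 0:9 * 30 + 100)
  scattered <- span_tohs(spans)
  Ss <- positional_similarity(scattered)
  tree_d <- build_cluster_tree(scattered, Ss,
                               cluster_params(max_depth = 1, threshold = 0.99,
                                              min_node_size = 2))
  expect_lte(max(tidy(tree_d)$depth), 1L)

  tree_deep <- build_cluster_tree(scattered, Ss,
                                  cluster_params(threshold = 0.99,
                                                 min_node_size = 2))
  td <- tidy(tree_deep)
  expect_setequal(unlist(td$members), seq_len(nrow(scattered)))
  expect_equal(sum(lengths(td$members)), nrow(scattered))  # exact partition
  gl <- glance(tree_deep)
  expect_equal(gl$n_tohs, 10L)
  expect_equal(gl$n_leaves, nrow(td))
})

test_that("two planted positional groups are recovered as two reported leaves", {
  set.seed(42)
  g1 <- cbind(100 + sample(-3:3, 8, TRUE), 250 + sample(-3:3, 8, TRUE))
  g2 <- cbind(400 + sample(-3:3, 8, TRUE), 560 + sample(-3:3, 8, TRUE))
  tohs <- span_tohs(rbind(g1, g2))
  S <- positional_similarity(tohs)
  expect_lt(max(S[1:8, 9:16]), 0.3)
  tree <- build_cluster_tree(tohs, S, cluster_params(), seed = 5)
  regions <- extract_regions(tree, "gtoh")
  expect_equal(nrow(regions), 2L)
  expect_setequal(regions$member_tohs[[1]], 1:8)
  expect_setequal(regions$member_tohs[[2]], 9:16)
  expect_true(all(regions$stat >= 0.75))
  lab_planted <- rep(1:2, each = 8)
  lab_found <- integer(16)
  for (k in 1:2) lab_found[regions$member_tohs[[k]]] <- k
  expect_equal(rand_index(lab_planted, lab_found), 1)
})

test_that("region boundaries snap interpolated quantiles to member SNP positions", {
  tohs <- span_tohs(matrix(c(99, 899, 109, 909, 119, 919, 129, 929),
                           ncol = 2, byrow = TRUE))
  # member starts at bp {100, 110, 120, 130} x 1000, ends {900..930} x 1000
  expect_equal(tohs$start_bp, c(100L, 110L, 120L, 130L) * 1000L)
  S <- positional_similarity(tohs)
  tree <- build_cluster_tree(tohs, S, cluster_params(min_report_size = 2))
  # interior mode: 0.75 quantile of starts, 0.25 of ends
  reg <- extract_regions(tree, "gtoh",
                         cluster_params(boundary_quantiles = c(0.75, 0.25)))
  expect_equal(reg$start_bp, 130000L)  # q = 122500 -> next member start
  expect_equal(reg$end_bp, 910000L)    # q = 907500 -> next member end
  # literal mode: lower quartile of both
  reg_l <- extract_regions(tree, "gtoh",
                           cluster_params(boundary_mode = "literal"))
  expect_equal(reg_l$start_bp, 110000L)  # q = 107500
  expect_equal(reg_l$end_bp, 910000L)
})

test_that("report gates drop below-threshold and undersized leaves", {
  spans <- cbind(0:5 * 40, 0:5 * 40 + 90)
  tohs <- span_tohs(spans)
  S <- positional_similarity(tohs)
  params <- cluster_params(threshold = 0.95, min_node_size = 2,
                           min_report_size = 2)
  tree <- build_cluster_tree(tohs, S, params)
  regions <- extract_regions(tree, "gtoh", params)
  td <- tidy(tree)
  # every reported leaf meets both gates; singletons and loose leaves don't
  expect_true(all(regions$n_members >= 2))
  expect_true(all(regions$stat >= 0.95))
  expect_equal(nrow(regions),
               sum(td$n_members >= 2 & !is.na(td$stat) & td$stat >= 0.95))
})
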