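test_that("background homozygosity hits the Hardy-Weinberg target", {
  sim <- simulate_toh_data(sim_spec(n_subjects = 200, n_snps = 5000,
                                    hom_rate = 0.665, seed = 3))
  expect_equal(homozygosity_rate(sim$geno), 0.665, tolerance = 0.01 / 0.665)
  sim50 <- simulate_toh_data(sim_spec(n_subjects = 100, n_snps = 2000,
                                      maf = 0.5, seed = 3))
  expect_equal(homozygosity_rate(sim50$geno), 0.5, tolerance = 0.03)
})

test_that("planted tracts without jitter are recovered exactly by the scanner", {
  spec <- sim_spec(n_subjects = 20, n_snps = 1000,
                   tracts = plant_tracts(list(
                     list(start = 300, end = 449, carriers = 1:12))),
                   seed = 11)
  sim <- simulate_toh_data(spec)
  tohs <- scan_toh(sim$geno, scan_params(min_snps = 100, max_het = 0,
                                         max_missing = 0))
  hits <- tohs[tohs$start_idx <= 449 & tohs$end_idx >= 300, ]
  expect_equal(nrow(hits), 12L)
  expect_setequal(hits$subject, sim$truth$subject)
  # detected spans contain the planted span (background may extend them)
  expect_true(all(hits$start_idx <= 300 & hits$end_idx >= 449))
  expect_equal(nrow(sim$truth), 12L)
  expect_equal(unique(sim$truth$start_idx), 300L)
  expect_equal(unique(sim$truth$end_idx), 449L)
})

test_that("same seed gives byte-identical files; different seed does not", {
  spec <- sim_spec(n_subjects = 10, n_snps = 300, seed = 5,
                   tracts = plant_tracts(list(
                     list(start = 50, end = 200, carriers = 1:5,
                          jitter_sd = 2))))
  d <- withr::local_tempdir()
  write_simulation(simulate_toh_data(spec), file.path(d, "a"))
  write_simulation(simulate_toh_data(spec), file.path(d, "b"))
  for (ext in c(".ped", ".map", ".pheno.tsv", ".truth.tsv")) {
    expect_identical(readLines(file.path(d, paste0("a", ext))),
                     readLines(file.path(d, paste0("b", ext))))
  }
  spec2 <- sim_spec(n_subjects = 10, n_snps = 300, seed = 6,
                    tracts = spec$tracts)
  write_simulation(simulate_toh_data(spec2), file.path(d, "c"))
  expect_false(identical(readLines(file.path(d, "a.ped")),
                         readLines(file.path(d, "c.ped"))))
})

test_that("generated files round-trip through the ped/map parser", {
  spec <- sim_spec(n_subjects = 15, n_snps = 400, seed = 9,
                   background_missing_rate = 0.02,
                   tracts = plant_tracts(list(
                     list(start = 100, end = 250, carriers = 1:8,
                          pattern = "random", jitter_sd = 1))))
  sim <- simulate_toh_data(spec)
  d <- withr::local_tempdir()
  write_simulation(sim, file.path(d, "sim"))
  g2 <- read_ped_map(file.path(d, "sim.ped"), file.path(d, "sim.map"))
  expect_equal(g2$a1, sim$geno$a1)
  expect_equal(g2$a2, sim$geno$a2)
  expect_equal(g2$map, sim$geno$map)
  ph <- read_phenotypes(file.path(d, "sim.pheno.tsv"))
  expect_equal(as.character(ph$status), as.character(sim$phenotypes$status))
})

test_that("overlapping planted loci with shared carriers are rejected", {
  expect_error(sim_spec(n_subjects = 10, n_snps = 500,
                        tracts = plant_tracts(list(
                          list(start = 100, end = 200, carriers = 1:5),
                          list(start = 150, end = 250, carriers = 4:8)))),
               "contradictory")
  # same locus overlap but disjoint carriers is fine
  expect_s3_class(sim_spec(n_subjects = 10, n_snps = 500,
                           tracts = plant_tracts(list(
                             list(start = 100, end = 200, carriers = 1:4),
                             list(start = 150, end = 250, carriers = 5:8)))),
                  "toh_sim_spec")
})

test_that("phenotype effects shift the case rate of carriers", {
  spec <- sim_spec(n_subjects = 600, n_snps = 50,
                   tracts = plant_tracts(list(
                     list(start = 10, end = 30, carriers = 1:300))),
                   baseline_case_prob = 0.3,
                   effects = c(tract1 = log(4)), seed = 21)
  sim <- simulate_toh_data(spec)
  carriers <- sim$phenotypes$iid %in% sim$truth$subject
  rate_c <- mean(sim$phenotypes$status[carriers] == "case")
  rate_n <- mean(sim$phenotypes$status[!carriers] == "case")
  expect_gt(rate_c, rate_n + 0.2)  # log(4) effect on a 0.3 baseline
})

test_that("truth comparison scores detection and membership agreement", {
  truth <- tibble::tibble(
    cluster = rep(c("t1", "t2"), each = 3),
    subject = sprintf("s%d", 1:6), allele_group = 1L,
    start_idx = rep(c(100L, 500L), each = 3),
    end_idx = rep(c(250L, 640L), each = 3),
    nominal_start = rep(c(100L, 500L), each = 3),
    nominal_end = rep(c(250L, 640L), each = 3))
  regions <- tibble::tibble(
    region_id = c("g1", "g2"),
    start_idx = c(101L, 498L), end_idx = c(248L, 642L),
    present_subjects = list(sprintf("s%d", 1:3), sprintf("s%d", 4:6)))
  res <- truth_compare(truth, regions)
  expect_true(all(res$detected))
  expect_equal(res$rand_index, rep(1, 2))

  none <- truth_compare(truth, regions[0, ])
  expect_false(any(none$detected))
  expect_equal(none$reciprocal_overlap, c(0, 0))
})

test_that("rand index is 1 on identical partitions and penalizes disagreement", {
  expect_equal(rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  expect_equal(rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), 1 / 3)
  expect_equal(rand_index(1:4, rep(1, 4)), 0)
})

test_that("an allele-split locus separates under the allelic kernel but not the positional one", {
  spec <- sim_spec(n_subjects = 40, n_snps = 1200,
                   tracts = plant_tracts(list(
                     list(start = 400, end = 599, carriers = 1:24,
                          pattern = "allele_groups", jitter_sd = 2))),
                   seed = 33)
  sim <- simulate_toh_data(spec)
  tohs <- scan_toh(sim$geno)
  ctohs <- call_ctoh(tohs, sim$geno$map)
  expect_equal(nrow(ctohs), 1L)
  gtoh <- find_surrogate_regions(tohs, ctohs, "gtoh", seed = 2)
  atoh <- find_surrogate_regions(tohs, ctohs, "atoh", geno = sim$geno, seed = 2)
  expect_equal(nrow(gtoh), 1L)
  expect_equal(nrow(atoh), 2L)
  groups <- split(sim$truth$subject, sim$truth$allele_group)
  expect_setequal(atoh$present_subjects[[1]], groups[[1]])
  expect_setequal(atoh$present_subjects[[2]], groups[[2]])
})
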