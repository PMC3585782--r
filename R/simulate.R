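#' Describe planted homozygous tracts
#'
#' Convenience constructor for the `tracts` argument of [sim_spec()]:
#' takes a list of lists with fields `start`, `end` (0-based inclusive
#' SNP indices), `carriers` (subject indices), and optionally `pattern`
#' (`"matched"`, `"allele_groups"`, `"random"`; default `"matched"`),
#' `jitter_sd` (boundary jitter in SNPs, default 0) and `cluster` (label,
#' default `tract<k>`).
#'
#' @param tracts List of tract descriptions.
#' @return Tibble with one row per planted tract group.
#' @export
plant_tracts <- function(tracts) {
  rows <- lapply(seq_along(tracts), function(k) {
    tr <- tracts[[k]]
    tibble::tibble(
      cluster = tr$cluster %||% sprintf("tract%d", k),
      start = as.integer(tr$start), end = as.integer(tr$end),
      carriers = list(as.integer(tr$carriers)),
      pattern = tr$pattern %||% "matched",
      jitter_sd = tr$jitter_sd %||% 0
    )
  })
  dplyr::bind_rows(rows)
}

#' Simulation specification
#'
#' Defines a synthetic diploid genotype study on one chromosome:
#' Hardy-Weinberg background genotypes at a given per-SNP minor-allele
#' frequency (or a MAF solved to hit a target homozygosity rate),
#' planted homozygous tracts shared across chosen carriers with
#' controllable boundary jitter and allele matching, heterozygote and
#' missing-call noise, and a logistic phenotype model with optional
#' per-tract presence effects.
#'
#' @param n_subjects,n_snps Study dimensions.
#' @param chrom Chromosome label (single chromosome; default `"1"`).
#' @param hom_rate Target background homozygosity rate; the fixed MAF
#'   `m` solving `1 - 2 m (1 - m) = hom_rate` is used (default 0.665,
#'   giving MAF 0.2128). Ignored when `maf` is supplied.
#' @param maf Fixed per-SNP MAF, or a length-2 range for per-SNP uniform
#'   draws.
#' @param tracts Tibble from [plant_tracts()], or `NULL` for none.
#' @param tract_het_rate,tract_missing_rate Per-call noise rates inside
#'   planted tracts (default 0).
#' @param background_missing_rate Missing-call rate outside tracts
#'   (default 0).
#' @param baseline_case_prob Case probability for subjects carrying no
#'   effect tract (default 0.5).
#' @param effects Named numeric vector of per-cluster presence log-odds
#'   added to the baseline logit (default none).
#' @param bp_spacing Fixed bp distance between adjacent SNPs
#'   (default 1000).
#' @param seed Integer seed; the whole simulation is reproducible from it.
#' @return A list of class `toh_sim_spec`.
#' @export
sim_spec <- function(n_subjects = 200L, n_snps = 5000L, chrom = "1",
                     hom_rate = 0.665, maf = NULL, tracts = NULL,
                     tract_het_rate = 0, tract_missing_rate = 0,
                     background_missing_rate = 0,
                     baseline_case_prob = 0.5, effects = NULL,
                     bp_spacing = 1000L, seed = 1L) {
  stopifnot(n_subjects >= 1, n_snps >= 1,
            tract_het_rate >= 0, tract_het_rate <= 1,
            tract_missing_rate >= 0, tract_missing_rate <= 1,
            baseline_case_prob > 0, baseline_case_prob < 1)
  if (is.null(maf)) {
    stopifnot(hom_rate >= 0.5, hom_rate < 1)
    maf <- (1 - sqrt(2 * hom_rate - 1)) / 2
  }
  if (!is.null(tracts)) {
    stopifnot(all(tracts$start >= 0), all(tracts$end < n_snps),
              all(tracts$start <= tracts$end), all(tracts$jitter_sd >= 0))
    check_tract_conflicts(tracts)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_snps = as.integer(n_snps), chrom = chrom, maf = maf,
                 tracts = tracts, tract_het_rate = tract_het_rate,
                 tract_missing_rate = tract_missing_rate,
                 background_missing_rate = background_missing_rate,
                 baseline_case_prob = baseline_case_prob,
                 effects = effects, bp_spacing = as.integer(bp_spacing),
                 seed = as.integer(seed)),
            class = "toh_sim_spec")
}

# overlapping planted loci sharing carriers would overwrite each other's
# alleles contradictorily
check_tract_conflicts <- function(tracts) {
  n <- nrow(tracts)
  if (n < 2) return(invisible(tracts))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      overlap <- tracts$start[i] <= tracts$end[j] &&
                 tracts$end[i] >= tracts$start[j]
      shared <- length(intersect(tracts$carriers[[i]], tracts$carriers[[j]])) > 0
      if (overlap && shared) {
        stop("planted tracts ", tracts$cluster[i], " and ", tracts$cluster[j],
             " overlap with shared carriers: contradictory alleles")
      }
    }
  }
  invisible(tracts)
}

draw_tract_haplotype <- function(ref, alt, m) {
  ifelse(stats::runif(length(ref)) < 1 - m, ref, alt)
}

#' Simulate a genotype study with planted homozygous tracts
#'
#' Draws background genotypes per SNP under Hardy-Weinberg proportions,
#' overwrites planted spans of each carrier with homozygous calls (allele
#' chosen per the tract's match pattern; boundaries independently
#' jittered per carrier by a rounded centered Gaussian), injects
#' heterozygote/missing noise, and assigns case-control status from a
#' logistic model with optional per-tract presence effects. Fully
#' reproducible from the spec's seed.
#'
#' @param spec A [sim_spec()] object.
#' @return A list of class `toh_simulation`:
#'   * `geno`: a `toh_genotypes` object;
#'   * `phenotypes`: tibble `fid`, `iid`, `status`, `age`, `sex`,
#'     `smoking`;
#'   * `truth`: tibble with one row per (tract, carrier): `cluster`,
#'     `subject`, `allele_group`, realized `start_idx`/`end_idx` and the
#'     nominal locus bounds.
#' @export
simulate_toh_data <- function(spec) {
  stopifnot(inherits(spec, "toh_sim_spec"))
  withr::with_seed(spec$seed, simulate_toh_data_impl(spec))
}

simulate_toh_data_impl <- function(spec) {
  n <- spec$n_subjects
  p <- spec$n_snps
  m <- if (length(spec$maf) == 2) stats::runif(p, spec$maf[1], spec$maf[2])
       else rep(spec$maf, p)

  pairs <- rbind(c("A", "G"), c("A", "C"), c("A", "T"),
                 c("C", "G"), c("C", "T"), c("G", "T"))
  pk <- sample.int(6, p, replace = TRUE)
  ref <- pairs[pk, 1]  # major allele
  alt <- pairs[pk, 2]

  # genotype class per call: 1 ref-hom, 2 het, 3 alt-hom (HW proportions)
  u <- matrix(stats::runif(n * p), n, p)
  p_rr <- matrix((1 - m)^2, n, p, byrow = TRUE)
  p_het <- matrix(2 * m * (1 - m), n, p, byrow = TRUE)
  cls <- 1L + (u >= p_rr) + (u >= p_rr + p_het)

  ref_m <- matrix(ref, n, p, byrow = TRUE)
  alt_m <- matrix(alt, n, p, byrow = TRUE)
  a1 <- ifelse(cls == 3L, alt_m, ref_m)
  a2 <- ifelse(cls == 1L, ref_m, alt_m)

  if (spec$background_missing_rate > 0) {
    drop <- matrix(stats::runif(n * p) < spec$background_missing_rate, n, p)
    a1[drop] <- NA_character_
    a2[drop] <- NA_character_
  }

  subjects_id <- sprintf("s%04d", seq_len(n))
  truth <- list()
  carrier_of <- list()  # cluster -> subject ids

  if (!is.null(spec$tracts)) {
    for (k in seq_len(nrow(spec$tracts))) {
      tr <- spec$tracts[k, ]
      carriers <- tr$carriers[[1]]
      span <- tr$start:tr$end
      hap1 <- draw_tract_haplotype(ref[span + 1L], alt[span + 1L], mean(m))
      hap2 <- ifelse(hap1 == ref[span + 1L], alt[span + 1L], ref[span + 1L])
      n_car <- length(carriers)
      group <- rep(1L, n_car)
      if (tr$pattern == "allele_groups") {
        group[seq_len(n_car) > n_car / 2] <- 2L
      }
      for (ci in seq_len(n_car)) {
        s_j <- tr$start + round(stats::rnorm(1, 0, tr$jitter_sd))
        e_j <- tr$end + round(stats::rnorm(1, 0, tr$jitter_sd))
        s_j <- max(0L, min(s_j, spec$n_snps - 1L))
        e_j <- max(s_j, min(e_j, spec$n_snps - 1L))
        idx <- (s_j:e_j) + 1L
        hap <- switch(tr$pattern,
          matched = hap1,
          allele_groups = if (group[ci] == 1L) hap1 else hap2,
          random = draw_tract_haplotype(ref[span + 1L], alt[span + 1L], mean(m)),
          stop("unknown tract pattern: ", tr$pattern))
        # align the haplotype to the jittered span; SNPs outside the
        # nominal locus copy the reference allele
        hv <- ref[idx]
        inside <- idx - 1L >= tr$start & idx - 1L <= tr$end
        hv[inside] <- hap[(idx[inside] - 1L) - tr$start + 1L]
        sr <- carriers[ci]
        a1[sr, idx] <- hv
        a2[sr, idx] <- hv
        if (spec$tract_het_rate > 0) {
          flip <- idx[stats::runif(length(idx)) < spec$tract_het_rate]
          a2[sr, flip] <- ifelse(a1[sr, flip] == ref[flip], alt[flip], ref[flip])
        }
        if (spec$tract_missing_rate > 0) {
          drop <- idx[stats::runif(length(idx)) < spec$tract_missing_rate]
          a1[sr, drop] <- NA_character_
          a2[sr, drop] <- NA_character_
        }
        truth[[length(truth) + 1L]] <- tibble::tibble(
          cluster = tr$cluster, subject = subjects_id[sr],
          allele_group = group[ci],
          start_idx = s_j, end_idx = e_j,
          nominal_start = tr$start, nominal_end = tr$end)
      }
      carrier_of[[tr$cluster]] <- subjects_id[carriers]
    }
  }

  truth <- if (length(truth)) dplyr::bind_rows(truth) else tibble::tibble(
    cluster = character(), subject = character(), allele_group = integer(),
    start_idx = integer(), end_idx = integer(),
    nominal_start = integer(), nominal_end = integer())

  # phenotype model
  age <- round(stats::rnorm(n, 60, 8))
  sex <- sample(c("male", "female"), n, replace = TRUE)
  smoking <- sample(c("never", "former", "current"), n, replace = TRUE)
  logit <- rep(stats::qlogis(spec$baseline_case_prob), n)
  if (!is.null(spec$effects)) {
    for (cl in names(spec$effects)) {
      carriers <- carrier_of[[cl]]
      if (is.null(carriers)) stop("effect for unknown cluster: ", cl)
      logit <- logit + spec$effects[[cl]] * (subjects_id %in% carriers)
    }
  }
  status <- ifelse(stats::runif(n) < stats::plogis(logit), "case", "control")

  map <- tibble::tibble(
    chrom = rep(spec$chrom, p),
    snp_id = sprintf("rs%06d", seq_len(p)),
    genetic_dist = rep(0, p),
    pos_bp = as.integer(seq_len(p)) * spec$bp_spacing
  )
  map$chrom_idx <- chrom_local_index(map$chrom)
  subjects <- tibble::tibble(
    fid = subjects_id, iid = subjects_id, pat = "0", mat = "0",
    sex = ifelse(sex == "male", "1", "2"),
    phenotype = ifelse(status == "case", "2", "1"))
  geno <- new_toh_genotypes(a1, a2, subjects, map)

  phenotypes <- tibble::tibble(
    fid = subjects_id, iid = subjects_id,
    status = factor(status, levels = c("control", "case")),
    age = age, sex = sex, smoking = smoking)

  structure(list(geno = geno, phenotypes = phenotypes, truth = truth,
                 spec = spec), class = "toh_simulation")
}

#' Write a simulation to ped/map/phenotype/truth files
#'
#' @param sim A `toh_simulation` from [simulate_toh_data()].
#' @param prefix Output path prefix; writes `<prefix>.ped`,
#'   `<prefix>.map`, `<prefix>.pheno.tsv` and `<prefix>.truth.tsv`.
#' @return Invisibly, the vector of paths written.
#' @export
write_simulation <- function(sim, prefix) {
  stopifnot(inherits(sim, "toh_simulation"))
  paths <- paste0(prefix, c(".ped", ".map", ".pheno.tsv", ".truth.tsv"))
  write_ped_map(sim$geno, paths[1], paths[2])
  ph <- sim$phenotypes
  ph$status <- ifelse(ph$status == "case", 2L, 1L)
  utils::write.table(ph, paths[3], quote = FALSE, sep = "\t", row.names = FALSE)
  utils::write.table(sim$truth, paths[4], quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(paths)
}

#' Rand index between two labelings
#'
#' Fraction of item pairs on which two partitions agree (both together or
#' both apart); 1 for identical partitions.
#'
#' @param x,y Equal-length label vectors.
#' @return Number in \[0, 1\].
#' @export
rand_index <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 2) return(1)
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  row_s <- sum(choose(rowSums(tab), 2))
  col_s <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  (total + 2 * a - row_s - col_s) / total
}

#' Compare detected regions against planted ground truth
#'
#' For every planted cluster, finds the detected region with the best
#' reciprocal overlap of its span with the planted (nominal) locus and
#' calls the cluster detected when that overlap reaches
#' `min_reciprocal_overlap`. Membership agreement is measured by the
#' Rand index between the planted carrier labeling and the detected
#' region's presence labeling over all carriers of any planted cluster.
#'
#' @param truth Truth tibble from [simulate_toh_data()].
#' @param regions Detected region tibble (`start_idx`, `end_idx`,
#'   `present_subjects`).
#' @param min_reciprocal_overlap Detection threshold (default 0.8).
#' @return Tibble with one row per planted cluster: `cluster`,
#'   `detected`, `reciprocal_overlap`, `matched_region`, `rand_index`.
#' @export
truth_compare <- function(truth, regions, min_reciprocal_overlap = 0.8) {
  loci <- dplyr::distinct(truth, .data$cluster, .data$nominal_start,
                          .data$nominal_end)
  per_cluster <- lapply(seq_len(nrow(loci)), function(k) {
    ps <- loci$nominal_start[k]; pe <- loci$nominal_end[k]
    plen <- pe - ps + 1L
    if (nrow(regions)) {
      ov <- pmax(0L, pmin(regions$end_idx, pe) - pmax(regions$start_idx, ps) + 1L)
      rlen <- regions$end_idx - regions$start_idx + 1L
      rec <- pmin(ov / plen, ov / rlen)
      best <- which.max(rec)
      tibble::tibble(cluster = loci$cluster[k],
                     detected = rec[best] >= min_reciprocal_overlap,
                     reciprocal_overlap = rec[best],
                     matched_region = if (rec[best] > 0)
                       regions$region_id[best] else NA_character_)
    } else {
      tibble::tibble(cluster = loci$cluster[k], detected = FALSE,
                     reciprocal_overlap = 0, matched_region = NA_character_)
    }
  })
  out <- dplyr::bind_rows(per_cluster)
  # membership agreement over all planted carriers
  carriers <- unique(truth$subject)
  if (length(carriers) >= 2) {
    planted_lab <- truth$cluster[match(carriers, truth$subject)]
    detected_lab <- rep("none", length(carriers))
    for (k in seq_len(nrow(out))) {
      if (is.na(out$matched_region[k])) next
      r <- which(regions$region_id == out$matched_region[k])
      present <- regions$present_subjects[[r]]
      detected_lab[carriers %in% present] <- out$matched_region[k]
    }
    out$rand_index <- rand_index(planted_lab, detected_lab)
  } else {
    out$rand_index <- NA_real_
  }
  out
}
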