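#' Read PLINK-style ped/map genotype files
#'
#' Parses a whitespace-delimited PLINK text pedigree file (six leading
#' columns -- family id, individual id, paternal id, maternal id, sex,
#' phenotype -- followed by two allele tokens per SNP) together with its
#' companion map file (chromosome, SNP id, genetic distance, bp position).
#' The allele code `"0"` marks a missing allele; a genotype call is missing
#' when either of its two alleles is missing. Allele order within a call is
#' not meaningful (`"A G"` and `"G A"` are the same unordered call), and both
#' ACGT and 1/2/3/4 allele dialects are accepted.
#'
#' @param ped_path Path to the `.ped` file.
#' @param map_path Path to the `.map` file.
#' @return A `toh_genotypes` object: a list with components
#'   * `a1`, `a2`: character matrices (subjects x SNPs) of allele tokens,
#'     `NA` where missing;
#'   * `subjects`: tibble with columns `fid`, `iid`, `pat`, `mat`, `sex`,
#'     `phenotype`;
#'   * `map`: tibble with columns `chrom`, `snp_id`, `genetic_dist`,
#'     `pos_bp`, `chrom_idx` (0-based SNP index within its chromosome).
#' @details Map positions must be strictly increasing within each chromosome
#'   and SNP ids unique; every ped row must carry exactly
#'   `6 + 2 * nrow(map)` tokens, otherwise a format error naming the
#'   offending line is raised.
#' @seealso [write_ped_map()], [scan_toh()]
#' @export
read_ped_map <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("ped file not found: ", ped_path)
  if (!file.exists(map_path)) stop("map file not found: ", map_path)

  map <- utils::read.table(map_path, header = FALSE, colClasses = "character",
                           col.names = c("chrom", "snp_id", "genetic_dist", "pos_bp"))
  map <- tibble::tibble(
    chrom = map$chrom,
    snp_id = map$snp_id,
    genetic_dist = as.numeric(map$genetic_dist),
    pos_bp = as.integer(map$pos_bp)
  )
  validate_snp_map(map)
  map$chrom_idx <- chrom_local_index(map$chrom)

  n_snps <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  tokens <- strsplit(trimws(lines), "[ \t]+")
  want <- 6L + 2L * n_snps
  bad <- which(lengths(tokens) != want)
  if (length(bad)) {
    stop(sprintf(
      "ped format error: line %d has %d fields, expected %d (6 + 2 x %d map SNPs)",
      bad[1], lengths(tokens)[bad[1]], want, n_snps
    ))
  }

  n_sub <- length(tokens)
  tok <- matrix(unlist(tokens), nrow = n_sub, byrow = TRUE)
  subjects <- tibble::tibble(
    fid = tok[, 1], iid = tok[, 2], pat = tok[, 3], mat = tok[, 4],
    sex = tok[, 5], phenotype = tok[, 6]
  )
  al <- tok[, -(1:6), drop = FALSE]
  non_allele <- nchar(al) != 1L | grepl("[[:space:]]", al)
  if (any(non_allele)) {
    idx <- which(non_allele)[1]
    stop(sprintf("ped parse error: token '%s' is not a single-character allele",
                 al[idx]))
  }
  a1 <- al[, seq(1L, 2L * n_snps, by = 2L), drop = FALSE]
  a2 <- al[, seq(2L, 2L * n_snps, by = 2L), drop = FALSE]
  miss <- a1 == "0" | a2 == "0"
  a1[miss] <- NA_character_
  a2[miss] <- NA_character_

  new_toh_genotypes(a1, a2, subjects, map)
}

new_toh_genotypes <- function(a1, a2, subjects, map) {
  dimnames(a1) <- dimnames(a2) <- list(subjects$iid, map$snp_id)
  structure(list(a1 = a1, a2 = a2, subjects = subjects, map = map),
            class = "toh_genotypes")
}

validate_snp_map <- function(map) {
  if (anyDuplicated(map$snp_id)) {
    stop("map error: duplicated SNP ids (first: ",
         map$snp_id[anyDuplicated(map$snp_id)], ")")
  }
  bad <- unlist(lapply(split(map$pos_bp, factor(map$chrom, unique(map$chrom))),
                       function(p) any(diff(p) <= 0)))
  if (any(bad)) {
    stop("map error: positions not strictly increasing on chromosome ",
         names(bad)[bad][1])
  }
  if (length(rle(map$chrom)$values) != length(unique(map$chrom))) {
    stop("map error: chromosome records must be contiguous")
  }
  if (any(map$pos_bp <= 0)) stop("map error: non-positive bp position")
  invisible(map)
}

# 0-based index of each SNP within its chromosome (map file order)
chrom_local_index <- function(chrom) {
  as.integer(stats::ave(seq_along(chrom), factor(chrom, unique(chrom)),
                        FUN = seq_along)) - 1L
}

#' @export
print.toh_genotypes <- function(x, ...) {
  cat(sprintf("<toh_genotypes> %d subjects x %d SNPs on %d chromosome(s)\n",
              nrow(x$a1), ncol(x$a1), length(unique(x$map$chrom))))
  invisible(x)
}

#' Genotype call codes
#'
#' Collapses the two allele matrices of a [read_ped_map()] object into a
#' single integer matrix of call states: `2` homozygous, `1` heterozygous,
#' `0` missing.
#'
#' @param geno A `toh_genotypes` object.
#' @return Integer matrix, subjects x SNPs.
#' @export
genotype_codes <- function(geno) {
  stopifnot(inherits(geno, "toh_genotypes"))
  codes <- matrix(1L, nrow(geno$a1), ncol(geno$a1), dimnames = dimnames(geno$a1))
  codes[geno$a1 == geno$a2] <- 2L
  codes[is.na(geno$a1)] <- 0L
  codes
}

#' Write a toh_genotypes object back to PLINK ped/map text files
#'
#' @param geno A `toh_genotypes` object.
#' @param ped_path,map_path Output paths.
#' @return Invisibly, `geno`.
#' @export
write_ped_map <- function(geno, ped_path, map_path) {
  stopifnot(inherits(geno, "toh_genotypes"))
  map <- geno$map
  utils::write.table(
    data.frame(map$chrom, map$snp_id, map$genetic_dist, map$pos_bp),
    map_path, quote = FALSE, sep = "\t", row.names = FALSE, col.names = FALSE)
  a1 <- geno$a1; a2 <- geno$a2
  a1[is.na(a1)] <- "0"; a2[is.na(a2)] <- "0"
  n_snps <- ncol(a1)
  inter <- matrix("", nrow(a1), 2L * n_snps)
  inter[, seq(1L, 2L * n_snps, 2L)] <- a1
  inter[, seq(2L, 2L * n_snps, 2L)] <- a2
  s <- geno$subjects
  lines <- paste(s$fid, s$iid, s$pat, s$mat, s$sex, s$phenotype,
                 apply(inter, 1, paste, collapse = " "))
  writeLines(lines, ped_path)
  invisible(geno)
}

#' Read a phenotype/covariate table
#'
#' Tab- or space-delimited text with a header line
#' `fid iid status age sex smoking` (extra covariate columns allowed).
#' `status` is binary: 1 = control, 2 = case (PLINK convention) or
#' 0 = control, 1 = case.
#'
#' @param path File path.
#' @return Tibble with at least columns `fid`, `iid`, `status`
#'   (factor with levels `control`, `case`) plus covariates.
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("fid", "iid", "status") %in% names(ph))) {
    stop("phenotype file must have columns fid, iid, status")
  }
  ph <- tibble::as_tibble(ph)
  ph$iid <- as.character(ph$iid)
  ph$status <- code_status(ph$status)
  ph
}

code_status <- function(status) {
  if (is.factor(status)) status <- as.character(status)
  if (is.character(status)) {
    st <- tolower(status)
    if (!all(st %in% c("case", "control"))) {
      stop("status must be binary (0/1, 1/2 or case/control)")
    }
    return(factor(st, levels = c("control", "case")))
  }
  u <- sort(unique(status))
  if (identical(u, c(1, 2)) || identical(u, c(1L, 2L))) {
    factor(ifelse(status == 2, "case", "control"), levels = c("control", "case"))
  } else if (all(u %in% c(0, 1))) {
    factor(ifelse(status == 1, "case", "control"), levels = c("control", "case"))
  } else {
    stop("status must be binary (0/1, 1/2 or case/control)")
  }
}

#' Write per-subject TOH calls to a tab-delimited file
#'
#' One row per tract with subject, chromosome, start/end SNP id and bp,
#' SNP count and interior heterozygous/missing counts, sorted by
#' (chromosome, start_bp, subject) for reproducible output.
#'
#' @param tohs Tibble from [scan_toh()].
#' @param path Output path.
#' @return Invisibly, the sorted tibble that was written.
#' @export
write_toh_calls <- function(tohs, path) {
  cols <- c("toh_id", "subject", "chrom", "start_snp", "end_snp",
            "start_bp", "end_bp", "n_snps", "n_het", "n_missing")
  out <- dplyr::arrange(tohs[, intersect(cols, names(tohs))],
                        .data$chrom, .data$start_bp, .data$subject)
  utils::write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(out)
}

#' Write surrogate-TOH regions (with association results) to file
#'
#' Tab-delimited, one header line; mirrors the layout used for reporting
#' significant regions: region, start/end SNP, length in bp (closed
#' interval, `end_bp - start_bp + 1`), number of SNPs, cases and controls
#' present, p-value, odds ratio and confidence interval.
#'
#' @param regions Tibble of regions; association columns (`p_value`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `n_cases_present`,
#'   `n_controls_present`) are included when present.
#' @param path Output path.
#' @return Invisibly, the data frame written.
#' @export
write_regions <- function(regions, path) {
  df <- data.frame(
    region = if (nrow(regions)) regions$region_id else character(),
    chrom = regions$chrom,
    start_snp = regions$start_snp,
    end_snp = regions$end_snp,
    length_bp = regions$end_bp - regions$start_bp + 1L,
    n_snps = regions$n_snps,
    n_cases = pick_col(regions, "n_cases_present"),
    n_controls = pick_col(regions, "n_controls_present"),
    p_value = pick_col(regions, "p_value"),
    odds_ratio = pick_col(regions, "odds_ratio"),
    ci_95 = if ("ci_low" %in% names(regions)) {
      sprintf("(%.3g,%.3g)", regions$ci_low, regions$ci_high)
    } else rep(NA_character_, nrow(regions))
  )
  utils::write.table(df, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(df)
}

pick_col <- function(df, nm) {
  if (nm %in% names(df)) df[[nm]] else rep(NA, nrow(df))
}
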