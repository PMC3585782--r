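#' Run the full surrogate-TOH pipeline
#'
#' Scan tracts of homozygosity, call cTOH regions, cluster each cTOH's
#' members into gTOH (positional) and aTOH (allelic) regions, and test
#' every region's presence against case-control status. Per-stage counts
#' are logged with `message()`. With `out_dir` set, every intermediate is
#' written as a tab-delimited file.
#'
#' @param geno A `toh_genotypes` object, or the path to a `.ped` file
#'   (then `map` must be the `.map` path).
#' @param map `.map` path when `geno` is a `.ped` path; ignored otherwise.
#' @param phenotypes Phenotype tibble or path to a phenotype TSV; `NULL`
#'   skips association.
#' @param scan A [scan_params()] object.
#' @param min_tohs,min_ctoh_snps cTOH parameters (see [call_ctoh()]).
#' @param cluster A [cluster_params()] object.
#' @param covariates Covariate names for the logistic path.
#' @param alpha Significance threshold (default 0.01).
#' @param seed Integer seed for the clustering stage.
#' @param out_dir Optional output directory.
#' @return List of class `toh_pipeline`: `tohs`, `ctohs`, `gtoh`, `atoh`,
#'   and (when phenotypes are given) `assoc` (tibble over all region
#'   kinds).
#' @export
run_toh_pipeline <- function(geno, map = NULL, phenotypes = NULL,
                             scan = scan_params(), min_tohs = 10L,
                             min_ctoh_snps = 100L,
                             cluster = cluster_params(),
                             covariates = character(), alpha = 0.01,
                             seed = 1L, out_dir = NULL) {
  if (is.character(geno)) {
    if (is.null(map)) stop("map path required when geno is a ped path")
    geno <- read_ped_map(geno, map)
  }
  if (is.character(phenotypes)) phenotypes <- read_phenotypes(phenotypes)

  tohs <- scan_toh(geno, scan)
  message(sprintf("scan: %d TOHs in %d subjects", nrow(tohs),
                  nrow(geno$subjects)))
  ctohs <- call_ctoh(tohs, geno$map, min_tohs = min_tohs,
                     min_snps = min_ctoh_snps)
  message(sprintf("ctoh: %d regions (n >= %d, L >= %d)", nrow(ctohs),
                  min_tohs, min_ctoh_snps))
  gtoh <- find_surrogate_regions(tohs, ctohs, "gtoh", params = cluster,
                                 seed = seed)
  atoh <- find_surrogate_regions(tohs, ctohs, "atoh", geno = geno,
                                 params = cluster, seed = seed)
  message(sprintf("cluster: %d gTOHs, %d aTOHs", nrow(gtoh), nrow(atoh)))

  res <- list(tohs = tohs, ctohs = ctohs, gtoh = gtoh, atoh = atoh)
  if (!is.null(phenotypes)) {
    all_regions <- dplyr::bind_rows(
      dplyr::mutate(ctohs, kind = "ctoh", .after = "region_id"),
      gtoh[, setdiff(names(gtoh), c("parent", "n_members", "stat"))],
      atoh[, setdiff(names(atoh), c("parent", "n_members", "stat"))]
    )
    res$assoc <- test_regions(all_regions, phenotypes,
                              covariates = covariates, alpha = alpha)
    message(sprintf("assoc: %d regions tested, %d significant at p < %g",
                    nrow(res$assoc), sum(res$assoc$significant), alpha))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_toh_calls(tohs, file.path(out_dir, "tohs.tsv"))
    for (nm in c("ctohs", "gtoh", "atoh")) {
      reg <- res[[nm]]
      if (!is.null(res$assoc)) {
        reg <- dplyr::left_join(
          reg, res$assoc[, c("region_id", "p_value", "odds_ratio",
                             "ci_low", "ci_high", "n_cases_present",
                             "n_controls_present")], by = "region_id")
      }
      write_regions(reg, file.path(out_dir, paste0(nm, ".tsv")))
    }
    if (!is.null(res$assoc)) {
      utils::write.table(res$assoc[, setdiff(names(res$assoc), character())],
                         file.path(out_dir, "assoc.tsv"),
                         quote = FALSE, sep = "\t", row.names = FALSE)
    }
  }
  structure(res, class = "toh_pipeline")
}

#' @export
print.toh_pipeline <- function(x, ...) {
  cat(sprintf("<toh_pipeline> %d TOHs | %d cTOHs | %d gTOHs | %d aTOHs\n",
              nrow(x$tohs), nrow(x$ctohs), nrow(x$gtoh), nrow(x$atoh)))
  if (!is.null(x$assoc)) {
    cat(sprintf("  association: %d regions, %d significant\n",
                nrow(x$assoc), sum(x$assoc$significant)))
  }
  invisible(x)
}

#' Plot per-SNP TOH coverage with called regions
#'
#' Step plot of the number of tract calls covering each SNP along one
#' chromosome, with called cTOH regions shaded and the calling threshold
#' marked.
#'
#' @param counts Tibble from [toh_call_counts()].
#' @param ctohs Optional cTOH tibble from [call_ctoh()].
#' @param chrom Chromosome to plot (default: first in the map).
#' @param min_tohs Threshold line (default 10).
#' @return A ggplot object.
#' @export
plot_toh_coverage <- function(counts, ctohs = NULL, chrom = NULL,
                              min_tohs = 10L) {
  if (is.null(chrom)) chrom <- counts$chrom[1]
  df <- counts[counts$chrom == chrom, ]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$pos_bp / 1e6, .data$n_toh)) +
    ggplot2::geom_step(color = "steelblue") +
    ggplot2::geom_hline(yintercept = min_tohs, linetype = "dashed") +
    ggplot2::labs(x = sprintf("position on chromosome %s (Mb)", chrom),
                  y = "TOH calls", title = "Per-SNP TOH coverage") +
    ggplot2::theme_minimal()
  if (!is.null(ctohs) && nrow(ctohs)) {
    cc <- ctohs[ctohs$chrom == chrom, ]
    if (nrow(cc)) {
      p <- p + ggplot2::annotate("rect",
        xmin = cc$start_bp / 1e6, xmax = cc$end_bp / 1e6,
        ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "firebrick")
    }
  }
  p
}
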