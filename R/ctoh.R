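#' Per-SNP TOH call counts
#'
#' Accumulates tract calls across subjects: for every SNP in the map,
#' counts the number of TOHs whose span contains it.
#'
#' @param tohs Tibble of tract calls from [scan_toh()].
#' @param map SNP map tibble (component `map` of a `toh_genotypes`
#'   object, or any tibble with `chrom`, `snp_id`, `pos_bp`).
#' @return The map tibble with an integer `n_toh` column appended.
#' @export
toh_call_counts <- function(tohs, map) {
  if (!"chrom_idx" %in% names(map)) map$chrom_idx <- chrom_local_index(map$chrom)
  counts <- integer(nrow(map))
  if (nrow(tohs)) {
    chroms <- unique(map$chrom)
    if (!all(tohs$chrom %in% chroms)) {
      stop("TOH on chromosome absent from map: ",
           setdiff(tohs$chrom, chroms)[1])
    }
    for (ch in unique(tohs$chrom)) {
      sel <- which(map$chrom == ch)
      n <- length(sel)
      tt <- tohs[tohs$chrom == ch, ]
      if (any(tt$start_idx < 0L | tt$end_idx >= n | tt$start_idx > tt$end_idx)) {
        stop("TOH span outside map range on chromosome ", ch)
      }
      # difference-array accumulation over 0-based local spans
      d <- integer(n + 1L)
      starts <- tabulate(tt$start_idx + 1L, nbins = n)
      ends <- tabulate(tt$end_idx + 2L, nbins = n + 1L)
      d[seq_len(n)] <- starts
      d <- d - ends
      counts[sel] <- cumsum(d[seq_len(n)])
    }
  }
  dplyr::mutate(tibble::as_tibble(map), n_toh = counts)
}

#' Call common-TOH (cTOH) regions
#'
#' A cTOH is a maximal stretch of consecutive same-chromosome SNPs, each
#' covered by at least `min_tohs` tract calls, retained when it spans at
#' least `min_snps` SNPs. Subjects whose individual tracts overlap a
#' region by one or more SNPs are recorded as present.
#'
#' @param tohs Tibble from [scan_toh()].
#' @param map SNP map tibble.
#' @param min_tohs Minimum TOH calls per SNP (`n`, default 10).
#' @param min_snps Minimum consecutive qualifying SNPs (`L`, default 100).
#' @return Tibble with one row per region: `region_id`, `chrom`,
#'   `start_idx`, `end_idx`, `start_snp`, `end_snp`, `start_bp`, `end_bp`,
#'   `n_snps`, plus list-columns `member_tohs` (toh_id of every overlapping
#'   tract) and `present_subjects`.
#' @export
call_ctoh <- function(tohs, map, min_tohs = 10L, min_snps = 100L) {
  stopifnot(min_tohs >= 1, min_snps >= 1)
  cm <- toh_call_counts(tohs, map)
  acc <- list()
  for (ch in unique(cm$chrom)) {
    sub <- cm[cm$chrom == ch, ]
    ok <- sub$n_toh >= min_tohs
    if (!any(ok)) next
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_snps
    for (k in which(keep)) {
      i <- starts[k]; j <- ends[k]
      acc[[length(acc) + 1L]] <- tibble::tibble(
        chrom = ch,
        start_idx = sub$chrom_idx[i], end_idx = sub$chrom_idx[j],
        start_snp = sub$snp_id[i], end_snp = sub$snp_id[j],
        start_bp = sub$pos_bp[i], end_bp = sub$pos_bp[j],
        n_snps = j - i + 1L
      )
    }
  }
  out <- if (length(acc)) dplyr::bind_rows(acc) else tibble::tibble(
    chrom = character(), start_idx = integer(), end_idx = integer(),
    start_snp = character(), end_snp = character(),
    start_bp = integer(), end_bp = integer(), n_snps = integer())
  out <- dplyr::arrange(out, match(.data$chrom, unique(cm$chrom)), .data$start_bp)
  out <- dplyr::bind_cols(
    tibble::tibble(region_id = sprintf("ctoh_%d", seq_len(nrow(out)))), out)
  out$member_tohs <- lapply(seq_len(nrow(out)), function(k) {
    region_member_tohs(out[k, ], tohs)
  })
  out$present_subjects <- lapply(out$member_tohs, function(ids) {
    unique(tohs$subject[match(ids, tohs$toh_id)])
  })
  out
}

region_member_tohs <- function(region, tohs) {
  hit <- tohs$chrom == region$chrom &
    tohs$start_idx <= region$end_idx &
    tohs$end_idx >= region$start_idx
  tohs$toh_id[hit]
}

#' Subjects present for a region
#'
#' A subject is present for a surrogate region when at least one of its
#' tracts overlaps the region by one or more SNPs.
#'
#' @param region A one-row region tibble (with `chrom`, `start_idx`,
#'   `end_idx`).
#' @param tohs Tibble of tract calls.
#' @return Character vector of subject ids.
#' @export
ctoh_presence <- function(region, tohs) {
  unique(tohs$subject[match(region_member_tohs(region, tohs), tohs$toh_id)])
}
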