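#' Clustering parameters for the TOH cluster tree
#'
#' Controls the repeated binary spectral clustering of the tracts inside
#' one cTOH and the reporting of its leaf clusters as gTOH/aTOH regions.
#'
#' @param gamma Minimum pairwise overlap fraction for the allelic kernel
#'   gate (default 0.5): pairs overlapping by less than `gamma` of either
#'   member's length get similarity 0.
#' @param stat Summary statistic over a node's pairwise similarities used
#'   by the stop and report rules: `"lower_quartile"` (default),
#'   `"minimum"` or `"mean"`.
#' @param threshold Similarity cut-off (default 0.75): a node stops
#'   splitting when `stat > threshold` and a leaf is reported when
#'   `stat >= threshold`.
#' @param max_depth Maximum tree depth (default 100).
#' @param min_node_size Nodes smaller than this are not split (default 5).
#' @param min_report_size Minimum members for a reported region (default 2).
#' @param boundary_mode `"interior"` (default) or `"literal"`; see
#'   [extract_regions()].
#' @param boundary_quantiles Length-2 numeric `(q_start, q_end)`; overrides
#'   `boundary_mode` when supplied.
#' @param kernel Positional similarity kernel: `"min"` (default),
#'   the pairwise overlap fraction `min(o/l_i, o/l_j)`, or `"geometric"`,
#'   `o^2/(l_i l_j)`.
#' @param unit Length unit for the positional kernel: `"snps"` (default)
#'   or `"bp"`.
#' @return A list of class `toh_cluster_params`.
#' @export
cluster_params <- function(gamma = 0.5,
                           stat = c("lower_quartile", "minimum", "mean"),
                           threshold = 0.75, max_depth = 100L,
                           min_node_size = 5L, min_report_size = 2L,
                           boundary_mode = c("interior", "literal"),
                           boundary_quantiles = NULL,
                           kernel = c("min", "geometric"),
                           unit = c("snps", "bp")) {
  stat <- match.arg(stat)
  boundary_mode <- match.arg(boundary_mode)
  kernel <- match.arg(kernel)
  unit <- match.arg(unit)
  stopifnot(gamma > 0, gamma <= 1, threshold > 0, threshold <= 1,
            max_depth >= 1, min_node_size >= 1, min_report_size >= 1)
  if (is.null(boundary_quantiles)) {
    boundary_quantiles <- if (boundary_mode == "interior") c(0.75, 0.25)
                          else c(0.25, 0.25)
  }
  stopifnot(length(boundary_quantiles) == 2,
            all(boundary_quantiles >= 0), all(boundary_quantiles <= 1))
  structure(list(gamma = gamma, stat = stat, threshold = threshold,
                 max_depth = as.integer(max_depth),
                 min_node_size = as.integer(min_node_size),
                 min_report_size = as.integer(min_report_size),
                 boundary_quantiles = boundary_quantiles,
                 kernel = kernel, unit = unit),
            class = "toh_cluster_params")
}

toh_overlap_snps <- function(tohs) {
  s <- tohs$start_idx; e <- tohs$end_idx
  o <- outer(e, e, pmin) - outer(s, s, pmax) + 1L
  o[o < 0L] <- 0L
  same <- outer(tohs$chrom, tohs$chrom, "==")
  o * same
}

#' Positional similarity matrix
#'
#' Pairwise similarity between tracts based on span overlap. With the
#' default `"min"` kernel, `s_ij = min(o/l_i, o/l_j)` where `o` is the
#' overlap length and `l_i`, `l_j` the member lengths -- exactly the
#' pairwise criterion defining a positional (gTOH) group. The alternative
#' `"geometric"` kernel is `o^2/(l_i l_j)`. Tracts on different
#' chromosomes have similarity 0; the diagonal is 1.
#'
#' @param tohs Tibble of tracts (rows become matrix order).
#' @param kernel,unit See [cluster_params()].
#' @return Symmetric numeric matrix with entries in \[0, 1\].
#' @export
positional_similarity <- function(tohs, kernel = c("min", "geometric"),
                                  unit = c("snps", "bp")) {
  kernel <- match.arg(kernel)
  unit <- match.arg(unit)
  n <- nrow(tohs)
  if (unit == "snps") {
    o <- toh_overlap_snps(tohs)
    len <- as.numeric(tohs$n_snps)
  } else {
    s <- tohs$start_bp; e <- tohs$end_bp
    o <- outer(e, e, pmin) - outer(s, s, pmax) + 1
    o[o < 0] <- 0
    o <- o * outer(tohs$chrom, tohs$chrom, "==")
    len <- as.numeric(tohs$end_bp - tohs$start_bp + 1)
  }
  S <- if (kernel == "min") {
    pmin(o / matrix(len, n, n, byrow = FALSE), o / matrix(len, n, n, byrow = TRUE))
  } else {
    o^2 / (matrix(len, n, n) * matrix(len, n, n, byrow = TRUE))
  }
  diag(S) <- 1
  S
}

#' Allelic similarity matrix
#'
#' For pairs of tracts whose pairwise overlap fraction
#' `min(o/l_i, o/l_j)` is at least `gamma`, similarity is the proportion
#' of overlap SNPs at which both subjects carry the same homozygous
#' allele; pairs below the gate get similarity 0 (short overlaps are not
#' of interest for extended homozygosity). Heterozygous or missing calls
#' in the overlap never count as matches. Unordered allele pairs make the
#' result invariant to allele-token order.
#'
#' @param tohs Tibble of tracts.
#' @param geno The `toh_genotypes` object the tracts were scanned from.
#' @param gamma Overlap-fraction gate (default 0.5).
#' @return Symmetric numeric matrix with entries in \[0, 1\], diagonal 1.
#' @export
allelic_similarity <- function(tohs, geno, gamma = 0.5) {
  n <- nrow(tohs)
  frac <- positional_similarity(tohs, kernel = "min", unit = "snps")
  S <- matrix(0, n, n)
  diag(S) <- 1
  if (n < 2) return(S)
  codes <- genotype_codes(geno)
  subj_row <- match(tohs$subject, geno$subjects$iid)
  if (anyNA(subj_row)) stop("TOH subject not found in genotypes")
  # global column index of each tract's span start
  chrom_offset <- cumsum(c(0L, rle(geno$map$chrom)$lengths))
  chroms <- unique(geno$map$chrom)
  off <- chrom_offset[match(tohs$chrom, chroms)]
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (frac[i, j] < gamma || frac[i, j] == 0) next
      a <- max(tohs$start_idx[i], tohs$start_idx[j])
      b <- min(tohs$end_idx[i], tohs$end_idx[j])
      cols <- (off[i] + a + 1L):(off[i] + b + 1L)
      ri <- subj_row[i]; rj <- subj_row[j]
      hom_both <- codes[ri, cols] == 2L & codes[rj, cols] == 2L
      match_allele <- hom_both & geno$a1[ri, cols] == geno$a1[rj, cols]
      S[i, j] <- S[j, i] <- sum(match_allele, na.rm = TRUE) / length(cols)
    }
  }
  S
}

#' Similarity matrix for one cTOH's member tracts
#'
#' @param tohs Member tracts (tibble).
#' @param kind `"gtoh"` (positional) or `"atoh"` (allelic).
#' @param geno Required for `kind = "atoh"`.
#' @param params A [cluster_params()] object.
#' @return Symmetric similarity matrix.
#' @export
similarity_matrix <- function(tohs, kind = c("gtoh", "atoh"), geno = NULL,
                              params = cluster_params()) {
  kind <- match.arg(kind)
  if (kind == "gtoh") {
    positional_similarity(tohs, kernel = params$kernel, unit = params$unit)
  } else {
    if (is.null(geno)) stop("allelic similarity requires genotypes")
    allelic_similarity(tohs, geno, gamma = params$gamma)
  }
}

node_similarity_stat <- function(S, members, stat) {
  if (length(members) < 2L) return(NA_real_)
  v <- S[members, members][upper.tri(diag(length(members)))]
  switch(stat,
         minimum = min(v),
         lower_quartile = unname(stats::quantile(v, 0.25, type = 7)),
         mean = mean(v))
}

#' Binary spectral bisection (normalized, NJW-style)
#'
#' Splits the members of a similarity matrix into two non-empty parts:
#' with degree matrix `D = diag(rowSums(S))`, the symmetric normalized
#' Laplacian `L = I - D^{-1/2} S D^{-1/2}` is eigendecomposed, the
#' eigenvectors of its two smallest eigenvalues are taken as columns,
#' rows are normalized to unit Euclidean norm and clustered by k-means
#' with `k = 2` (10 restarts, best inertia). Members with zero
#' off-diagonal similarity (disconnected from everything) are separated
#' before the eigendecomposition and returned as one side of the split.
#' Output is deterministic for a given `seed`.
#'
#' @param S Symmetric similarity matrix (at least 2 members).
#' @param seed Integer RNG seed for the k-means restarts.
#' @return List of two integer vectors (member indices), each non-empty,
#'   partitioning `seq_len(nrow(S))`; the part containing member 1 first.
#' @export
binary_spectral_split <- function(S, seed = 1L) {
  n <- nrow(S)
  stopifnot(n >= 2L, ncol(S) == n)
  off_deg <- rowSums(S) - diag(S)
  zero <- which(off_deg <= 0)
  if (length(zero) > 0L && length(zero) < n) {
    parts <- list(zero, setdiff(seq_len(n), zero))
  } else if (length(zero) == n || n == 2L) {
    parts <- list(1L, 2:n)  # only one bipartition of two members
  } else {
    d <- rowSums(S)
    inv_sqrt_d <- 1 / sqrt(d)
    L <- diag(n) - (inv_sqrt_d * S) %*% diag(inv_sqrt_d, n)
    ev <- eigen((L + t(L)) / 2, symmetric = TRUE)
    U <- ev$vectors[, c(n, n - 1L), drop = FALSE]  # two smallest eigenvalues
    norms <- sqrt(rowSums(U^2))
    norms[norms == 0] <- 1
    U <- U / norms
    if (nrow(unique(round(U, 12))) < 2L) {
      parts <- list(1L, 2:n)  # degenerate embedding (e.g. all-ones S)
    } else {
      km <- withr::with_seed(as.integer(seed),
                             stats::kmeans(U, centers = 2L, nstart = 10L))
      parts <- list(which(km$cluster == km$cluster[1]),
                    which(km$cluster != km$cluster[1]))
    }
  }
  if (1L %in% parts[[2]]) parts <- parts[c(2, 1)]
  parts
}

#' Build a TOH cluster tree for one cTOH
#'
#' Repeated binary spectral clustering: all member tracts start in the
#' root node; a node becomes a leaf when the depth limit is reached, it
#' has fewer than `min_node_size` members, or the summary statistic of
#' its pairwise similarities exceeds `threshold`; otherwise it is split
#' by [binary_spectral_split()] and the two children are processed
#' recursively. Leaves partition the root member set.
#'
#' @param tohs Member tracts of one cTOH (tibble).
#' @param S Similarity matrix over `tohs` rows (see
#'   [similarity_matrix()]).
#' @param params A [cluster_params()] object.
#' @param seed Integer seed; each split uses a seed derived
#'   deterministically from it.
#' @return A `toh_cluster_tree` object (fields `root`, `tohs`, `params`).
#' @export
build_cluster_tree <- function(tohs, S, params = cluster_params(), seed = 1L) {
  stopifnot(nrow(tohs) == nrow(S))
  counter <- 0L
  recurse <- function(members, depth) {
    counter <<- counter + 1L
    st <- node_similarity_stat(S, members, params$stat)
    node <- list(members = members, depth = depth, stat = st,
                 leaf = TRUE, children = NULL)
    stop_rule <- depth >= params$max_depth ||
      length(members) < params$min_node_size ||
      (!is.na(st) && st > params$threshold)
    if (!stop_rule) {
      parts <- binary_spectral_split(S[members, members, drop = FALSE],
                                     seed = as.integer(seed) + counter)
      node$leaf <- FALSE
      node$children <- list(recurse(members[parts[[1]]], depth + 1L),
                            recurse(members[parts[[2]]], depth + 1L))
    }
    node
  }
  root <- recurse(seq_len(nrow(tohs)), 0L)
  structure(list(root = root, tohs = tohs, S = S, params = params),
            class = "toh_cluster_tree")
}

tree_leaves <- function(node) {
  if (node$leaf) return(list(node))
  c(tree_leaves(node$children[[1]]), tree_leaves(node$children[[2]]))
}

#' @export
print.toh_cluster_tree <- function(x, ...) {
  lv <- tree_leaves(x$root)
  cat(sprintf("<toh_cluster_tree> %d tracts, %d leaves, max depth %d\n",
              nrow(x$tohs), length(lv), max(vapply(lv, `[[`, 0L, "depth"))))
  invisible(x)
}

#' Tidy a TOH cluster tree
#'
#' One row per leaf with member count, depth and the node's similarity
#' summary statistic.
#'
#' @param x A `toh_cluster_tree`.
#' @param ... Unused.
#' @return Tibble with columns `leaf`, `depth`, `n_members`, `stat`,
#'   and list-column `members` (row indices into the tree's tracts).
#' @export
tidy.toh_cluster_tree <- function(x, ...) {
  lv <- tree_leaves(x$root)
  tibble::tibble(
    leaf = seq_along(lv),
    depth = vapply(lv, `[[`, 0L, "depth"),
    n_members = lengths(lapply(lv, `[[`, "members")),
    stat = vapply(lv, `[[`, 0, "stat"),
    members = lapply(lv, `[[`, "members")
  )
}

#' Summarize a TOH cluster tree
#'
#' @param x A `toh_cluster_tree`.
#' @param ... Unused.
#' @return One-row tibble: number of tracts, leaves, reported leaves and
#'   maximum depth.
#' @export
glance.toh_cluster_tree <- function(x, ...) {
  td <- tidy.toh_cluster_tree(x)
  p <- x$params
  reported <- td$n_members >= p$min_report_size &
    !is.na(td$stat) & td$stat >= p$threshold
  tibble::tibble(n_tohs = nrow(x$tohs), n_leaves = nrow(td),
                 n_reported = sum(reported), max_depth = max(td$depth))
}

# interpolated (type-7) quantile of member boundary positions, snapped to
# the smallest actual member boundary at or above it, so region ends are
# genuine member SNP positions
snap_quantile <- function(values, q) {
  qv <- unname(stats::quantile(values, q, type = 7))
  at_or_above <- values[values >= qv]
  if (length(at_or_above)) min(at_or_above) else max(values)
}

#' Extract surrogate regions from a cluster tree
#'
#' Each leaf with at least `min_report_size` members whose similarity
#' statistic reaches `threshold` is reported as a gTOH/aTOH region. Region
#' boundaries are quantiles of the member start and end positions
#' (defaults: 0.75 of starts, 0.25 of ends -- an interior span that avoids
#' extreme member boundaries; `boundary_mode = "literal"` uses the lower
#' quartile of both), snapped to actual member SNP positions.
#'
#' @param tree A `toh_cluster_tree` from [build_cluster_tree()].
#' @param kind `"gtoh"` or `"atoh"` (label recorded in the output).
#' @param params A [cluster_params()] object; defaults to the tree's own.
#' @param parent Optional parent cTOH region id.
#' @return Tibble with one row per reported region: `region_id`, `kind`,
#'   `parent`, `chrom`, `start_idx`, `end_idx`, `start_snp`, `end_snp`,
#'   `start_bp`, `end_bp`, `n_snps`, `n_members`, `stat`, and
#'   list-columns `member_tohs`, `present_subjects`.
#' @export
extract_regions <- function(tree, kind = c("gtoh", "atoh"), params = NULL,
                            parent = NA_character_) {
  kind <- match.arg(kind)
  if (is.null(params)) params <- tree$params
  tohs <- tree$tohs
  td <- tidy.toh_cluster_tree(tree)
  keep <- td$n_members >= params$min_report_size &
    !is.na(td$stat) & td$stat >= params$threshold
  rows <- lapply(which(keep), function(k) {
    m <- td$members[[k]]
    mem <- tohs[m, ]
    sb <- snap_quantile(mem$start_bp, params$boundary_quantiles[1])
    eb <- snap_quantile(mem$end_bp, params$boundary_quantiles[2])
    if (sb > eb) {  # degenerate quantile inversion: fall back to envelope
      sb <- min(mem$start_bp); eb <- max(mem$end_bp)
    }
    i_s <- which(mem$start_bp == sb)[1]
    i_e <- which(mem$end_bp == eb)[1]
    tibble::tibble(
      kind = kind, parent = parent, chrom = mem$chrom[1],
      start_idx = mem$start_idx[i_s], end_idx = mem$end_idx[i_e],
      start_snp = mem$start_snp[i_s], end_snp = mem$end_snp[i_e],
      start_bp = sb, end_bp = eb,
      n_snps = mem$end_idx[i_e] - mem$start_idx[i_s] + 1L,
      n_members = length(m), stat = td$stat[k],
      member_tohs = list(mem$toh_id), present_subjects = list(unique(mem$subject))
    )
  })
  out <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(
    kind = character(), parent = character(), chrom = character(),
    start_idx = integer(), end_idx = integer(),
    start_snp = character(), end_snp = character(),
    start_bp = integer(), end_bp = integer(), n_snps = integer(),
    n_members = integer(), stat = numeric(),
    member_tohs = list(), present_subjects = list())
  dplyr::bind_cols(
    tibble::tibble(region_id = sprintf("%s_%s_%d", kind,
                                       ifelse(is.na(parent), "na", parent),
                                       seq_len(nrow(out)))), out)
}

#' Find gTOH or aTOH regions across all cTOHs
#'
#' For every cTOH, builds the similarity matrix over its member tracts
#' (positional for gTOH, allelic for aTOH), grows the binary spectral
#' cluster tree and reports qualifying leaves as surrogate regions.
#'
#' @param tohs Tract calls from [scan_toh()].
#' @param ctohs cTOH regions from [call_ctoh()].
#' @param kind `"gtoh"` or `"atoh"`.
#' @param geno Genotypes (required for `kind = "atoh"`).
#' @param params A [cluster_params()] object.
#' @param seed Integer seed (deterministic output for a given seed).
#' @return Tibble of surrogate regions (see [extract_regions()]).
#' @examples
#' spec <- sim_spec(n_subjects = 40, n_snps = 800,
#'                  tracts = plant_tracts(list(
#'                    list(start = 200, end = 400, carriers = 1:15))),
#'                  seed = 2)
#' sim <- simulate_toh_data(spec)
#' tohs <- scan_toh(sim$geno)
#' ctohs <- call_ctoh(tohs, sim$geno$map)
#' find_surrogate_regions(tohs, ctohs, "gtoh")
#' @export
find_surrogate_regions <- function(tohs, ctohs, kind = c("gtoh", "atoh"),
                                   geno = NULL, params = cluster_params(),
                                   seed = 1L) {
  kind <- match.arg(kind)
  out <- lapply(seq_len(nrow(ctohs)), function(k) {
    mem <- tohs[tohs$toh_id %in% ctohs$member_tohs[[k]], ]
    if (!nrow(mem)) return(NULL)
    S <- similarity_matrix(mem, kind, geno = geno, params = params)
    tree <- build_cluster_tree(mem, S, params = params,
                               seed = as.integer(seed) + k)
    extract_regions(tree, kind, params, parent = ctohs$region_id[k])
  })
  out <- dplyr::bind_rows(out[!vapply(out, is.null, TRUE)])
  if (!nrow(out)) return(extract_regions(
    structure(list(root = list(members = integer(), depth = 0L, stat = NA_real_,
                               leaf = TRUE, children = NULL),
                   tohs = tohs[0, ], S = matrix(0, 0, 0), params = params),
              class = "toh_cluster_tree"), kind, params))
  out$region_id <- sprintf("%s_%d", kind, seq_len(nrow(out)))
  out
}
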