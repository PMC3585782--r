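#' Cross-tabulate region presence against case-control status
#'
#' @param present_subjects Character vector of subject ids present for a
#'   region.
#' @param phenotypes Phenotype tibble (see [read_phenotypes()]): columns
#'   `iid` and `status` (factor control/case or 0/1, 1/2 coding).
#' @return Named integer vector `c(a, b, c, d)`: cases present, cases
#'   absent, controls present, controls absent.
#' @export
build_table <- function(present_subjects, phenotypes) {
  status <- code_status(phenotypes$status)
  missing_subj <- setdiff(present_subjects, phenotypes$iid)
  if (length(missing_subj)) {
    stop("present subject absent from phenotype table: ", missing_subj[1])
  }
  present <- phenotypes$iid %in% present_subjects
  a <- sum(present & status == "case")
  c_ <- sum(present & status == "control")
  c(a = a, b = sum(status == "case") - a,
    c = c_, d = sum(status == "control") - c_)
}

#' Fisher's exact test for a 2x2 presence table
#'
#' Two-sided p-value by the point-probability rule (sum of hypergeometric
#' probabilities of all tables, at fixed margins, no more probable than
#' the observed one), the conditional maximum-likelihood estimate of the
#' odds ratio (0 or `Inf` for zero cells), and the 95% exact conditional
#' confidence interval, as computed by [stats::fisher.test()].
#'
#' @param a,b,c,d Cell counts: cases present/absent, controls
#'   present/absent. `a` may also be the full length-4 vector from
#'   [build_table()].
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `test`, `p_value`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `n_cases_present`, `n_controls_present`.
#' @examples
#' fisher_exact(7, 781, 0, 830)   # case-only region in 788 vs 830
#' @export
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL, conf_level = 0.95) {
  if (length(a) == 4 && is.null(b)) { d <- a[[4]]; c <- a[[3]]; b <- a[[2]]; a <- a[[1]] }
  ft <- stats::fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE),
                           conf.level = conf_level)
  tibble::tibble(test = "fisher_exact", p_value = ft$p.value,
                 odds_ratio = unname(ft$estimate),
                 ci_low = ft$conf.int[1], ci_high = ft$conf.int[2],
                 n_cases_present = as.integer(a),
                 n_controls_present = as.integer(c))
}

#' Covariate-adjusted logistic test of region presence
#'
#' Fits `status ~ presence + covariates` by maximum-likelihood logistic
#' regression; the p-value is the Wald test on the presence coefficient,
#' the odds ratio `exp(coef)` with a `exp(coef +/- 1.96 SE)` confidence
#' interval. Smoking-style categorical covariates enter as indicator
#' contrasts against their reference level. On separation or
#' non-convergence the test falls back to [fisher_exact()] with a
#' warning; a rank-deficient design (e.g. a covariate collinear with
#' presence) is an error.
#'
#' @param presence Logical/0-1 vector aligned to `phenotypes` rows.
#' @param phenotypes Phenotype tibble with `status`.
#' @param covariates Character vector of covariate column names in
#'   `phenotypes` (default none).
#' @return One-row tibble as in [fisher_exact()], with
#'   `test = "logistic_wald"` (or `"fisher_exact"` after fallback).
#' @export
logistic_wald <- function(presence, phenotypes, covariates = character()) {
  status <- code_status(phenotypes$status)
  stopifnot(length(presence) == length(status))
  df <- data.frame(.y = as.integer(status == "case"),
                   .presence = as.numeric(presence))
  for (cv in covariates) {
    if (!cv %in% names(phenotypes)) stop("covariate not found: ", cv)
    v <- phenotypes[[cv]]
    df[[cv]] <- if (is.character(v)) factor(v) else v
  }
  form <- stats::as.formula(paste(".y ~ .presence",
                                  if (length(covariates))
                                    paste("+", paste(covariates, collapse = " + "))
                                  else ""))
  X <- stats::model.matrix(form, df)
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient design: a covariate is collinear with presence")
  }
  fit <- suppressWarnings(stats::glm(form, data = df, family = stats::binomial()))
  co <- summary(fit)$coefficients
  beta <- co[".presence", "Estimate"]
  se <- co[".presence", "Std. Error"]
  separated <- !fit$converged || abs(beta) > 15 || se > 10
  if (separated) {
    warning("separation or non-convergence in logistic fit; ",
            "falling back to Fisher's exact test")
    tab <- c(a = sum(df$.y == 1 & presence > 0), b = sum(df$.y == 1 & presence == 0),
             c = sum(df$.y == 0 & presence > 0), d = sum(df$.y == 0 & presence == 0))
    return(fisher_exact(tab))
  }
  z <- beta / se
  tibble::tibble(test = "logistic_wald",
                 p_value = 2 * stats::pnorm(-abs(z)),
                 odds_ratio = exp(beta),
                 ci_low = exp(beta - 1.96 * se),
                 ci_high = exp(beta + 1.96 * se),
                 n_cases_present = sum(df$.y == 1 & presence > 0),
                 n_controls_present = sum(df$.y == 0 & presence > 0))
}

#' Test surrogate regions for case-control association
#'
#' For each region, presence/absence is cross-tabulated against status;
#' when every cell of the 2x2 table is at least `min_cell` (default 5)
#' the covariate-adjusted logistic Wald test is used, otherwise Fisher's
#' exact test. Results are sorted by p-value; an optional
#' Benjamini-Hochberg column can be added (off by default; raw p-values
#' against a fixed alpha are the primary read-out).
#'
#' @param regions Region tibble with `region_id` and `present_subjects`
#'   list-column ([call_ctoh()], [find_surrogate_regions()]).
#' @param phenotypes Phenotype tibble (`iid`, `status`, covariates).
#' @param covariates Character vector of covariate names for the logistic
#'   path (default none).
#' @param alpha Significance threshold recorded in the `significant`
#'   column (default 0.01).
#' @param min_cell Dispatch threshold: any observed 2x2 cell below it
#'   sends the region to Fisher's exact test (default 5).
#' @param adjust Add a Benjamini-Hochberg `p_adj` column (default FALSE).
#' @return A `toh_assoc` tibble: one row per region with `region_id`,
#'   `test`, `p_value`, `odds_ratio`, `ci_low`, `ci_high`,
#'   `n_cases_present`, `n_controls_present`, `significant`.
#' @export
test_regions <- function(regions, phenotypes, covariates = character(),
                         alpha = 0.01, min_cell = 5L, adjust = FALSE) {
  rows <- lapply(seq_len(nrow(regions)), function(k) {
    pres_ids <- regions$present_subjects[[k]]
    tab <- build_table(pres_ids, phenotypes)
    res <- if (any(tab < min_cell)) {
      fisher_exact(tab)
    } else {
      logistic_wald(phenotypes$iid %in% pres_ids, phenotypes, covariates)
    }
    dplyr::bind_cols(tibble::tibble(region_id = regions$region_id[k]), res)
  })
  out <- if (length(rows)) dplyr::bind_rows(rows) else tibble::tibble(
    region_id = character(), test = character(), p_value = numeric(),
    odds_ratio = numeric(), ci_low = numeric(), ci_high = numeric(),
    n_cases_present = integer(), n_controls_present = integer())
  out$significant <- out$p_value < alpha
  if (adjust) out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out <- dplyr::arrange(out, .data$p_value)
  class(out) <- c("toh_assoc", class(out))
  out
}

#' Plot association results
#'
#' Bar chart of -log10 p-values per region, colored by test used, with a
#' dashed line at the significance threshold.
#'
#' @param object A `toh_assoc` tibble from [test_regions()].
#' @param alpha Threshold line (default 0.01).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.toh_assoc <- function(object, alpha = 0.01, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$region_id, -.data$p_value),
    y = -log10(.data$p_value), fill = .data$test)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(-log[10]~p),
                  title = "Surrogate-TOH region association") +
    ggplot2::theme_minimal()
}
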