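#' Kruskal-Wallis test of equal group distributions
#'
#' Rank-based H statistic with mid-ranks for ties and the standard tie
#' correction; p-value from the chi-square approximation with k-1 degrees of
#' freedom (used at all sample sizes, matching common practice in the
#' field's tooling). A degenerate all-tied input returns H = 0, p = 1. An
#' exact permutation p-value (full enumeration of group assignments) is
#' available for validation at small n.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels (coerced to factor), at least two groups with
#'   at least one observation each and three observations in total.
#' @param exact If `TRUE`, also compute the exact permutation p-value
#'   (feasible only for small samples).
#' @return A tibble with `H`, `p` (and `p_exact` when requested).
#' @examples
#' kw_test(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' @export
kw_test <- function(values, groups, exact = FALSE) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (any(table(groups) < 1L)) stop("every group needs at least one value")
  if (length(values) < 3L) stop("need at least three observations in total")
  if (anyNA(values)) stop("values must not contain NA")
  if (length(unique(values)) == 1L) {
    out <- tibble::tibble(H = 0, p = 1)
    if (exact) out$p_exact <- 1
    return(out)
  }
  kt <- stats::kruskal.test(values, groups)
  out <- tibble::tibble(H = unname(kt$statistic), p = kt$p.value)
  if (exact) out$p_exact <- kw_exact_p(values, groups)
  out
}

# exact permutation p-value by full enumeration (k = 2 only)
kw_exact_p <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) != 2L) stop("exact mode implemented for two groups")
  n <- length(values)
  n1 <- sum(groups == levels(groups)[1])
  if (choose(n, n1) > 2e5) stop("exact enumeration infeasible at this n")
  h_of <- function(idx) {
    g <- rep(2L, n); g[idx] <- 1L
    kw_h_stat(values, g)
  }
  observed <- kw_h_stat(values, as.integer(groups))
  combos <- utils::combn(n, n1)
  hs <- apply(combos, 2, h_of)
  mean(hs >= observed - 1e-12)
}

# tie-corrected H from first principles (shared by the exact mode)
kw_h_stat <- function(values, g) {
  r <- rank(values)
  n <- length(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(x) sum(x)^2 / length(x))) - 3 * (n + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr <= 0) return(0)
  h / corr
}

#' Eta-squared effect size from the Kruskal-Wallis H statistic
#'
#' The H-based effect size `(H - k + 1) / (n - k)`, floored at zero: the
#' proportion of rank variance attributable to group membership, adjusted
#' for the k - 1 expected under the null.
#'
#' @param H Kruskal-Wallis H statistic.
#' @param n Total number of observations.
#' @param k Number of groups (default 2).
#' @return Effect size in `[0, 1]`.
#' @examples
#' eta_squared_from_h(8.65, 56) # 0.1417
#' @export
eta_squared_from_h <- function(H, n, k = 2) {
  if (any(n <= k)) stop("need more observations than groups")
  pmax(0, (H - k + 1) / (n - k))
}

#' Orientation-free AUROC
#'
#' Probability that a randomly drawn subject of one group exceeds one of the
#' other on the biomarker, with ties counted half (the Mann-Whitney
#' statistic scaled to `[0, 1]`). Reported orientation-free as
#' `max(A, 1 - A)`, so values are always at least 0.5 — direction is carried
#' separately by the observed behavior.
#'
#' @param cn,pd Numeric biomarker values for the control and PD groups.
#' @return AUROC in `[0.5, 1]`.
#' @export
auroc_stat <- function(cn, pd) {
  if (length(cn) == 0L || length(pd) == 0L) stop("both groups must be non-empty")
  r <- rank(c(cn, pd))
  rp <- r[(length(cn) + 1L):length(r)]
  a <- (sum(rp) - length(pd) * (length(pd) + 1) / 2) / (length(cn) * length(pd))
  max(a, 1 - a)
}

#' Benjamini-Hochberg adjustment within a family
#'
#' Step-up FDR control: adjusted p-values are monotone (cumulative minimum
#' from the largest rank) and the rejection set at level `alpha` is every
#' hypothesis whose adjusted p is at most `alpha`.
#'
#' @param p Vector of raw p-values in `[0, 1]`.
#' @param alpha Significance level (default 0.05).
#' @return A tibble with `p`, `p_adj`, `significant`.
#' @export
bh_adjust <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p_adj <- stats::p.adjust(p, method = "BH")
  tibble::tibble(p = p, p_adj = p_adj, significant = !is.na(p_adj) & p_adj <= alpha)
}

#' Observed behavior of a biomarker
#'
#' Direction in which the PD group's median moved relative to the control
#' group's: `"up"`, `"down"`, or `"tie"`.
#'
#' @inheritParams auroc_stat
#' @return One of `"up"`, `"down"`, `"tie"`.
#' @export
observed_behavior <- function(cn, pd) {
  d <- stats::median(pd) - stats::median(cn)
  if (d > 0) "up" else if (d < 0) "down" else "tie"
}

#' Spearman rank correlation with a severity score
#'
#' Mid-rank Spearman rho with its asymptotic p-value. Biomarker values are
#' standardized first (a strictly monotone transform, so rho is unchanged —
#' kept for parity with how the correlations are reported).
#'
#' @param x Biomarker values.
#' @param y Severity scores, paired with `x`.
#' @return A tibble with `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) {
    return(tibble::tibble(rho = NA_real_, p = NA_real_, n = length(x)))
  }
  xs <- if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x
  ct <- suppressWarnings(stats::cor.test(xs, y, method = "spearman", exact = FALSE))
  tibble::tibble(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Biomarker families
#'
#' The family a biomarker belongs to for FDR purposes: acoustic, linguistic,
#' or cognitive. Multiple-testing correction is applied within each family
#' separately (per dataset and task).
#'
#' @param biomarker Character vector of biomarker names.
#' @return Character vector of family names.
#' @export
biomarker_family <- function(biomarker) {
  acoustic <- c("F0STD", "F1STD", "INTSTD", "SPTIME", "SILTIME", "SILPERC",
                "SILSPRAT", "SILDUR", "SILVAR")
  linguistic <- c("WORDCNT", "WORDLEN", "SENTCNT", "SENTLEN", "NOUNCNT",
                  "VERBCNT", "ADJCNT", "ADVCNT", "NUMCNT", "AUXCNT",
                  "NPCNT", "VPCNT", "PPCNT")
  cognitive <- c("RHYSTD", "IU")
  out <- rep(NA_character_, length(biomarker))
  out[biomarker %in% acoustic] <- "acoustic"
  out[biomarker %in% linguistic] <- "linguistic"
  out[biomarker %in% cognitive] <- "cognitive"
  if (anyNA(out)) stop("unknown biomarker(s): ",
                       toString(unique(biomarker[is.na(out)])))
  out
}

#' Group-comparison tests over a biomarker table
#'
#' Runs the Kruskal-Wallis test for every dataset x task x biomarker cell
#' of a biomarker table, then applies Benjamini-Hochberg correction within
#' each biomarker family (per dataset and task), and reports the columns of
#' a cross-cohort results table: group sizes, H, raw and adjusted p,
#' significance at `alpha`, observed behavior, H-based eta-squared, and
#' orientation-free AUROC.
#'
#' @param table Long biomarker table: `subject_id`, `dataset`, `task`,
#'   `biomarker`, `value` (missing values dropped per cell).
#' @param metadata Subject metadata: `subject_id`, `group` (`"CN"`/`"PD"`).
#' @param alpha Family-wise FDR level (default 0.05).
#' @return A tibble with one row per tested cell. Cells with one group only
#'   are skipped with a warning.
#' @export
group_tests <- function(table, metadata, alpha = 0.05) {
  df <- dplyr::inner_join(
    dplyr::filter(table, !is.na(.data$value)),
    dplyr::distinct(metadata[, c("subject_id", "group")]),
    by = "subject_id"
  )
  cells <- dplyr::group_split(dplyr::group_by(df, .data$dataset, .data$task,
                                              .data$biomarker))
  rows <- purrr::map(cells, function(cell) {
    cn <- cell$value[cell$group == "CN"]
    pd <- cell$value[cell$group == "PD"]
    if (length(cn) == 0L || length(pd) == 0L) {
      warning(sprintf("skipping %s/%s/%s: only one group present",
                      cell$dataset[1], cell$task[1], cell$biomarker[1]))
      return(NULL)
    }
    kt <- kw_test(cell$value, cell$group)
    tibble::tibble(
      dataset = cell$dataset[1], task = cell$task[1],
      biomarker = cell$biomarker[1],
      n_cn = length(cn), n_pd = length(pd),
      H = kt$H, p = kt$p,
      OB = observed_behavior(cn, pd),
      eta2 = eta_squared_from_h(kt$H, length(cn) + length(pd), 2),
      auroc = auroc_stat(cn, pd)
    )
  })
  res <- dplyr::bind_rows(rows)
  if (nrow(res) == 0L) return(res)
  res$family <- biomarker_family(res$biomarker)
  res <- dplyr::mutate(
    dplyr::group_by(res, .data$dataset, .data$task, .data$family),
    p_adj = stats::p.adjust(.data$p, method = "BH")
  )
  res <- dplyr::ungroup(res)
  res$significant <- res$p_adj <= alpha
  dplyr::relocate(res, "family", .after = "biomarker")
}

#' Severity correlations over a biomarker table
#'
#' Spearman correlations between each biomarker and each available clinical
#' scale (UPDRS-III, its speech item, Hoehn & Yahr), computed on PD subjects
#' only (severity scores exist only for PD), per dataset and task, with
#' Benjamini-Hochberg correction within each biomarker family (per dataset
#' and task, pooled across scales).
#'
#' @param table Long biomarker table (see [group_tests()]).
#' @param metadata Subject metadata with `subject_id`, `group` and any of
#'   `updrs3`, `updrs3_1`, `hy`.
#' @param alpha FDR level.
#' @return A tibble: `dataset`, `task`, `biomarker`, `family`, `scale`,
#'   `n`, `rho`, `p`, `p_adj`, `significant`.
#' @export
correlate_severity <- function(table, metadata, alpha = 0.05) {
  scales <- intersect(c("updrs3", "updrs3_1", "hy"), names(metadata))
  pd_meta <- metadata[metadata$group == "PD", c("subject_id", scales)]
  df <- dplyr::inner_join(dplyr::filter(table, !is.na(.data$value)),
                          pd_meta, by = "subject_id")
  cells <- dplyr::group_split(dplyr::group_by(df, .data$dataset, .data$task,
                                              .data$biomarker))
  rows <- purrr::map(cells, function(cell) {
    purrr::map(scales, function(sc) {
      est <- spearman_cor(cell$value, cell[[sc]])
      if (is.na(est$rho)) return(NULL)
      tibble::tibble(dataset = cell$dataset[1], task = cell$task[1],
                     biomarker = cell$biomarker[1], scale = sc,
                     n = est$n, rho = est$rho, p = est$p)
    })
  })
  res <- dplyr::bind_rows(purrr::flatten(rows))
  if (nrow(res) == 0L) return(res)
  res$family <- biomarker_family(res$biomarker)
  res <- dplyr::ungroup(dplyr::mutate(
    dplyr::group_by(res, .data$dataset, .data$task, .data$family),
    p_adj = stats::p.adjust(.data$p, method = "BH")
  ))
  res$significant <- res$p_adj <= alpha
  dplyr::relocate(res, "family", .after = "biomarker")
}
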