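#' Variant fraction of a region
#'
#' Density statistic for region comparisons: the number of variants
#' overlapping a region divided by the region's length in nucleotides.
#' A fraction of 0.25 corresponds to one variant every 4 bp.
#'
#' @param variant_count Non-negative count (vectorized).
#' @param region_length_nt Region length in nucleotides, at least 1.
#' @return Exact ratio.
#' @examples
#' variant_fraction(15, 60)
#' @export
variant_fraction <- function(variant_count, region_length_nt) {
  if (any(region_length_nt < 1)) {
    stop("region length must be at least 1 nt", call. = FALSE)
  }
  if (any(variant_count < 0)) {
    stop("variant count must be non-negative", call. = FALSE)
  }
  variant_count / region_length_nt
}

#' Variant-fraction table over clusters and regions
#'
#' @param counts Data frame with columns `cluster_id`, `region_tag`,
#'   `variant_count`, `region_length_nt`.
#' @return The same rows with a `fraction` column appended.
#' @export
variant_fraction_table <- function(counts) {
  counts$fraction <- variant_fraction(counts$variant_count,
                                      counts$region_length_nt)
  counts
}

#' Chi-square test of homogeneity
#'
#' Pearson chi-square on a contingency table of non-negative counts with
#' at least two rows and columns: expected counts from the products of
#' marginals, no continuity correction. A warning is logged (not fatal)
#' when any expected count falls below 5.
#'
#' @param tab Matrix or data frame of counts.
#' @return List with `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_square_homogeneity <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop("contingency table needs at least 2 rows and 2 columns",
         call. = FALSE)
  }
  if (any(tab < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero marginal row or column", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  if (any(res$expected < 5)) {
    warning("some expected counts are below 5; chi-square approximation ",
            "may be poor", call. = FALSE)
  }
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = unname(res$p.value), expected = res$expected)
}

.as_group_data <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  if (any(lengths(groups) < 2L)) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)),
                   levels = names(groups)))
}

#' One-way analysis of variance
#'
#' Standard one-way decomposition over named groups of observations
#' (cluster-level variant fractions in the pipeline): F is the ratio of
#' the between-group to the within-group mean square.
#'
#' @param groups Named list of numeric vectors, each of length >= 2.
#' @return List with `F`, `df_between`, `df_within`, `p_value`,
#'   `group_means`, and the fitted `aov` object (`fit`).
#' @export
one_way_anova <- function(groups) {
  d <- .as_group_data(groups)
  within_ss <- sum(tapply(d$value, d$group,
                          function(v) sum((v - mean(v))^2)))
  if (within_ss == 0) {
    stop("degenerate input: zero within-group variance in every group",
         call. = FALSE)
  }
  fit <- stats::aov(value ~ group, data = d)
  s <- summary(fit)[[1]]
  list(F = s[["F value"]][1], df_between = s[["Df"]][1],
       df_within = s[["Df"]][2], p_value = s[["Pr(>F)"]][1],
       group_means = tapply(d$value, d$group, mean), fit = fit)
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range-based adjusted p-values for every pair of groups,
#' with the Tukey-Kramer correction for unequal group sizes.
#'
#' @inheritParams one_way_anova
#' @return Data frame with columns `pair`, `diff`, `lwr`, `upr`,
#'   `p_adj`.
#' @export
tukey_hsd <- function(groups) {
  res <- one_way_anova(groups)
  tk <- stats::TukeyHSD(res$fit)$group
  data.frame(pair = rownames(tk), diff = tk[, "diff"], lwr = tk[, "lwr"],
             upr = tk[, "upr"], p_adj = tk[, "p adj"],
             row.names = NULL, stringsAsFactors = FALSE)
}
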