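#' Two-way ANOVA with interaction
#'
#' Standard sum-of-squares decomposition for a (near-)balanced two-factor
#' design with interaction. The repeated-measures variant adds subject as a
#' blocking factor (no sphericity correction).
#'
#' @param values Numeric response vector.
#' @param factorA,factorB Factor vectors (>= 2 levels each).
#' @param subject Subject identifiers; required when `repeated = TRUE`.
#' @param repeated Block on subject (repeated measures).
#' @return An `anova_table` data frame: one row per term (`A`, `B`, `A:B`)
#'   with `df`, `F`, `p`, plus the residual `df` in the `df_resid` column.
#' @export
two_way_anova <- function(values, factorA, factorB, subject = NULL,
                          repeated = FALSE) {
  a <- factor(factorA); b <- factor(factorB)
  if (nlevels(a) < 2 || nlevels(b) < 2)
    stop("each factor needs at least 2 levels", call. = FALSE)
  d <- data.frame(y = values, A = a, B = b)
  if (sd(values) == 0) {
    # no variance anywhere: every sum of squares is zero
    out <- data.frame(term = c("A", "B", "A:B"),
                      df = c(nlevels(a) - 1, nlevels(b) - 1,
                             (nlevels(a) - 1) * (nlevels(b) - 1)),
                      F = 0, p = 1,
                      df_resid = length(values) - nlevels(a) * nlevels(b))
    return(structure(out, class = c("anova_table", "data.frame")))
  }
  if (repeated) {
    if (is.null(subject))
      stop("repeated = TRUE requires subject identifiers", call. = FALSE)
    d$subject <- factor(subject)
    fit <- aov(y ~ subject + A * B, data = d)
  } else {
    fit <- aov(y ~ A * B, data = d)
  }
  tab <- summary(fit)[[1]]
  term <- trimws(rownames(tab))
  keep <- term %in% c("A", "B", "A:B")
  df_resid <- tab[term == "Residuals", "Df"]
  out <- data.frame(term = term[keep], df = tab[keep, "Df"],
                    F = tab[keep, "F value"], p = tab[keep, "Pr(>F)"],
                    df_resid = df_resid)
  rownames(out) <- NULL
  structure(out, class = c("anova_table", "data.frame"),
            factorA = deparse(substitute(factorA)),
            factorB = deparse(substitute(factorB)))
}

#' Sidak multiple-comparison adjustment
#'
#' `p_adj = 1 - (1 - p)^m` for `m` planned comparisons, capped at 1.
#'
#' @param p_values Raw p-values in \[0, 1\].
#' @param m Number of comparisons; defaults to `length(p_values)`.
#' @return Adjusted p-values.
#' @export
sidak_adjust <- function(p_values, m = length(p_values)) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  pmin(1, 1 - (1 - p_values)^m)
}

#' Pearson chi-squared test on a contingency table
#'
#' Groups x categories counts (e.g. treatment x ensemble membership), no
#' continuity correction, df = (rows - 1)(cols - 1).
#'
#' @param table Numeric matrix of counts, at least 2 x 2, all >= 0.
#' @return A list: `chi2`, `df`, `p`, `expected`.
#' @export
chi_squared_test <- function(table) {
  tab <- as.matrix(table)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("contingency table must be at least 2x2", call. = FALSE)
  if (any(tab < 0)) stop("counts must be >= 0", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal: expected counts undefined", call. = FALSE)
  res <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, expected = res$expected)
}

#' Two-tailed paired t-test
#'
#' Standard paired t on the within-pair differences. When the differences
#' have zero variance but a nonzero mean, the degenerate infinite-t case is
#' flagged (`t = +/-Inf`, `p = 0`) instead of erroring.
#'
#' @param x,y Paired numeric vectors of equal length >= 2.
#' @return A list: `t`, `df`, `p`, `mean_diff`, `degenerate`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2)
    stop("x and y must be paired vectors of equal length >= 2", call. = FALSE)
  d <- x - y
  n <- length(d)
  # treat numerically-constant differences as the degenerate case
  if (sd(d) <= 1e-12 * max(1, abs(mean(d)))) {
    md <- mean(d)
    if (md == 0) return(list(t = 0, df = n - 1, p = 1, mean_diff = 0,
                             degenerate = TRUE))
    return(list(t = sign(md) * Inf, df = n - 1, p = 0, mean_diff = md,
                degenerate = TRUE))
  }
  res <- t.test(x, y, paired = TRUE)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, mean_diff = unname(res$estimate), degenerate = FALSE)
}
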