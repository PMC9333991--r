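#' Welch two-sample t-test
#'
#' Two-tailed t-test assuming unequal group variances
#' (Welch-Satterthwaite degrees of freedom), via `stats::t.test`.  When both
#' groups have zero variance and equal means, `p = 1` by convention.
#'
#' @param a,b numeric samples (>= 2 each).
#' @return list of class `test_result`: `statistic`, `dof` (fractional),
#'   `p` (two-tailed), `n` (per-group sizes).
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("need at least 2 values per group")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(structure(list(statistic = 0, dof = length(a) + length(b) - 2,
                            p = 1, n = c(length(a), length(b))),
                       class = "test_result"))
    return(structure(list(statistic = sign(mean(a) - mean(b)) * Inf,
                          dof = length(a) + length(b) - 2, p = 0,
                          n = c(length(a), length(b))),
                     class = "test_result"))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  structure(list(statistic = unname(tt$statistic), dof = unname(tt$parameter),
                 p = tt$p.value, n = c(length(a), length(b))),
            class = "test_result")
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure via `stats::p.adjust(method = "BH")`; flags hypotheses
#' with adjusted p below `q`.
#'
#' @param pvals p-values in [0, 1].
#' @param q FDR level (default 0.05).
#' @return list: `flag` (logical), `adjusted` (monotone adjusted p-values).
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (!length(pvals)) return(list(flag = logical(0), adjusted = numeric(0)))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  adj <- stats::p.adjust(pvals, method = "BH")
  list(flag = !is.na(adj) & adj < q, adjusted = adj)
}

#' Cohen's d (pooled SD)
#'
#' `(mean(a) - mean(b)) / s_pooled` with the two-group pooled SD using
#' n - 1 weights.  `NA` when the pooled SD is zero.
#'
#' @param a,b numeric samples (>= 2 each).
#' @return scalar effect size.
#' @export
cohens_d <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("need at least 2 values per group")
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
               (na + nb - 2))
  if (sp == 0) return(NA_real_)
  (mean(a) - mean(b)) / sp
}
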