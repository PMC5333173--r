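# Contingency-table statistics for subjective rating data: rating grouping,
# Yates-corrected chi-square, Cramer's V and the chi-square tail probability.
#
# The Yates continuity correction is applied per cell for any table size
# (with the corrected deviation floored at zero), matching its use on
# interface-by-rating tables with 2 degrees of freedom.

#' Group 5-level ratings into 3 levels
#'
#' Rating levels 1 and 2 are rarely assigned on a 5-point ease-of-use scale;
#' grouping them with level 3 keeps expected cell counts large enough for a
#' legitimate chi-square test.  Levels 4 and 5 pass through unchanged.
#'
#' @param raw counts over rating levels 1..5: a length-5 vector or a matrix
#'   with 5 columns (rows = interfaces).
#' @return Counts over the 3 grouped levels (`<=3`, `4`, `5`); totals are
#'   preserved.
#' @export
group_ratings <- function(raw) {
  vec <- is.null(dim(raw))
  m <- if (vec) matrix(raw, nrow = 1) else as.matrix(raw)
  if (ncol(m) != 5L) stop("expected counts over 5 rating levels")
  if (any(m < 0)) stop("counts must be non-negative")
  out <- cbind(rowSums(m[, 1:3, drop = FALSE]), m[, 4], m[, 5])
  storage.mode(out) <- storage.mode(m)
  colnames(out) <- c("<=3", "4", "5")
  rownames(out) <- rownames(m)
  if (vec) out[1, ] else out
}

#' Yates-corrected chi-square statistic
#'
#' Expected counts from the row/column marginals; each cell contributes
#' `(max(|O - E| - 0.5, 0))^2 / E`.  Degrees of freedom are
#' `(rows - 1) * (cols - 1)`.
#'
#' @param table non-negative count matrix, at least 2 x 2.
#' @return List with `chi2` and `df`.
#' @export
chi2_yates <- function(table) {
  O <- as.matrix(table)
  if (nrow(O) < 2L || ncol(O) < 2L) stop("table must be at least 2 x 2")
  if (any(O < 0)) stop("counts must be non-negative")
  rs <- rowSums(O); cs <- colSums(O); N <- sum(O)
  if (any(rs == 0) || any(cs == 0))
    stop("degenerate table: a row or column marginal is zero")
  E <- outer(rs, cs) / N
  chi2 <- sum(pmax(abs(O - E) - 0.5, 0)^2 / E)
  list(chi2 = chi2, df = (nrow(O) - 1L) * (ncol(O) - 1L))
}

# uncorrected counterpart, used for the large-count invariance checks
chi2_pearson <- function(table) {
  O <- as.matrix(table)
  rs <- rowSums(O); cs <- colSums(O); N <- sum(O)
  E <- outer(rs, cs) / N
  list(chi2 = sum((O - E)^2 / E), df = (nrow(O) - 1L) * (ncol(O) - 1L))
}

#' Cramer's V
#'
#' Effect size `V = sqrt(chi2 / (N * (k - 1)))` where `k` is the lesser of
#' the table's row and column counts and `N` the total count; 0 means no
#' association, 1 complete association.  Clipped to `[0, 1]`.
#'
#' @param chi2 chi-square statistic (Yates-corrected or not).
#' @param N total sample size.
#' @param k lesser of the number of rows and columns, `>= 2`.
#' @export
cramers_v <- function(chi2, N, k) {
  if (!is.finite(N) || N <= 0) stop("'N' must be positive")
  if (!is.finite(k) || k < 2) stop("'k' must be >= 2")
  if (chi2 < 0) stop("'chi2' must be non-negative")
  min(1, sqrt(chi2 / (N * (k - 1))))
}

#' Upper-tail chi-square probability
#'
#' @param chi2 statistic, `>= 0`.
#' @param df degrees of freedom, `>= 1`.
#' @export
chi2_pvalue <- function(chi2, df) {
  if (any(chi2 < 0)) stop("'chi2' must be non-negative")
  if (any(df < 1)) stop("'df' must be >= 1")
  stats::pchisq(chi2, df = df, lower.tail = FALSE)
}

#' Contingency-table association report
#'
#' Runs the full pipeline on an interface-by-rating count table: optional
#' 5-to-3 rating grouping, Yates-corrected chi-square, upper-tail p-value
#' and Cramer's V (with `k` the lesser table dimension and `N` the table
#' total).
#'
#' @param table count matrix, rows = interfaces, columns = rating levels.
#' @param group logical; apply [group_ratings()] first (requires 5 columns).
#' @return A `chisq_assoc`: `chi2`, `df`, `p`, `V`, `N`, `k`.
#' @export
chi2_report <- function(table, group = FALSE) {
  m <- as.matrix(table)
  if (group) m <- group_ratings(m)
  res <- chi2_yates(m)
  N <- sum(m); k <- min(dim(m))
  structure(list(chi2 = res$chi2, df = res$df,
                 p = chi2_pvalue(res$chi2, res$df),
                 V = cramers_v(res$chi2, N, k), N = N, k = k),
            class = "chisq_assoc")
}

#' @export
print.chisq_assoc <- function(x, ...) {
  cat(sprintf("<chisq_assoc> chi2 = %.4g (Yates), df = %d, p = %.4g, V = %.3f (N = %d, k = %d)\n",
              x$chi2, x$df, x$p, x$V, x$N, x$k))
  invisible(x)
}
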