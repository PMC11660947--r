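#' @include cohort.R
NULL

#' Group summary table (mean +/- SD)
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of
#' every measure per group x hemisphere x mode cell, in the layout used
#' for cohort result tables. Cells with a single record report SD = 0 and
#' are marked by their n.
#'
#' @param records long-format data.frame as returned by [makeCohort()]
#'   (needs columns group, hemisphere, mode plus the measures).
#' @param measures character vector of measure columns to summarize;
#'   default the ALPS index and the per-ROI FA/MD columns present.
#' @return data.frame with columns group, hemisphere, mode, measure, mean,
#'   sd, n.
#' @export
groupSummary <- function(records,
                         measures = intersect(
                           c("alps", "faProj", "faAssoc", "mdProj", "mdAssoc"),
                           names(records))) {
  stopifnot(all(c("group", "hemisphere", "mode") %in% names(records)),
            length(measures) >= 1L, all(measures %in% names(records)))
  cells <- unique(records[, c("group", "hemisphere", "mode")])
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- records$group == cells$group[i] &
      records$hemisphere == cells$hemisphere[i] &
      records$mode == cells$mode[i]
    n <- sum(sel)
    if (n == 0L) { warning("empty cell omitted"); next }
    for (m in measures) {
      x <- records[[m]][sel]
      rows[[length(rows) + 1L]] <- data.frame(
        group = cells$group[i], hemisphere = cells$hemisphere[i],
        mode = cells$mode[i], measure = m, mean = mean(x),
        sd = if (n > 1L) sd(x) else 0, n = n, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$group, out$hemisphere, out$measure, out$mode), ]
  rownames(out) <- NULL
  out
}

#' Paired comparison of conventional and adjusted indices
#'
#' Two-sided Wilcoxon signed-rank test on paired values. Zero differences
#' are dropped (the standard convention). The exact null distribution is
#' used for up to 25 non-zero differences without ties in |d|; the normal
#' approximation with continuity correction otherwise.
#'
#' @param conventional,adjusted equal-length numeric vectors paired by
#'   subject.
#' @return list: `statistic` (V, sum of positive-difference ranks),
#'   `p.value`, `medianDifference` (median of conventional - adjusted),
#'   `n` (non-zero pairs), `nZero`, `method`.
#' @examples
#' pairedCompare(c(1.5, 1.6, 1.4), c(1.4, 1.5, 1.3))
#' @export
pairedCompare <- function(conventional, adjusted) {
  if (length(conventional) != length(adjusted))
    stop("paired vectors must have equal length")
  ok <- is.finite(conventional) & is.finite(adjusted)
  x <- conventional[ok]; y <- adjusted[ok]
  d <- x - y
  nZero <- sum(d == 0)
  dnz <- d[d != 0]
  n <- length(dnz)
  if (n == 0L)
    return(list(statistic = NA_real_, p.value = 1, medianDifference = 0,
                n = 0L, nZero = nZero,
                method = "Wilcoxon signed rank: all differences zero"))
  exact <- n <= 25L && !anyDuplicated(abs(dnz))
  wt <- suppressWarnings(
    wilcox.test(dnz, mu = 0, alternative = "two.sided", exact = exact,
                correct = TRUE))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       medianDifference = median(d), n = n, nZero = nZero,
       method = if (exact) "Wilcoxon signed rank, exact"
                else "Wilcoxon signed rank, normal approximation")
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties. The p-value uses the
#' exact permutation null for n <= 10 without ties and the asymptotic
#' t-approximation otherwise. Constant input yields an undefined rho,
#' returned as NA with a note.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @return list: `rho`, `p.value`, `n`, `method`.
#' @examples
#' spearmanCorrelation(1:5, c(1, 3, 2, 5, 4))$rho  # 0.8
#' @export
spearmanCorrelation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0)
    return(list(rho = NA_real_, p.value = NA_real_, n = n,
                method = "Spearman rho undefined for constant input"))
  ties <- anyDuplicated(x) || anyDuplicated(y)
  exact <- n <= 10L && !ties
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = exact))
  list(rho = unname(ct$estimate), p.value = ct$p.value, n = n,
       method = if (exact) "Spearman rho, exact permutation null"
                else "Spearman rho, asymptotic")
}
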