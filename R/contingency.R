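#' Observed dive counts by year and shape class
#'
#' Rows are years, columns are `U`, `V-early`, `V-late`. U dives are counted
#' regardless of phase; V dives are split by chick-rearing phase.
#'
#' @param events dive-event data.frame with `year`, `shape`, `phase`.
#' @return integer matrix of observed counts (possibly all-zero when
#'   `events` is empty; rows and columns labelled).
#' @export
build_table <- function(events) {
  years <- sort(unique(events$year))
  cols <- c("U", "V-early", "V-late")
  if (length(years) == 0L)
    return(matrix(0L, 0, 3, dimnames = list(NULL, cols)))
  cls <- ifelse(events$shape == "U", "U",
                paste0("V-", events$phase))
  out <- matrix(0L, length(years), 3, dimnames = list(years, cols))
  tab <- table(events$year, factor(cls, levels = cols))
  out[rownames(tab), ] <- as.integer(tab)
  out
}

#' Chi-square test of independence with expected counts and residuals
#'
#' Computes expected counts `E_ij = row_i * col_j / N`, Pearson residuals
#' `(O - E) / sqrt(E)`, the chi-square statistic (sum of squared residuals,
#' no continuity correction), degrees of freedom `(r-1)(c-1)` and the
#' upper-tail p-value.
#'
#' @param observed matrix of non-negative counts, at least 2 x 2.
#' @return object of class `dive_contingency`: `observed`, `expected`,
#'   `residuals`, `statistic`, `df`, `p_value`.
#' @export
chi_square_independence <- function(observed) {
  observed <- as.matrix(observed)
  if (nrow(observed) < 2L || ncol(observed) < 2L)
    stop("need at least a 2 x 2 table")
  if (any(observed < 0) || any(observed != round(observed)))
    stop("observed counts must be non-negative integers")
  N <- sum(observed)
  if (N <= 0) stop("grand total must be positive")
  expected <- outer(rowSums(observed), colSums(observed)) / N
  if (any(expected == 0))
    stop("degenerate margin: an expected cell is zero")
  residuals <- (observed - expected) / sqrt(expected)
  stat <- sum(residuals^2)
  df <- (nrow(observed) - 1L) * (ncol(observed) - 1L)
  structure(list(observed = observed, expected = expected,
                 residuals = residuals, statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE)),
            class = "dive_contingency")
}

#' @export
print.dive_contingency <- function(x, digits = 2, ...) {
  cat("Chi-square test of independence (year x dive shape class)\n\n")
  cat("Observed:\n"); print(x$observed)
  cat("\nExpected:\n"); print(round(x$expected, digits))
  cat("\nPearson residuals:\n"); print(round(x$residuals, 1))
  cat(sprintf("\nX-squared = %.2f, df = %d, p-value %s\n",
              x$statistic, x$df,
              if (x$p_value < 0.001) "< 0.001"
              else sprintf("= %.3g", x$p_value)))
  invisible(x)
}
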