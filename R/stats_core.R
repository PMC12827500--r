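# Shared statistical primitives with pinned conventions. All hypothesis
# tests in the package route through these so that degenerate inputs
# (zero variance, single observations) behave identically everywhere.

#' Two-sample Student's t-test with pinned degenerate-case conventions
#'
#' Wraps [stats::t.test()] (pooled-variance by default, Welch optionally)
#' and pins down the degenerate cases that arise routinely in sparse
#' single-cell data: if both groups are constant and equal the test is
#' defined as t = 0, p = 1; if both are constant but unequal the p-value
#' is taken to its limit 0 (with a warning), since no finite-variance
#' model can reconcile the groups.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param equal_var Logical; pooled-variance (classical Student) test if
#'   `TRUE` (default), Welch otherwise.
#' @return A list of class `"mt_ttest"` with elements `statistic`, `df`,
#'   `p_value`, `means` (named length-2), and `n` (named length-2).
#' @examples
#' student_t(c(1, 2, 3), c(2, 3, 4))
#' @export
student_t <- function(x, y, equal_var = TRUE) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L) {
    stop("student_t() requires at least 2 observations per group (got ",
         length(x), " and ", length(y), ")")
  }
  if (anyNA(x) || anyNA(y)) stop("student_t() does not accept missing values")
  mx <- mean(x); my <- mean(y)
  vx <- stats::var(x); vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mx == my) {
      out <- list(statistic = 0, df = length(x) + length(y) - 2L, p_value = 1)
    } else {
      warning("zero variance in both groups with unequal means; p-value taken as limit 0")
      out <- list(statistic = sign(mx - my) * Inf,
                  df = length(x) + length(y) - 2L, p_value = 0)
    }
  } else {
    tt <- stats::t.test(x, y, var.equal = equal_var)
    out <- list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                p_value = tt$p.value)
  }
  out$means <- c(x = mx, y = my)
  out$n <- c(x = length(x), y = length(y))
  class(out) <- "mt_ttest"
  out
}

#' @export
print.mt_ttest <- function(x, ...) {
  cat(sprintf("Student t-test: t = %.4f, df = %.2f, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  cat(sprintf("  means: %.4f vs %.4f (n = %d, %d)\n",
              x$means[1], x$means[2], x$n[1], x$n[2]))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; a thin wrapper over
#' [stats::p.adjust()] kept as the single adjustment route for the
#' package. Input order is preserved.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
#' @export
bh_adjust <- function(p) {
  p <- as.numeric(p)
  if (length(p) && (anyNA(p) || any(p < 0 | p > 1))) {
    stop("p-values must lie in [0, 1] with no missing values")
  }
  stats::p.adjust(p, method = "BH")
}

#' Significance star labels
#'
#' Maps p-values to the conventional star annotation with strict
#' thresholds: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, otherwise
#' an empty string (so p = 0.05 exactly earns no star).
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of labels.
#' @examples
#' star_label(c(0.04, 0.05, 5e-4))
#' @export
star_label <- function(p) {
  p <- as.numeric(p)
  out <- character(length(p))
  out[p < 0.05]  <- "*"
  out[p < 0.01]  <- "**"
  out[p < 0.001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}

# Vectorised equal-variance one-way ANOVA across the rows of a matrix.
# Returns F statistics and upper-tail p-values; rows with no
# between- or within-group variability get F = 0, p = 1. Verified
# against stats::aov in the test-suite.
row_anova <- function(mat, groups) {
  groups <- as.factor(groups)
  k <- nlevels(groups)
  n <- length(groups)
  if (ncol(mat) != n) stop("group vector length must equal number of columns")
  if (k < 2L) stop("one-way ANOVA needs at least 2 groups")
  idx <- split(seq_len(n), groups)
  gn <- lengths(idx)
  gmeans <- vapply(idx, function(j) Matrix::rowMeans(mat[, j, drop = FALSE]),
                   numeric(nrow(mat)))
  if (nrow(mat) == 1L) gmeans <- matrix(gmeans, nrow = 1L)
  grand <- as.numeric(Matrix::rowMeans(mat))
  ssb <- as.numeric(gmeans^2 %*% gn) - n * grand^2
  tot <- as.numeric(Matrix::rowSums(mat^2)) - n * grand^2
  ssw <- pmax(tot - ssb, 0)
  ssb <- pmax(ssb, 0)
  df1 <- k - 1L
  df2 <- n - k
  f <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  flat <- ssw <= .Machine$double.eps * pmax(tot, 1) & ssb <= .Machine$double.eps * pmax(tot, 1)
  f[flat] <- 0
  p[flat] <- 1
  list(statistic = f, p_value = p, df1 = df1, df2 = df2,
       group_means = gmeans)
}
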