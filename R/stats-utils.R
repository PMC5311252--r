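#' Row-wise two-sample t statistics
#'
#' Vectorized two-sided two-sample t-test applied to each row of a pair of
#' matrices (features in rows, replicates in columns). Welch's unequal-variance
#' form is the default; Student's pooled-variance form is available via
#' `var_equal = TRUE`. Rows where both groups have zero variance are handled by
#' the analytic limit of the t-test: p = 1 when the group means are equal and
#' p = 0 when they differ; such rows are flagged in the `degenerate` column.
#'
#' @param x numeric matrix (or vector), first group; features in rows.
#' @param y numeric matrix (or vector), second group, same number of rows.
#' @param var_equal logical; pooled-variance (Student) t instead of Welch.
#' @return data.frame with columns `estimate` (mean(x) - mean(y) per row),
#'   `statistic`, `df`, `p_value`, `degenerate`.
#' @examples
#' x <- matrix(rnorm(30), nrow = 10)
#' y <- matrix(rnorm(30, mean = 1), nrow = 10)
#' head(row_t_test(x, y))
#' @export
row_t_test <- function(x, y, var_equal = FALSE) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (is.null(dim(y))) y <- matrix(y, nrow = 1)
  if (nrow(x) != nrow(y)) {
    stop("'x' and 'y' must have the same number of rows")
  }
  nx <- ncol(x)
  ny <- ncol(y)
  if (nx < 2L || ny < 2L) {
    stop("each group needs at least 2 replicates")
  }
  mx <- rowMeans(x)
  my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1L)
  vy <- rowSums((y - my)^2) / (ny - 1L)
  estimate <- mx - my

  if (var_equal) {
    vp <- ((nx - 1L) * vx + (ny - 1L) * vy) / (nx + ny - 2L)
    se <- sqrt(vp * (1 / nx + 1 / ny))
    df <- rep.int(nx + ny - 2L, length(se))
  } else {
    sx2 <- vx / nx
    sy2 <- vy / ny
    se <- sqrt(sx2 + sy2)
    df <- (sx2 + sy2)^2 / (sx2^2 / (nx - 1L) + sy2^2 / (ny - 1L))
  }

  statistic <- estimate / se
  p_value <- 2 * stats::pt(-abs(statistic), df)

  degenerate <- se == 0
  if (any(degenerate)) {
    eq <- degenerate & (estimate == 0)
    statistic[degenerate] <- ifelse(eq[degenerate], 0, sign(estimate[degenerate]) * Inf)
    p_value[degenerate] <- ifelse(eq[degenerate], 1, 0)
    df[degenerate] <- NA_real_
  }

  data.frame(
    estimate = estimate,
    statistic = statistic,
    df = df,
    p_value = p_value,
    degenerate = degenerate,
    row.names = rownames(x)
  )
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment: q_(i) = min_{j >= i} m p_(j) / j,
#' clipped at 1 and mapped back to the input order. A thin, validating wrapper
#' around [stats::p.adjust()] so signature derivation and tests share one
#' entry point.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed, propagated).
#' @return numeric vector of FDR-adjusted values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("'p' must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

# Seed handling: every generator is a pure function of its config. The
# stage offset keeps the streams of the three generators distinct even when
# the user passes one top-level seed to all of them.
.resolve_seed <- function(seed, stage_offset = 0L) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer")
  }
  as.integer((as.numeric(seed) + stage_offset) %% .Machine$integer.max)
}
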