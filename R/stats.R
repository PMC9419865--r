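#' Two-group comparison (paired t or Welch t)
#'
#' Paired: \eqn{t = \bar d / (s_d/\sqrt n)} on the differences, df = n - 1.
#' Unpaired: Welch statistic with Welch-Satterthwaite degrees of freedom.
#' Two-sided p from the t distribution. Degenerate inputs (zero variance)
#' are flagged rather than silently propagated: identical paired groups
#' give t = 0, p = 1; zero-variance differences with nonzero mean give a
#' p-value reported at the machine-precision bound.
#'
#' @param a,b Numeric vectors; paired requires equal lengths >= 2.
#' @param paired Logical (default TRUE).
#' @return An object of class `group_comparison`: `statistic`, `df`,
#'   `p_value`, `n_a`, `n_b`, `paired`, `mean_diff`, `degenerate`.
#' @export
compare_groups <- function(a, b, paired = TRUE) {
  n_a <- length(a); n_b <- length(b)
  degenerate <- FALSE
  if (paired) {
    if (n_a != n_b) stop("paired comparison requires equal group sizes")
    if (n_a < 2) stop("need n >= 2")
    d <- a - b
    md <- mean(d); s <- stats::sd(d); df <- n_a - 1
    if (s == 0) {
      degenerate <- TRUE
      if (md == 0) { t <- 0; p <- 1 }
      else { t <- sign(md) * Inf; p <- .Machine$double.xmin }
    } else {
      t <- md / (s / sqrt(n_a))
      p <- 2 * stats::pt(-abs(t), df)
    }
  } else {
    if (n_a < 2 || n_b < 2) stop("need n >= 2 in each group")
    va <- stats::var(a); vb <- stats::var(b)
    md <- mean(a) - mean(b)
    se2 <- va / n_a + vb / n_b
    if (se2 == 0) {
      degenerate <- TRUE; df <- n_a + n_b - 2
      if (md == 0) { t <- 0; p <- 1 }
      else { t <- sign(md) * Inf; p <- .Machine$double.xmin }
    } else {
      t <- md / sqrt(se2)
      df <- se2^2 / ((va / n_a)^2 / (n_a - 1) + (vb / n_b)^2 / (n_b - 1))
      p <- 2 * stats::pt(-abs(t), df)
    }
  }
  structure(list(statistic = t, df = df, p_value = p, n_a = n_a, n_b = n_b,
                 paired = paired, mean_diff = md, degenerate = degenerate),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s t-test: t = %.4g, df = %.4g, p = %.4g (n = %d, %d)\n",
              if (x$paired) "Paired" else "Welch", x$statistic, x$df,
              x$p_value, x$n_a, x$n_b))
  if (x$degenerate) cat("  note: degenerate input (zero variance)\n")
  invisible(x)
}
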