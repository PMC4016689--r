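#' Group summary: mean and coefficient of variation
#'
#' CV = SD/mean with the sample (n-1) standard deviation, the convention
#' used for between-animal variability in stereological tables.
#'
#' @param values Per-animal values (n >= 2).
#' @return List of class `group_summary`: `n`, `mean`, `sd`, `cv`.
#' @export
summarize_group <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L || anyNA(values)) {
    stop("at least two non-missing values are required", call. = FALSE)
  }
  m <- mean(values)
  s <- stats::sd(values)
  if (m == 0 && s > 0) {
    stop("CV undefined: mean is zero with nonzero SD", call. = FALSE)
  }
  cv <- if (s == 0) 0 else s / m
  structure(list(n = length(values), mean = m, sd = s, cv = cv),
            class = "group_summary")
}

comparison_result <- function(parameter, mean_a, mean_b, t, df, p, alpha) {
  structure(
    list(parameter = parameter, mean_a = mean_a, mean_b = mean_b,
         t = t, df = df, p = p, significant = is.finite(p) && p < alpha,
         alpha = alpha),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: means %.4g vs %.4g, t = %.3f (df %.1f), p = %.4g%s\n",
              x$parameter, x$mean_a, x$mean_b, x$t, x$df, x$p,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Two-sample t-test between groups of animal-level values
#'
#' Classical two-tailed independent-samples test; the pooled-variance
#' (Student) variant is the default, Welch is available. When both groups
#' have zero variance and equal means the statistic is 0/0; by convention
#' `t = 0, p = 1` is returned (zero variance with unequal means gives
#' `t = Inf, p = 0`).
#'
#' @param group_a,group_b Numeric vectors (each n >= 2).
#' @param variant `"pooled"` or `"welch"`.
#' @param parameter Label carried into the result.
#' @param alpha Significance level for the `significant` flag.
#' @return A `comparison_result`: group means, `t`, `df`, two-tailed `p`,
#'   `significant`.
#' @export
t_test_groups <- function(group_a, group_b,
                          variant = c("pooled", "welch"),
                          parameter = "value", alpha = 0.05) {
  variant <- match.arg(variant)
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least two values", call. = FALSE)
  }
  va <- stats::var(group_a); vb <- stats::var(group_b)
  if (va == 0 && vb == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(comparison_result(parameter, mean(group_a), mean(group_b),
                               0, length(group_a) + length(group_b) - 2,
                               1, alpha))
    }
    return(comparison_result(parameter, mean(group_a), mean(group_b),
                             Inf, length(group_a) + length(group_b) - 2,
                             0, alpha))
  }
  tt <- stats::t.test(group_a, group_b, var.equal = variant == "pooled")
  comparison_result(parameter, mean(group_a), mean(group_b),
                    unname(tt$statistic), unname(tt$parameter),
                    tt$p.value, alpha)
}

#' Two-sample t-test reconstructed from summary statistics
#'
#' Rebuilds group SDs as `mean * cv` and applies the chosen t-test formula
#' directly — the route used to check printed tables when raw per-animal
#' data are unavailable.
#'
#' @param mean_a,mean_b Group means.
#' @param cv_a,cv_b Group coefficients of variation (SD/mean, >= 0).
#' @param n_a,n_b Group sizes (>= 2).
#' @inheritParams t_test_groups
#' @return A `comparison_result`.
#' @export
t_test_from_summary <- function(mean_a, cv_a, n_a, mean_b, cv_b, n_b,
                                variant = c("pooled", "welch"),
                                parameter = "value", alpha = 0.05) {
  variant <- match.arg(variant)
  if (n_a < 2 || n_b < 2) stop("group sizes must be >= 2", call. = FALSE)
  if (cv_a < 0 || cv_b < 0) stop("CVs must be >= 0", call. = FALSE)
  sd_a <- abs(mean_a) * cv_a
  sd_b <- abs(mean_b) * cv_b
  if (sd_a == 0 && sd_b == 0) {
    if (mean_a == mean_b) {
      return(comparison_result(parameter, mean_a, mean_b, 0,
                               n_a + n_b - 2, 1, alpha))
    }
    return(comparison_result(parameter, mean_a, mean_b, Inf,
                             n_a + n_b - 2, 0, alpha))
  }
  if (variant == "pooled") {
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
  } else {
    se <- sqrt(sd_a^2 / n_a + sd_b^2 / n_b)
    df <- (sd_a^2 / n_a + sd_b^2 / n_b)^2 /
      ((sd_a^2 / n_a)^2 / (n_a - 1) + (sd_b^2 / n_b)^2 / (n_b - 1))
  }
  t <- (mean_a - mean_b) / se
  p <- 2 * stats::pt(-abs(t), df)
  comparison_result(parameter, mean_a, mean_b, t, df, p, alpha)
}

#' Compare two somal-size distributions on common bins
#'
#' Histograms both groups on shared fixed-width bins (per-animal relative
#' frequencies averaged within group, with the between-animal SEM per bin)
#' and summarises the location shift as the difference of pooled means.
#'
#' @param volumes_a,volumes_b Lists of per-animal numeric vectors of
#'   per-cell volumes (a plain vector is treated as one animal).
#' @param bin_width Common bin width in um^3; `NULL` gives at least 10 bins
#'   over the pooled range.
#' @return List of class `distribution_comparison`: `bins` (data frame
#'   `mid`, `prop_a`, `sem_a`, `prop_b`, `sem_b`), `mean_a`, `mean_b`,
#'   `mean_diff` (b - a), `shift` (`"left"` when group b is smaller,
#'   `"right"` when larger, `"none"`), `sem_defined`.
#' @export
compare_distributions <- function(volumes_a, volumes_b, bin_width = NULL) {
  as_list <- function(v) if (is.list(v)) v else list(v)
  va <- as_list(volumes_a); vb <- as_list(volumes_b)
  pooled <- c(unlist(va), unlist(vb))
  if (length(unlist(va)) == 0L || length(unlist(vb)) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  rng <- range(pooled)
  if (is.null(bin_width)) {
    span <- max(rng[2] - rng[1], max(rng[2], 1) * 1e-6)
    bin_width <- span / 10
  }
  breaks <- seq(floor(rng[1] / bin_width) * bin_width,
                rng[2] + bin_width, by = bin_width)
  freq <- function(x) {
    h <- table(cut(x, breaks, right = FALSE, include.lowest = TRUE))
    as.numeric(h) / length(x)
  }
  fa <- vapply(va, freq, numeric(length(breaks) - 1L))
  fb <- vapply(vb, freq, numeric(length(breaks) - 1L))
  fa <- matrix(fa, ncol = length(va)); fb <- matrix(fb, ncol = length(vb))
  sem <- function(m) {
    if (ncol(m) < 2L) return(rep(NA_real_, nrow(m)))
    apply(m, 1, stats::sd) / sqrt(ncol(m))
  }
  mean_a <- mean(unlist(va)); mean_b <- mean(unlist(vb))
  d <- mean_b - mean_a
  shift <- if (d < 0) "left" else if (d > 0) "right" else "none"
  structure(
    list(
      bins = data.frame(mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
                        prop_a = rowMeans(fa), sem_a = sem(fa),
                        prop_b = rowMeans(fb), sem_b = sem(fb)),
      mean_a = mean_a, mean_b = mean_b, mean_diff = d, shift = shift,
      sem_defined = ncol(fa) >= 2L && ncol(fb) >= 2L
    ),
    class = "distribution_comparison"
  )
}

#' Plot a somal-size distribution comparison
#'
#' Base-graphics rendering of a [compare_distributions()] result: mean
#' per-bin relative frequency per group with between-animal SEM bars.
#'
#' @param x A `distribution_comparison`.
#' @param ... Passed to [plot()].
#' @export
plot.distribution_comparison <- function(x, ...) {
  b <- x$bins
  ylim <- range(0, b$prop_a + ifelse(is.na(b$sem_a), 0, b$sem_a),
                b$prop_b + ifelse(is.na(b$sem_b), 0, b$sem_b))
  plot(b$mid, b$prop_a, type = "b", pch = 1, ylim = ylim,
       xlab = "somal volume (um^3)", ylab = "relative frequency", ...)
  graphics::lines(b$mid, b$prop_b, type = "b", pch = 16)
  err <- function(mid, p, s) {
    ok <- !is.na(s) & s > 0
    if (any(ok)) {
      graphics::arrows(mid[ok], p[ok] - s[ok], mid[ok], p[ok] + s[ok],
                       angle = 90, code = 3, length = 0.02)
    }
  }
  err(b$mid, b$prop_a, b$sem_a)
  err(b$mid, b$prop_b, b$sem_b)
  graphics::legend("topright", legend = c("group A", "group B"),
                   pch = c(1, 16), bty = "n")
  invisible(x)
}
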