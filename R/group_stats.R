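# Group-level statistics on dN/dS: one-way and two-way ANOVA, Tukey HSD
# with simultaneous group-mean intervals, location correlation, and the
# omega histogram. The standard model fits are delegated to base R
# (aov/lm/anova, ptukey/qtukey, cor.test); this module shapes inputs and
# outputs to the analysis's conventions.

check_groups <- function(values, labels) {
  if (length(values) != length(labels)) stopf("values and labels differ in length")
  keep <- is.finite(values) & !is.na(labels)
  values <- values[keep]; labels <- factor(labels[keep])
  labels <- droplevels(labels)
  if (nlevels(labels) < 2L) stopf("need at least two groups")
  if (any(table(labels) == 0L)) stopf("empty group level")
  list(values = values, labels = labels)
}

#' One-way analysis of variance
#'
#' Fixed-effects decomposition of omega by functional group, with the F
#' statistic and upper-tail p-value on (k-1, n-k) degrees of freedom.
#'
#' @param values numeric response (per-pair omega).
#' @param labels group labels (coerced to factor); non-finite responses are
#'   dropped.
#' @return object of class `anova_table`: data.frame with rows Groups,
#'   Error, Total and columns Source, SS, df, MS, F, p. If the within-group
#'   variance is zero with unequal means, F is `Inf` and p is 0.
#' @export
one_way_anova <- function(values, labels) {
  d <- check_groups(values, labels)
  fit <- aov(d$values ~ d$labels)
  tab <- suppressWarnings(anova(fit))   # perfect fits warn inside anova.lm
  ss_g <- tab$`Sum Sq`[1]; ss_e <- tab$`Sum Sq`[2]
  df_g <- tab$Df[1]; df_e <- tab$Df[2]
  # zero within-group variance up to floating round-off
  if (ss_e < (ss_g + ss_e) * 1e-12) ss_e <- 0
  ms_g <- ss_g / df_g; ms_e <- ss_e / df_e
  f <- if (ms_e > 0) ms_g / ms_e else if (ms_g > 0) Inf else 0
  p <- if (is.infinite(f)) 0 else pf(f, df_g, df_e, lower.tail = FALSE)
  out <- data.frame(
    Source = c("Groups", "Error", "Total"),
    SS = c(ss_g, ss_e, ss_g + ss_e),
    df = c(df_g, df_e, df_g + df_e),
    MS = c(ms_g, ms_e, NA_real_),
    F = c(f, NA_real_, NA_real_),
    p = c(p, NA_real_, NA_real_),
    stringsAsFactors = FALSE)
  class(out) <- c("anova_table", "data.frame")
  out
}

#' @export
print.anova_table <- function(x, ...) {
  y <- as.data.frame(x)
  names(y)[names(y) == "p"] <- "Prob>F"
  print(y, row.names = FALSE, digits = 5)
  invisible(x)
}

#' Tukey honestly-significant-difference comparison
#'
#' Tukey-Kramer simultaneous pairwise comparison of group means based on the
#' studentized range distribution, plus simultaneous group-mean intervals
#' `mean_i +/- (q / sqrt(2)) * sqrt(MSE / n_i)` with
#' `q = q_{1-alpha, k, n-k}`. Under this convention two balanced group means
#' are declared different exactly when their intervals are disjoint; for
#' unequal group sizes the pairwise Tukey-Kramer test is authoritative and
#' the intervals are the plotted visual aid.
#'
#' @inheritParams one_way_anova
#' @param alpha familywise error rate (default 0.05).
#' @return object of class `tukey_result`: list with `groups` (group, n,
#'   mean, lo, hi), `pairs` (group1, group2, diff, p_adj, significant),
#'   `q_crit`, `alpha`, `df_error`, `ms_error`.
#' @export
tukey_hsd <- function(values, labels, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  d <- check_groups(values, labels)
  k <- nlevels(d$labels)
  n <- length(d$values)
  fit <- aov(d$values ~ d$labels)
  ms_e <- deviance(fit) / df.residual(fit)
  df_e <- df.residual(fit)
  means <- tapply(d$values, d$labels, mean)
  ns <- tapply(d$values, d$labels, length)
  q_crit <- qtukey(1 - alpha, k, df_e)
  half <- q_crit / sqrt(2) * sqrt(ms_e / ns)
  groups <- data.frame(group = names(means), n = as.integer(ns),
                       mean = as.numeric(means),
                       lo = as.numeric(means - half),
                       hi = as.numeric(means + half),
                       stringsAsFactors = FALSE)
  combs <- utils::combn(levels(d$labels), 2)
  g1 <- combs[1, ]; g2 <- combs[2, ]
  diff <- means[g2] - means[g1]
  se <- sqrt(ms_e / 2 * (1 / ns[g1] + 1 / ns[g2]))
  qstat <- abs(diff) / se
  p_adj <- ptukey(qstat, k, df_e, lower.tail = FALSE)
  pairs <- data.frame(group1 = g1, group2 = g2,
                      diff = as.numeric(diff),
                      q = as.numeric(qstat),
                      p_adj = as.numeric(p_adj),
                      significant = as.numeric(p_adj) < alpha,
                      stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  structure(list(groups = groups, pairs = pairs, q_crit = q_crit,
                 alpha = alpha, df_error = df_e, ms_error = ms_e),
            class = "tukey_result")
}

#' @export
print.tukey_result <- function(x, ...) {
  cat(sprintf("tukey_result: %d groups, %d comparisons, %d significant at alpha=%g\n",
              nrow(x$groups), nrow(x$pairs), sum(x$pairs$significant), x$alpha))
  invisible(x)
}

#' Groups significantly different from every other group
#'
#' The "extreme" groups highlighted in the mean-interval figures: groups
#' whose Tukey-adjusted comparison is significant against all others.
#'
#' @param tukey a [tukey_hsd()] result.
#' @return character vector of group labels (possibly empty).
#' @export
extreme_groups <- function(tukey) {
  stopifnot(inherits(tukey, "tukey_result"))
  gs <- tukey$groups$group
  vapply(gs, function(g) {
    rows <- tukey$pairs$group1 == g | tukey$pairs$group2 == g
    all(tukey$pairs$significant[rows])
  }, logical(1)) -> flag
  gs[flag]
}

#' Two-way analysis of variance (main effects, Type II)
#'
#' Additive model `omega ~ functional group + copy-number class` on an
#' unbalanced design; each factor's sum of squares is the Type II increment
#' (residual SS of the model without that factor minus the full model's),
#' tested against the full model's mean squared error.
#'
#' @param values numeric response.
#' @param group_labels functional-group factor.
#' @param copy_labels copy-number factor (e.g. `"single"`/`"multiple"`).
#' @return `anova_table` data.frame with rows Groups, CopyNumber, Error,
#'   Total.
#' @export
two_way_anova <- function(values, group_labels, copy_labels) {
  if (length(values) != length(group_labels) ||
      length(values) != length(copy_labels)) {
    stopf("values and labels differ in length")
  }
  keep <- is.finite(values) & !is.na(group_labels) & !is.na(copy_labels)
  if (sum(!keep)) warnf("dropping %d incomplete observations", sum(!keep))
  v <- values[keep]
  A <- droplevels(factor(group_labels[keep]))
  B <- droplevels(factor(copy_labels[keep]))
  if (nlevels(A) < 2L) stopf("functional-group factor has a single level")
  if (nlevels(B) < 2L) stopf("copy-number factor has a single level")
  full <- lm(v ~ A + B)
  if (full$rank < nlevels(A) + nlevels(B) - 1L) {
    stopf("factors are confounded (aliased design)")
  }
  rss_full <- deviance(full); df_full <- df.residual(full)
  ms_e <- rss_full / df_full
  ss_A <- deviance(lm(v ~ B)) - rss_full
  ss_B <- deviance(lm(v ~ A)) - rss_full
  df_A <- nlevels(A) - 1L; df_B <- nlevels(B) - 1L
  f_A <- (ss_A / df_A) / ms_e; f_B <- (ss_B / df_B) / ms_e
  ss_tot <- sum((v - mean(v))^2)
  out <- data.frame(
    Source = c("Groups", "CopyNumber", "Error", "Total"),
    SS = c(ss_A, ss_B, rss_full, ss_tot),
    df = c(df_A, df_B, df_full, length(v) - 1L),
    MS = c(ss_A / df_A, ss_B / df_B, ms_e, NA_real_),
    F = c(f_A, f_B, NA_real_, NA_real_),
    p = c(pf(f_A, df_A, df_full, lower.tail = FALSE),
          pf(f_B, df_B, df_full, lower.tail = FALSE),
          NA_real_, NA_real_),
    stringsAsFactors = FALSE)
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Pearson correlation with parametric p-value
#'
#' Sample correlation with a two-sided p-value from the t transform on
#' `n - 2` degrees of freedom; used for the omega versus centromere-distance
#' check.
#'
#' @param x,y numeric vectors of equal length (at least 3).
#' @return list with `r`, `p`, `n` (class `correlation_result`).
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y differ in length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stopf("need at least 3 complete observations")
  if (sd(x) == 0 || sd(y) == 0) stopf("zero variance in input")
  ct <- cor.test(x, y, method = "pearson")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("pearson r = %.4f (p = %.3g, n = %d)\n", x$r, x$p, x$n))
  invisible(x)
}

#' Histogram of omega values in fixed-width bins
#'
#' Half-open bins `[k*w, (k+1)*w)` anchored at zero; a value exactly on an
#' edge falls in the upper bin. Also reports the fraction of values strictly
#' below each requested threshold.
#'
#' @param values non-negative numeric vector (NA dropped; negative values
#'   are an error).
#' @param bin_width positive bin width (default 0.1).
#' @param thresholds thresholds for cumulative fractions (default 0.3).
#' @return list with `edges`, `counts`, `bin_width`, `n`,
#'   `fraction_below` (named by threshold); class `omega_histogram`.
#' @export
omega_histogram <- function(values, bin_width = 0.1, thresholds = 0.3) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stopf("no omega values to bin")
  if (any(values < 0)) stopf("negative omega value")
  stopifnot(bin_width > 0)
  idx <- floor(values / bin_width)
  nbin <- max(idx) + 1L
  counts <- tabulate(idx + 1L, nbins = nbin)
  edges <- bin_width * (0:nbin)
  fb <- vapply(thresholds, function(t) mean(values < t), numeric(1))
  structure(list(edges = edges, counts = counts, bin_width = bin_width,
                 n = length(values),
                 fraction_below = setNames(fb, as.character(thresholds))),
            class = "omega_histogram")
}

#' @export
print.omega_histogram <- function(x, ...) {
  cat(sprintf("omega_histogram: %d values, %d bins of width %g\n",
              x$n, length(x$counts), x$bin_width))
  invisible(x)
}
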