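#' Labelled contingency table of counts
#'
#' @param counts Matrix (r x c) of non-negative integers.
#' @param row_labels,col_labels Optional label vectors.
#' @return An object of class `contingency_table` (a labelled integer
#'   matrix).
#' @export
contingency_table <- function(counts, row_labels = NULL, col_labels = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) <= 0) stop("table must contain at least one observation")
  if (!is.null(row_labels)) rownames(counts) <- row_labels
  if (!is.null(col_labels)) colnames(counts) <- col_labels
  structure(counts, class = c("contingency_table", class(counts)))
}

#' Pearson chi-square test of independence
#'
#' `sum((O - E)^2 / E)` with expected counts from the row/column margins,
#' `df = (r - 1)(c - 1)`, no continuity correction.
#'
#' @param tab A [contingency_table()] or plain count matrix.
#' @return List with `statistic`, `df`, `p`.
#' @export
pearson_chi2 <- function(tab) {
  tab <- as.matrix(tab)
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  if (any(rs == 0) || any(cs == 0)) stop("degenerate margin")
  e <- outer(rs, cs) / n
  stat <- sum((tab - e)^2 / e)
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Linear-by-linear (Mantel-Haenszel trend) association test
#'
#' For an ordered r x c table, `M^2 = (N - 1) r^2` on 1 df, where `r` is
#' the Pearson correlation between row and column scores over the N
#' individuals. Default scores are the integer ranks `1..r` and `1..c`;
#' the statistic is invariant to affine rescaling of either score set.
#'
#' @param tab A [contingency_table()] or plain count matrix.
#' @param row_scores,col_scores Numeric score vectors (defaults `1:r`,
#'   `1:c`).
#' @return List with `statistic`, `df` (= 1), `p`.
#' @export
linear_by_linear <- function(tab, row_scores = NULL, col_scores = NULL) {
  tab <- as.matrix(tab)
  r <- nrow(tab); k <- ncol(tab); n <- sum(tab)
  if (is.null(row_scores)) row_scores <- seq_len(r)
  if (is.null(col_scores)) col_scores <- seq_len(k)
  w <- as.vector(tab)
  u <- rep(row_scores, times = k)
  v <- rep(col_scores, each = r)
  mu_u <- sum(w * u) / n; mu_v <- sum(w * v) / n
  var_u <- sum(w * (u - mu_u)^2); var_v <- sum(w * (v - mu_v)^2)
  if (var_u == 0 || var_v == 0) stop("zero variance in scores")
  rho <- sum(w * (u - mu_u) * (v - mu_v)) / sqrt(var_u * var_v)
  stat <- (n - 1) * rho^2
  list(statistic = stat, df = 1L,
       p = stats::pchisq(stat, 1L, lower.tail = FALSE))
}

#' One-sample t test (raw values or summary statistics)
#'
#' @param x Numeric vector of observations, or `NULL` to use summaries.
#' @param mean,sd,n Summary statistics (used when `x` is `NULL`).
#' @param mu0 Reference value (default 0).
#' @return List with `t`, `df`, `p` (two-tailed).
#' @export
one_sample_t <- function(x = NULL, mean = NULL, sd = NULL, n = NULL, mu0 = 0) {
  if (!is.null(x)) {
    n <- length(x); mean <- base::mean(x); sd <- stats::sd(x)
  }
  if (is.null(mean) || is.null(sd) || is.null(n))
    stop("supply x, or mean, sd and n")
  if (n < 2) stop("n must be at least 2")
  if (sd <= 0) {
    if (mean == mu0) return(list(t = 0, df = n - 1, p = 1))
    stop("zero standard deviation with mean != mu0: t is infinite")
  }
  t <- (mean - mu0) / (sd / sqrt(n))
  df <- n - 1
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Two-sample t test
#'
#' Pooled-variance Student form by default; Welch on request.
#'
#' @param x,y Numeric vectors.
#' @param var_equal Pooled variance (default `TRUE`).
#' @return List with `t`, `df`, `p` (two-tailed).
#' @export
two_sample_t <- function(x, y, var_equal = TRUE) {
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("each sample needs at least 2 observations")
  vx <- stats::var(x); vy <- stats::var(y)
  if (var_equal) {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    if (sp2 <= 0) stop("zero pooled variance")
    t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  } else {
    se2 <- vx / nx + vy / ny
    if (se2 <= 0) stop("zero variance")
    t <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' One-way analysis of variance
#'
#' @param groups List of numeric vectors, one per group.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
oneway_anova <- function(groups) {
  k <- length(groups)
  if (k < 2) stop("need at least two groups")
  ns <- lengths(groups)
  if (any(ns < 1)) stop("empty group")
  n <- sum(ns)
  if (n - k < 1) stop("no residual degrees of freedom")
  gm <- mean(unlist(groups))
  ss_b <- sum(ns * (vapply(groups, mean, numeric(1)) - gm)^2)
  ss_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1; df2 <- n - k
  if (ss_w == 0) stop("zero within-group variance")
  f <- (ss_b / df1) / (ss_w / df2)
  list(F = f, df1 = df1, df2 = df2,
       p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' Mann-Whitney / Wilcoxon rank-sum test
#'
#' Reports the rank-sum `W` of the first sample, with a tie-corrected
#' normal approximation for the p-value (no continuity correction).
#'
#' @param x,y Numeric vectors.
#' @return List with `W`, `z`, `p` (two-tailed).
#' @export
mann_whitney <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 1 || ny < 1) stop("both samples must be non-empty")
  all_v <- c(x, y)
  r <- rank(all_v)
  if (length(unique(all_v)) == 1L) stop("all observations tied")
  w <- sum(r[seq_len(nx)])
  n <- nx + ny
  mu <- nx * (n + 1) / 2
  ties <- table(all_v)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v <- nx * ny / 12 * ((n + 1) - tie_term)
  z <- (w - mu) / sqrt(v)
  list(W = w, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return List with `r`, `df`, `p` (two-tailed).
#' @export
pearson_r <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3) stop("need at least 3 pairs")
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) stop("zero variance")
  r <- sum((x - mean(x)) * (y - mean(y))) / ((n - 1) * sx * sy)
  df <- n - 2
  t <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Spearman rank correlation
#'
#' Pearson correlation of the (mid-)ranks, with the t approximation for
#' the p-value.
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return List with `rho`, `df`, `p` (two-tailed).
#' @export
spearman_rho <- function(x, y) {
  res <- pearson_r(rank(x), rank(y))
  list(rho = res$r, df = res$df, p = res$p)
}

#' Intraclass correlation for odd/even split-half reliability
#'
#' Single-measures two-way intraclass correlation across subjects'
#' (odd, even) LI pairs, in the absolute-agreement form ICC(A,1) by
#' default (consistency form ICC(C,1) on request), with the F-based 95%
#' confidence interval of McGraw and Wong.
#'
#' @param pairs Two-column matrix or data frame: one row per subject,
#'   columns odd and even LIs (at least 3 rows).
#' @param form `"agreement"` (default) or `"consistency"`.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `icc`, `ci` (length 2), `form`, `n`.
#' @export
icc_oddeven <- function(pairs, form = c("agreement", "consistency"),
                        conf_level = 0.95) {
  form <- match.arg(form)
  m <- as.matrix(pairs)
  if (ncol(m) != 2L) stop("pairs must have two columns (odd, even)")
  if (anyNA(m)) stop("missing values in pairs")
  n <- nrow(m); k <- 2L
  if (n < 3L) stop("need at least 3 subjects")
  gm <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_r <- k * sum((row_m - gm)^2)
  ss_c <- n * sum((col_m - gm)^2)
  ss_t <- sum((m - gm)^2)
  ss_e <- ss_t - ss_r - ss_c
  msr <- ss_r / (n - 1); msc <- ss_c / (k - 1)
  mse <- ss_e / ((n - 1) * (k - 1))
  if (msr <= 0) stop("zero between-subject variance")
  alpha <- 1 - conf_level
  if (form == "consistency") {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    f_obs <- msr / mse
    fl <- f_obs / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- f_obs * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    fc <- msc / mse
    v <- ((a * fc + b)^2) /
         (a^2 * fc^2 / (k - 1) + b^2 / ((n - 1) * (k - 1)))
    f1 <- stats::qf(1 - alpha / 2, n - 1, v)
    f2 <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - f1 * mse) /
          (f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f2 * msr - mse) /
          (k * msc + (k * n - k - n) * mse + n * f2 * msr)
    ci <- c(lo, hi)
  }
  list(icc = icc, ci = ci, form = form, n = n)
}

#' Handedness record
#'
#' Item counts for the Edinburgh Handedness Inventory (9 items) and the
#' Quantification of Hand Preference reaching task.
#'
#' @param ehi_right_items,ehi_left_items Right/left preferred item counts
#'   (sum at most 9).
#' @param qhp_right_reaches,qhp_total_reaches Right-hand and total reaches.
#' @return An object of class `handedness_record`.
#' @export
handedness_record <- function(ehi_right_items, ehi_left_items,
                              qhp_right_reaches, qhp_total_reaches) {
  stopifnot(ehi_right_items >= 0, ehi_left_items >= 0,
            ehi_right_items + ehi_left_items <= 9,
            qhp_right_reaches >= 0,
            qhp_right_reaches <= qhp_total_reaches)
  structure(list(ehi_right_items = ehi_right_items,
                 ehi_left_items = ehi_left_items,
                 qhp_right_reaches = qhp_right_reaches,
                 qhp_total_reaches = qhp_total_reaches),
            class = "handedness_record")
}

#' Edinburgh Handedness Inventory quotient
#'
#' `100 * (R - L) / (R + L)`; positive means right-handed.
#'
#' @param h A [handedness_record()].
#' @return Quotient in `[-100, 100]`.
#' @export
ehi_quotient <- function(h) {
  r <- h$ehi_right_items; l <- h$ehi_left_items
  if (r + l == 0) stop("no lateralized items: quotient undefined")
  100 * (r - l) / (r + l)
}

#' Quantification-of-Hand-Preference laterality quotient
#'
#' Proportion of right-hand reaches minus 0.50: +0.50 for exclusively
#' right-handed reaching, -0.50 for exclusively left.
#'
#' @param h A [handedness_record()].
#' @return LQ in `[-0.50, 0.50]`.
#' @export
qhp_lq <- function(h) {
  if (h$qhp_total_reaches == 0) stop("no reaches recorded")
  h$qhp_right_reaches / h$qhp_total_reaches - 0.5
}

#' Classify language impairment from standardized scores
#'
#' Impaired when the child scores more than `abs(threshold)` SD below the
#' normative mean (strictly `z < threshold`) on `min_failures` or more
#' measures.
#'
#' @param zscores Named numeric vector of z-scores.
#' @param threshold Cut-off (default -1).
#' @param min_failures Minimum failing measures (default 2).
#' @return Logical: impaired or not.
#' @export
classify_language_status <- function(zscores, threshold = -1,
                                     min_failures = 2) {
  zscores <- unlist(zscores)
  if (!length(zscores)) stop("no language measures supplied")
  if (length(zscores) < min_failures)
    stop("fewer measures than min_failures")
  sum(zscores < threshold) >= min_failures
}

#' Developmental subgroup label
#'
#' Crosses late-talker status at 20 months with language impairment at 4
#' years: neither = typical; late talker only = late bloomer; impaired
#' only = plateau; both = persistent SLI.
#'
#' @param late_talker,impaired_4y Logicals.
#' @return One of `"typical"`, `"late_bloomer"`, `"plateau"`,
#'   `"persistent_sli"`.
#' @export
subgroup_label <- function(late_talker, impaired_4y) {
  if (late_talker && impaired_4y) "persistent_sli"
  else if (late_talker) "late_bloomer"
  else if (impaired_4y) "plateau"
  else "typical"
}

#' Principal-component language composite
#'
#' First principal component of the (internally standardized) measures,
#' sign-oriented to correlate positively with the mean of the standardized
#' columns, affinely rescaled to sample mean 100 and SD 15.
#'
#' @param measures Numeric matrix, subjects x measures (more subjects than
#'   measures).
#' @return Numeric vector of composite scores.
#' @export
composite_language_score <- function(measures) {
  m <- as.matrix(measures)
  if (nrow(m) <= ncol(m)) stop("need more subjects than measures")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) stop("constant measure column")
  z <- scale(m)
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  scores <- pc$x[, 1]
  if (stats::sd(scores) == 0) stop("degenerate input: no variance on PC1")
  if (stats::cor(scores, rowMeans(z)) < 0) scores <- -scores
  100 + 15 * (scores - mean(scores)) / stats::sd(scores)
}

#' Laterality-category count table with percentages
#'
#' @param categories Character vector of per-subject categories (levels
#'   `left`, `bilateral`, `right`; `insufficient` is dropped with a count).
#' @return List with `counts`, `percent` (rounded to 1 decimal), `n`,
#'   `n_insufficient`.
#' @export
laterality_table <- function(categories) {
  n_insuf <- sum(categories == "insufficient")
  categories <- categories[categories != "insufficient"]
  lv <- c("left", "bilateral", "right")
  counts <- vapply(lv, function(l) sum(categories == l), integer(1))
  n <- sum(counts)
  list(counts = counts,
       percent = if (n > 0) round(100 * counts / n, 1) else counts * NA_real_,
       n = n, n_insufficient = n_insuf)
}
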