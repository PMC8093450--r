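#' Confusion counts for psychometric task scoring
#'
#' Trial outcomes for a go/no-go style working-memory task: `correct`
#' (response on a target), `wrong` (response on a non-target), `avoid`
#' (correctly withheld response), `missed` (target without response).
#'
#' @param correct,wrong,avoid,missed Non-negative integer counts.
#' @return Object of class `cwl_confusion`.
#' @export
confusion_counts <- function(correct = 0, wrong = 0, avoid = 0, missed = 0) {
  cts <- c(correct = correct, wrong = wrong, avoid = avoid, missed = missed)
  if (any(cts < 0) || any(cts != round(cts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  structure(as.list(cts), class = "cwl_confusion")
}

#' N-back task accuracy
#'
#' `(correct + avoid) / (correct + wrong + avoid + missed)`: both acting
#' on targets and withholding on non-targets count as success.
#'
#' @param counts A `cwl_confusion`.
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy_nback <- function(counts) {
  stopifnot(inherits(counts, "cwl_confusion"))
  denom <- counts$correct + counts$wrong + counts$avoid + counts$missed
  if (denom <= 0) stop("no trials: zero denominator", call. = FALSE)
  (counts$correct + counts$avoid) / denom
}

#' Arithmetic task accuracy
#'
#' `correct / (correct + wrong)`: every question draws an answer, so
#' there is nothing to avoid or miss.
#'
#' @param counts A `cwl_confusion`.
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy_arithmetic <- function(counts) {
  stopifnot(inherits(counts, "cwl_confusion"))
  denom <- counts$correct + counts$wrong
  if (denom <= 0) stop("no answered trials: zero denominator", call. = FALSE)
  counts$correct / denom
}

.cwl_report <- function(test, statistic, df = NULL, p_value = NULL,
                        effect_size = NULL, n = NULL, ...) {
  structure(list(test = test, statistic = statistic, df = df,
                 p_value = p_value, effect_size = effect_size, n = n, ...),
            class = "cwl_test")
}

#' @export
print.cwl_test <- function(x, ...) {
  st <- paste(sprintf("%s = %.4g", names(x$statistic), x$statistic),
              collapse = ", ")
  dfs <- if (!is.null(x$df)) sprintf("df = %s, ", paste(x$df, collapse = ", ")) else ""
  es <- if (!is.null(x$effect_size))
    sprintf(", %s = %.3g", names(x$effect_size), x$effect_size) else ""
  cat(sprintf("<cwl_test> %s: %s, %sp = %.4g%s\n",
              x$test, st, dfs, x$p_value, es))
  invisible(x)
}

#' Anderson-Darling test of normality
#'
#' The composite-hypothesis ("case 3") Anderson-Darling test: mean and
#' variance are estimated from the sample, the statistic
#' `A^2 = -n - (1/n) * sum((2i-1) * (log(z_i) + log(1 - z_{n+1-i})))`
#' is size-adjusted as `A* = A^2 * (1 + 0.75/n + 2.25/n^2)`, and the
#' p-value follows the standard piecewise-exponential approximation for
#' that case.
#'
#' @param x Numeric vector with at least 8 finite values and non-zero
#'   variance.
#' @return A `cwl_test` with statistic `A2` (adjusted statistic in
#'   `Astar`).
#' @export
anderson_darling_normal <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop("Anderson-Darling test needs n >= 8", call. = FALSE)
  s <- stats::sd(x)
  if (s == 0) stop("degenerate input: zero variance", call. = FALSE)
  z <- sort((x - mean(x)) / s)
  logp <- stats::pnorm(z, log.p = TRUE)
  logq <- stats::pnorm(z, lower.tail = FALSE, log.p = TRUE)
  i <- seq_len(n)
  A2 <- -n - mean((2 * i - 1) * (logp + rev(logq)))
  Astar <- A2 * (1 + 0.75 / n + 2.25 / n^2)
  p <- if (Astar >= 0.6) {
    exp(1.2937 - 5.709 * Astar + 0.0186 * Astar^2)
  } else if (Astar >= 0.34) {
    exp(0.9177 - 4.279 * Astar - 1.38 * Astar^2)
  } else if (Astar > 0.2) {
    1 - exp(-8.318 + 42.796 * Astar - 59.938 * Astar^2)
  } else {
    1 - exp(-13.436 + 101.14 * Astar - 223.73 * Astar^2)
  }
  .cwl_report("Anderson-Darling normality",
              statistic = c(A2 = A2), p_value = min(max(p, 0), 1),
              n = n, Astar = Astar)
}

#' Friedman rank test for repeated measures
#'
#' Nonparametric omnibus test for a complete participants-by-conditions
#' table: values are ranked within each participant (average ranks for
#' ties) and the tie-corrected chi-square statistic
#' `12 * sum((R_j - n(k+1)/2)^2) / (n k (k+1) - sum(t^3 - t)/(k-1))`
#' on `k - 1` degrees of freedom is reported. Rows with missing cells
#' are dropped with a warning.
#'
#' @param table Numeric matrix or data frame, participants in rows,
#'   conditions in columns.
#' @return A `cwl_test` with statistic `chisq`.
#' @export
friedman_test <- function(table) {
  m <- as.matrix(table)
  if (ncol(m) < 2) stop("need at least 2 conditions", call. = FALSE)
  complete <- stats::complete.cases(m)
  if (!all(complete)) {
    warning(sprintf("%d incomplete row(s) dropped", sum(!complete)),
            call. = FALSE)
    m <- m[complete, , drop = FALSE]
  }
  n <- nrow(m); k <- ncol(m)
  if (n < 2) stop("need at least 2 complete rows", call. = FALSE)
  r <- t(apply(m, 1, rank))
  Rj <- colSums(r)
  ties <- apply(r, 1, function(row) {
    tb <- table(row)
    sum(tb^3 - tb)
  })
  denom <- n * k * (k + 1) - sum(ties) / (k - 1)
  # every row fully tied: no rank information at all, no evidence
  chisq <- if (denom <= 0) 0 else
    12 * sum((Rj - n * (k + 1) / 2)^2) / denom
  df <- k - 1
  .cwl_report("Friedman", statistic = c(chisq = chisq), df = df,
              p_value = stats::pchisq(chisq, df, lower.tail = FALSE),
              n = n, mean_ranks = Rj / n)
}

# exact null distribution of W+ over ranks 1..n (counts, index = W+ + 1)
.signrank_counts <- function(n) {
  cnt <- 1
  for (r in seq_len(n)) cnt <- c(cnt, numeric(r)) + c(numeric(r), cnt)
  cnt
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Differences of exactly zero are discarded; the absolute differences
#' are ranked (average ranks for ties) and `W = min(W+, W-)` is formed.
#' With no ties and `n <= 25` retained pairs the two-sided p-value is
#' exact, from the full enumeration of the `2^n` sign assignments;
#' otherwise a normal approximation with tie and continuity corrections
#' is used. Both `W` and the standardised `Z` are always reported, since
#' summaries in the field quote either.
#'
#' @param a,b Paired numeric vectors.
#' @return A `cwl_test` with statistics `W` and `Z`; `method` records
#'   whether the p-value is exact or approximate.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  keep <- is.finite(d) & d != 0
  d <- d[keep]
  n <- length(d)
  if (n == 0) stop("degenerate input: all differences zero", call. = FALSE)
  if (n < 5) warning("fewer than 5 non-zero differences; test has little power",
                     call. = FALSE)
  r <- rank(abs(d))
  Wpos <- sum(r[d > 0])
  Wneg <- sum(r[d < 0])
  W <- min(Wpos, Wneg)
  has_ties <- anyDuplicated(abs(d)) > 0
  mu <- n * (n + 1) / 4
  tb <- table(abs(d))
  sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - sum(tb^3 - tb) / 48)
  zraw <- Wpos - mu
  z <- (zraw - sign(zraw) * 0.5) / sigma
  if (!has_ties && n <= 25) {
    cnt <- .signrank_counts(n)
    p <- min(1, 2 * sum(cnt[seq_len(W + 1)]) / 2^n)
    method <- "exact"
  } else {
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  .cwl_report("Wilcoxon signed-rank",
              statistic = c(W = W, Z = z), p_value = p, n = n,
              W_pos = Wpos, W_neg = Wneg, method = method)
}

#' Spearman rank correlation
#'
#' With untied data the textbook formula
#' `rho = 1 - 6 * sum(d_i^2) / (n^3 - n)` over rank differences `d_i`;
#' with ties, the Pearson correlation of the average ranks (to which the
#' formula reduces when ties are absent). Two-sided p-value via the
#' t approximation `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` degrees
#' of freedom.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`.
#' @return A `cwl_test` with statistic `rho` (also exposed as the effect
#'   size).
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  rx <- rank(x); ry <- rank(y)
  if (anyDuplicated(rx) || anyDuplicated(ry)) {
    rho <- stats::cor(rx, ry)
  } else {
    rho <- 1 - 6 * sum((rx - ry)^2) / (n^3 - n)
  }
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
  }
  .cwl_report("Spearman rank correlation", statistic = c(rho = rho),
              df = n - 2, p_value = p, effect_size = c(rho = rho), n = n)
}

#' One-way repeated-measures ANOVA
#'
#' Subjects act as a blocking factor: `F = MS_condition / MS_error` with
#' `SS_error = SS_total - SS_condition - SS_subject`, on
#' `(k - 1, (k - 1)(n - 1))` degrees of freedom. The effect size is
#' partial eta-squared, `SS_condition / (SS_condition + SS_error)`. The
#' table must be complete (no imputation); a perfectly additive table
#' (`SS_error = 0`) is reported as degenerate with infinite `F`.
#'
#' @param table Numeric matrix or data frame, participants in rows,
#'   conditions in columns; at least 3 rows and 2 columns.
#' @return A `cwl_test` with statistic `F` and effect size `eta_sq_p`.
#' @export
rm_anova_oneway <- function(table) {
  m <- as.matrix(table)
  n <- nrow(m); k <- ncol(m)
  if (k < 2 || n < 3) stop("need >= 2 conditions and >= 3 participants",
                           call. = FALSE)
  if (anyNA(m)) stop("incomplete table: missing cells are not imputed",
                     call. = FALSE)
  grand <- mean(m)
  ss_cond <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- max(ss_tot - ss_cond - ss_subj, 0)
  df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  degenerate <- ss_err <= .Machine$double.eps * ss_tot
  if (degenerate && ss_cond == 0) {
    f <- 0; p <- 1; eta <- 0
  } else if (degenerate) {
    f <- Inf; p <- 0; eta <- 1
  } else {
    f <- (ss_cond / df1) / (ss_err / df2)
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
    eta <- ss_cond / (ss_cond + ss_err)
  }
  .cwl_report("repeated-measures one-way ANOVA", statistic = c(F = f),
              df = c(df1, df2), p_value = p,
              effect_size = c(eta_sq_p = eta), n = n,
              degenerate = degenerate,
              ss = c(condition = ss_cond, subject = ss_subj, error = ss_err))
}
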