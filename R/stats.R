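#' Shapiro-Wilk normality check
#'
#' Thin wrapper over [stats::shapiro.test()] with explicit preconditions:
#' sample size 3..5000, non-constant data.
#'
#' @param x Numeric sample.
#' @return List with `W` and `p`.
#' @export
shapiro_normality <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3 || length(x) > 5000)
    stop("sample size must be between 3 and 5000")
  if (stats::sd(x) == 0) stop("constant sample; normality test undefined")
  st <- stats::shapiro.test(x)
  list(W = unname(st$statistic), p = st$p.value)
}

rm_table <- function(table) {
  m <- as.matrix(table)
  if (is.null(colnames(m))) colnames(m) <- paste0("S", seq_len(ncol(m)))
  if (is.null(rownames(m))) rownames(m) <- paste0("subj", seq_len(nrow(m)))
  keep <- stats::complete.cases(m)
  m <- m[keep, , drop = FALSE]
  if (ncol(m) < 2) stop("need at least 2 stages")
  if (nrow(m) < 3) stop("need at least 3 complete-case subjects")
  m
}

#' One-way repeated-measures ANOVA across stages
#'
#' Subject-blocked one-way ANOVA for a subjects x stages table of a summary
#' variable (e.g. MAP or RSNA% at each pump level): the stage effect is
#' tested against the subject-by-stage residual,
#' `F = MS_stage / MS_residual` with `(k - 1, (k - 1)(n - 1))` degrees of
#' freedom. Implemented via [stats::aov()] with an `Error(subject)` stratum;
#' subjects with missing stages are dropped (complete-case), and the
#' retained n is reported. `design = "oneway"` gives the plain between-cell
#' one-way ANOVA ignoring the subject blocking.
#'
#' Degenerate tables where the residual mean square is zero are handled
#' explicitly: if the stage effect is also zero the result is `F = 0`,
#' `p = 1`; otherwise `F = Inf`, `p = 0`.
#'
#' @param table Numeric matrix or data.frame, subjects in rows, stages in
#'   columns.
#' @param design `"rm"` (repeated measures, default) or `"oneway"`.
#' @return Object of class `"rm_anova"`: list with `F`, `df1`, `df2`, `p`,
#'   `n` (subjects retained), `k` (stages), `design`, and the sums of
#'   squares `ss` (`stage`, `subject`, `residual`).
#' @export
rm_anova <- function(table, design = c("rm", "oneway")) {
  design <- match.arg(design)
  m <- rm_table(table)
  n <- nrow(m); k <- ncol(m)
  long <- data.frame(y = as.vector(m),
                     subject = factor(rep(rownames(m), times = k)),
                     stage = factor(rep(colnames(m), each = n),
                                    levels = colnames(m)))
  pick <- function(tab, what) tab[trimws(rownames(tab)) == what, "Sum Sq"]
  if (design == "rm") {
    fit <- stats::aov(y ~ stage + Error(subject), data = long)
    tab <- summary(fit)[["Error: Within"]][[1]]
    ss_stage <- pick(tab, "stage")
    ss_resid <- pick(tab, "Residuals")
    ss_subj <- pick(summary(fit)[["Error: subject"]][[1]], "Residuals")
    df1 <- k - 1; df2 <- (k - 1) * (n - 1)
  } else {
    fit <- stats::aov(y ~ stage, data = long)
    tab <- summary(fit)[[1]]
    ss_stage <- pick(tab, "stage")
    ss_resid <- pick(tab, "Residuals")
    ss_subj <- NA_real_
    df1 <- k - 1; df2 <- n * k - k
  }
  eps <- 1e-12 * max(ss_stage, ss_resid, 1)
  if (ss_resid <= eps) {
    if (ss_stage <= eps) {
      F <- 0; p <- 1
    } else {
      F <- Inf; p <- 0
    }
  } else {
    F <- (ss_stage / df1) / (ss_resid / df2)
    p <- stats::pf(F, df1, df2, lower.tail = FALSE)
  }
  structure(list(F = F, df1 = df1, df2 = df2, p = p, n = n, k = k,
                 design = design,
                 ss = c(stage = ss_stage, subject = ss_subj,
                        residual = ss_resid)),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("%s one-way ANOVA: F(%g, %g) = %.4g, p = %.4g (n = %d subjects, %d stages)\n",
              if (x$design == "rm") "Repeated-measures" else "Between-cell",
              x$df1, x$df2, x$F, x$p, x$n, x$k))
  invisible(x)
}

#' Post-hoc pairwise contrasts against a reference stage
#'
#' Paired two-tailed t-tests of every stage against a reference stage
#' (typically pump level `"P0"`), with multiplicity correction (Holm
#' step-down by default; Bonferroni or none selectable). Pairing is
#' complete-case per contrast. A stage identical to the reference yields a
#' zero difference with adjusted p = 1.
#'
#' @param table Subjects x stages matrix or data.frame.
#' @param reference Reference stage name (must be a column).
#' @param correction `"holm"` (default), `"bonferroni"` or `"none"`.
#' @return `data.frame` with one row per non-reference stage: `stage`,
#'   `estimate` (mean difference stage - reference), `sem`, `t`, `df`,
#'   `p_raw`, `p_adj`, `n`, `significant` (p_adj < 0.05), plus attribute
#'   `correction`.
#' @export
posthoc_vs_reference <- function(table, reference,
                                 correction = c("holm", "bonferroni", "none")) {
  correction <- match.arg(correction)
  m <- as.matrix(table)
  if (is.null(colnames(m))) colnames(m) <- paste0("S", seq_len(ncol(m)))
  if (!reference %in% colnames(m))
    stop("reference stage '", reference, "' not in table")
  stages <- setdiff(colnames(m), reference)
  rows <- lapply(stages, function(s) {
    ok <- is.finite(m[, s]) & is.finite(m[, reference])
    d <- m[ok, s] - m[ok, reference]
    nn <- length(d)
    if (nn < 2)
      return(data.frame(stage = s, estimate = NA_real_, sem = NA_real_,
                        t = NA_real_, df = NA_real_, p_raw = NA_real_,
                        n = nn))
    if (stats::sd(d) == 0) {
      est <- mean(d)
      data.frame(stage = s, estimate = est, sem = 0,
                 t = if (est == 0) 0 else Inf * sign(est),
                 df = nn - 1, p_raw = if (est == 0) 1 else 0, n = nn)
    } else {
      tt <- stats::t.test(d)
      data.frame(stage = s, estimate = mean(d),
                 sem = stats::sd(d) / sqrt(nn),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_raw = tt$p.value, n = nn)
    }
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_raw, method = correction)
  out$significant <- !is.na(out$p_adj) & out$p_adj < 0.05
  attr(out, "correction") <- correction
  out
}

#' Two-sample t-tests with summary statistics
#'
#' Paired or unpaired two-tailed t-test (unpaired defaults to Welch's
#' unequal-variance form; `var_equal = TRUE` gives the pooled-variance
#' test), reporting the statistic with mean +/- SEM of each arm. The
#' degenerate case of two zero-variance arms with equal means returns
#' `t = 0, p = 1`.
#'
#' @param a,b Numeric vectors (equal length when `paired`).
#' @param paired Logical (default `FALSE`).
#' @param var_equal Pooled-variance unpaired test (default `FALSE` = Welch).
#' @return List with `t`, `df`, `p`, `estimate` (mean difference a - b),
#'   `mean_a`, `sem_a`, `mean_b`, `sem_b`, `n_a`, `n_b`, `paired`.
#' @export
t_tests <- function(a, b, paired = FALSE, var_equal = FALSE) {
  if (paired && length(a) != length(b))
    stop("paired test requires equal lengths")
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per arm")
  sem <- function(v) stats::sd(v) / sqrt(length(v))
  degenerate <- if (paired) stats::sd(a - b) == 0 else
    (stats::sd(a) == 0 && stats::sd(b) == 0)
  if (degenerate) {
    est <- mean(a) - mean(b)
    t <- if (est == 0) 0 else Inf * sign(est)
    p <- if (est == 0) 1 else 0
    df <- if (paired) length(a) - 1 else length(a) + length(b) - 2
  } else {
    tt <- stats::t.test(a, b, paired = paired, var.equal = var_equal)
    t <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
    est <- mean(a) - mean(b)
  }
  list(t = t, df = df, p = p, estimate = est,
       mean_a = mean(a), sem_a = sem(a), mean_b = mean(b), sem_b = sem(b),
       n_a = length(a), n_b = length(b), paired = paired)
}
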