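# Nonparametric phase-trend statistics: questionnaire scoring, Friedman
# test across phases, and pairwise Wilcoxon signed-rank comparisons.
# Both tests are implemented here (within-subject mid-ranks, tie
# corrections, exact signed-rank distribution for small samples); base
# distribution functions (pchisq, psignrank, pnorm) supply the p-values.

#' Score a visual-fatigue questionnaire response
#'
#' The questionnaire has five items (dry/burning eyes; eye pain or
#' foreign-body sensation; blurred vision; difficulty concentrating;
#' headache or dizziness), each answered no / unsure / yes and scored
#' 0 / 1 / 2. The total score ranges 0--10; higher means more severe
#' fatigue.
#'
#' @param answers Character vector of exactly five answers among
#'   `"no"`, `"unsure"`, `"yes"` (case-insensitive), or an integer
#'   vector of five item scores in 0..2.
#' @return Integer total score in 0..10.
#' @export
#' @examples
#' score_questionnaire(c("yes", "unsure", "no", "no", "yes"))  # 5
score_questionnaire <- function(answers) {
  if (length(answers) != 5L || anyNA(answers))
    stop("incomplete response: exactly 5 answered items required",
         call. = FALSE)
  if (is.numeric(answers)) {
    if (any(!answers %in% 0:2))
      stop("item scores must be 0, 1 or 2", call. = FALSE)
    return(as.integer(sum(answers)))
  }
  key <- c(no = 0L, unsure = 1L, yes = 2L)
  scores <- key[tolower(trimws(answers))]
  if (anyNA(scores))
    stop("answers must be 'no', 'unsure' or 'yes'", call. = FALSE)
  as.integer(sum(scores))
}

.stat_result <- function(test, statistic, p, comparison = NA_character_,
                         df = NA_real_, n = NA_integer_) {
  if (!is.na(p)) p <- min(max(p, 0), 1)
  structure(list(test = test, statistic = unname(statistic),
                 df = df, n = n, p_value = p, comparison = comparison,
                 significant_05 = p < 0.05, significant_01 = p < 0.01),
            class = "blink_stat")
}

#' @export
print.blink_stat <- function(x, ...) {
  mark <- if (isTRUE(x$significant_01)) " **"
          else if (isTRUE(x$significant_05)) " *" else ""
  cmp <- if (!is.na(x$comparison)) paste0(" [", x$comparison, "]") else ""
  cat(sprintf("%s%s: statistic = %.4f, p = %.4g%s\n",
              x$test, cmp, x$statistic, x$p_value, mark))
  invisible(x)
}

#' Friedman test across phases
#'
#' Rank-based test for a difference among k >= 2 repeated measurements
#' (phases) on the same subjects. Each subject's values are replaced by
#' within-subject ranks (mid-ranks for ties); the tie-corrected
#' chi-square approximation gives the p-value. Subjects with missing
#' cells are dropped with a warning; if every subject's values are
#' constant the test is degenerate and returns p = 1 with a warning.
#'
#' @param mat Numeric matrix, subjects in rows, phases in columns.
#' @return A `blink_stat` result (statistic, df = k - 1, p-value,
#'   significance flags at 0.05 and 0.01).
#' @export
friedman_trend <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop("need at least 2 phases", call. = FALSE)
  ok <- stats::complete.cases(mat)
  if (any(!ok)) {
    warning(sum(!ok), " subject(s) with missing cells dropped",
            call. = FALSE)
    mat <- mat[ok, , drop = FALSE]
  }
  n <- nrow(mat); k <- ncol(mat)
  if (n < 2L) stop("need at least 2 complete subjects", call. = FALSE)
  r <- t(apply(mat, 1L, rank))
  # tie correction: sum over subjects of sum(t^3 - t) over tie groups
  tie_term <- sum(apply(mat, 1L, function(row) {
    tt <- table(row)
    sum(tt^3 - tt)
  }))
  denom <- n * k * (k + 1) - tie_term / (k - 1)
  if (denom <= 0) {
    warning("degenerate data: all subjects constant across phases",
            call. = FALSE)
    return(.stat_result("Friedman", 0, 1, df = k - 1, n = n))
  }
  stat <- 12 * sum((colSums(r) - n * (k + 1) / 2)^2) / denom
  p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
  .stat_result("Friedman", stat, p, df = k - 1, n = n)
}

#' Wilcoxon signed-rank test for one phase pair
#'
#' Paired two-sided test. Zero differences are dropped; the absolute
#' differences are mid-ranked and the statistic is the sum of ranks of
#' positive differences. With `n <= exact_max` untied differences the
#' exact signed-rank distribution is used (the study-scale n = 23 falls
#' in this range); otherwise, or in the presence of ties, a normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y Paired numeric vectors.
#' @param exact_max Largest n for which the exact distribution is used
#'   (default 25).
#' @param comparison Optional label stored in the result.
#' @return A `blink_stat` result; the statistic is the signed-rank V
#'   (sum of positive ranks).
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 25L,
                                 comparison = NA_character_) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  ok <- stats::complete.cases(cbind(x, y))
  d <- (x - y)[ok]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("all paired differences are zero", call. = FALSE)
    return(.stat_result("Wilcoxon signed-rank", 0, 1,
                        comparison = comparison, n = 0L))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (!ties && n <= exact_max) {
    p <- if (v > n * (n + 1) / 4)
      2 * stats::psignrank(v - 1, n, lower.tail = FALSE)
    else
      2 * stats::psignrank(v, n)
    p <- min(1, p)
  } else {
    z <- v - n * (n + 1) / 4
    nties <- table(r)
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 -
                    sum(nties^3 - nties) / 48)
    if (sigma == 0) {
      warning("degenerate signed-rank variance", call. = FALSE)
      return(.stat_result("Wilcoxon signed-rank", v, 1,
                          comparison = comparison, n = n))
    }
    z <- (z - sign(z) * 0.5) / sigma
    p <- 2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE))
    p <- min(1, p)
  }
  .stat_result("Wilcoxon signed-rank", v, p, comparison = comparison, n = n)
}

#' Pairwise Wilcoxon signed-rank comparisons between phases
#'
#' Runs [wilcoxon_signed_rank()] for each requested pair of columns of a
#' subjects x phases matrix. No multiplicity correction is applied by
#' default (raw per-pair p-values are reported); Bonferroni scaling is
#' available.
#'
#' @param mat Numeric matrix, subjects in rows, phases in columns.
#' @param pairs Two-column matrix (or list of length-2 vectors) of
#'   column indices to compare; default all unordered pairs.
#' @param correction `"none"` (default) or `"bonferroni"`.
#' @param exact_max Passed to [wilcoxon_signed_rank()].
#' @return Data frame with one row per pair: `phase_a`, `phase_b`,
#'   `statistic`, `p_value`, `p_adjusted`, `significant_05`,
#'   `significant_01` (flags on the adjusted p).
#' @export
pairwise_wilcoxon <- function(mat, pairs = NULL,
                              correction = c("none", "bonferroni"),
                              exact_max = 25L) {
  correction <- match.arg(correction)
  mat <- as.matrix(mat)
  if (is.null(pairs)) {
    pairs <- t(utils::combn(ncol(mat), 2L))
  } else if (is.list(pairs)) {
    pairs <- do.call(rbind, pairs)
  }
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs[i, 1L]; b <- pairs[i, 2L]
    w <- wilcoxon_signed_rank(mat[, a], mat[, b], exact_max = exact_max,
                              comparison = paste0("phase", a, " vs phase", b))
    data.frame(phase_a = a, phase_b = b, statistic = w$statistic,
               p_value = w$p_value)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = correction)
  out$significant_05 <- out$p_adjusted < 0.05
  out$significant_01 <- out$p_adjusted < 0.01
  out
}

#' Phase-trend report over a cohort's feature tables
#'
#' Takes per-subject per-phase feature tables (as returned by
#' [session_features()]) and, for each of the seven blink features,
#' runs the Friedman test across phases plus pairwise Wilcoxon
#' signed-rank comparisons. Subjects missing a feature in some phase are
#' dropped for that feature.
#'
#' @param tables Named list of per-subject feature data frames (each
#'   with a `phase` column and feature columns).
#' @param features Feature columns to analyse (default the seven blink
#'   features present).
#' @param correction Multiplicity correction for the pairwise tests.
#' @return List with one element per feature: `medians` (per phase),
#'   `friedman` (a `blink_stat`), and `pairwise` (data frame).
#' @export
fatigue_report <- function(tables,
                           features = c("BN", "Mean_BI", "Mean_BD", "GBN",
                                        "Mean_GBI", "IBN", "Mean_IBI"),
                           correction = "none") {
  stopifnot(length(tables) >= 2L)
  phases <- sort(unique(tables[[1L]]$phase))
  out <- list()
  for (f in features) {
    if (!f %in% names(tables[[1L]])) next
    mat <- t(vapply(tables, function(tb) {
      as.numeric(tb[[f]][match(phases, tb$phase)])
    }, numeric(length(phases))))
    colnames(mat) <- paste0("phase", phases)
    ok <- stats::complete.cases(mat)
    if (sum(ok) < 2L) {
      # feature undefined for nearly all subjects (e.g. too few groups
      # for an interval): report medians only
      out[[f]] <- list(medians = apply(mat, 2L, stats::median, na.rm = TRUE),
                       n_subjects = sum(ok),
                       friedman = .stat_result("Friedman", NA_real_, NA),
                       pairwise = NULL)
      next
    }
    fr <- suppressWarnings(friedman_trend(mat))
    pw <- suppressWarnings(pairwise_wilcoxon(mat[ok, , drop = FALSE],
                                             correction = correction))
    out[[f]] <- list(medians = apply(mat, 2L, stats::median, na.rm = TRUE),
                     n_subjects = sum(ok),
                     friedman = fr,
                     pairwise = pw)
  }
  class(out) <- "fatigue_report"
  out
}

#' @export
print.fatigue_report <- function(x, ...) {
  cat("Phase trends (medians per phase; Friedman p):\n")
  for (f in names(x)) {
    med <- paste(sprintf("%.2f", x[[f]]$medians), collapse = "  ")
    cat(sprintf("  %-9s %s   p = %.4g%s\n", f, med,
                x[[f]]$friedman$p_value,
                if (isTRUE(x[[f]]$friedman$significant_01)) " **"
                else if (isTRUE(x[[f]]$friedman$significant_05)) " *" else ""))
  }
  invisible(x)
}
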