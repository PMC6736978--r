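#' One-way repeated-measures ANOVA
#'
#' Within-subject one-way decomposition of an `n_subjects x k_conditions`
#' table of session means: variance is partitioned into conditions,
#' subjects, and their interaction (the error term), giving
#' `F = MS_conditions / MS_error` on `(k - 1, (k - 1)(n - 1))` degrees of
#' freedom. No sphericity correction is applied. Fitted via
#' [stats::aov()] with an `Error(subject)` stratum.
#'
#' @param table Numeric matrix, rows = subjects, columns = conditions;
#'   complete (no missing cells), `n >= 2`, `k >= 2`.
#' @return List of class `rm_anova` with `F`, `df_factor`, `df_error`, `p`,
#'   `ms_error`, `ms_factor`, and `grand_mean`.
#' @export
#' @examples
#' tab <- rbind(c(1, 2, 4), c(2, 3, 5), c(1, 3, 6))
#' rm_anova(tab)
rm_anova <- function(table) {
  table <- as.matrix(table)
  if (any(!is.finite(table)))
    stop("missing or non-finite cells; repeated-measures table must be complete",
         call. = FALSE)
  n <- nrow(table); k <- ncol(table)
  if (n < 2 || k < 2)
    stop("need at least 2 subjects and 2 conditions", call. = FALSE)
  d <- data.frame(y = as.vector(table),
                  subject = factor(rep(seq_len(n), times = k)),
                  condition = factor(rep(seq_len(k), each = n)))
  fit <- stats::aov(y ~ condition + Error(subject), data = d)
  within <- summary(fit)[["Error: Within"]][[1L]]
  Fv <- within["condition", "F value"]
  structure(list(F = Fv,
                 df_factor = within["condition", "Df"],
                 df_error = within["Residuals", "Df"],
                 p = within["condition", "Pr(>F)"],
                 ms_error = within["Residuals", "Mean Sq"],
                 ms_factor = within["condition", "Mean Sq"],
                 grand_mean = mean(table)),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA: F(%d,%d) = %.4f, p = %s\n",
              x$df_factor, x$df_error, x$F, format_p(x$p)))
  invisible(x)
}

# p-values are reported truncated at 4 decimals, flooring at < 0.0001
format_p <- function(p) {
  if (p < 1e-4) "< 0.0001" else sprintf("%.4f", trunc(p * 1e4) / 1e4)
}

#' Tukey HSD over a set of condition means
#'
#' For every pair of means computes the studentized-range statistic
#' `q = |mean_i - mean_j| / sqrt(ms_error / n_per_mean)` and its p-value
#' from the studentized-range distribution with `nmeans` groups and
#' `df_error` error degrees of freedom.
#'
#' @param condition_means Named (or unnamed) numeric vector of means.
#' @param ms_error Error mean square from the ANOVA (> 0).
#' @param df_error Error degrees of freedom.
#' @param n_per_mean Number of observations behind each mean.
#' @param nmeans Number of means in the family for the studentized-range
#'   distribution; defaults to `length(condition_means)`.
#' @return data.frame with one row per pair: `i`, `j`, `diff`, `q`, `p`.
#' @export
tukey_hsd <- function(condition_means, ms_error, df_error, n_per_mean,
                      nmeans = length(condition_means)) {
  if (ms_error <= 0) stop("ms_error must be positive", call. = FALSE)
  k <- length(condition_means)
  if (k < 2) stop("need at least two means", call. = FALSE)
  nm <- names(condition_means)
  if (is.null(nm)) nm <- as.character(seq_len(k))
  pairs <- utils::combn(k, 2L)
  se <- sqrt(ms_error / n_per_mean)
  diffs <- condition_means[pairs[2L, ]] - condition_means[pairs[1L, ]]
  q <- abs(diffs) / se
  p <- 1 - stats::ptukey(q, nmeans = nmeans, df = df_error)
  data.frame(i = nm[pairs[1L, ]], j = nm[pairs[2L, ]],
             diff = unname(diffs), q = unname(q), p = unname(p))
}

#' Early-versus-late session comparison
#'
#' Builds the `n_subjects x (2 * n_group)` repeated-measures table from the
#' first and last `n_group` session means of each participant, runs the
#' omnibus [rm_anova()] over the individual sessions (the factor levels are
#' the session slots, matching the `(2 n_group - 1, (2 n_group - 1)(n - 1))`
#' degrees-of-freedom structure), and applies a Tukey studentized-range
#' comparison to the early-vs-late grouped means using the ANOVA's error
#' mean square.
#'
#' Two aggregations of the improvement are reported and labelled
#' distinctly: `group_diff`, the difference of the early and late group
#' means (equal, for a complete table, to the mean per-participant
#' difference), and the per-participant differences themselves
#' (`participant_diffs`, `mean_participant_diff`).
#'
#' @param session_means Numeric matrix, rows = participants, columns =
#'   sessions in chronological order (>= `2 * n_group` columns), of
#'   per-session mean outcomes (e.g. supporting-leg peak %BW).
#' @param n_group Number of sessions per group (default 5).
#' @return List of class `period_comparison`: `anova` ([rm_anova()]),
#'   `tukey_grouped` (1-row data.frame), `tukey_all_pairs`, `early_mean`,
#'   `late_mean`, `early_sd`, `late_sd`, `early_se`, `late_se`,
#'   `group_diff`, `participant_diffs`, `mean_participant_diff`.
#' @export
compare_periods <- function(session_means, n_group = 5L) {
  session_means <- as.matrix(session_means)
  n <- nrow(session_means); S <- ncol(session_means)
  if (S < 2L * n_group)
    stop("need at least ", 2L * n_group, " sessions per participant",
         call. = FALSE)
  early <- session_means[, seq_len(n_group), drop = FALSE]
  late <- session_means[, (S - n_group + 1L):S, drop = FALSE]
  tab <- cbind(early, late)
  colnames(tab) <- c(paste0("early", seq_len(n_group)),
                     paste0("late", seq_len(n_group)))
  an <- rm_anova(tab)
  k <- ncol(tab)
  cond_means <- colMeans(tab)
  grouped_means <- c(early = mean(early), late = mean(late))
  tk_grouped <- tukey_hsd(grouped_means, an$ms_error, an$df_error,
                          n_per_mean = n * n_group, nmeans = k)
  tk_all <- tukey_hsd(cond_means, an$ms_error, an$df_error,
                      n_per_mean = n, nmeans = k)
  pd <- rowMeans(late) - rowMeans(early)
  structure(list(
    anova = an,
    tukey_grouped = tk_grouped,
    tukey_all_pairs = tk_all,
    early_mean = mean(early), late_mean = mean(late),
    early_sd = stats::sd(early), late_sd = stats::sd(late),
    early_se = stats::sd(early) / sqrt(length(early)),
    late_se = stats::sd(late) / sqrt(length(late)),
    group_diff = mean(late) - mean(early),
    participant_diffs = pd,
    mean_participant_diff = mean(pd)),
    class = "period_comparison")
}

#' @export
print.period_comparison <- function(x, ...) {
  cat(sprintf("Early sessions: %.2f (SD %.2f, SE %.2f)\n",
              x$early_mean, x$early_sd, x$early_se))
  cat(sprintf("Late sessions:  %.2f (SD %.2f, SE %.2f)\n",
              x$late_mean, x$late_sd, x$late_se))
  cat(sprintf("Group difference: %.2f; mean per-participant difference: %.2f\n",
              x$group_diff, x$mean_participant_diff))
  print(x$anova)
  cat(sprintf("Tukey (grouped early vs late): q = %.3f, p = %s\n",
              x$tukey_grouped$q[1L], format_p(x$tukey_grouped$p[1L])))
  invisible(x)
}
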