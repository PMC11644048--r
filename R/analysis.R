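#' Single-pass outlier removal on trial errors
#'
#' Removes trial errors lying strictly outside `mean +/- k * SD` of the
#' pooled task distribution, with mean and SD computed once on the full set
#' (no iteration). The SD is the population SD (divide by n); values exactly
#' on the boundary are kept. With fewer than two values nothing can be
#' removed and the full mask is returned with a warning.
#'
#' @param errors Numeric vector of trial errors (cm) for one task, pooled
#'   across the group's participants.
#' @param k SD multiplier (default 2).
#' @return List with `keep` (logical mask), `n_removed`, `mean`, `sd`,
#'   `bounds`.
#' @export
remove_outliers <- function(errors, k = 2) {
  errors <- as.numeric(errors)
  n <- length(errors)
  if (n < 2L) {
    warning("fewer than 2 values: no outlier removal performed")
    return(list(keep = rep(TRUE, n), n_removed = 0L,
                mean = if (n) mean(errors) else NA_real_, sd = NA_real_,
                bounds = c(NA_real_, NA_real_)))
  }
  m <- mean(errors)
  s <- sqrt(mean((errors - m)^2))
  bounds <- c(m - k * s, m + k * s)
  keep <- if (is.finite(k)) errors >= bounds[1L] & errors <= bounds[2L]
          else rep(TRUE, n)
  list(keep = keep, n_removed = sum(!keep), mean = m, sd = s, bounds = bounds)
}

#' Build a cohort trial table
#'
#' @param participant_id,group,task_id,trial_id,final_error_cm Parallel
#'   vectors, one element per trial. Errors must be non-negative and each
#'   (participant, task, trial) combination unique.
#' @return A `data.frame` of class `cohort_table`.
#' @export
cohort_table <- function(participant_id, group, task_id, trial_id,
                         final_error_cm) {
  df <- data.frame(participant_id = as.character(participant_id),
                   group = as.character(group),
                   task_id = as.character(task_id),
                   trial_id = as.integer(trial_id),
                   final_error_cm = as.numeric(final_error_cm),
                   stringsAsFactors = FALSE)
  if (any(df$final_error_cm < 0, na.rm = TRUE))
    stop("pointing errors must be non-negative", call. = FALSE)
  key <- paste(df$participant_id, df$task_id, df$trial_id)
  if (anyDuplicated(key))
    stop("duplicate (participant, task, trial) rows", call. = FALSE)
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Per-participant mean pointing error
#'
#' Arithmetic mean of the kept (non-outlier, non-missing) trial errors of one
#' participant on one task. Zero kept trials yields a flagged missing value.
#'
#' @param table A [cohort_table()] (or compatible data frame).
#' @param participant,task Identifiers selecting the rows.
#' @param keep Optional logical mask aligned with `table` rows (e.g. from
#'   [remove_outliers()]); default keeps everything.
#' @return List with `mean_error_cm` (`NA` if no kept trials), `n_trials`,
#'   `n_used`.
#' @export
participant_mean <- function(table, participant, task, keep = NULL) {
  sel <- table$participant_id == participant & table$task_id == task
  if (!is.null(keep)) {
    stopifnot(length(keep) == nrow(table))
    used <- sel & keep
  } else used <- sel
  vals <- table$final_error_cm[used]
  vals <- vals[is.finite(vals)]
  list(mean_error_cm = if (length(vals)) mean(vals) else NA_real_,
       n_trials = sum(sel), n_used = length(vals))
}

#' Summarise a cohort table to participant means
#'
#' Applies [remove_outliers()] per (group, task) on the pooled trial errors,
#' then averages the kept trials per participant.
#'
#' @param table A [cohort_table()].
#' @param k Outlier SD multiplier (default 2); `Inf` disables removal.
#' @return Data frame with one row per (participant, group, task):
#'   `mean_error_cm`, `n_trials`, `n_used`, `n_outliers_removed`.
#' @export
summarise_cohort <- function(table, k = 2) {
  keep <- rep(TRUE, nrow(table))
  nrem <- integer(nrow(table))
  for (g in unique(table$group)) {
    for (tk in unique(table$task_id[table$group == g])) {
      sel <- which(table$group == g & table$task_id == tk)
      if (length(sel) >= 2L) {
        res <- remove_outliers(table$final_error_cm[sel], k = k)
        keep[sel] <- res$keep
        nrem[sel] <- res$n_removed
      }
    }
  }
  combos <- unique(table[, c("participant_id", "group", "task_id")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    pm <- participant_mean(table, combos$participant_id[i], combos$task_id[i],
                           keep = keep)
    sel <- table$participant_id == combos$participant_id[i] &
      table$task_id == combos$task_id[i]
    data.frame(participant_id = combos$participant_id[i],
               group = combos$group[i], task_id = combos$task_id[i],
               mean_error_cm = pm$mean_error_cm, n_trials = pm$n_trials,
               n_used = pm$n_used, n_outliers_removed = sum(sel & !keep),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Normative reference for flagging impaired performance
#'
#' @param reference_mean,reference_sd Mean and SD (cm) of the normative
#'   (e.g. older unimpaired) group's participant means; `reference_sd > 0`.
#' @param group Label of the reference group.
#' @return An object of class `normative_reference`.
#' @export
normative_reference <- function(reference_mean, reference_sd,
                                group = "older") {
  stopifnot(is.finite(reference_mean), is.finite(reference_sd),
            reference_sd > 0)
  structure(list(reference_mean = reference_mean, reference_sd = reference_sd,
                 group = group),
            class = "normative_reference")
}

#' Flag a participant mean against normative bounds
#'
#' Upper-tail flags only: means exceeding the reference mean by more than
#' 2 (or 3) reference SDs are outside the normative range.
#'
#' @param mean_error Participant mean pointing error (cm).
#' @param ref A [normative_reference()].
#' @return `"within"`, `"above_2sd"` or `"above_3sd"`.
#' @export
normative_flag <- function(mean_error, ref) {
  stopifnot(inherits(ref, "normative_reference"))
  vapply(mean_error, function(m) {
    if (!is.finite(m)) return(NA_character_)
    if (m > ref$reference_mean + 3 * ref$reference_sd) "above_3sd"
    else if (m > ref$reference_mean + 2 * ref$reference_sd) "above_2sd"
    else "within"
  }, character(1))
}

#' Concurrent validity against an external proprioception measure
#'
#' Pearson correlation (with two-sided p value) between per-participant
#' pointing errors and an external measure such as the robotic Crisscross
#' crossing error. Pairs with missing values are dropped and counted.
#'
#' @param pointing_means Numeric vector of participant mean pointing errors
#'   (cm).
#' @param external_errors Paired external errors (e.g. degrees).
#' @return List with `r`, `p`, `n_used`, `n_dropped`.
#' @export
concurrent_validity <- function(pointing_means, external_errors) {
  if (length(pointing_means) != length(external_errors))
    stop("vectors must be paired (equal length)", call. = FALSE)
  ok <- is.finite(pointing_means) & is.finite(external_errors)
  x <- pointing_means[ok]
  y <- external_errors[ok]
  if (length(x) < 3L)
    stop("need at least 3 complete pairs for a correlation", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: one of the measures has zero variance",
         call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_used = length(x),
       n_dropped = sum(!ok))
}
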