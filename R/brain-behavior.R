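#' Response-time validity filter
#'
#' Retains trials whose RT is at least `min_rt` (inclusive, matching a
#' ">= 150 ms" validity rule) and sets the `valid` flag on the result.
#' Order is preserved and the operation is idempotent.
#'
#' @param trials trial data frame with an `rt` column (seconds).
#' @param min_rt validity threshold in seconds, default 0.150.
#' @return the filtered trial data frame.
#' @export
filter_valid <- function(trials, min_rt = 0.150) {
  if (!is.numeric(min_rt) || length(min_rt) != 1 || min_rt < 0)
    abort_config("min_rt must be a non-negative scalar")
  if (!"rt" %in% names(trials)) abort_data("trials must have an rt column")
  out <- trials[trials$rt >= min_rt, , drop = FALSE]
  out$valid <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Group-level behavioral summaries
#'
#' Subject-level mean RT and percent accuracy, aggregated to group means
#' with standard errors, split by emotion (default) or condition.  Groups
#' or cells with no trials are reported as `NA`, not zero.
#'
#' @param trials valid trial data frame (`subject_id, group, condition,
#'   emotion, correct, rt`).
#' @param by `"emotion"` (OVAL trials appear as their own level) or
#'   `"condition"` (FACE vs OVAL).
#' @param groups groups to report; a listed group with no trials yields an
#'   explicit `NA` row rather than being dropped.
#' @return data frame with columns `group`, the `by` column, `n_subjects`,
#'   `mean_rt`, `sem_rt`, `accuracy_pct`, `sem_accuracy`.
#' @export
summarize_behavior <- function(trials, by = c("emotion", "condition"),
                               groups = sort(unique(as.character(trials$group)))) {
  by <- match.arg(by)
  need <- c("subject_id", "group", "condition", "emotion", "correct", "rt")
  if (!all(need %in% names(trials)))
    abort_data(sprintf("trials must have columns: %s", paste(need, collapse = ", ")))
  cell <- if (by == "emotion") {
    ifelse(trials$condition == "OVAL", "OVAL", as.character(trials$emotion))
  } else {
    as.character(trials$condition)
  }
  key <- data.frame(group = as.character(trials$group), cell = cell,
                    subject_id = trials$subject_id,
                    rt = trials$rt, correct = as.numeric(trials$correct))
  cells <- unique(key[, c("group", "cell")])
  empty_groups <- setdiff(groups, cells$group)
  if (length(empty_groups) > 0)
    cells <- rbind(cells, data.frame(group = empty_groups, cell = NA_character_))
  cells <- cells[cells$group %in% groups, , drop = FALSE]
  cells <- cells[order(cells$group, cells$cell), , drop = FALSE]
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sub <- key[key$group == cells$group[i] & !is.na(cells$cell[i]) &
                 key$cell %in% cells$cell[i], ]
    if (nrow(sub) == 0) {
      return(data.frame(group = cells$group[i], cell = cells$cell[i],
                        n_subjects = 0L, mean_rt = NA_real_, sem_rt = NA_real_,
                        accuracy_pct = NA_real_, sem_accuracy = NA_real_))
    }
    per_rt <- tapply(sub$rt, sub$subject_id, mean)
    per_acc <- 100 * tapply(sub$correct, sub$subject_id, mean)
    data.frame(group = cells$group[i], cell = cells$cell[i],
               n_subjects = length(per_rt),
               mean_rt = mean(per_rt), sem_rt = sem(per_rt),
               accuracy_pct = mean(per_acc), sem_accuracy = sem(per_acc))
  }))
  names(out)[names(out) == "cell"] <- by
  rownames(out) <- NULL
  out
}

#' Per-subject posterior medians
#'
#' The individual-level point estimate used for brain-behavior linking:
#' the median over all retained (chain, iteration) draws of one
#' subject-level parameter, per subject.
#'
#' @param draws an `lba_draws` object with subject-level draws retained.
#' @param parameter subject-level parameter name, default `"v_c_face"`.
#' @param subjects subjects to extract; default all fitted subjects.
#' @return named numeric vector of medians.
#' @export
posterior_medians <- function(draws, parameter = "v_c_face",
                              subjects = draws$subjects) {
  if (!parameter %in% .param_names)
    abort_lookup(sprintf("unknown parameter: %s", parameter))
  missing <- setdiff(subjects, draws$subjects)
  if (length(missing) > 0)
    abort_lookup(sprintf("no retained draws for subject(s): %s",
                         paste(missing, collapse = ", ")))
  vapply(subjects, function(sid) {
    median(draws_matrix(draws, paste(sid, parameter, sep = ".")))
  }, numeric(1))
}

#' Spearman rank correlation with a two-sided test
#'
#' Midrank-based Spearman coefficient; the two-sided p-value uses the
#' t-approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` (the default
#' large-sample test), or a seeded permutation test on request.  A
#' coefficient of exactly +-1 is reported with `p = 0`.
#'
#' @param x,y numeric vectors of equal length `>= 3`, neither constant.
#' @param method `"t"` (default) or `"permutation"`.
#' @param n_perm number of permutations in permutation mode.
#' @return list with `rho`, `p_two_sided`, `n`, `method`.
#' @export
spearman_cor <- function(x, y, method = c("t", "permutation"),
                         n_perm = 1e4) {
  method <- match.arg(method)
  if (length(x) != length(y)) abort_data("x and y must have equal length")
  n <- length(x)
  if (n < 3) abort_data("need at least 3 pairs")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    abort_data("x and y must be finite")
  if (var(rank(x)) == 0 || var(rank(y)) == 0)
    abort_data("rho undefined for a constant sequence (zero rank variance)")
  rho <- unname(cor(x, y, method = "spearman"))
  if (abs(rho) >= 1 - 1e-12) {
    p <- 0
  } else if (method == "t") {
    ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
    p <- unname(ct$p.value)
  } else {
    obs <- abs(rho)
    hits <- sum(vapply(seq_len(n_perm), function(i) {
      abs(cor(x, sample(y), method = "spearman")) >= obs - 1e-12
    }, logical(1)))
    p <- (1 + hits) / (n_perm + 1)
  }
  list(rho = rho, p_two_sided = p, n = n, method = method)
}

#' Read / write per-subject ROI activation tables
#'
#' Long-format delimited text with columns `subject_id, roi, psc` (percent
#' signal change for a contrast, one record per subject x region).
#'
#' @param path file path (`.csv` comma, otherwise tab).
#' @param roi in-memory ROI data frame.
#' @return `read_roi` the data frame; `write_roi` the path, invisibly.
#' @export
read_roi <- function(path) {
  if (!file.exists(path)) abort_data(sprintf("ROI table not found: %s", path))
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  if (!all(c("subject_id", "roi", "psc") %in% names(df)))
    abort_data("ROI table must have columns subject_id, roi, psc")
  df
}

#' @rdname read_roi
#' @export
write_roi <- function(roi, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::write.table(roi[c("subject_id", "roi", "psc")], path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Within-group correlations of drift medians with ROI activation
#'
#' For each group and each region in the ROI table, Spearman-correlates the
#' subjects' posterior medians with their percent-signal-change values.
#' Subjects present in one table but not the other are a consistency error
#' (all offenders listed).
#'
#' @param medians named numeric vector of per-subject posterior medians
#'   (from [posterior_medians()]).
#' @param roi ROI data frame (`subject_id, roi, psc`).
#' @param subj_group named character vector mapping subject id to group.
#' @param method p-value method passed to [spearman_cor()].
#' @return data frame with columns `roi, group, rho, p_two_sided, n`.
#' @export
roi_correlations <- function(medians, roi, subj_group, method = "t") {
  off_a <- setdiff(names(medians), unique(roi$subject_id))
  off_b <- setdiff(unique(roi$subject_id), names(medians))
  if (length(off_a) + length(off_b) > 0)
    abort_consistency(sprintf(
      "subject mismatch between posterior and ROI tables: %s",
      paste(c(off_a, off_b), collapse = ", ")))
  out <- list()
  for (region in unique(roi$roi)) {
    rsub <- roi[roi$roi == region, ]
    for (g in sort(unique(unname(subj_group)))) {
      ids <- names(subj_group)[subj_group == g]
      ids <- intersect(ids, rsub$subject_id)
      if (length(ids) < 3) next
      res <- spearman_cor(medians[ids],
                          rsub$psc[match(ids, rsub$subject_id)],
                          method = method)
      out[[length(out) + 1]] <- data.frame(
        roi = region, group = g, rho = res$rho,
        p_two_sided = res$p_two_sided, n = res$n)
    }
  }
  do.call(rbind, out)
}
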