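#' Mean absolute error in log10 space
#'
#' The headline error metric: the mean of `|pred - truth|` with both sides
#' on the log10 incidence scale. An MAE of `m` means predictions are
#' typically a factor `10^m` above or below the truth (see
#' [error_factor()]).
#'
#' @param pred,truth Equal-length finite numeric vectors (log10 scale).
#' @return A single non-negative number.
#' @export
mae_log <- function(pred, truth) {
  if (length(pred) == 0 || length(pred) != length(truth)) {
    abort("pred and truth must be non-empty and of equal length",
          "incembed_invalid_argument")
  }
  if (!all(is.finite(pred)) || !all(is.finite(truth))) {
    abort("pred and truth must be finite", "incembed_invalid_argument")
  }
  mean(abs(pred - truth))
}

#' Multiplicative error factor of a log10 MAE
#'
#' `10^mae`: the typical factor by which predictions over- or
#' under-estimate the truth. An MAE of 0.2 corresponds to a factor of 1.58.
#'
#' @param mae Non-negative log10-space MAE.
#' @return The factor `10^mae` (>= 1).
#' @export
error_factor <- function(mae) {
  if (length(mae) != 1L || !is.finite(mae) || mae < 0) {
    abort("`mae` must be a single non-negative number",
          "incembed_invalid_argument")
  }
  10^mae
}

# Pair-concordance score for one group: over all item pairs, 1 for a
# concordant ordering of (pred, truth), 0 for discordant, 0.5 for a tie in
# either variable.
group_concordance <- function(pred, truth) {
  sp <- sign(outer(pred, pred, "-"))
  st <- sign(outer(truth, truth, "-"))
  up <- upper.tri(sp)
  score <- ifelse(sp[up] == 0 | st[up] == 0, 0.5, (sp[up] == st[up]) * 1)
  mean(score)
}

#' Inter-group concordance of predicted and true rankings
#'
#' A rank-agreement statistic bounded in `[0, 1]`: within each group, every
#' item pair scores 1 if predictions and truth order it the same way, 0 if
#' they disagree, and 0.5 if either variable is tied; the group's score is
#' the mean over its pairs, and the statistic is the unweighted mean over
#' groups. Identical orderings give 1, fully reversed orderings give 0, and
#' the value is invariant under any strictly increasing transform of either
#' argument. With no `group_of`, all items form a single group.
#'
#' @param pred,truth Equal-length numeric vectors.
#' @param group_of Optional per-item group key (e.g. the country, so the
#'   ranking of diseases within each country is compared).
#' @return The concordance statistic in `[0, 1]`.
#' @export
concordance <- function(pred, truth, group_of = NULL) {
  if (length(pred) != length(truth)) {
    abort("pred and truth must have equal length", "incembed_invalid_argument")
  }
  if (is.null(group_of)) group_of <- rep("all", length(pred))
  if (length(group_of) != length(pred)) {
    abort("group_of must match pred in length", "incembed_invalid_argument")
  }
  groups <- split(seq_along(pred), group_of)
  sizes <- lengths(groups)
  if (any(sizes < 2)) {
    warning(sprintf("%d group(s) of size 1 excluded from concordance",
                    sum(sizes < 2)))
    groups <- groups[sizes >= 2]
  }
  if (length(groups) == 0) {
    abort("every group has fewer than 2 items", "incembed_invalid_argument")
  }
  mean(vapply(groups, function(idx)
    group_concordance(pred[idx], truth[idx]), numeric(1)))
}

#' Residuals binned by predicted incidence magnitude
#'
#' Stratifies the log-space residual `pred - truth` (positive when the
#' model overestimates) by the predicted exponent of the incidence value:
#' items fall into bins of width `bin_width` by the floor of their
#' prediction. Each bin reports its centre exponent, the signed mean
#' residual, the MAE, the residual standard deviation and the item count —
#' the ingredients of a residual-vs-magnitude plot.
#'
#' @param pred,truth Finite numeric vectors on the log10 scale.
#' @param bin_width Bin width in exponent units (default 1).
#' @return A data frame with columns `bin_center`, `n`, `mean_residual`,
#'   `mae`, `sd`.
#' @export
residual_bins <- function(pred, truth, bin_width = 1) {
  if (length(pred) != length(truth) || !all(is.finite(c(pred, truth)))) {
    abort("pred and truth must be finite and of equal length",
          "incembed_invalid_argument")
  }
  check_number(bin_width, "bin_width", min = 0, strict_min = TRUE)
  resid <- pred - truth
  bin <- floor(pred / bin_width)
  out <- do.call(rbind, lapply(split(seq_along(pred), bin), function(idx) {
    data.frame(bin_center = (bin[idx[1]] + 0.5) * bin_width,
               n = length(idx),
               mean_residual = mean(resid[idx]),
               mae = mean(abs(resid[idx])),
               sd = if (length(idx) > 1) sd(resid[idx]) else NA_real_)
  }))
  out <- out[order(out$bin_center), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-stratum error and concordance
#'
#' Computes the log-space MAE, concordance (single group within each
#' stratum) and count per stratum — used for age-band and disease-type
#' breakdowns. Strata with fewer than 2 items are flagged and get `NA`
#' concordance.
#'
#' @param pred,truth Finite numeric vectors on the log10 scale.
#' @param strata Per-item stratum key.
#' @return A data frame with columns `stratum`, `n`, `mae`, `concordance`,
#'   `flagged`.
#' @export
stratified_report <- function(pred, truth, strata) {
  if (length(strata) != length(pred) || length(pred) != length(truth)) {
    abort("pred, truth and strata must have equal length",
          "incembed_invalid_argument")
  }
  out <- do.call(rbind, lapply(split(seq_along(pred), strata), function(idx) {
    data.frame(
      n = length(idx),
      mae = mae_log(pred[idx], truth[idx]),
      concordance = if (length(idx) >= 2)
        group_concordance(pred[idx], truth[idx]) else NA_real_,
      flagged = length(idx) < 2
    )
  }))
  out <- data.frame(stratum = rownames(out), out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Evaluate pooled predictions
#'
#' Assembles the full evaluation report from pooled (cross-validated)
#' predictions: log-space MAE and its multiplicative error factor, the
#' inter-group concordance, per-stratum metrics and magnitude-binned
#' residuals. Not-applicable predictions (`NA`, produced by the global and
#' one-hot baselines for entities absent from training) are excluded from
#' every metric and counted separately.
#'
#' @param pred Predictions on the log10 scale; `NA` = not applicable.
#' @param truth Finite log10 targets.
#' @param group_of Optional concordance grouping key (default: one global
#'   group); the pipeline passes the country.
#' @param strata Optional stratification key for the per-stratum table.
#' @param bin_width Residual bin width in exponent units.
#' @return An `evaluation_report`.
#' @export
evaluate_predictions <- function(pred, truth, group_of = NULL, strata = NULL,
                                 bin_width = 1) {
  if (length(pred) != length(truth)) {
    abort("pred and truth must have equal length", "incembed_invalid_argument")
  }
  scored <- is.finite(pred)
  n_scored <- sum(scored)
  report <- list(n_scored = n_scored,
                 n_not_applicable = length(pred) - n_scored,
                 concordance_grouping = if (is.null(group_of)) "global"
                                        else "supplied")
  if (n_scored == 0) {
    report <- c(report, list(mae = NA_real_, error_factor = NA_real_,
                             concordance = NA_real_, per_stratum = NULL,
                             residual_bins = NULL))
    class(report) <- "evaluation_report"
    return(report)
  }
  p <- pred[scored]
  t <- truth[scored]
  report$mae <- mae_log(p, t)
  report$error_factor <- error_factor(report$mae)
  report$concordance <- concordance(
    p, t, if (is.null(group_of)) NULL else group_of[scored])
  report$per_stratum <- if (!is.null(strata)) {
    stratified_report(p, t, strata[scored])
  }
  report$residual_bins <- residual_bins(p, t, bin_width)
  class(report) <- "evaluation_report"
  report
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  cat(sprintf("  scored: %d   not applicable: %d\n",
              x$n_scored, x$n_not_applicable))
  if (is.finite(x$mae %||% NA)) {
    cat(sprintf("  MAE (log10): %.4f   error factor: %.2fx\n",
                x$mae, x$error_factor))
    cat(sprintf("  concordance: %.4f (%s grouping)\n",
                x$concordance, x$concordance_grouping))
  } else {
    cat("  all predictions not applicable\n")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize an evaluation report to JSON
#'
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = 10,
                       dataframe = "columns", na = "null")
  invisible(path)
}
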