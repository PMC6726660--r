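#' Assay quantification configuration
#'
#' Defaults mirror the study design: at least 40 cells per condition per
#' experiment, at least five independent transfections (replicates), dye
#' transfer called when the acceptor cell reaches 10% of the donor
#' fluorescence, and whiskers at 1.5 interquartile ranges.
#'
#' @param min_cells_per_condition,min_replicates design minima; groups below
#'   them are reported with a warning, not dropped.
#' @param transfer_fraction acceptor/donor fraction defining dye transfer.
#' @param whisker_factor whisker multiplier for box plots.
#' @return a list of class `cx_assay_config`.
#' @export
assay_config <- function(min_cells_per_condition = 40, min_replicates = 5,
                         transfer_fraction = 0.10, whisker_factor = 1.5) {
  stopifnot(min_cells_per_condition > 0, min_replicates > 0,
            transfer_fraction > 0, transfer_fraction < 1, whisker_factor > 0)
  structure(list(min_cells_per_condition = min_cells_per_condition,
                 min_replicates = min_replicates,
                 transfer_fraction = transfer_fraction,
                 whisker_factor = whisker_factor),
            class = "cx_assay_config")
}

.ASSAY_CONDITIONS <- c("pco2_35", "pco2_55", "pco2_70", "zero_ca")

#' Summarise a dye-loading assay table
#'
#' Per cell, the image background is subtracted from the measured mean pixel
#' intensity; per replicate and condition, the median of the corrected
#' intensities is taken; and per replicate, each condition is expressed as
#' the change from the control condition (`pco2_35`): `delta = median(cond) -
#' median(pco2_35)`. Downstream statistics operate on these per-replicate
#' deltas — one value per independent transfection — which is the guard
#' against pseudoreplication.
#'
#' @param table a data frame with columns `replicate`, `condition` (one of
#'   `pco2_35`, `pco2_55`, `pco2_70`, `zero_ca`), `cell`, `intensity`,
#'   `background` (arbitrary fluorescence units, >= 0).
#' @param config a [assay_config].
#' @return a list: `per_condition` (replicate, condition, n_cells,
#'   median_corrected), `delta` (replicate, condition, delta),
#'   `warnings` (character).
#' @export
dye_loading_summary <- function(table, config = assay_config()) {
  req <- c("replicate", "condition", "cell", "intensity", "background")
  stopifnot(all(req %in% names(table)))
  bad <- setdiff(unique(table$condition), .ASSAY_CONDITIONS)
  if (length(bad) > 0L) stop("unknown condition: ", bad[1L], call. = FALSE)
  if (any(table$intensity < 0) || any(table$background < 0)) {
    stop("intensities must be >= 0", call. = FALSE)
  }
  table$corrected <- table$intensity - table$background
  agg <- stats::aggregate(corrected ~ replicate + condition, data = table,
                          FUN = stats::median)
  names(agg)[names(agg) == "corrected"] <- "median_corrected"
  ncell <- stats::aggregate(cell ~ replicate + condition, data = table,
                            FUN = length)
  names(ncell)[names(ncell) == "cell"] <- "n_cells"
  per_condition <- merge(agg, ncell, by = c("replicate", "condition"))
  per_condition <- per_condition[order(per_condition$replicate,
                                       match(per_condition$condition,
                                             .ASSAY_CONDITIONS)), ]
  rownames(per_condition) <- NULL

  warns <- character(0)
  low <- per_condition[per_condition$n_cells <
                         config$min_cells_per_condition, , drop = FALSE]
  for (i in seq_len(nrow(low))) {
    w <- sprintf("replicate %s, condition %s: %d cells (< %d)",
                 low$replicate[i], low$condition[i], low$n_cells[i],
                 config$min_cells_per_condition)
    warns <- c(warns, w)
    warning(w, call. = FALSE)
  }

  reps <- unique(per_condition$replicate)
  ctrl <- per_condition[per_condition$condition == "pco2_35", , drop = FALSE]
  if (!all(reps %in% ctrl$replicate)) {
    stop("missing pco2_35 control condition for replicate(s): ",
         paste(setdiff(reps, ctrl$replicate), collapse = ", "), call. = FALSE)
  }
  ctrl_med <- stats::setNames(ctrl$median_corrected, ctrl$replicate)
  noncontrol <- per_condition[per_condition$condition != "pco2_35", ,
                              drop = FALSE]
  delta <- data.frame(replicate = noncontrol$replicate,
                      condition = noncontrol$condition,
                      delta = noncontrol$median_corrected -
                        ctrl_med[as.character(noncontrol$replicate)],
                      row.names = NULL, stringsAsFactors = FALSE)
  list(per_condition = per_condition, delta = delta, warnings = warns)
}

#' Mann-Whitney U test with exact enumeration for small samples
#'
#' The package's own rank-sum test: when both groups have at most
#' `exact_max` observations the permutation distribution of U is enumerated
#' in full (ties handled exactly via midranks), otherwise a tie-corrected
#' normal approximation with continuity correction is used.
#'
#' @param x,y numeric vectors (each of length >= 1).
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (of `x`
#'   relative to `y`).
#' @param exact_max enumeration threshold per group.
#' @return a list: `statistic` (U for `x`), `p_value`, `method`.
#' @export
mann_whitney <- function(x, y, alternative = c("two.sided", "less", "greater"),
                         exact_max = 8L) {
  alternative <- match.arg(alternative)
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 >= 1L, n2 >= 1L)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 <= exact_max && n2 <= exact_max) {
    idx <- utils::combn(n1 + n2, n1)
    u_all <- apply(idx, 2L, function(ii) sum(r[ii])) - n1 * (n1 + 1) / 2
    p <- switch(alternative,
                less = mean(u_all <= u_obs),
                greater = mean(u_all >= u_obs),
                two.sided = mean(abs(u_all - mu) >= abs(u_obs - mu)))
    return(list(statistic = u_obs, p_value = p,
                method = "exact enumeration"))
  }
  n <- n1 + n2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) {
    return(list(statistic = u_obs, p_value = 1,
                method = "normal approximation (degenerate)"))
  }
  z <- (u_obs - mu)
  cc <- 0.5
  p <- switch(alternative,
              less = stats::pnorm((z + cc) / sqrt(sigma2)),
              greater = stats::pnorm((z - cc) / sqrt(sigma2),
                                     lower.tail = FALSE),
              two.sided = 2 * min(
                stats::pnorm((z + cc) / sqrt(sigma2)),
                stats::pnorm((z - cc) / sqrt(sigma2), lower.tail = FALSE), 0.5))
  list(statistic = u_obs, p_value = p,
       method = "tie-corrected normal approximation")
}

#' Group comparisons of per-replicate deltas
#'
#' Kruskal-Wallis across all groups, Mann-Whitney for every pair. The
#' analysis unit is the per-replicate delta (one number per independent
#' transfection), never the cell. A pair is flagged significant only when the
#' omnibus Kruskal-Wallis test is itself significant at `alpha` — pairwise
#' comparisons are gated on the omnibus test, the standard guard for the
#' multiple-comparison setting this workflow uses.
#'
#' @param values numeric vector of per-replicate deltas.
#' @param groups grouping factor/character of the same length.
#' @param alpha significance level for the gate and the flags.
#' @return a list: `kruskal` (statistic, df, p_value), `pairwise` (data
#'   frame: group1, group2, n1, n2, U, p_value, method, significant).
#' @export
group_tests <- function(values, groups, alpha = 0.05) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  split_vals <- split(values, groups)
  if (length(split_vals) < 2L) stop("need >= 2 groups", call. = FALSE)
  small <- names(split_vals)[vapply(split_vals, length, 1L) < 2L]
  if (length(small) > 0L) {
    stop("group(s) with < 2 values: ", paste(small, collapse = ", "),
         call. = FALSE)
  }
  kw <- stats::kruskal.test(values, factor(groups))
  gnames <- names(split_vals)
  pairs <- utils::combn(gnames, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1L, j]; g2 <- pairs[2L, j]
    mw <- mann_whitney(split_vals[[g1]], split_vals[[g2]])
    data.frame(group1 = g1, group2 = g2,
               n1 = length(split_vals[[g1]]), n2 = length(split_vals[[g2]]),
               U = mw$statistic, p_value = mw$p_value, method = mw$method,
               significant = kw$p.value <= alpha & mw$p_value <= alpha,
               stringsAsFactors = FALSE)
  })
  list(kruskal = list(statistic = unname(kw$statistic),
                      df = unname(kw$parameter), p_value = kw$p.value),
       pairwise = do.call(rbind, rows))
}

#' Call the dye-transfer time from a donor/acceptor trace
#'
#' The transfer time is the first sampled time point at which the acceptor
#' fluorescence reaches `transfer_fraction` (10% by default) of the donor
#' fluorescence at that time; both series are assumed background-corrected.
#' A linearly interpolated crossing time between samples is reported as a
#' refinement; the grid call is the primary value. If the threshold is never
#' reached, the call is censored at the final time point.
#'
#' @param trace a list or data frame with `time` (seconds, strictly
#'   increasing), `donor` and `acceptor` (equal-length numeric series).
#' @param config a [assay_config].
#' @return a list: `time` (grid call, or last time if censored),
#'   `interpolated`, `censored`.
#' @export
call_transfer_time <- function(trace, config = assay_config()) {
  t <- trace$time; d <- trace$donor; a <- trace$acceptor
  stopifnot(length(t) == length(d), length(d) == length(a), length(t) >= 1L)
  if (any(diff(t) <= 0)) stop("time must be strictly increasing", call. = FALSE)
  if (all(d <= 0)) stop("no donor signal", call. = FALSE)
  f <- config$transfer_fraction
  excess <- a - f * d
  hit <- which(excess >= 0)
  if (length(hit) == 0L) {
    return(list(time = t[length(t)], interpolated = NA_real_,
                censored = TRUE))
  }
  i <- hit[1L]
  interp <- if (i == 1L) {
    t[1L]
  } else {
    # linear interpolation of the excess between the bracketing samples
    t[i - 1L] + (t[i] - t[i - 1L]) * (0 - excess[i - 1L]) /
      (excess[i] - excess[i - 1L])
  }
  list(time = t[i], interpolated = interp, censored = FALSE)
}

#' Box-and-whisker summary with median-anchored whiskers
#'
#' The box is the first and third quartile and the bar the median; whiskers
#' extend to the most extreme data point no further than
#' `whisker_factor * IQR` from the *median* — the rule as stated in the
#' figure legends this package reproduces, which anchors the whisker to the
#' median rather than to the quartiles. The conventional Tukey variant
#' (fences at the quartiles) is available via `anchor = "quartile"`.
#' Quartiles use linear interpolation of order statistics
#' ([stats::quantile] type 7).
#'
#' @param values numeric vector (length >= 1).
#' @param anchor `"median"` (the legend rule; default) or `"quartile"`
#'   (Tukey).
#' @param config a [assay_config] (supplies `whisker_factor`).
#' @return a list: `median`, `q1`, `q3`, `iqr`, `whisker_low`,
#'   `whisker_high`, `outliers`.
#' @export
box_whisker_stats <- function(values, anchor = c("median", "quartile"),
                              config = assay_config()) {
  anchor <- match.arg(anchor)
  if (length(values) == 0L) stop("empty input", call. = FALSE)
  med <- stats::median(values)
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2L] - q[1L]
  k <- config$whisker_factor
  if (anchor == "median") {
    lo_fence <- med - k * iqr; hi_fence <- med + k * iqr
  } else {
    lo_fence <- q[1L] - k * iqr; hi_fence <- q[2L] + k * iqr
  }
  inside <- values[values >= lo_fence & values <= hi_fence]
  list(median = med, q1 = q[1L], q3 = q[2L], iqr = iqr,
       whisker_low = min(inside), whisker_high = max(inside),
       outliers = sort(values[values < lo_fence | values > hi_fence]))
}
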