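#' Percentile background adjustment
#'
#' Subtracts, per sample, a low percentile of that sample's intensities as a
#' background estimate, flooring the result at 1.0 so the log2 transform is
#' defined. This is a deliberately simple stand-in for the convolution-model
#' background of full RMA; it can be disabled by the pipeline.
#'
#' @param values Linear-scale intensity matrix (probes x samples), strictly
#'   positive.
#' @param percentile Percentile (0--100) of each sample used as its
#'   background; default 2.
#' @return Adjusted matrix, same dimensions, all values >= 1.
#' @export
background_adjust <- function(values, percentile = 2) {
  values <- as.matrix(values)
  if (any(values <= 0)) stop("background adjustment requires strictly positive intensities")
  bg <- apply(values, 2L, quantile, probs = percentile / 100, names = FALSE)
  out <- sweep(values, 2L, bg, "-")
  out[out < 1] <- 1
  out
}

#' Quantile normalization across samples
#'
#' Forces every sample (column) to the same distribution: each value is
#' replaced by the mean of the order statistics across samples at its rank
#' (the across-sample mean of sorted columns), so that after the call every
#' column has an identical sorted vector and a second application is a
#' no-op. Tied input values receive the mean of the target values at the
#' ranks the tie group occupies (for ties the collapsed values make the
#' per-column sorted vectors differ at the tied positions, as with any
#' tie-averaging rule). Within-sample rank order is preserved.
#'
#' @param values Numeric matrix (probes x samples), no missing values.
#' @return Normalized matrix with the input dimnames.
#' @export
quantile_normalize <- function(values) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("missing values are not supported")
  if (ncol(values) < 2L) {
    warning("single sample: quantile normalization is the identity")
    return(values)
  }
  target <- rowMeans(apply(values, 2L, sort))
  out <- apply(values, 2L, function(x) {
    res <- numeric(length(x))
    res[order(x)] <- target
    # tie groups share the mean of the target values at their ranks
    stats::ave(res, match(x, x), FUN = mean)
  })
  dimnames(out) <- dimnames(values)
  out
}

#' Median-polish summarization of probesets
#'
#' Summarizes each probeset (a sub-matrix of log2 probe intensities) into one
#' value per sample by an additive two-way decomposition fitted with iterated
#' row/column median sweeps ([stats::medpolish()], at most 10 iterations or
#' total-change below 0.01). The summary for a sample is the overall effect
#' plus that sample's column effect, the usual robust probeset expression
#' measure.
#'
#' @param probe_groups Named list mapping probeset id to a numeric matrix
#'   (probes x samples) on the log2 scale; all matrices must share columns.
#' @return Matrix of summarized values, one row per probeset.
#' @export
median_polish_summarize <- function(probe_groups) {
  stopifnot(is.list(probe_groups), length(probe_groups) >= 1L)
  rows <- lapply(names(probe_groups), function(ps) {
    m <- as.matrix(probe_groups[[ps]])
    if (nrow(m) == 0L || ncol(m) == 0L) stop("empty probeset: ", ps)
    if (nrow(m) == 1L) return(m[1L, ])
    fit <- medpolish(m, eps = 0.01, maxiter = 10L, trace.iter = FALSE)
    fit$overall + fit$col
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(probe_groups)
  out
}

#' One-way analysis of variance for a single probe
#'
#' Classical fixed-effects one-way ANOVA: F = between-group mean square over
#' within-group mean square, with an upper-tail F p-value
#' ([stats::oneway.test()] with equal variances). Degenerate inputs with zero
#' within-group variance are resolved by the group means: p = 0 if they
#' differ, p = 1 if they are all equal (with a warning either way).
#'
#' @param values_by_group Named list mapping group label to a numeric vector
#'   of observations (>= 2 groups; error degrees of freedom >= 1 unless all
#'   within-group variances are zero).
#' @return List with `statistic` (F), `p_value`, `df1`, `df2`.
#' @examples
#' anova_one_way(list(a = c(1, 2), b = c(3, 4)))  # F = 8, p ~ 0.1056
#' @export
anova_one_way <- function(values_by_group) {
  stopifnot(is.list(values_by_group), length(values_by_group) >= 2L)
  sizes <- lengths(values_by_group)
  if (any(sizes < 1L)) stop("every group needs at least one observation")
  k <- length(values_by_group)
  n <- sum(sizes)
  df1 <- k - 1L
  df2 <- n - k
  if (df2 < 1L) stop("error degrees of freedom < 1")
  y <- unlist(values_by_group, use.names = FALSE)
  g <- factor(rep(names(values_by_group), sizes))
  means <- vapply(values_by_group, mean, numeric(1L))
  ssw <- sum((y - rep(means, sizes))^2)
  if (ssw == 0) {
    if (max(means) - min(means) > 0) {
      warning("zero within-group variance with unequal means; p = 0")
      return(list(statistic = Inf, p_value = 0, df1 = df1, df2 = df2))
    }
    warning("zero within-group variance with equal means; p = 1")
    return(list(statistic = 0, p_value = 1, df1 = df1, df2 = df2))
  }
  ft <- oneway.test(y ~ g, var.equal = TRUE)
  list(statistic = unname(ft$statistic), p_value = unname(ft$p.value),
       df1 = df1, df2 = df2)
}

# vectorized per-row one-way F test (same model as anova_one_way) for
# screening thousands of probes without a per-probe model fit
.row_anova_p <- function(values, groups) {
  g <- factor(groups)
  k <- nlevels(g)
  n <- ncol(values)
  df1 <- k - 1L
  df2 <- n - k
  if (df2 < 1L) stop("error degrees of freedom < 1")
  gm <- rowMeans(values)
  ssb <- numeric(nrow(values))
  ssw <- numeric(nrow(values))
  for (lev in levels(g)) {
    sel <- g == lev
    m <- rowMeans(values[, sel, drop = FALSE])
    ssb <- ssb + sum(sel) * (m - gm)^2
    ssw <- ssw + rowSums((values[, sel, drop = FALSE] - m)^2)
  }
  f <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  p[ssw == 0 & ssb > 0] <- 0
  p[ssw == 0 & ssb == 0] <- 1
  p
}

#' Signed fold change from log2 group means
#'
#' Converts a log2 difference into the signed fold-change convention in which
#' magnitudes are always >= 1 and down-regulation is negative: with
#' `r = 2^(treated - control)`, returns `r` when `r >= 1` and `-1/r`
#' otherwise, so a halving is reported as -2 rather than 0.5.
#'
#' @param mean_log2_treated,mean_log2_control Finite log2-scale means.
#' @return Signed fold change with `|fc| >= 1`.
#' @examples
#' signed_fold_change(5, 6)  # -2
#' @export
signed_fold_change <- function(mean_log2_treated, mean_log2_control) {
  stopifnot(is.finite(mean_log2_treated), is.finite(mean_log2_control))
  r <- 2^(mean_log2_treated - mean_log2_control)
  ifelse(r >= 1, r, -1 / r)
}

#' Screen differential-expression results at p-value and fold-change cuts
#'
#' Keeps probes with `p_value < p_cut` and `|fc| >= fc_cut` for the requested
#' contrast and counts how many pass in each direction.
#'
#' @param results Data.frame with columns `probe_id`, `p_value` and one
#'   signed fold-change column per contrast named `fc_<contrast>` (as
#'   produced by [array_screen()]).
#' @param contrast Contrast name, e.g. `"dose_low"`.
#' @param p_cut P-value cut (probes strictly below pass); default 0.05.
#' @param fc_cut Fold-change magnitude cut (>= 1); default 1.5.
#' @return List of class `de_screen`: `screened` (the passing rows),
#'   `counts` (`total`, `up`, `down`), `contrast`, `p_cut`, `fc_cut`.
#' @export
de_screen <- function(results, contrast, p_cut = 0.05, fc_cut = 1.5) {
  stopifnot(p_cut > 0, p_cut <= 1, fc_cut >= 1)
  fc_col <- paste0("fc_", contrast)
  if (!fc_col %in% names(results)) {
    stop("unknown contrast: ", contrast)
  }
  fc <- results[[fc_col]]
  keep <- results$p_value < p_cut & abs(fc) >= fc_cut
  screened <- results[keep, , drop = FALSE]
  counts <- c(total = sum(keep),
              up = sum(keep & fc >= fc_cut),
              down = sum(keep & fc <= -fc_cut))
  structure(list(screened = screened, counts = counts, contrast = contrast,
                 p_cut = p_cut, fc_cut = fc_cut),
            class = "de_screen")
}

#' @export
print.de_screen <- function(x, ...) {
  cat(sprintf("DE screen [%s]: p < %g and |FC| >= %g\n",
              x$contrast, x$p_cut, x$fc_cut))
  cat(sprintf("  %d probes pass (%d up, %d down)\n",
              x$counts["total"], x$counts["up"], x$counts["down"]))
  invisible(x)
}

#' Full probe-matrix differential-expression pipeline
#'
#' Runs the array processing chain on a linear-scale probe matrix:
#' optional percentile background adjustment, log2 transform, quantile
#' normalization, a per-probe one-way ANOVA across all groups, and per-dose
#' signed fold changes against the control group. Probe-level data from a
#' mature-RNA array carries one probe per feature, so no probeset
#' summarization is applied here; use [median_polish_summarize()] first when
#' multiple probes map to one feature.
#'
#' @param values Linear-scale intensity matrix (probes x samples) with
#'   dimnames, or a `probe_matrix_sim` from [gen_probe_matrix()].
#' @param groups Named character vector mapping sample id to group label
#'   (ignored when `values` is a `probe_matrix_sim`).
#' @param control Label of the control group; every other group defines a
#'   contrast `<group> vs control`.
#' @param background `TRUE` to apply [background_adjust()] first.
#' @param bg_percentile Percentile for the background step.
#' @return Data.frame with `probe_id`, `p_value`, and per contrast
#'   `fc_<group>` and `direction_<group>` ("up"/"down"/"flat") columns.
#' @export
array_screen <- function(values, groups = NULL, control = "control",
                         background = TRUE, bg_percentile = 2) {
  if (inherits(values, "probe_matrix_sim")) {
    groups <- values$groups
    values <- values$values
  }
  values <- as.matrix(values)
  if (is.null(groups)) stop("groups are required")
  groups <- groups[colnames(values)]
  if (anyNA(groups)) stop("every sample needs a group assignment")
  if (!control %in% groups) stop("control group not present: ", control)
  if (background) values <- background_adjust(values, percentile = bg_percentile)
  norm <- quantile_normalize(log2(values))
  p <- .row_anova_p(norm, groups)
  out <- data.frame(probe_id = rownames(norm), p_value = p,
                    stringsAsFactors = FALSE)
  ctrl_mean <- rowMeans(norm[, groups == control, drop = FALSE])
  for (g in setdiff(unique(groups), control)) {
    fc <- signed_fold_change(rowMeans(norm[, groups == g, drop = FALSE]),
                             ctrl_mean)
    out[[paste0("fc_", g)]] <- fc
    out[[paste0("direction_", g)]] <-
      ifelse(fc > 1, "up", ifelse(fc < -1, "down", "flat"))
  }
  rownames(out) <- NULL
  out
}
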