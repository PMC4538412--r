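#' Delta-delta-Ct relative quantification with signed fold change
#'
#' Computes the classic `2^-ddCt` relative quantity of a target gene between
#' a treated and a control condition, normalized against one or more
#' reference genes. Per condition, `dCt` is the target's mean Ct minus the
#' reference aggregate (the arithmetic mean of the reference genes' mean Cts,
#' equivalent to a geometric mean of reference quantities on the linear
#' scale); `ddCt = dCt_treated - dCt_control`; the linear fold change
#' `2^-ddCt` is reported in the signed convention (`fc` if >= 1, else
#' `-1/fc`). Dispersion is the SD of the signed fold change over all
#' pairings of a treated-replicate dCt with a control-replicate dCt.
#'
#' @param ct Ct table: data.frame with columns `condition`, `gene_id`,
#'   `replicate`, `ct` (as from [gen_ct_table()] or [read_ct_table()]).
#' @param gene Target gene id.
#' @param reference_genes Character vector of reference gene ids.
#' @param treated,control Condition labels (defaults "treated", "control").
#' @return List of class `fold_change_result`: `gene_id`, `ddct`,
#'   `fc_signed`, `dispersion`, `n_combinations`.
#' @examples
#' tab <- gen_ct_table(c(RUNX2 = -3.25), c("RPII", "HPRT"), noise_sd = 0)
#' ddct_fold_change(tab, "RUNX2", c("RPII", "HPRT"))$fc_signed  # -3.25
#' @export
ddct_fold_change <- function(ct, gene, reference_genes,
                             treated = "treated", control = "control") {
  stopifnot(is.data.frame(ct),
            all(c("condition", "gene_id", "replicate", "ct") %in% names(ct)))
  if (length(reference_genes) == 0L) stop("at least one reference gene is required")
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0)) stop("Ct values must be finite and > 0")
  for (cond in c(control, treated)) {
    sub <- ct[ct$condition == cond, ]
    if (nrow(sub) == 0L) stop("condition absent from Ct table: ", cond)
    absent <- setdiff(c(gene, reference_genes), sub$gene_id)
    if (length(absent)) {
      stop("gene(s) absent in condition '", cond, "': ",
           paste(absent, collapse = ", "))
    }
  }
  dct_mean <- function(cond) {
    sub <- ct[ct$condition == cond, ]
    gmean <- function(g) mean(sub$ct[sub$gene_id == g])
    gmean(gene) - mean(vapply(reference_genes, gmean, numeric(1L)))
  }
  ddct <- dct_mean(treated) - dct_mean(control)
  to_signed <- function(lin) ifelse(lin >= 1, lin, -1 / lin)
  fc_signed <- to_signed(2^(-ddct))

  # replicate-level dCt: target Ct minus same-replicate reference aggregate
  dct_reps <- function(cond) {
    sub <- ct[ct$condition == cond, ]
    reps <- sort(unique(sub$replicate[sub$gene_id == gene]))
    keep <- vapply(reps, function(r) {
      all(reference_genes %in% sub$gene_id[sub$replicate == r])
    }, logical(1L))
    vapply(reps[keep], function(r) {
      sr <- sub[sub$replicate == r, ]
      sr$ct[sr$gene_id == gene][1L] -
        mean(vapply(reference_genes,
                    function(g) sr$ct[sr$gene_id == g][1L], numeric(1L)))
    }, numeric(1L))
  }
  combos <- outer(dct_reps(treated), dct_reps(control), "-")
  if (length(combos) <= 1L) {
    warning("single replicate combination; dispersion reported as 0")
    dispersion <- 0
  } else {
    dispersion <- sd(to_signed(2^(-as.vector(combos))))
  }
  structure(list(gene_id = gene, ddct = ddct, fc_signed = fc_signed,
                 dispersion = dispersion, n_combinations = length(combos)),
            class = "fold_change_result")
}

#' @export
print.fold_change_result <- function(x, ...) {
  cat(sprintf("%s: signed fold change %.4g (ddCt %.4g, dispersion %.3g, %d replicate pairings)\n",
              x$gene_id, x$fc_signed, x$ddct, x$dispersion, x$n_combinations))
  invisible(x)
}

#' Fold changes for several genes at once
#'
#' @inheritParams ddct_fold_change
#' @param genes Character vector of target gene ids.
#' @return Data.frame with one row per gene: `gene_id`, `ddct`, `fc_signed`,
#'   `dispersion`.
#' @export
ddct_table <- function(ct, genes, reference_genes,
                       treated = "treated", control = "control") {
  rows <- lapply(genes, function(g) {
    r <- ddct_fold_change(ct, g, reference_genes, treated, control)
    data.frame(gene_id = r$gene_id, ddct = r$ddct, fc_signed = r$fc_signed,
               dispersion = r$dispersion, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Interpolate the LC50 from a dose--viability curve
#'
#' Finds the first crossing of viability 0.5 and linearly interpolates the
#' dose on the log10 scale between the bracketing doses; an exact 0.5
#' observation returns its dose directly.
#'
#' @param doses Strictly increasing dose vector (mg/L).
#' @param viability Viability fractions, same length.
#' @return LC50 estimate (mg/L).
#' @examples
#' lc50_interpolate(c(10, 100), c(0.9, 0.1))  # ~31.62
#' @export
lc50_interpolate <- function(doses, viability) {
  stopifnot(length(doses) == length(viability), length(doses) >= 2L)
  if (any(diff(doses) <= 0)) stop("doses must be strictly increasing")
  if (any(doses <= 0)) stop("doses must be positive for log interpolation")
  hit <- which(viability == 0.5)
  cross <- which((viability[-length(viability)] - 0.5) *
                   (viability[-1L] - 0.5) < 0)
  if (length(hit) && (!length(cross) || hit[1L] <= cross[1L])) {
    return(doses[hit[1L]])
  }
  if (!length(cross)) stop("viability never crosses 0.5; LC50 undefined")
  i <- cross[1L]
  l1 <- log10(doses[i]); l2 <- log10(doses[i + 1L])
  v1 <- viability[i]; v2 <- viability[i + 1L]
  10^(l1 + (0.5 - v1) * (l2 - l1) / (v2 - v1))
}
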