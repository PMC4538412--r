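# Synthetic inputs with known ground truth for every pipeline stage.
# All generators take an explicit seed and are byte-reproducible.

.BASES <- c("A", "C", "G", "U")

# First-order Markov background: uniform transition weights except that the
# weight of G after U is multiplied by ug_enrichment, making the UG
# dinucleotide frequency controllable (1 = neutral).
.markov_background <- function(len, ug_enrichment = 1) {
  out <- character(len)
  out[1L] <- sample(.BASES, 1L)
  w_after_u <- c(1, 1, ug_enrichment, 1)  # A C G U
  for (i in seq_len(len - 1L) + 1L) {
    w <- if (out[i - 1L] == "U") w_after_u else rep(1, 4)
    out[i] <- sample(.BASES, 1L, prob = w)
  }
  paste(out, collapse = "")
}

# Sample non-overlapping start positions (1-based) for motifs of the given
# widths inside a sequence of length len; some positions may carry window
# constraints (range of allowed starts). Returns NULL when placement fails.
.place_motifs <- function(len, widths, constraints) {
  taken <- logical(len)
  starts <- integer(length(widths))
  for (k in seq_along(widths)) {
    w <- widths[k]
    lo <- max(1L, constraints[[k]][1L])
    hi <- min(len - w + 1L, constraints[[k]][2L])
    if (hi < lo) return(NULL)
    ok <- FALSE
    for (try in 1:50) {
      s <- if (hi == lo) lo else sample(lo:hi, 1L)
      if (!any(taken[s:(s + w - 1L)])) { ok <- TRUE; break }
    }
    if (!ok) return(NULL)
    starts[k] <- s
    taken[s:(s + w - 1L)] <- TRUE
  }
  starts
}

#' Generate a synthetic C/D-box snoRNA sequence set
#'
#' Draws a set of RNA sequences with planted C-box (`UGAUGA`) and D-box
#' (`CUGA`) motifs on a Markov background, emulating a snoRNA probe set with
#' a main length mode plus a group of long outliers. The first planted C-box
#' is placed in the 5'-terminal window and one D-box in the 3'-terminal
#' window, mirroring the canonical box architecture; remaining D-boxes are
#' internal. After planting, each sequence is re-scanned with [scan_boxes()]
#' and redrawn until the found motif counts equal the planted counts, so no
#' accidental motif survives at junctions or in the background.
#'
#' @param n_core Number of sequences drawn from `core_length_range`.
#' @param n_outliers Number of long sequences drawn from
#'   `outlier_length_range`.
#' @param core_length_range,outlier_length_range Disjoint integer length
#'   intervals (nt); defaults 48--112 and 114--237.
#' @param c_box_count_per_seq C-boxes planted in every sequence (default 1).
#' @param d_box_counts Integer vector, one D-box count per sequence
#'   (length `n_core + n_outliers`); defaults to 1 per core sequence and 2
#'   per outlier.
#' @param ug_enrichment Relative weight of G following U in the background
#'   chain (1 = uniform background).
#' @param seed Integer seed; identical seeds give identical output.
#' @return Data.frame with columns `id`, `sequence`, `length`, `is_outlier`,
#'   `c_box_count`, `d_box_count` (the planted truth).
#' @examples
#' gen_snorna_set(3, 1, d_box_counts = c(1, 1, 1, 3), seed = 7)
#' @export
gen_snorna_set <- function(n_core, n_outliers,
                           core_length_range = c(48L, 112L),
                           outlier_length_range = c(114L, 237L),
                           c_box_count_per_seq = 1L,
                           d_box_counts = NULL,
                           ug_enrichment = 1,
                           seed = 1L) {
  n <- n_core + n_outliers
  if (is.null(d_box_counts)) {
    d_box_counts <- c(rep(1L, n_core), rep(2L, n_outliers))
  }
  stopifnot(n_core >= 0, n_outliers >= 0,
            length(core_length_range) == 2L, length(outlier_length_range) == 2L,
            c_box_count_per_seq >= 0, all(d_box_counts >= 0),
            ug_enrichment >= 0)
  if (length(d_box_counts) != n) {
    stop("d_box_counts must have one entry per sequence (n_core + n_outliers)")
  }
  if (min(core_length_range) < 6L || min(outlier_length_range) < 6L) {
    stop("length ranges must admit the longest motif (6 nt)")
  }
  if (max(core_length_range) >= min(outlier_length_range) &&
      max(outlier_length_range) >= min(core_length_range)) {
    stop("core and outlier length ranges must be disjoint")
  }
  if (n == 0L) {
    return(data.frame(id = character(), sequence = character(),
                      length = integer(), is_outlier = logical(),
                      c_box_count = integer(), d_box_count = integer(),
                      stringsAsFactors = FALSE))
  }
  set.seed(seed)
  is_outlier <- c(rep(FALSE, n_core), rep(TRUE, n_outliers))
  seqs <- character(n)
  lens <- integer(n)
  for (i in seq_len(n)) {
    rng <- if (is_outlier[i]) outlier_length_range else core_length_range
    n_c <- c_box_count_per_seq
    n_d <- d_box_counts[i]
    need <- 6L * n_c + 4L * n_d
    if (need > rng[2L]) {
      stop(sprintf("impossible spec: %d motif nt cannot fit in length <= %d",
                   need, rng[2L]))
    }
    lo <- max(rng[1L], need)
    len <- if (lo >= rng[2L]) rng[2L] else sample(lo:rng[2L], 1L)
    widths <- c(rep(6L, n_c), rep(4L, n_d))
    motifs <- c(rep("UGAUGA", n_c), rep("CUGA", n_d))
    # first C-box in the 5' window, first D-box ending in the 3' window
    constraints <- rep(list(c(1L, len)), n_c + n_d)
    if (n_c >= 1L) constraints[[1L]] <- c(1L, 10L)
    if (n_d >= 1L) constraints[[n_c + 1L]] <- c(len - 14L, len - 3L)
    done <- FALSE
    for (attempt in 1:500) {
      starts <- .place_motifs(len, widths, constraints)
      if (is.null(starts)) next
      s <- strsplit(.markov_background(len, ug_enrichment), "", fixed = TRUE)[[1L]]
      for (k in seq_along(starts)) {
        s[starts[k]:(starts[k] + widths[k] - 1L)] <-
          strsplit(motifs[k], "", fixed = TRUE)[[1L]]
      }
      cand <- paste(s, collapse = "")
      found <- scan_boxes(cand)
      if (sum(found$box_type == "C") == n_c &&
          sum(found$box_type == "D") == n_d) {
        seqs[i] <- cand
        lens[i] <- len
        done <- TRUE
        break
      }
    }
    if (!done) {
      stop(sprintf("could not plant %d C-box(es) and %d D-box(es) in %d nt",
                   n_c, n_d, len))
    }
  }
  data.frame(id = sprintf("sno%03d", seq_len(n)), sequence = seqs,
             length = lens, is_outlier = is_outlier,
             c_box_count = rep(as.integer(c_box_count_per_seq), n),
             d_box_count = as.integer(d_box_counts),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic probe-intensity matrix with planted differential probes
#'
#' Simulates a 3-group (control, low dose, high dose) single-channel array
#' experiment: per-probe baseline levels on the log2 scale, Gaussian sample
#' noise, and a chosen fraction of probes shifted by `effect_log2` (random
#' sign, same direction at both doses) in the treated groups. Intensities are
#' returned on the linear scale, as exported probe-level data would be.
#'
#' @param n_probes Number of probes.
#' @param group_sizes Integer vector of length 3: samples in control, low
#'   dose, high dose (all >= 1).
#' @param de_fraction Fraction of probes planted as differential, in `[0,1]`.
#' @param effect_log2 Planted log2 shift in treated groups.
#' @param noise_sd Per-sample Gaussian noise SD on the log2 scale (> 0).
#' @param seed Integer seed.
#' @return List of class `probe_matrix_sim`: `values` (linear-scale matrix,
#'   probes x samples), `groups` (named character vector sample -> group,
#'   groups `control`, `dose_low`, `dose_high`), `truth` (data.frame
#'   `probe_id`, `direction` of planted probes).
#' @export
gen_probe_matrix <- function(n_probes, group_sizes = c(3L, 3L, 3L),
                             de_fraction = 0.1, effect_log2 = 2,
                             noise_sd = 0.25, seed = 1L) {
  stopifnot(n_probes >= 1, length(group_sizes) == 3L,
            de_fraction >= 0, de_fraction <= 1, noise_sd > 0)
  if (any(group_sizes < 1L)) stop("every group needs at least one sample")
  set.seed(seed)
  grp_names <- c("control", "dose_low", "dose_high")
  groups <- rep(grp_names, times = group_sizes)
  sample_ids <- unlist(lapply(seq_along(grp_names), function(g) {
    sprintf("%s_%d", grp_names[g], seq_len(group_sizes[g]))
  }))
  names(groups) <- sample_ids
  probe_ids <- sprintf("probe_%04d", seq_len(n_probes))

  base <- runif(n_probes, 4, 12)
  log2m <- matrix(base, n_probes, length(groups)) +
    matrix(rnorm(n_probes * length(groups), 0, noise_sd),
           n_probes, length(groups))
  n_de <- round(n_probes * de_fraction)
  truth <- data.frame(probe_id = character(), direction = character(),
                      stringsAsFactors = FALSE)
  if (n_de > 0L) {
    de_idx <- sample(n_probes, n_de)
    dir <- sample(c(1, -1), n_de, replace = TRUE)
    treated <- groups != "control"
    log2m[de_idx, treated] <- log2m[de_idx, treated] + dir * effect_log2
    truth <- data.frame(probe_id = probe_ids[de_idx],
                        direction = ifelse(dir > 0, "up", "down"),
                        stringsAsFactors = FALSE)
  }
  values <- 2^log2m
  dimnames(values) <- list(probe_ids, sample_ids)
  structure(list(values = values, groups = groups, truth = truth),
            class = "probe_matrix_sim")
}

#' @export
print.probe_matrix_sim <- function(x, ...) {
  cat(sprintf("synthetic probe matrix: %d probes x %d samples (%s), %d planted DE probes\n",
              nrow(x$values), ncol(x$values),
              paste(table(x$groups)[unique(x$groups)], collapse = "/"),
              nrow(x$truth)))
  invisible(x)
}

#' Generate a synthetic qPCR Ct table with known fold changes
#'
#' Builds a replicate-level Ct table for a control and a treated condition in
#' which each target gene's treated Ct is shifted by exactly
#' `-log2(linear fold change)` relative to control while reference genes stay
#' flat, so the delta-delta-Ct pipeline recovers `true_fc_signed` exactly at
#' `noise_sd = 0`.
#'
#' @param true_fc_signed Named numeric vector of signed fold changes
#'   (`|fc| >= 1`; negative = down-regulated, reported as `-1/ratio`).
#' @param reference_genes Character vector of reference gene ids (>= 1,
#'   disjoint from the targets).
#' @param replicates Replicates per condition and gene (>= 1).
#' @param noise_sd Gaussian Ct noise SD in cycles (>= 0).
#' @param seed Integer seed.
#' @return Data.frame with columns `sample_id`, `condition`
#'   ("control"/"treated"), `gene_id`, `replicate`, `ct`.
#' @export
gen_ct_table <- function(true_fc_signed, reference_genes,
                         replicates = 3L, noise_sd = 0.1, seed = 1L) {
  genes <- names(true_fc_signed)
  if (is.null(genes) || any(!nzchar(genes))) {
    stop("true_fc_signed must be a named vector")
  }
  if (length(reference_genes) == 0L) stop("at least one reference gene is required")
  if (any(reference_genes %in% genes)) {
    stop("reference genes must be disjoint from target genes")
  }
  stopifnot(replicates >= 1L, noise_sd >= 0, all(abs(true_fc_signed) >= 1))
  set.seed(seed)
  base_ref <- setNames(runif(length(reference_genes), 16, 22), reference_genes)
  base_tgt <- setNames(runif(length(genes), 22, 30), genes)
  linear <- ifelse(true_fc_signed >= 0, true_fc_signed, -1 / true_fc_signed)
  ddct <- -log2(linear)  # treated-minus-control Ct shift for targets

  rows <- list()
  for (cond in c("control", "treated")) {
    for (g in c(reference_genes, genes)) {
      mu <- if (g %in% reference_genes) base_ref[[g]] else {
        base_tgt[[g]] + if (cond == "treated") ddct[[g]] else 0
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("%s_r%d", cond, seq_len(replicates)),
        condition = cond, gene_id = g, replicate = seq_len(replicates),
        ct = mu + rnorm(replicates, 0, noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic dose--viability table
#'
#' Hill-type viability decay `v(d) = 1 / (1 + (d / lc50)^slope)`, so the
#' viability at `d = lc50` is exactly 0.5 and [lc50_interpolate()] has a known
#' truth. Default doses span the 10--250 mg/L exposure range typical of
#' sodium fluoride cytotoxicity assays, with a true LC50 of 40 mg/L.
#'
#' @param doses Increasing dose vector (mg/L).
#' @param lc50 True LC50 (mg/L).
#' @param slope Hill slope (> 0).
#' @param noise_sd Gaussian noise SD on the viability fraction.
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return Data.frame with columns `dose_mg_l`, `viability`.
#' @export
gen_viability_table <- function(doses = c(10, 20, 40, 80, 160, 250),
                                lc50 = 40, slope = 1.5, noise_sd = 0,
                                seed = 1L) {
  stopifnot(all(diff(doses) > 0), lc50 > 0, slope > 0, noise_sd >= 0)
  v <- 1 / (1 + (doses / lc50)^slope)
  if (noise_sd > 0) {
    set.seed(seed)
    v <- pmin(1.2, pmax(0, v + rnorm(length(doses), 0, noise_sd)))
  }
  data.frame(dose_mg_l = doses, viability = v)
}
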