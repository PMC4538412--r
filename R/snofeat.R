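#' Normalize a raw nucleotide string to the RNA alphabet
#'
#' Uppercases the input and converts T to U. Any character outside
#' `ACGTU` (plus `N` when `allow_n = TRUE`) is rejected with an error naming
#' the first offending 1-based position.
#'
#' @param raw Non-empty character scalar.
#' @param allow_n Logical; permit `N` (kept as `N`, excluded from motif and
#'   dinucleotide windows by the downstream scanners).
#' @return A character scalar over `ACGU` (and possibly `N`).
#' @examples
#' normalize_sequence("acgt")   # "ACGU"
#' @export
normalize_sequence <- function(raw, allow_n = FALSE) {
  stopifnot(is.character(raw), length(raw) == 1L)
  if (!nzchar(raw)) stop("sequence is empty")
  s <- chartr("t", "u", toupper(raw))
  s <- chartr("T", "U", s)
  allowed <- c("A", "C", "G", "U", if (allow_n) "N")
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% allowed)
  if (length(bad)) {
    stop(sprintf("disallowed character '%s' at position %d", chars[bad[1L]], bad[1L]))
  }
  s
}

#' Scan a snoRNA sequence for C-box and D-box motifs
#'
#' Reports every occurrence (overlaps included) of the C-box `UGAUGA` and the
#' D-box `CUGA` with 0-based half-open coordinates, and classifies each
#' occurrence as 5'-terminal, 3'-terminal or internal. The C-box of a mature
#' C/D-box snoRNA sits near the 5' end and the D-box near the 3' end;
#' additional internal copies (notably internal D-boxes) occur and are
#' reported with `position_class = "internal"`.
#'
#' @param seq Normalized RNA string (see [normalize_sequence()]).
#' @param terminal_window Width in nt of the terminal windows: a box starting
#'   before `terminal_window` is `terminal_5p`; one ending after
#'   `length - terminal_window` is `terminal_3p` (5' takes precedence when the
#'   sequence is short enough for both windows to apply).
#' @return A data.frame with columns `box_type` ("C"/"D"), `motif`, `start`,
#'   `end` (0-based half-open) and `position_class`; zero rows when no motif
#'   occurs.
#' @examples
#' scan_boxes("CUGA")
#' @export
scan_boxes <- function(seq, terminal_window = 15L) {
  seq <- normalize_sequence(seq, allow_n = TRUE)
  len <- nchar(seq)
  subject <- Biostrings::RNAString(seq)
  one <- function(box_type, motif) {
    hits <- Biostrings::matchPattern(motif, subject, fixed = TRUE)
    if (length(hits) == 0L) return(NULL)
    start0 <- Biostrings::start(hits) - 1L
    end0 <- Biostrings::end(hits)
    data.frame(box_type = box_type, motif = motif,
               start = start0, end = end0,
               position_class = ifelse(
                 start0 < terminal_window, "terminal_5p",
                 ifelse(end0 > len - terminal_window, "terminal_3p", "internal")),
               stringsAsFactors = FALSE)
  }
  out <- rbind(one("C", "UGAUGA"), one("D", "CUGA"))
  if (is.null(out)) {
    out <- data.frame(box_type = character(), motif = character(),
                      start = integer(), end = integer(),
                      position_class = character(), stringsAsFactors = FALSE)
  } else {
    out <- out[order(out$start, out$box_type), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Count overlapping dinucleotides
#'
#' Counts step-1 overlapping windows equal to each requested dinucleotide.
#' Windows containing `N` never match.
#'
#' @param seq Normalized RNA string.
#' @param pairs Character vector of 2-nt motifs; defaults to UG and CG, the
#'   pair contrasted in C/D-box snoRNA composition analysis.
#' @return Named integer vector of counts.
#' @examples
#' dinucleotide_counts("UGUG")  # UG 2, CG 0
#' @export
dinucleotide_counts <- function(seq, pairs = c("UG", "CG")) {
  seq <- normalize_sequence(seq, allow_n = TRUE)
  n <- nchar(seq)
  if (n < 2L) {
    warning("sequence shorter than 2 nt; all dinucleotide counts are 0")
    return(setNames(integer(length(pairs)), pairs))
  }
  windows <- substring(seq, 1:(n - 1L), 2:n)
  setNames(vapply(pairs, function(p) sum(windows == p), integer(1L)), pairs)
}

#' Interquartile-range outlier bounds for snoRNA lengths
#'
#' Computes the first and third quartiles of a length distribution and the
#' Tukey fences `lower = q25 - 1.5 * IQR`, `upper = q75 + 1.5 * IQR` used to
#' flag unusually long (or short) probe sequences.
#'
#' @param lengths Numeric vector of at least 4 sequence lengths (nt).
#' @param quantile_type Quantile estimator passed to [stats::quantile()]
#'   (1--9). Default 7, linear interpolation between order statistics.
#' @return An object of class `length_outlier_bounds`: a list with `q25`,
#'   `q75`, `iqr`, `lower`, `upper`, `n` and `quantile_type`.
#' @seealso [flag_length_outliers()], [bounds_estimator_sweep()]
#' @examples
#' length_outlier_bounds(c(48, 70, 75, 80, 88, 90, 120))
#' @export
length_outlier_bounds <- function(lengths, quantile_type = 7L) {
  lengths <- as.numeric(lengths)
  if (length(lengths) < 4L) stop("at least 4 lengths are required")
  if (anyNA(lengths)) stop("lengths contain NA")
  q <- quantile(lengths, c(0.25, 0.75), type = quantile_type, names = FALSE)
  bounds_from_quartiles(q[1L], q[2L], n = length(lengths),
                        quantile_type = quantile_type)
}

#' Outlier bounds from pre-computed quartiles
#'
#' Applies the Tukey fence arithmetic to quartiles obtained elsewhere (for
#' example quartiles reported for a probe set whose raw lengths are not at
#' hand).
#'
#' @param q25,q75 First and third quartile (nt).
#' @param n Optional number of observations behind the quartiles.
#' @param quantile_type Optional estimator label carried through.
#' @return An object of class `length_outlier_bounds`.
#' @examples
#' bounds_from_quartiles(70.995, 87.745)  # lower 45.87, upper 112.87
#' @export
bounds_from_quartiles <- function(q25, q75, n = NA_integer_, quantile_type = NA) {
  if (q75 < q25) stop("q75 must be >= q25")
  iqr <- q75 - q25
  structure(list(q25 = q25, q75 = q75, iqr = iqr,
                 lower = q25 - 1.5 * iqr, upper = q75 + 1.5 * iqr,
                 n = n, quantile_type = quantile_type),
            class = "length_outlier_bounds")
}

#' @export
print.length_outlier_bounds <- function(x, ...) {
  cat("IQR length-outlier bounds",
      if (!is.na(x$n)) sprintf(" (n = %d)", x$n), "\n", sep = "")
  cat(sprintf("  q25 = %.4g, q75 = %.4g, IQR = %.4g\n", x$q25, x$q75, x$iqr))
  cat(sprintf("  lower = %.4g, upper = %.4g\n", x$lower, x$upper))
  invisible(x)
}

#' Tukey-fence bounds under every standard quantile estimator
#'
#' Recomputes [length_outlier_bounds()] for quantile types 1 through 9, so a
#' reported pair of fences can be traced back to the estimator that produced
#' it.
#'
#' @inheritParams length_outlier_bounds
#' @return Data.frame with one row per estimator type.
#' @export
bounds_estimator_sweep <- function(lengths) {
  rows <- lapply(1:9, function(ty) {
    b <- length_outlier_bounds(lengths, quantile_type = ty)
    data.frame(quantile_type = ty, q25 = b$q25, q75 = b$q75,
               iqr = b$iqr, lower = b$lower, upper = b$upper)
  })
  do.call(rbind, rows)
}

#' Flag snoRNA length outliers
#'
#' Flags sequences outside the IQR fences. By default only the long side is
#' used (`length > upper`), matching the practice of isolating unusually long
#' probes for homogeneity analysis; `side = "both"` also flags
#' `length < lower`. When a bare `threshold` is supplied instead of bounds,
#' the comparison is `length >= threshold`.
#'
#' @param lengths Integer vector of sequence lengths, or a character vector of
#'   sequences (lengths are taken with [nchar()]).
#' @param bounds A `length_outlier_bounds` object.
#' @param threshold Optional explicit length threshold; overrides `bounds`.
#' @param side `"upper"` (default) or `"both"`.
#' @return Logical vector, same order as the input.
#' @export
flag_length_outliers <- function(lengths, bounds = NULL, threshold = NULL,
                                 side = c("upper", "both")) {
  side <- match.arg(side)
  if (is.character(lengths)) lengths <- nchar(lengths)
  lengths <- as.numeric(lengths)
  if (!is.null(threshold)) {
    return(lengths >= threshold)
  }
  if (is.null(bounds)) stop("supply either bounds or threshold")
  stopifnot(inherits(bounds, "length_outlier_bounds"))
  out <- lengths > bounds$upper
  if (side == "both") out <- out | lengths < bounds$lower
  out
}

# pair the two rows of an alignment, dropping gap columns
.aligned_columns <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  keep <- ca != "-" & cb != "-" & ca != "N" & cb != "N"
  list(a = ca[keep], b = cb[keep])
}

.is_transition <- function(x, y) {
  (x == "A" & y == "G") | (x == "G" & y == "A") |
    (x == "C" & y == "U") | (x == "U" & y == "C")
}

#' Condition signalled when the K2P log arguments leave their domain
#' @noRd
.saturation_error <- function(P, Q) {
  stop(structure(class = c("fluorosnc_saturation", "error", "condition"),
                 list(message = sprintf(
                   "K2P distance undefined (saturated): P = %.4g, Q = %.4g", P, Q),
                   call = sys.call(-1L))))
}

#' Kimura two-parameter distance between two RNA sequences
#'
#' Estimates the K2P substitution distance, which models transitions
#' (A<->G, C<->U) and transversions at different rates:
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` with `P` and `Q` the
#' transition and transversion proportions over compared columns. Sequences
#' of unequal length (or any pair under the default `aligner = "global"`) are
#' first aligned with a global Needleman--Wunsch aligner (match +1, mismatch
#' -1, gap -2 per position, ties resolved toward the diagonal); columns
#' containing a gap are excluded from the proportions.
#'
#' @param a,b RNA strings (normalized with [normalize_sequence()] on entry).
#' @param aligner `"global"` (default) to align first, `"none"` to compare
#'   position-by-position (requires equal lengths).
#' @return Object of class `k2p_result`: list with `p_transitions`,
#'   `q_transversions`, `sites_compared`, `distance`.
#' @section Errors: when `1 - 2P - Q <= 0` or `1 - 2Q <= 0` the distance is
#'   undefined and an error of class `fluorosnc_saturation` is raised;
#'   zero comparable columns is an error.
#' @examples
#' k2p_distance("ACGU", "ACGU")$distance  # 0
#' @export
k2p_distance <- function(a, b, aligner = c("global", "none")) {
  aligner <- match.arg(aligner)
  a <- normalize_sequence(a, allow_n = TRUE)
  b <- normalize_sequence(b, allow_n = TRUE)
  if (aligner == "none") {
    if (nchar(a) != nchar(b)) stop("aligner = \"none\" requires equal lengths")
    al <- list(a = a, b = b)
  } else {
    al <- .nw_align_cpp(a, b)
  }
  cols <- .aligned_columns(al$a, al$b)
  n <- length(cols$a)
  if (n == 0L) stop("no comparable (gap-free) columns")
  diff <- cols$a != cols$b
  ts <- diff & .is_transition(cols$a, cols$b)
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) .saturation_error(P, Q)
  structure(list(p_transitions = P, q_transversions = Q,
                 sites_compared = n,
                 distance = -0.5 * log(w1) - 0.25 * log(w2)),
            class = "k2p_result")
}

#' @export
print.k2p_result <- function(x, ...) {
  cat(sprintf("K2P distance = %.6g (P = %.4g, Q = %.4g over %d sites)\n",
              x$distance, x$p_transitions, x$q_transversions, x$sites_compared))
  invisible(x)
}

#' Mean pairwise Kimura two-parameter distance
#'
#' Arithmetic mean of [k2p_distance()] over all unordered pairs of a sequence
#' set; used as a homogeneity summary of, for example, the long-outlier
#' snoRNA probes. Pairs whose distance is saturated (undefined) are excluded
#' from the mean and counted.
#'
#' @param seqs Character vector (length >= 2) of RNA sequences, optionally
#'   named.
#' @inheritParams k2p_distance
#' @return Numeric scalar, with attributes `n_pairs` (pairs averaged) and
#'   `n_saturated` (pairs excluded).
#' @export
mean_pairwise_k2p <- function(seqs, aligner = "global") {
  seqs <- as.character(seqs)
  if (length(seqs) < 2L) stop("at least 2 sequences are required")
  idx <- combn(length(seqs), 2L)
  d <- numeric(0)
  n_sat <- 0L
  for (k in seq_len(ncol(idx))) {
    r <- tryCatch(
      k2p_distance(seqs[idx[1L, k]], seqs[idx[2L, k]], aligner = aligner)$distance,
      fluorosnc_saturation = function(e) NA_real_)
    if (is.na(r)) n_sat <- n_sat + 1L else d <- c(d, r)
  }
  if (!length(d)) stop("all pairs saturated; mean K2P undefined")
  structure(mean(d), n_pairs = length(d), n_saturated = n_sat)
}

#' Per-sequence C/D-box feature records
#'
#' Builds the feature table underlying the snoRNA analysis: length, C-box and
#' D-box counts, UG and CG dinucleotide counts, and a length-outlier flag.
#'
#' @param seqs Named character vector of RNA sequences (names are ids).
#' @param bounds Optional `length_outlier_bounds`; when `NULL`, bounds are
#'   computed from the lengths of `seqs` themselves (requires >= 4 sequences).
#' @param regulation Optional data.frame with columns `id`, `dose`,
#'   `direction` ("up"/"down"/"flat") joined onto the records.
#' @param terminal_window Passed to [scan_boxes()].
#' @return Data.frame with one row per sequence: `id`, `length`,
#'   `c_box_count`, `d_box_count`, `ug_count`, `cg_count`,
#'   `is_length_outlier`.
#' @export
snorna_features <- function(seqs, bounds = NULL, regulation = NULL,
                            terminal_window = 15L) {
  seqs <- setNames(as.character(seqs), names(seqs))
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    names(seqs) <- sprintf("seq%03d", seq_along(seqs))
  }
  lens <- nchar(seqs)
  if (is.null(bounds)) bounds <- length_outlier_bounds(lens)
  rows <- lapply(seq_along(seqs), function(i) {
    boxes <- scan_boxes(seqs[[i]], terminal_window = terminal_window)
    din <- dinucleotide_counts(seqs[[i]])
    data.frame(id = names(seqs)[i], length = lens[i],
               c_box_count = sum(boxes$box_type == "C"),
               d_box_count = sum(boxes$box_type == "D"),
               ug_count = unname(din["UG"]), cg_count = unname(din["CG"]),
               is_length_outlier = unname(flag_length_outliers(lens[i], bounds)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "bounds") <- bounds
  if (!is.null(regulation)) out <- merge(out, regulation, by = "id", sort = FALSE)
  out
}

#' D-box multiplicity versus regulation direction among length outliers
#'
#' Cross-tabulates, over the length-outlier sequences only, D-box multiplicity
#' (two or more D-boxes vs fewer) against regulation direction (down vs not
#' down), and reports the downregulated fraction in each stratum. This is the
#' summary used to ask whether long snoRNAs carrying extra D-boxes respond
#' differently to treatment.
#'
#' @param records Feature data.frame from [snorna_features()] carrying a
#'   `direction` column (and optionally a `dose` column).
#' @param dose Optional dose label to filter the `dose` column on.
#' @return List of class `dbox_regulation_summary`: `table` (2x2 integer
#'   matrix), `down_fraction` (named numeric, strata `">=2"` and `"<2"`),
#'   `n_outliers`.
#' @export
dbox_regulation_summary <- function(records, dose = NULL) {
  stopifnot(is.data.frame(records))
  if (!is.null(dose) && "dose" %in% names(records)) {
    records <- records[records$dose == dose, , drop = FALSE]
  }
  if (!"direction" %in% names(records) || anyNA(records$direction)) {
    missing_ids <- if ("direction" %in% names(records)) {
      records$id[is.na(records$direction)]
    } else records$id
    stop("missing regulation calls for: ", paste(missing_ids, collapse = ", "))
  }
  out <- records[records$is_length_outlier, , drop = FALSE]
  strata <- factor(ifelse(out$d_box_count >= 2, ">=2", "<2"),
                   levels = c(">=2", "<2"))
  down <- factor(ifelse(out$direction == "down", "down", "not_down"),
                 levels = c("down", "not_down"))
  tab <- table(d_box = strata, regulation = down)
  if (nrow(out) == 0L) warning("no length outliers; summary table is all zeros")
  frac <- vapply(levels(strata), function(s) {
    n <- sum(strata == s)
    if (n == 0L) NA_real_ else sum(strata == s & down == "down") / n
  }, numeric(1L))
  structure(list(table = tab, down_fraction = frac, n_outliers = nrow(out)),
            class = "dbox_regulation_summary")
}

#' @export
print.dbox_regulation_summary <- function(x, ...) {
  cat(sprintf("D-box multiplicity vs regulation, %d length outlier(s)\n",
              x$n_outliers))
  print(x$table)
  cat("down-regulated fraction: >=2 D-boxes ",
      format(x$down_fraction[">=2"]), ", <2 D-boxes ",
      format(x$down_fraction["<2"]), "\n", sep = "")
  invisible(x)
}
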