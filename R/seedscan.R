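.rna_complement <- function(s) chartr("ACGU", "UGCA", s)

.rna_revcomp <- function(s) {
  paste(rev(strsplit(.rna_complement(s), "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Extract the seed region of a miRNA
#'
#' Returns nucleotides 2--8 (1-based from the 5' end), the 7-nt seed whose
#' complementarity to a UTR defines canonical miRNA target sites.
#'
#' @param mirna RNA string of length >= 8.
#' @return 7-nt character scalar.
#' @examples
#' extract_seed("UGAGGUAGUAGGUUGUAUAGUU")  # "GAGGUAG" (let-7a)
#' @export
extract_seed <- function(mirna) {
  mirna <- normalize_sequence(mirna)
  if (nchar(mirna) < 8L) stop("miRNA must be at least 8 nt to have a seed")
  substr(mirna, 2L, 8L)
}

#' Find canonical miRNA seed-complementary sites in a UTR
#'
#' Scans the UTR (given 5' to 3') for exact Watson--Crick reverse complements
#' of the miRNA seed (no G:U wobble) and classifies each site:
#'
#' * `6mer` — match to miRNA positions 2--7;
#' * `7mer-m8` — 6mer extended by a match to position 8;
#' * `7mer-A1` — 6mer plus an adenosine opposite miRNA position 1;
#' * `8mer` — both the position-8 match and the A1 adenosine.
#'
#' Each 6mer-core window is reported once with its best (most specific) type;
#' overlapping windows are all reported. Coordinates are 0-based half-open on
#' the UTR as provided; strand/orientation handling is the caller's
#' responsibility.
#'
#' @param utr UTR sequence (RNA or DNA letters; normalized on entry).
#' @param mirna Mature miRNA sequence, length >= 8.
#' @param utr_id,mirna_id Identifiers carried into the output.
#' @return Data.frame with columns `mirna_id`, `target_id`, `site_start`,
#'   `site_end`, `site_type`, `paired_seed` (the miRNA positions the site
#'   pairs: 2--8 for m8 types, 2--7 otherwise); zero rows when no site.
#' @export
find_seed_sites <- function(utr, mirna, utr_id = "utr", mirna_id = "mirna") {
  utr <- normalize_sequence(utr, allow_n = TRUE)
  mirna <- normalize_sequence(mirna)
  if (nchar(mirna) < 8L) stop("miRNA must be at least 8 nt")
  seed27 <- substr(mirna, 2L, 7L)
  seed28 <- substr(mirna, 2L, 8L)
  core <- .rna_revcomp(seed27)            # target-strand match to positions 2-7
  m8c <- .rna_complement(substr(mirna, 8L, 8L))
  n <- nchar(utr)
  if (n < 6L) {
    return(data.frame(mirna_id = character(), target_id = character(),
                      site_start = integer(), site_end = integer(),
                      site_type = character(), paired_seed = character(),
                      stringsAsFactors = FALSE))
  }
  starts <- which(substring(utr, 1:(n - 5L), 6:n) == core)  # 1-based
  rows <- lapply(starts, function(i) {
    has_m8 <- i > 1L && substr(utr, i - 1L, i - 1L) == m8c
    has_a1 <- i + 6L <= n && substr(utr, i + 6L, i + 6L) == "A"
    if (has_m8 && has_a1) {
      type <- "8mer";    s0 <- i - 2L; e0 <- i + 6L; paired <- seed28
    } else if (has_m8) {
      type <- "7mer-m8"; s0 <- i - 2L; e0 <- i + 5L; paired <- seed28
    } else if (has_a1) {
      type <- "7mer-A1"; s0 <- i - 1L; e0 <- i + 6L; paired <- seed27
    } else {
      type <- "6mer";    s0 <- i - 1L; e0 <- i + 5L; paired <- seed27
    }
    data.frame(mirna_id = mirna_id, target_id = utr_id,
               site_start = s0, site_end = e0, site_type = type,
               paired_seed = paired, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(mirna_id = character(), target_id = character(),
               site_start = integer(), site_end = integer(),
               site_type = character(), paired_seed = character(),
               stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Scan every miRNA against every UTR
#'
#' @param mirnas,utrs Named character vectors of sequences (e.g. from
#'   [read_fasta_set()]).
#' @return Row-bound data.frame of [find_seed_sites()] results over all
#'   miRNA/UTR pairs.
#' @export
scan_seed_sets <- function(mirnas, utrs) {
  stopifnot(length(mirnas) >= 1L, length(utrs) >= 1L)
  if (is.null(names(mirnas))) names(mirnas) <- sprintf("mir%02d", seq_along(mirnas))
  if (is.null(names(utrs))) names(utrs) <- sprintf("utr%02d", seq_along(utrs))
  out <- list()
  for (m in names(mirnas)) {
    for (u in names(utrs)) {
      out[[length(out) + 1L]] <-
        find_seed_sites(utrs[[u]], mirnas[[m]], utr_id = u, mirna_id = m)
    }
  }
  do.call(rbind, out)
}
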