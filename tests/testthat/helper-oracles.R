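# Independent oracles used across tests: naive substring scans, a reference
# quantile normalizer, base-by-base seed-pairing rules, random sequences.

random_rna <- function(len, prob = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE, prob = prob),
        collapse = "")
}

# every (overlapping) occurrence of motif, 0-based starts
brute_force_starts <- function(seq, motif) {
  n <- nchar(seq)
  w <- nchar(motif)
  if (n < w) return(integer())
  hits <- which(vapply(1:(n - w + 1L),
                       function(i) substr(seq, i, i + w - 1L) == motif,
                       logical(1L)))
  hits - 1L
}

# mean-of-order-statistics quantile normalization, ties averaged; written
# rank-by-rank, independently of limma
ref_quantile_normalize <- function(m) {
  target <- rowMeans(apply(m, 2L, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    r <- rank(m[, j], ties.method = "min")
    # mean target value over the ranks each tie group occupies
    for (v in unique(m[, j])) {
      idx <- which(m[, j] == v)
      occupied <- r[idx[1L]] + seq_along(idx) - 1L
      out[idx, j] <- mean(target[occupied])
    }
  }
  out
}

RNA_COMP <- c(A = "U", C = "G", G = "C", U = "A")

# seed-site enumeration straight from the pairing rules, base by base
brute_force_seed_sites <- function(utr, mirna) {
  u <- strsplit(utr, "")[[1L]]
  m <- strsplit(mirna, "")[[1L]]
  n <- length(u)
  out <- list()
  for (s in 1:(n - 5L)) {
    ok6 <- all(vapply(1:6, function(j) u[s + j - 1L] == RNA_COMP[[m[8L - j]]],
                      logical(1L)))
    if (!ok6) next
    has_m8 <- s > 1L && u[s - 1L] == RNA_COMP[[m[8L]]]
    has_a1 <- s + 6L <= n && u[s + 6L] == "A"
    if (has_m8 && has_a1) {
      type <- "8mer"; s0 <- s - 2L; e0 <- s + 6L
    } else if (has_m8) {
      type <- "7mer-m8"; s0 <- s - 2L; e0 <- s + 5L
    } else if (has_a1) {
      type <- "7mer-A1"; s0 <- s - 1L; e0 <- s + 6L
    } else {
      type <- "6mer"; s0 <- s - 1L; e0 <- s + 5L
    }
    out[[length(out) + 1L]] <- data.frame(site_start = s0, site_end = e0,
                                          site_type = type,
                                          stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else {
    data.frame(site_start = integer(), site_end = integer(),
               site_type = character(), stringsAsFactors = FALSE)
  }
}

# minimal series-matrix text fixture around a value matrix
write_series_matrix_fixture <- function(path, values, titles) {
  gsm <- colnames(values)
  lines <- c(
    "!Series_title\t\"synthetic fixture\"",
    paste0("!Sample_title\t", paste(sprintf("\"%s\"", titles), collapse = "\t")),
    paste0("!Sample_geo_accession\t", paste(sprintf("\"%s\"", gsm), collapse = "\t")),
    "!series_matrix_table_begin",
    paste(c("\"ID_REF\"", sprintf("\"%s\"", gsm)), collapse = "\t"),
    vapply(seq_len(nrow(values)), function(i) {
      paste(c(sprintf("\"%s\"", rownames(values)[i]),
              format(values[i, ], digits = 10)), collapse = "\t")
    }, character(1L)),
    "!series_matrix_table_end")
  writeLines(lines, path)
  invisible(path)
}
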