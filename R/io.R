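# File interchange: FASTA via Biostrings, TSV tables, GEO series-matrix text.

#' Read a FASTA file as a named character vector of RNA sequences
#'
#' T is tolerated and converted to U; sequences are validated against the
#' RNA alphabet (N allowed).
#'
#' @param path FASTA file path.
#' @return Named character vector.
#' @export
read_fasta_set <- function(path) {
  set <- Biostrings::readBStringSet(path)
  out <- vapply(as.character(set), normalize_sequence, character(1L),
                allow_n = TRUE)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write sequences to FASTA (80-column wrap)
#'
#' @param seqs Named character vector, or a data.frame with `id` and
#'   `sequence` columns (as from [gen_snorna_set()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_set <- function(seqs, path) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$sequence, seqs$id)
  set <- Biostrings::RNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Write a probe matrix and its sample sheet as TSV
#'
#' The matrix file has a `probe_id` first column and one column per sample;
#' the sample sheet has columns `sample_id` and `group`.
#'
#' @param sim A `probe_matrix_sim`, or a matrix (then `groups` is required).
#' @param matrix_path,samples_path Output paths.
#' @param groups Named character vector sample -> group when `sim` is a bare
#'   matrix.
#' @return Invisibly, `c(matrix_path, samples_path)`.
#' @export
write_probe_matrix <- function(sim, matrix_path, samples_path, groups = NULL) {
  if (inherits(sim, "probe_matrix_sim")) {
    groups <- sim$groups
    values <- sim$values
  } else values <- as.matrix(sim)
  df <- data.frame(probe_id = rownames(values), values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = names(groups), group = unname(groups)),
              samples_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(matrix_path, samples_path))
}

#' Read a probe matrix TSV and its sample sheet
#'
#' @param matrix_path TSV with `probe_id` first column, samples after.
#' @param samples_path TSV with `sample_id` and `group` columns.
#' @return List with `values` (matrix) and `groups` (named vector).
#' @export
read_probe_matrix <- function(matrix_path, samples_path) {
  df <- read.delim(matrix_path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1L, drop = FALSE])
  rownames(values) <- df[[1L]]
  ss <- read.delim(samples_path, stringsAsFactors = FALSE)
  list(values = values, groups = setNames(ss$group, ss$sample_id))
}

#' Read a replicate-level Ct table TSV
#'
#' Expects columns `sample_id`, `condition`, `gene_id`, `replicate`, `ct`.
#'
#' @param path TSV path.
#' @return Data.frame.
#' @export
read_ct_table <- function(path) {
  ct <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("condition", "gene_id", "replicate", "ct")
  absent <- setdiff(need, names(ct))
  if (length(absent)) stop("Ct table lacks column(s): ", paste(absent, collapse = ", "))
  ct
}

#' Write a Ct table TSV
#' @param ct Data.frame as produced by [gen_ct_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(ct, path) {
  write.table(ct, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse a GEO series-matrix file
#'
#' Minimal reader for the line-oriented series-matrix text format: sample
#' metadata lines (`!Sample_*`) and the expression block between
#' `!series_matrix_table_begin` and `!series_matrix_table_end`. Values are
#' returned as exported (typically already normalized, log2 scale for array
#' series).
#'
#' @param path Path to an (uncompressed) series-matrix txt file.
#' @return List with `values` (matrix, features x samples), `sample_titles`
#'   (named character vector GSM id -> title) and `characteristics`
#'   (data.frame of `!Sample_characteristics_ch1` lines, one row per field).
#' @export
read_series_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  unquote <- function(x) gsub("^\"|\"$", "", x)
  meta <- function(key) {
    hit <- grep(paste0("^!", key, "\t"), lines, value = TRUE)
    lapply(hit, function(l) unquote(strsplit(l, "\t", fixed = TRUE)[[1L]][-1L]))
  }
  titles <- meta("Sample_title")
  accession <- meta("Sample_geo_accession")
  sample_titles <- if (length(titles) && length(accession)) {
    setNames(titles[[1L]], accession[[1L]])
  } else character()
  chars <- meta("Sample_characteristics_ch1")
  characteristics <- if (length(chars)) {
    as.data.frame(do.call(rbind, chars), stringsAsFactors = FALSE)
  } else data.frame()
  b <- grep("^!series_matrix_table_begin", lines)
  e <- grep("^!series_matrix_table_end", lines)
  if (length(b) != 1L || length(e) != 1L || e <= b + 1L) {
    stop("no series-matrix table found in ", path)
  }
  block <- lines[(b + 1L):(e - 1L)]
  con <- textConnection(block)
  on.exit(close(con))
  tab <- read.delim(con, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(values) <- unquote(as.character(tab[[1L]]))
  colnames(values) <- unquote(colnames(values))
  list(values = values, sample_titles = sample_titles,
       characteristics = characteristics)
}
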