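# Shared readers/writers: expression matrices and metadata (TSV, no
# quoting), Ct and anchor tables (CSV), FASTQ. All writers emit UTF-8 with
# LF endings; readers accept CRLF.

#' Write / read an expression matrix as TSV
#'
#' Layout: header `feature_id` followed by sample ids; one row per feature;
#' tab-separated, no quoting.
#'
#' @param m numeric matrix with feature row names and sample column names.
#' @param path file path.
#' @return `read_expression_matrix` returns the numeric matrix.
#' @export
write_expression_matrix <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "feature_id")
    stopf("%s: first column must be feature_id (found %s)", path, names(df)[1])
  if (anyDuplicated(df$feature_id))
    stopf("%s: duplicate feature ids", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    stopf("%s: non-numeric values in column %s", path, names(df)[-1][bad])
  }
  rownames(m) <- df$feature_id
  m
}

#' Write / read per-sample metadata as TSV
#'
#' @param metadata data.frame with at least `sample_id`, `cell_line`,
#'   `medium`; `serum_free` is coerced to logical on read if present.
#' @param path file path.
#' @return `read_sample_metadata` returns the data.frame.
#' @export
write_sample_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_sample_metadata
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "cell_line", "medium")
  miss <- setdiff(req, names(md))
  if (length(miss))
    stopf("%s: missing column(s): %s", path, paste(miss, collapse = ", "))
  if ("serum_free" %in% names(md)) md$serum_free <- as.logical(md$serum_free)
  md
}

#' Write / read a Ct table as CSV
#'
#' Columns: `sample_id, cell_line, medium, bio_rep, tech_rep, gene, ct`.
#'
#' @param ct a `ct_table` (or compatible data.frame).
#' @param path file path.
#' @return `read_ct_table` returns a `ct_table`.
#' @export
write_ct_table <- function(ct, path) {
  utils::write.csv(as.data.frame(ct), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ct_table
#' @export
read_ct_table <- function(path) {
  ct <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "cell_line", "medium", "bio_rep", "tech_rep", "gene", "ct")
  miss <- setdiff(req, names(ct))
  if (length(miss))
    stopf("%s: missing column(s): %s", path, paste(miss, collapse = ", "))
  class(ct) <- c("ct_table", "data.frame")
  ct
}

#' Write / read a condition-level anchor table as CSV
#'
#' Columns: `cell_line, medium, value`.
#'
#' @param anchor data.frame with columns `cell_line`, `medium`, `value`.
#' @param path file path.
#' @return `read_anchor` returns the data.frame.
#' @export
write_anchor <- function(anchor, path) {
  utils::write.csv(anchor[, c("cell_line", "medium", "value")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_anchor
#' @export
read_anchor <- function(path) {
  a <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("cell_line", "medium", "value"), names(a))
  if (length(miss))
    stopf("%s: missing column(s): %s", path, paste(miss, collapse = ", "))
  a
}

#' Write / read FASTQ
#'
#' `write_fastq` writes a mate file per call with constant quality `I`;
#' `read_fastq` parses ids and sequences (qualities are ignored).
#'
#' @param reads data.frame with columns `id`, `seq` (as in `sim_reads$r1`).
#' @param path file path.
#' @return `read_fastq` returns a data.frame with `id`, `seq`.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq") %in% names(reads)))
  qual <- strrep("I", nchar(reads$seq))
  out <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", qual))
  writeLines(out, path, sep = "\n")
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  dna <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(id = sub("\\s.*$", "", names(dna)),
             seq = toupper(as.character(dna)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a paired simulated read set as two FASTQ files
#'
#' @param reads a `sim_reads` object.
#' @param r1_path,r2_path output paths for mates 1 and 2.
#' @return Invisibly, the two paths.
#' @export
write_fastq_pair <- function(reads, r1_path, r2_path) {
  stopifnot(inherits(reads, "sim_reads"))
  write_fastq(reads$r1, r1_path)
  write_fastq(reads$r2, r2_path)
  invisible(c(r1 = r1_path, r2 = r2_path))
}

# Shared TSV writer for result tables.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}
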