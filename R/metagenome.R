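# Virus-metagenome reference: construction, validation, composition, export.

VALID_CATEGORIES <- c("endogenous_human", "housekeeping", "spacer")

#' Build a virus metagenome from a manifest and sequences
#'
#' Assembles and validates the reference used for virus-focused
#' quantification: a collection of endogenous viral elements (HERV families,
#' endogenous bornavirus-like elements), housekeeping-gene controls, and
#' unrelated-virus "spacer" decoys. Each element carries a family label; the
#' family index built here drives family-level FPKM aggregation.
#'
#' @param manifest data.frame with columns `element_id`, `accession_label`,
#'   `family`, `category` (one of `endogenous_human`, `housekeeping`,
#'   `spacer`). Row order is preserved.
#' @param sequences named character vector (or `DNAStringSet`) of nucleotide
#'   sequences over A/C/G/T/N, named by `element_id`. Every manifest row must
#'   have a sequence.
#' @return An object of class `virus_metagenome`: a list with `manifest`
#'   (including a `length_bp` column), `sequences` (named character, manifest
#'   order), and `family_index` (family -> member element ids; a partition of
#'   all elements).
#' @examples
#' man <- data.frame(
#'   element_id = c("k1", "k2", "sp1"),
#'   accession_label = c("A1.1", "A2.1", "S1.1"),
#'   family = c("HERV-K(HML-2)", "HERV-K(HML-2)", "spacer"),
#'   category = c("endogenous_human", "endogenous_human", "spacer")
#' )
#' seqs <- c(k1 = "ACGTACGTAC", k2 = "TTGCAATGCA", sp1 = "GGGCCCAAAT")
#' mg <- build_metagenome(man, seqs)
#' names(mg$family_index)
#' @export
build_metagenome <- function(manifest, sequences) {
  required <- c("element_id", "accession_label", "family", "category")
  miss <- setdiff(required, names(manifest))
  if (length(miss))
    stopf("manifest is missing column(s): %s", paste(miss, collapse = ", "))
  if (!nrow(manifest)) {
    mg <- list(manifest = cbind(manifest, length_bp = integer(0)),
               sequences = character(0), family_index = list())
    class(mg) <- "virus_metagenome"
    return(mg)
  }
  ids <- as.character(manifest$element_id)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stopf("duplicate element_id in manifest: %s", paste(dup, collapse = ", "))
  bad_cat <- setdiff(unique(as.character(manifest$category)), VALID_CATEGORIES)
  if (length(bad_cat))
    stopf("invalid category value(s): %s (expected one of %s)",
          paste(bad_cat, collapse = ", "), paste(VALID_CATEGORIES, collapse = ", "))
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  no_seq <- ids[!(ids %in% names(sequences))]
  if (length(no_seq))
    stopf("missing sequence for element(s): %s", paste(no_seq, collapse = ", "))
  seqs <- toupper(sequences[ids])
  empty <- ids[!nzchar(seqs)]
  if (length(empty))
    stopf("empty sequence for element(s): %s", paste(empty, collapse = ", "))
  bad_alpha <- ids[grepl("[^ACGTN]", seqs)]
  if (length(bad_alpha))
    stopf("sequence contains characters outside A/C/G/T/N: %s",
          paste(bad_alpha, collapse = ", "))
  spacer_bad <- ids[manifest$category == "spacer" & manifest$family != "spacer"]
  if (length(spacer_bad))
    stopf("spacer elements must carry family \"spacer\": %s",
          paste(spacer_bad, collapse = ", "))

  man <- data.frame(
    element_id = ids,
    accession_label = as.character(manifest$accession_label),
    family = as.character(manifest$family),
    category = as.character(manifest$category),
    length_bp = nchar(seqs),
    stringsAsFactors = FALSE
  )
  fam_levels <- unique(man$family)
  family_index <- split(man$element_id, factor(man$family, levels = fam_levels))
  mg <- list(manifest = man, sequences = stats::setNames(seqs, ids),
             family_index = family_index)
  class(mg) <- "virus_metagenome"
  mg
}

#' @export
print.virus_metagenome <- function(x, ...) {
  cat(sprintf("virus_metagenome: %d elements, %d families\n",
              nrow(x$manifest), length(x$family_index)))
  tab <- table(x$manifest$category)
  for (nm in names(tab)) cat(sprintf("  %-17s %d\n", nm, tab[[nm]]))
  invisible(x)
}

#' Summarize the composition of a virus metagenome
#'
#' Tallies elements by category and family: endogenous human viral elements,
#' how many of those are HERV elements (and over how many HERV families),
#' bornavirus-like EBLN elements, housekeeping controls, and spacers.
#'
#' @param mg a `virus_metagenome`.
#' @return Object of class `composition_report`: a list with counts
#'   `n_endogenous_human`, `n_housekeeping`, `n_spacer`, `n_herv_elements`,
#'   `n_herv_families`, `n_ebln`, `n_other`, and `family_sizes`
#'   (named integer, every distinct family).
#' @export
summarize_composition <- function(mg) {
  stopifnot(inherits(mg, "virus_metagenome"))
  man <- mg$manifest
  endo <- man[man$category == "endogenous_human", , drop = FALSE]
  is_herv <- startsWith(endo$family, "HERV")
  is_ebln <- endo$family == "EBLN"
  fam_sizes <- vapply(mg$family_index, length, integer(1))
  rep <- list(
    n_endogenous_human = nrow(endo),
    n_housekeeping = sum(man$category == "housekeeping"),
    n_spacer = sum(man$category == "spacer"),
    n_herv_elements = sum(is_herv),
    n_herv_families = length(unique(endo$family[is_herv])),
    n_ebln = sum(is_ebln),
    n_other = sum(!is_herv & !is_ebln),
    family_sizes = fam_sizes
  )
  class(rep) <- "composition_report"
  rep
}

#' @export
print.composition_report <- function(x, ...) {
  cat("virus metagenome composition\n")
  cat(sprintf("  endogenous human elements : %d\n", x$n_endogenous_human))
  cat(sprintf("    HERV elements           : %d (%d families)\n",
              x$n_herv_elements, x$n_herv_families))
  cat(sprintf("    EBLN elements           : %d\n", x$n_ebln))
  cat(sprintf("    other endogenous        : %d\n", x$n_other))
  cat(sprintf("  housekeeping controls     : %d\n", x$n_housekeeping))
  cat(sprintf("  spacers                   : %d\n", x$n_spacer))
  invisible(x)
}

#' Export a metagenome as FASTA plus SAF annotation
#'
#' Writes the reference FASTA (one record per element, element id as header)
#' and a featureCounts-compatible SAF annotation (columns GeneID, Chr, Start,
#' End, Strand; 1-based inclusive; each element is its own "chromosome" on
#' the forward strand).
#'
#' @param mg a `virus_metagenome`.
#' @param fasta_path output FASTA path.
#' @param annotation_path output SAF path (tab-separated).
#' @param width FASTA line-wrap width.
#' @return Invisibly, the two paths.
#' @export
export_reference <- function(mg, fasta_path, annotation_path, width = 70L) {
  stopifnot(inherits(mg, "virus_metagenome"))
  dna <- Biostrings::DNAStringSet(mg$sequences)
  tryCatch(
    Biostrings::writeXStringSet(dna, filepath = fasta_path, width = width),
    error = function(e) stopf("failed to write FASTA to %s: %s",
                              fasta_path, conditionMessage(e))
  )
  saf <- data.frame(
    GeneID = mg$manifest$element_id,
    Chr = mg$manifest$element_id,
    Start = 1L,
    End = mg$manifest$length_bp,
    Strand = "+",
    stringsAsFactors = FALSE
  )
  tryCatch(
    utils::write.table(saf, annotation_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n"),
    error = function(e) stopf("failed to write SAF to %s: %s",
                              annotation_path, conditionMessage(e))
  )
  invisible(c(fasta = fasta_path, annotation = annotation_path))
}

#' Read a reference FASTA back as id/sequence pairs
#'
#' @param fasta_path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_reference_fasta <- function(fasta_path) {
  dna <- Biostrings::readDNAStringSet(fasta_path)
  stats::setNames(as.character(dna), sub("\\s.*$", "", names(dna)))
}

#' Write / read a metagenome manifest as TSV
#'
#' The manifest dialect is a header row `element_id accession_label family
#' category` (tab-separated, no quoting).
#'
#' @param manifest data.frame to write.
#' @param path file path.
#' @return `read_manifest` returns the manifest data.frame.
#' @export
write_manifest <- function(manifest, path) {
  cols <- c("element_id", "accession_label", "family", "category")
  utils::write.table(manifest[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  man <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("element_id", "accession_label", "family", "category")
  miss <- setdiff(required, names(man))
  if (length(miss))
    stopf("manifest %s is missing column(s): %s", path, paste(miss, collapse = ", "))
  man
}
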