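# Uniqueness-constrained fragment assignment and FPKM computation.
#
# "Uniquely mapped" is taken as: a fragment is credited to an element iff
# both mates match that element within the mismatch budget, at consistent
# positions and opposite orientations, AND no other element achieves the
# same best total score. Equal-best ties are ambiguous; fragments matching
# nothing are unassigned.

#' Assign paired-end fragments to metagenome elements
#'
#' Desk-scale seeded matcher standing in for an aligner + unique-read
#' counter: k-mer seeds from both mates (prefix and suffix, both
#' orientations) propose candidate placements, which are verified by full
#' gapless comparison of both mates; a fragment is counted for an element
#' only when that element uniquely achieves the best total mismatch score
#' with a properly oriented pair. Indels are not modelled.
#'
#' @param reads a `sim_reads` object, a list with character vectors `r1`,
#'   `r2` (same length), or a length-2 character vector of FASTQ paths
#'   `c(r1 = ..., r2 = ...)`.
#' @param mg a `virus_metagenome` (non-empty).
#' @param k seed k-mer length; must not exceed the read length.
#' @param max_mismatches per-mate mismatch budget for a valid placement.
#' @param max_frag maximal fragment span (bp) for a consistent pair.
#' @return Object of class `assignment_result`: list with `unique_counts`
#'   (named integer over all elements), `n_ambiguous`, `n_unassigned`,
#'   `n_total`, and `calls` (per-fragment element id, `"ambiguous"` or
#'   `"unassigned"`). `sum(unique_counts) + n_ambiguous + n_unassigned ==
#'   n_total` always holds.
#' @export
assign_fragments <- function(reads, mg, k = 31L, max_mismatches = 2L,
                             max_frag = 1000L) {
  stopifnot(inherits(mg, "virus_metagenome"))
  if (!length(mg$sequences)) stopf("empty reference metagenome")
  rp <- as_read_pairs(reads)
  r1 <- rp$r1; r2 <- rp$r2
  n <- length(r1)
  elems <- names(mg$sequences)
  res <- list(unique_counts = stats::setNames(integer(length(elems)), elems),
              n_ambiguous = 0L, n_unassigned = 0L, n_total = n,
              calls = character(n))
  class(res) <- "assignment_result"
  if (n == 0L) return(res)
  if (any(nchar(c(r1, r2)) < k))
    stopf("seed length k=%d exceeds the shortest read", k)

  o <- list(`1f` = r1, `1r` = revcomp(r1), `2f` = r2, `2r` = revcomp(r2))
  olen <- lapply(o, nchar)
  pref <- lapply(o, function(s) substr(s, 1L, k))
  suf <- lapply(seq_along(o), function(j)
    substr(o[[j]], olen[[j]] - k + 1L, olen[[j]]))
  names(suf) <- names(o)

  all_seeds <- unique(unlist(c(pref, suf), use.names = FALSE))
  all_seeds <- all_seeds[!grepl("[^ACGT]", all_seeds)]
  hits <- seed_index_lookup(all_seeds, mg$sequences)

  elem_raw <- lapply(mg$sequences, charToRaw)

  # verified placements of one oriented read: matrix cols (elem, pos, mm)
  lookup <- function(s) {
    if (exists(s, envir = hits, inherits = FALSE))
      get(s, envir = hits, inherits = FALSE) else NULL
  }
  verify_one <- function(seq_chr, pseed, sseed, len) {
    cand <- NULL
    hp <- lookup(pseed)
    if (!is.null(hp)) cand <- hp
    hs <- lookup(sseed)
    if (!is.null(hs)) {
      hs[, 2L] <- hs[, 2L] - (len - k)
      cand <- rbind(cand, hs)
    }
    if (is.null(cand)) return(NULL)
    cand <- unique(cand)
    rr <- charToRaw(seq_chr)
    keep_e <- integer(0); keep_p <- integer(0); keep_m <- integer(0)
    for (ci in seq_len(nrow(cand))) {
      e <- cand[ci, 1L]; p <- cand[ci, 2L]
      er <- elem_raw[[e]]
      if (p < 1L || p + len - 1L > length(er)) next
      mm <- sum(er[p:(p + len - 1L)] != rr)
      if (mm <= max_mismatches) {
        keep_e <- c(keep_e, e); keep_p <- c(keep_p, p); keep_m <- c(keep_m, mm)
      }
    }
    if (!length(keep_e)) return(NULL)
    cbind(elem = keep_e, pos = keep_p, mm = keep_m)
  }

  calls <- character(n)
  uc <- res$unique_counts
  n_amb <- 0L; n_un <- 0L
  for (i in seq_len(n)) {
    pl <- lapply(names(o), function(nm)
      verify_one(o[[nm]][i], pref[[nm]][i], suf[[nm]][i], olen[[nm]][i]))
    names(pl) <- names(o)
    best <- pair_best_scores(pl, nchar(r1[i]), nchar(r2[i]), max_frag)
    if (!length(best)) {
      calls[i] <- "unassigned"; n_un <- n_un + 1L
      next
    }
    bs <- min(best)
    winners <- names(best)[best == bs]
    if (length(winners) == 1L) {
      e <- as.integer(winners)
      uc[e] <- uc[e] + 1L
      calls[i] <- elems[e]
    } else {
      calls[i] <- "ambiguous"; n_amb <- n_amb + 1L
    }
  }
  res$unique_counts <- uc
  res$n_ambiguous <- n_amb
  res$n_unassigned <- n_un
  res$calls <- calls
  res
}

# Best per-element total mismatch score over consistent pair placements.
# Configuration A: mate1 forward / mate2 reverse, p1 <= p2; configuration B:
# mate2 forward / mate1 reverse, p2 <= p1. Returns named numeric
# (element index as name).
pair_best_scores <- function(pl, len1, len2, max_frag) {
  best <- numeric(0)
  take <- function(fwd, rev, len_rev) {
    if (is.null(fwd) || is.null(rev)) return()
    for (a in seq_len(nrow(fwd))) for (b in seq_len(nrow(rev))) {
      if (fwd[a, "elem"] != rev[b, "elem"]) next
      p_f <- fwd[a, "pos"]; p_r <- rev[b, "pos"]
      if (p_r < p_f) next
      if (p_r + len_rev - p_f > max_frag) next
      e <- as.character(fwd[a, "elem"])
      sc <- fwd[a, "mm"] + rev[b, "mm"]
      if (is.null(best[e]) || is.na(best[e]) || sc < best[e]) best[e] <<- sc
    }
  }
  take(pl[["1f"]], pl[["2r"]], len2)
  take(pl[["2f"]], pl[["1r"]], len1)
  best
}

# Exact positions of every seed k-mer on the forward strand of every
# element, via an Aho-Corasick dictionary scan. Returns an environment-like
# list: seed string -> matrix cols (elem index, pos).
seed_index_lookup <- function(seeds, sequences) {
  out <- new.env(parent = emptyenv())
  if (!length(seeds)) return(out)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds))
  for (e in seq_along(sequences)) {
    m <- Biostrings::matchPDict(pd, Biostrings::DNAString(sequences[[e]]))
    si <- Biostrings::startIndex(m)
    for (j in seq_along(si)) {
      pos <- si[[j]]
      if (is.null(pos) || !length(pos)) next
      add <- cbind(elem = rep.int(e, length(pos)), pos = pos)
      s <- seeds[j]
      prev <- if (exists(s, envir = out, inherits = FALSE))
        get(s, envir = out, inherits = FALSE) else NULL
      assign(s, if (is.null(prev)) add else rbind(prev, add), envir = out)
    }
  }
  out
}

as_read_pairs <- function(reads) {
  if (inherits(reads, "sim_reads"))
    return(list(r1 = reads$r1$seq, r2 = reads$r2$seq))
  if (is.character(reads) && length(reads) == 2L) {
    r1 <- read_fastq(reads[[1]]); r2 <- read_fastq(reads[[2]])
    if (length(r1$seq) != length(r2$seq))
      stopf("unpaired FASTQ files: %d vs %d reads", length(r1$seq), length(r2$seq))
    return(list(r1 = r1$seq, r2 = r2$seq))
  }
  if (is.list(reads) && all(c("r1", "r2") %in% names(reads))) {
    r1 <- if (is.data.frame(reads$r1)) reads$r1$seq else reads$r1
    r2 <- if (is.data.frame(reads$r2)) reads$r2$seq else reads$r2
    if (length(r1) != length(r2))
      stopf("unpaired reads: %d vs %d", length(r1), length(r2))
    return(list(r1 = toupper(r1), r2 = toupper(r2)))
  }
  stopf("`reads` must be a sim_reads object, list(r1=, r2=), or two FASTQ paths")
}

#' @export
print.assignment_result <- function(x, ...) {
  cat(sprintf("assignment_result: %d fragments\n", x$n_total))
  cat(sprintf("  uniquely assigned: %d\n", sum(x$unique_counts)))
  cat(sprintf("  ambiguous        : %d\n", x$n_ambiguous))
  cat(sprintf("  unassigned       : %d\n", x$n_unassigned))
  invisible(x)
}

#' Read a featureCounts-dialect count table
#'
#' Parses the layout written by featureCounts (and by
#' [write_counts_table()]): optional leading `#` comment lines, a header
#' row, then columns `Geneid`, `Chr`, `Start`, `End`, `Strand`, `Length`
#' followed by one or more sample count columns.
#'
#' @param path file path.
#' @return List with `ids` (character), `lengths` (named integer), and
#'   `counts` (integer matrix, elements x samples; row order preserved).
#' @export
read_counts_table <- function(path) {
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  n_comment <- 0L
  while (n_comment < length(lines) && startsWith(lines[n_comment + 1L], "#"))
    n_comment <- n_comment + 1L
  body <- lines[seq.int(n_comment + 1L, length.out = length(lines) - n_comment)]
  if (!length(body)) stopf("%s: no header row found", path)
  tab <- utils::read.delim(text = paste(body, collapse = "\n"),
                           stringsAsFactors = FALSE, check.names = FALSE)
  mandatory <- c("Geneid", "Chr", "Start", "End", "Strand", "Length")
  miss <- setdiff(mandatory, names(tab))
  if (length(miss))
    stopf("%s: missing mandatory column(s): %s", path, paste(miss, collapse = ", "))
  sample_cols <- setdiff(names(tab), mandatory)
  cmat <- NULL
  if (nrow(tab) && length(sample_cols)) {
    cmat <- as.matrix(tab[, sample_cols, drop = FALSE])
    bad <- which(!is.finite(suppressWarnings(as.numeric(cmat))) |
                   suppressWarnings(as.numeric(cmat)) %% 1 != 0)
    if (length(bad)) {
      row_bad <- ((bad[1] - 1L) %% nrow(tab)) + 1L
      stopf("%s: non-integer count at line %d", path,
            n_comment + 1L + row_bad)
    }
    cmat <- matrix(as.integer(cmat), nrow = nrow(tab),
                   dimnames = list(tab$Geneid, sample_cols))
  } else {
    cmat <- matrix(integer(0), nrow = nrow(tab), ncol = length(sample_cols),
                   dimnames = list(tab$Geneid, sample_cols))
  }
  list(ids = as.character(tab$Geneid),
       lengths = stats::setNames(as.integer(tab$Length), tab$Geneid),
       counts = cmat)
}

#' Write a featureCounts-dialect count table
#'
#' @param counts integer matrix (elements x samples) or named vector.
#' @param lengths named integer vector of element lengths (bp).
#' @param path output path.
#' @param comment logical; write a leading `#` comment line.
#' @return Invisibly, `path`.
#' @export
write_counts_table <- function(counts, lengths, path, comment = TRUE) {
  if (is.null(dim(counts)))
    counts <- matrix(counts, ncol = 1,
                     dimnames = list(names(counts), "sample1"))
  ids <- rownames(counts)
  if (is.null(ids)) stopf("counts must have element ids as row names")
  if (!all(ids %in% names(lengths)))
    stopf("lengths missing for some elements")
  df <- data.frame(Geneid = ids, Chr = ids, Start = 1L,
                   End = as.integer(lengths[ids]), Strand = "+",
                   Length = as.integer(lengths[ids]),
                   stringsAsFactors = FALSE, check.names = FALSE)
  df <- cbind(df, as.data.frame(counts, check.names = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  if (comment) writeLines("# Program:hervscape; fragment counts", con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Element-level FPKM
#'
#' Fragments per kilobase of element per million assigned fragments:
#' `fpkm_i = counts_i * 1e9 / (length_i * n_total_assigned)`. The
#' denominator is the total number of fragments uniquely assigned to the
#' metagenome — this changes absolute values relative to a whole-library
#' denominator but no fold change.
#'
#' @param counts named numeric vector of fragment counts.
#' @param lengths named numeric vector of element lengths (bp), covering
#'   `names(counts)`; all > 0.
#' @param n_total_assigned total assigned fragments (> 0).
#' @return data.frame with columns `element_id`, `counts`, `length_bp`,
#'   `fpkm`.
#' @export
element_fpkm <- function(counts, lengths, n_total_assigned) {
  ids <- names(counts)
  if (is.null(ids)) stopf("counts must be named by element id")
  if (!all(ids %in% names(lengths))) stopf("lengths missing for some elements")
  len <- as.numeric(lengths[ids])
  if (any(len <= 0)) stopf("element lengths must be positive")
  if (length(n_total_assigned) != 1 || n_total_assigned <= 0)
    stopf("n_total_assigned must be a single positive number")
  if (any(counts < 0)) stopf("counts must be non-negative")
  data.frame(element_id = ids, counts = as.numeric(counts),
             length_bp = len,
             fpkm = as.numeric(counts) * 1e9 / (len * n_total_assigned),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Family-level FPKM by count and length summation
#'
#' The family value is not a mean of member FPKMs: per family F,
#' `fpkm_F = sum(counts_i) * 1e9 / (sum(length_i) * n_total_assigned)`
#' over members i — i.e. the FPKM of the family treated as one merged
#' pseudo-element.
#'
#' @param counts named numeric vector of per-element fragment counts;
#'   elements of `mg` absent from `counts` contribute 0.
#' @param mg a `virus_metagenome` providing the family index and lengths.
#' @param n_total_assigned total assigned fragments (> 0).
#' @param include_controls logical; also report the `spacer` and
#'   `housekeeping` families (excluded by default).
#' @return data.frame with columns `family`, `counts`, `length_bp`, `fpkm`.
#' @export
family_fpkm <- function(counts, mg, n_total_assigned, include_controls = FALSE) {
  stopifnot(inherits(mg, "virus_metagenome"))
  if (is.null(names(counts)) && length(counts))
    stopf("counts must be named by element id")
  unknown <- setdiff(names(counts), mg$manifest$element_id)
  if (length(unknown))
    stopf("counts for unknown element(s): %s", paste(unknown, collapse = ", "))
  if (length(n_total_assigned) != 1 || n_total_assigned <= 0)
    stopf("n_total_assigned must be a single positive number")
  fams <- names(mg$family_index)
  if (!include_controls) fams <- setdiff(fams, c("spacer", "housekeeping"))
  full <- stats::setNames(numeric(nrow(mg$manifest)), mg$manifest$element_id)
  full[names(counts)] <- counts
  lens <- stats::setNames(mg$manifest$length_bp, mg$manifest$element_id)
  fc <- vapply(mg$family_index[fams], function(m) sum(full[m]), numeric(1))
  fl <- vapply(mg$family_index[fams], function(m) sum(lens[m]), numeric(1))
  data.frame(family = fams, counts = fc, length_bp = fl,
             fpkm = fc * 1e9 / (fl * n_total_assigned),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-sample FPKM matrices
#'
#' Applies [element_fpkm()] / [family_fpkm()] column-wise to a count
#' matrix; each sample's denominator is its own total of assigned fragments
#' (column sum over all elements, including controls).
#'
#' @param counts integer matrix, elements x samples, row names = element
#'   ids.
#' @param lengths named vector of element lengths (element matrix).
#' @param mg a `virus_metagenome` (family matrix).
#' @param include_controls see [family_fpkm()].
#' @param totals optional per-sample denominators; defaults to
#'   `colSums(counts)`.
#' @return Numeric matrix of FPKM values (features x samples).
#' @export
element_fpkm_matrix <- function(counts, lengths, totals = colSums(counts)) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  if (any(totals <= 0)) stopf("every sample must have assigned fragments")
  out <- vapply(seq_len(ncol(counts)), function(j)
    element_fpkm(counts[, j], lengths, totals[j])$fpkm,
    numeric(nrow(counts)))
  dimnames(out) <- dimnames(counts)
  out
}

#' @rdname element_fpkm_matrix
#' @export
family_fpkm_matrix <- function(counts, mg, include_controls = FALSE,
                               totals = colSums(counts)) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  if (any(totals <= 0)) stopf("every sample must have assigned fragments")
  cols <- lapply(seq_len(ncol(counts)), function(j)
    family_fpkm(counts[, j], mg, totals[j], include_controls))
  out <- vapply(cols, function(x) x$fpkm, numeric(nrow(cols[[1]])))
  dimnames(out) <- list(cols[[1]]$family, colnames(counts))
  out
}
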