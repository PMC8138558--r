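# Synthetic-data generators: study designs, NB count tables, paired-end
# reads with controlled multi-mapping, qPCR Ct tables, and the packaged
# default metagenome manifest. Every generator is deterministic under its
# seed and records ground truth.

#' Describe a cell-line x medium study design
#'
#' The default mirrors a neuroblastoma medium-switch experiment: three cell
#' lines grown in serum-supplemented standard medium, serum-supplemented
#' stem-cell medium, and serum-free stem-cell medium, with two biological
#' replicates for RNA-seq and three (times two technical) for qPCR.
#'
#' @param cell_lines character vector of cell-line labels.
#' @param media character vector of medium labels.
#' @param serum_free_media subset of `media` counting as serum-free.
#' @param n_bio_replicates biological replicates per arm.
#' @param n_tech_replicates technical replicates (qPCR only).
#' @return Object of class `study_design`.
#' @export
study_design <- function(cell_lines = c("SH-SY5Y", "IMR-32", "SiMa"),
                         media = c("DMEM+FBS", "Panserin+FBS", "Panserin-SF"),
                         serum_free_media = "Panserin-SF",
                         n_bio_replicates = 2L,
                         n_tech_replicates = 2L) {
  stopifnot(length(cell_lines) >= 1, length(media) >= 1,
            all(serum_free_media %in% media),
            is_count1(n_bio_replicates), is_count1(n_tech_replicates))
  d <- list(cell_lines = cell_lines, media = media,
            serum_free_media = serum_free_media,
            n_bio_replicates = as.integer(n_bio_replicates),
            n_tech_replicates = as.integer(n_tech_replicates))
  class(d) <- "study_design"
  d
}

#' Expand a design into a per-sample metadata table
#'
#' @param design a `study_design`.
#' @return data.frame with columns `sample_id`, `cell_line`, `medium`,
#'   `bio_rep`, `serum_free`; one row per biological sample, ids unique.
#' @export
design_samples <- function(design) {
  stopifnot(inherits(design, "study_design"))
  g <- expand.grid(bio_rep = seq_len(design$n_bio_replicates),
                   medium = design$media, cell_line = design$cell_lines,
                   stringsAsFactors = FALSE)
  g <- g[, c("cell_line", "medium", "bio_rep")]
  g$sample_id <- sprintf("%s.%s.r%d", gsub("[^A-Za-z0-9]+", "", g$cell_line),
                         gsub("[^A-Za-z0-9]+", "", g$medium), g$bio_rep)
  g$serum_free <- g$medium %in% design$serum_free_media
  g[, c("sample_id", "cell_line", "medium", "bio_rep", "serum_free")]
}

#' Specify a planted expression effect
#'
#' One row per feature: its baseline expected fragment count, the
#' multiplicative serum-free fold change, which cell lines respond, and the
#' negative-binomial dispersion.
#'
#' @param feature_id feature identifier.
#' @param baseline_mean expected fragments (or expression units) in
#'   serum-supplemented medium; > 0.
#' @param fold_change multiplicative serum-free effect; > 0 (1 = null).
#' @param affected_cell_lines `"all"` or a character vector of cell lines.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2);
#'   0 gives Poisson counts.
#' @return One-row data.frame.
#' @export
effect_spec <- function(feature_id, baseline_mean = 500, fold_change = 1,
                        affected_cell_lines = "all", dispersion = 0.02) {
  stopifnot(baseline_mean > 0, fold_change > 0, dispersion >= 0)
  data.frame(feature_id = feature_id, baseline_mean = baseline_mean,
             fold_change = fold_change,
             affected_cell_lines = paste(affected_cell_lines, collapse = ";"),
             dispersion = dispersion, stringsAsFactors = FALSE)
}

#' Simulate a negative-binomial count matrix with planted fold changes
#'
#' Draws fragment counts per feature and sample with mean
#' `baseline * fold_change^(serum-free indicator)` for affected cell lines,
#' NB-distributed with per-feature dispersion. Features without an effect
#' spec get the null defaults (`baseline_mean`, fold change 1).
#'
#' @param design a `study_design`.
#' @param effects data.frame of [effect_spec()] rows (may be empty/NULL).
#' @param features character vector of all feature ids (must cover the
#'   effect features).
#' @param seed integer seed; identical seeds give identical matrices.
#' @param baseline_mean,dispersion defaults for features without an effect
#'   row.
#' @return Object of class `sim_counts`: list with `counts` (integer matrix,
#'   features x samples), `samples` (metadata data.frame), and `truth`
#'   (per-feature planted baseline/fold change/affected lines).
#' @export
simulate_counts <- function(design, effects = NULL, features, seed,
                            baseline_mean = 500, dispersion = 0.02) {
  stopifnot(inherits(design, "study_design"), length(features) >= 1)
  if (anyDuplicated(features)) stopf("duplicate feature ids")
  if (is.null(effects) || !NROW(effects)) {
    effects <- data.frame(feature_id = character(0),
                          baseline_mean = numeric(0),
                          fold_change = numeric(0),
                          affected_cell_lines = character(0),
                          dispersion = numeric(0))
  }
  unknown <- setdiff(effects$feature_id, features)
  if (length(unknown))
    stopf("effect refers to unknown feature(s): %s", paste(unknown, collapse = ", "))
  if (anyDuplicated(effects$feature_id))
    stopf("multiple effect rows for one feature")

  samples <- design_samples(design)
  truth <- data.frame(feature_id = features,
                      baseline_mean = baseline_mean,
                      fold_change = 1,
                      affected_cell_lines = "all",
                      dispersion = dispersion,
                      stringsAsFactors = FALSE)
  idx <- match(effects$feature_id, truth$feature_id)
  truth$baseline_mean[idx] <- effects$baseline_mean
  truth$fold_change[idx] <- effects$fold_change
  truth$affected_cell_lines[idx] <- effects$affected_cell_lines
  truth$dispersion[idx] <- effects$dispersion

  counts <- with_seed(seed, {
    m <- matrix(0L, nrow = length(features), ncol = nrow(samples),
                dimnames = list(features, samples$sample_id))
    for (i in seq_along(features)) {
      affected <- truth$affected_cell_lines[i]
      hit <- samples$serum_free &
        (affected == "all" | samples$cell_line %in% strsplit(affected, ";")[[1]])
      mu <- truth$baseline_mean[i] * truth$fold_change[i]^as.numeric(hit)
      disp <- truth$dispersion[i]
      m[i, ] <- if (disp <= 0) stats::rpois(length(mu), mu)
                else stats::rnbinom(length(mu), mu = mu, size = 1 / disp)
    }
    m
  })
  out <- list(counts = counts, samples = samples, truth = truth)
  class(out) <- "sim_counts"
  out
}

#' Copy a sequence segment between two elements
#'
#' Overwrites a stretch of the acceptor element with a segment of the donor,
#' so that fragments falling wholly inside the copied stretch match both
#' elements exactly — the controlled multi-mapping used to exercise the
#' uniqueness rule.
#'
#' @param mg a `virus_metagenome`.
#' @param from,to donor and acceptor element ids.
#' @param length segment length (bp); must be shorter than both elements.
#' @param from_start,to_start 1-based segment starts; random (seeded by the
#'   caller's RNG state) when `NULL`.
#' @return The modified `virus_metagenome`.
#' @export
plant_shared_segment <- function(mg, from, to, length,
                                 from_start = NULL, to_start = NULL) {
  stopifnot(inherits(mg, "virus_metagenome"))
  for (id in c(from, to))
    if (!id %in% names(mg$sequences)) stopf("unknown element: %s", id)
  lf <- nchar(mg$sequences[[from]]); lt <- nchar(mg$sequences[[to]])
  if (length >= lf || length >= lt)
    stopf("shared segment (%d bp) must be shorter than both elements", length)
  if (is.null(from_start)) from_start <- sample.int(lf - length + 1L, 1L)
  if (is.null(to_start)) to_start <- sample.int(lt - length + 1L, 1L)
  seg <- substr(mg$sequences[[from]], from_start, from_start + length - 1L)
  s <- mg$sequences[[to]]
  substr(s, to_start, to_start + length - 1L) <- seg
  mg$sequences[[to]] <- s
  mg
}

#' Simulate paired-end reads from a metagenome
#'
#' Places fragments uniformly along each element (count per element drawn
#' multinomially around the expected abundances), emits both mates with
#' optional uniform substitution errors, and encodes the true source element
#' and position in each read id for oracle testing. Optional shared segments
#' are planted first (see [plant_shared_segment()]) so that some fragments
#' are genuinely ambiguous.
#'
#' @param mg a `virus_metagenome`.
#' @param abundances named numeric vector of expected fragment counts per
#'   element (names must be element ids; elements not named get 0).
#' @param read_len read length (bp).
#' @param frag_len fragment length (bp); `>= read_len` and no longer than
#'   any element with positive abundance.
#' @param error_rate per-base substitution probability.
#' @param seed integer seed.
#' @param shared_segments optional list of `list(from=, to=, length=)`
#'   entries passed to [plant_shared_segment()].
#' @return Object of class `sim_reads`: list with `r1`/`r2` (data.frames of
#'   `id`, `seq`), `truth` (element_id, n_fragments actually drawn),
#'   `metagenome` (after segment planting), and the generator parameters.
#' @export
simulate_reads <- function(mg, abundances, read_len = 150L, frag_len = 250L,
                           error_rate = 0, seed, shared_segments = NULL) {
  stopifnot(inherits(mg, "virus_metagenome"),
            frag_len >= read_len, error_rate >= 0, error_rate < 1)
  unknown <- setdiff(names(abundances), names(mg$sequences))
  if (length(unknown))
    stopf("abundance for unknown element(s): %s", paste(unknown, collapse = ", "))
  if (is.null(names(abundances)) || any(!nzchar(names(abundances))))
    stopf("abundances must be a named vector of element ids")

  with_seed(seed, {
    for (sh in shared_segments)
      mg <- plant_shared_segment(mg, sh$from, sh$to, sh$length,
                                 sh$from_start, sh$to_start)
    pos_ab <- abundances[abundances > 0]
    lens <- nchar(mg$sequences[names(pos_ab)])
    if (any(lens < frag_len))
      stopf("fragment length %d exceeds element length for: %s", frag_len,
            paste(names(pos_ab)[lens < frag_len], collapse = ", "))
    n_total <- round(sum(pos_ab))
    draw <- if (n_total > 0)
      as.vector(stats::rmultinom(1, n_total, prob = pos_ab)) else integer(0)
    truth <- data.frame(element_id = names(pos_ab), n_fragments = draw,
                        stringsAsFactors = FALSE)

    ids <- character(n_total); s1 <- character(n_total); s2 <- character(n_total)
    k <- 0L
    for (j in seq_along(pos_ab)) {
      nj <- draw[j]
      if (nj == 0) next
      el <- names(pos_ab)[j]
      L <- lens[j]
      starts <- sample.int(L - frag_len + 1L, nj, replace = TRUE)
      strands <- sample(c("+", "-"), nj, replace = TRUE)
      frags <- substring(mg$sequences[[el]], starts, starts + frag_len - 1L)
      flip <- strands == "-"
      if (any(flip)) frags[flip] <- revcomp(frags[flip])
      i <- k + seq_len(nj)
      ids[i] <- sprintf("frag%06d|%s|%d|%s", i, el, starts, strands)
      s1[i] <- substr(frags, 1L, read_len)
      s2[i] <- revcomp(substr(frags, frag_len - read_len + 1L, frag_len))
      k <- k + nj
    }
    if (error_rate > 0) {
      s1 <- add_substitutions(s1, error_rate)
      s2 <- add_substitutions(s2, error_rate)
    }
    out <- list(r1 = data.frame(id = ids, seq = s1, stringsAsFactors = FALSE),
                r2 = data.frame(id = ids, seq = s2, stringsAsFactors = FALSE),
                truth = truth, metagenome = mg,
                read_len = as.integer(read_len), frag_len = as.integer(frag_len),
                error_rate = error_rate)
    class(out) <- "sim_reads"
    out
  })
}

# Uniform substitution errors; the replacement base always differs from the
# original.
add_substitutions <- function(seqs, rate) {
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(stats::runif(n) < rate)
    if (!length(hit)) return(s)
    ch <- strsplit(s, "")[[1]]
    for (i in hit) ch[i] <- sample(setdiff(bases, ch[i]), 1L)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate a qPCR Ct table from true relative levels
#'
#' Inverts the doubling-per-cycle model: the reference gene cycles at
#' `ct_ref_base` and the target at `ct_ref_base - log2(level)`, each plus
#' independent Gaussian measurement noise per well, replicated over the
#' design's biological and technical replicates.
#'
#' @param design a `study_design` (uses `n_bio_replicates` and
#'   `n_tech_replicates`).
#' @param levels data.frame with columns `gene`, `cell_line`, `medium`,
#'   `level` (true relative expression, > 0) covering every design condition
#'   for every gene.
#' @param reference_gene reference gene name added to the table.
#' @param ct_ref_base expected reference-gene Ct (cycles).
#' @param noise_sd Gaussian noise sd on the Ct scale (cycles); >= 0.
#' @param seed integer seed.
#' @return Object of class `ct_table`: data.frame with columns `sample_id`,
#'   `cell_line`, `medium`, `bio_rep`, `tech_rep`, `gene`, `ct`.
#' @export
simulate_ct <- function(design, levels, reference_gene = "HPRT1",
                        ct_ref_base = 20, noise_sd = 0.25, seed) {
  stopifnot(inherits(design, "study_design"), noise_sd >= 0)
  req <- c("gene", "cell_line", "medium", "level")
  miss <- setdiff(req, names(levels))
  if (length(miss)) stopf("levels is missing column(s): %s", paste(miss, collapse = ", "))
  if (any(levels$level <= 0)) stopf("true relative levels must be positive")
  if (reference_gene %in% levels$gene)
    stopf("reference gene %s must not appear in `levels`", reference_gene)

  genes <- unique(levels$gene)
  samples <- design_samples(design)
  with_seed(seed, {
    rows <- vector("list", nrow(samples))
    for (i in seq_len(nrow(samples))) {
      cl <- samples$cell_line[i]; md <- samples$medium[i]
      rec <- list()
      for (g in genes) {
        lv <- levels$level[levels$gene == g & levels$cell_line == cl &
                           levels$medium == md]
        if (length(lv) != 1)
          stopf("levels must give exactly one level for gene %s in (%s, %s)",
                g, cl, md)
        ct_t <- ct_ref_base - log2(lv) +
          stats::rnorm(design$n_tech_replicates, 0, noise_sd)
        rec[[g]] <- data.frame(tech_rep = seq_len(design$n_tech_replicates),
                               gene = g, ct = ct_t, stringsAsFactors = FALSE)
      }
      ct_r <- ct_ref_base + stats::rnorm(design$n_tech_replicates, 0, noise_sd)
      rec[[reference_gene]] <- data.frame(
        tech_rep = seq_len(design$n_tech_replicates),
        gene = reference_gene, ct = ct_r, stringsAsFactors = FALSE)
      blk <- do.call(rbind, rec)
      blk <- cbind(samples[rep(i, nrow(blk)), c("sample_id", "cell_line",
                                                "medium", "bio_rep")], blk)
      rows[[i]] <- blk
    }
    ct <- do.call(rbind, rows)
    rownames(ct) <- NULL
    class(ct) <- c("ct_table", "data.frame")
    ct
  })
}

#' Packaged default metagenome manifest
#'
#' Generates the synthetic default reference whose composition matches the
#' published virus-metagenome design: 119 endogenous human viral elements —
#' 115 HERV elements over 14 families (92 of them full-length
#' HERV-K(HML-2)), 3 bornavirus-like EBLN elements, and 1 additional
#' unclassified endogenous element — plus 4 housekeeping controls and 124
#' unrelated-virus spacers. Sequences are pseudo-random (no real accessions
#' are reproduced); element lengths are drawn from 1,000-9,500 bp.
#' Composition is identical for every seed; sequences differ.
#'
#' @param seed integer seed.
#' @return List with `manifest` (data.frame) and `sequences` (named
#'   character), ready for [build_metagenome()].
#' @export
make_default_manifest <- function(seed = 20201204) {
  herv_families <- c(
    "HERV-K(HML-2)" = 92L, "HERV-W" = 3L, "HERV-Fc" = 3L, "HERV-H" = 3L,
    "HERV-R(ERV3)" = 2L, "HERV-E" = 2L, "HERV-L" = 2L, "HERV-T" = 2L,
    "HERV-FRD" = 1L, "HERV-P" = 1L, "HERV-I" = 1L, "HERV-S" = 1L,
    "HERV-V" = 1L, "HERV-ADP" = 1L)
  stopifnot(sum(herv_families) == 115L, length(herv_families) == 14L)

  rows <- list()
  for (fam in names(herv_families)) {
    n <- herv_families[[fam]]
    tag <- gsub("[^A-Za-z0-9]+", "", fam)
    rows[[fam]] <- data.frame(
      element_id = sprintf("%s_%03d", tag, seq_len(n)),
      family = fam, category = "endogenous_human", stringsAsFactors = FALSE)
  }
  rows[["EBLN"]] <- data.frame(
    element_id = c("EBLN-1", "EBLN-2", "EBLN-3P"),
    family = "EBLN", category = "endogenous_human", stringsAsFactors = FALSE)
  rows[["other"]] <- data.frame(
    element_id = "EVE-X1", family = "EVE-unclassified",
    category = "endogenous_human", stringsAsFactors = FALSE)
  rows[["housekeeping"]] <- data.frame(
    element_id = c("HPRT1", "ACTB", "GAPDH", "TUBB"),
    family = "housekeeping", category = "housekeeping", stringsAsFactors = FALSE)
  rows[["spacer"]] <- data.frame(
    element_id = sprintf("spacer_%03d", seq_len(124L)),
    family = "spacer", category = "spacer", stringsAsFactors = FALSE)
  man <- do.call(rbind, rows)
  rownames(man) <- NULL
  man <- data.frame(element_id = man$element_id,
                    accession_label = sprintf("SYN%06d.1", seq_len(nrow(man))),
                    family = man$family, category = man$category,
                    stringsAsFactors = FALSE)

  seqs <- with_seed(seed, {
    lens <- sample(1000:9500, nrow(man), replace = TRUE)
    stats::setNames(vapply(lens, random_dna, character(1)), man$element_id)
  })
  list(manifest = man, sequences = seqs)
}
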