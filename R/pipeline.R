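# End-to-end orchestrator: reference -> simulate -> quantify -> ddct ->
# screen, deterministic under one master seed. Each stage draws from its own
# seed substream (derived from the stage name), so enabling or reordering
# stages never perturbs another stage's draws.

#' Packaged study-shaped scenario configuration
#'
#' A declarative run configuration emulating the study design the package
#' targets: 3 neuroblastoma cell lines x 3 media (serum-free stem-cell
#' medium as the perturbation) with 2 RNA-seq and 3 qPCR biological
#' replicates; a default virus metagenome; planted serum-free up-regulation
#' of selected HERV families; a qPCR anchor gene (HERV-K GAG) elevated in
#' serum-free medium; and a human FPKM matrix with planted anchor-tracking
#' genes among nulls. Numbers are chosen for desk-scale runtimes.
#'
#' @return A nested list understood by [run_pipeline()].
#' @export
default_scenario <- function() {
  list(
    stages = c("reference", "reads", "counts", "ddct", "screen"),
    design = study_design(),
    qpcr_design = study_design(n_bio_replicates = 3L, n_tech_replicates = 2L),
    reads = list(
      per_endogenous = 8, per_housekeeping = 10, per_spacer = 2,
      read_len = 150L, frag_len = 250L, error_rate = 0.001,
      shared_segments = list(
        list(from = "HERVKHML2_001", to = "HERVKHML2_002", length = 900L))),
    assign = list(k = 31L, max_mismatches = 2L),
    counts = list(
      baseline = 200, dispersion = 0.02,
      family_fold_changes = c("HERV-E" = 2.0, "HERV-R(ERV3)" = 1.8,
                              "HERV-Fc" = 1.6, "HERV-K(HML-2)" = 1.3)),
    ct = list(
      reference_gene = "HPRT1", ct_ref_base = 20, noise_sd = 0.25,
      serum_free_levels = c("HERV-K_GAG" = 4, "CD200" = 3)),
    ct_file = NULL,
    screen = list(
      n_null = 500L, n_up = 20L, n_down = 10L, planted_fc = 2.0,
      baseline = 1000, dispersion = 0.02,
      config = screen_config(r_threshold = 0.7, fc_threshold = 1.4))
  )
}

#' Run the full pipeline into an output directory
#'
#' Executes the enabled stages of a scenario configuration, writing every
#' intermediate and final table under `out_dir` plus a provenance manifest
#' (`provenance.tsv`) with the seed, a configuration checksum and per-file
#' checksums. Re-running with the same configuration and seed reproduces
#' every output byte for byte.
#'
#' @param config scenario configuration (see [default_scenario()]).
#' @param seed master integer seed.
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the in-memory stage results and output
#'   paths.
#' @export
run_pipeline <- function(config = default_scenario(), seed, out_dir,
                         quiet = TRUE) {
  stopifnot(is.list(config), is.numeric(seed), length(seed) == 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stages <- config$stages
  if (is.null(stages)) stages <- default_scenario()$stages
  if (!is.null(config$ct_file) && "ddct" %in% stages &&
      !file.exists(config$ct_file))
    stopf("stage ddct: Ct file not found: %s", config$ct_file)

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stopf("stage %s failed: %s", name, conditionMessage(e)))
  }
  res <- list()
  outp <- function(f) file.path(out_dir, f)

  # --- reference ------------------------------------------------------
  say("stage reference")
  res$metagenome <- run_stage("reference", function() {
    def <- make_default_manifest(derive_seed(seed, "reference"))
    mg <- build_metagenome(def$manifest, def$sequences)
    export_reference(mg, outp("ref.fasta"), outp("ref.saf"))
    write_manifest(mg$manifest, outp("ref_manifest.tsv"))
    comp <- summarize_composition(mg)
    write_tsv(data.frame(
      metric = c("n_endogenous_human", "n_housekeeping", "n_spacer",
                 "n_herv_elements", "n_herv_families", "n_ebln", "n_other"),
      value = c(comp$n_endogenous_human, comp$n_housekeeping, comp$n_spacer,
                comp$n_herv_elements, comp$n_herv_families, comp$n_ebln,
                comp$n_other)), outp("composition.tsv"))
    write_tsv(data.frame(family = names(comp$family_sizes),
                         n_members = as.integer(comp$family_sizes)),
              outp("family_sizes.tsv"))
    list(mg = mg, composition = comp)
  })
  mg <- res$metagenome$mg

  # --- reads: one library through the assigner ------------------------
  if ("reads" %in% stages) {
    say("stage reads")
    res$reads <- run_stage("reads", function() {
      rc <- config$reads
      man <- mg$manifest
      ab <- stats::setNames(
        ifelse(man$category == "endogenous_human", rc$per_endogenous,
               ifelse(man$category == "housekeeping", rc$per_housekeeping,
                      rc$per_spacer)),
        man$element_id)
      sim <- simulate_reads(mg, ab, read_len = rc$read_len,
                            frag_len = rc$frag_len,
                            error_rate = rc$error_rate,
                            seed = derive_seed(seed, "reads"),
                            shared_segments = rc$shared_segments)
      write_fastq_pair(sim, outp("reads_R1.fastq"), outp("reads_R2.fastq"))
      write_tsv(sim$truth, outp("reads_truth.tsv"))
      asn <- assign_fragments(sim, sim$metagenome, k = config$assign$k,
                              max_mismatches = config$assign$max_mismatches)
      write_tsv(data.frame(
        metric = c("n_total", "n_unique", "n_ambiguous", "n_unassigned"),
        value = c(asn$n_total, sum(asn$unique_counts), asn$n_ambiguous,
                  asn$n_unassigned)), outp("assignment_summary.tsv"))
      lens <- stats::setNames(mg$manifest$length_bp, mg$manifest$element_id)
      ef <- element_fpkm(asn$unique_counts, lens, sum(asn$unique_counts))
      write_tsv(ef, outp("library_element_fpkm.tsv"))
      ff <- family_fpkm(asn$unique_counts, mg, sum(asn$unique_counts))
      write_tsv(ff, outp("library_family_fpkm.tsv"))
      list(sim = sim, assignment = asn, element_fpkm = ef, family_fpkm = ff)
    })
  }

  # --- counts: design-wide metagenome quantification ------------------
  if ("counts" %in% stages) {
    say("stage counts")
    res$counts <- run_stage("counts", function() {
      cc <- config$counts
      feats <- mg$manifest$element_id
      eff <- list()
      for (fam in names(cc$family_fold_changes)) {
        for (id in mg$family_index[[fam]])
          eff[[id]] <- effect_spec(id, baseline_mean = cc$baseline,
                                   fold_change = cc$family_fold_changes[[fam]],
                                   dispersion = cc$dispersion)
      }
      eff <- do.call(rbind, eff)
      sim <- simulate_counts(config$design, eff, feats,
                             seed = derive_seed(seed, "counts"),
                             baseline_mean = cc$baseline,
                             dispersion = cc$dispersion)
      lens <- stats::setNames(mg$manifest$length_bp, mg$manifest$element_id)
      write_counts_table(sim$counts, lens, outp("metagenome_counts.tsv"))
      fc_tab <- read_counts_table(outp("metagenome_counts.tsv"))
      fmat <- family_fpkm_matrix(fc_tab$counts, mg)
      write_expression_matrix(fmat, outp("family_fpkm_matrix.tsv"))
      write_sample_metadata(sim$samples, outp("rnaseq_metadata.tsv"))
      ranking <- rank_families(fmat, sim$samples$serum_free)
      write_tsv(ranking, outp("family_ranking.tsv"))
      list(sim = sim, family_fpkm = fmat, ranking = ranking)
    })
  }

  # --- ddct: qPCR relative quantification + statistics ----------------
  if ("ddct" %in% stages) {
    say("stage ddct")
    res$ddct <- run_stage("ddct", function() {
      tc <- config$ct
      if (!is.null(config$ct_file)) {
        ct <- read_ct_table(config$ct_file)
      } else {
        qd <- config$qpcr_design
        conds <- expand.grid(cell_line = qd$cell_lines, medium = qd$media,
                             stringsAsFactors = FALSE)
        levels <- do.call(rbind, lapply(names(tc$serum_free_levels), function(g) {
          data.frame(gene = g, cell_line = conds$cell_line,
                     medium = conds$medium,
                     level = ifelse(conds$medium %in% qd$serum_free_media,
                                    tc$serum_free_levels[[g]], 1),
                     stringsAsFactors = FALSE)
        }))
        ct <- simulate_ct(qd, levels, reference_gene = tc$reference_gene,
                          ct_ref_base = tc$ct_ref_base,
                          noise_sd = tc$noise_sd,
                          seed = derive_seed(seed, "ddct"))
        write_ct_table(ct, outp("ct.csv"))
      }
      dct <- delta_ct(ct, tc$reference_gene)
      rel <- rel_expression(dct)
      write_tsv(as.data.frame(rel), outp("rel_expression.tsv"))
      stats_rows <- list()
      for (g in unique(rel$gene)) {
        an <- two_way_anova(rel, g)
        an <- cbind(gene = g, kind = "anova", an,
                    comparison = NA, p_adj = NA, stars = NA)
        tk <- tukey_hsd(rel, g)
        tk <- data.frame(gene = g, kind = "tukey", term = tk$within,
                         df = NA, sum_sq = NA, mean_sq = NA,
                         statistic = tk$q, p_value = NA,
                         comparison = tk$comparison, p_adj = tk$p_adj,
                         stars = tk$stars, stringsAsFactors = FALSE)
        stats_rows[[g]] <- rbind(an, tk)
      }
      report <- do.call(rbind, stats_rows)
      rownames(report) <- NULL
      write_tsv(report, outp("stats_report.tsv"))
      list(ct = ct, rel = rel, report = report)
    })
  }

  # --- screen: anchor correlation + fold-change filter ----------------
  if ("screen" %in% stages) {
    say("stage screen")
    res$screen <- run_stage("screen", function() {
      sc <- config$screen
      stage_seed <- derive_seed(seed, "screen")
      genes <- c(sprintf("null_%04d", seq_len(sc$n_null)),
                 sprintf("up_%03d", seq_len(sc$n_up)),
                 sprintf("down_%03d", seq_len(sc$n_down)),
                 "CD200")
      eff <- rbind(
        do.call(rbind, lapply(sprintf("up_%03d", seq_len(sc$n_up)), effect_spec,
                              baseline_mean = sc$baseline,
                              fold_change = sc$planted_fc,
                              dispersion = sc$dispersion)),
        do.call(rbind, lapply(sprintf("down_%03d", seq_len(sc$n_down)),
                              effect_spec, baseline_mean = sc$baseline,
                              fold_change = 1 / sc$planted_fc,
                              dispersion = sc$dispersion)),
        effect_spec("CD200", baseline_mean = sc$baseline, fold_change = 3,
                    dispersion = sc$dispersion))
      sim <- simulate_counts(config$design, eff, genes, seed = stage_seed,
                             baseline_mean = sc$baseline,
                             dispersion = sc$dispersion)
      gene_lens <- with_seed(stage_seed + 1L,
                             stats::setNames(sample(500:5000, length(genes),
                                                    replace = TRUE), genes))
      fpkm <- element_fpkm_matrix(sim$counts, gene_lens)
      write_expression_matrix(fpkm, outp("human_fpkm_matrix.tsv"))
      write_sample_metadata(sim$samples, outp("screen_metadata.tsv"))

      # anchor: qPCR condition means of the HERV-K GAG relative expression
      rel <- res$ddct$rel
      if (is.null(rel))
        stopf("screen stage needs the ddct stage (anchor source)")
      anchor_gene <- names(config$ct$serum_free_levels)[1]
      rg <- rel[rel$gene == anchor_gene, ]
      anchor <- stats::aggregate(rel_expr ~ cell_line + medium, data = rg,
                                 FUN = mean)
      names(anchor)[names(anchor) == "rel_expr"] <- "value"
      write_anchor(anchor, outp("anchor.csv"))
      av <- expand_anchor(anchor, sim$samples)
      scr <- screen(fpkm, sim$samples, av, config = sc$config)
      write_tsv(scr$table, outp("screen.tsv"))
      write_expression_matrix(scr$z_matrix, outp("screen_zmatrix.tsv"))
      writeLines(scr$up, outp("screen_up_genes.txt"))
      writeLines(scr$down, outp("screen_down_genes.txt"))
      list(sim = sim, fpkm = fpkm, anchor = anchor, result = scr)
    })
  }

  # --- provenance -----------------------------------------------------
  cfg_file <- outp("config.txt")
  writeLines(deparse(config[setdiff(names(config), "stages")]), cfg_file)
  files <- sort(setdiff(list.files(out_dir), "provenance.tsv"))
  sums <- tools::md5sum(file.path(out_dir, files))
  prov <- data.frame(
    key = c("seed", "package_version", "config_md5",
            paste0("md5:", files)),
    value = c(as.character(seed),
              as.character(utils::packageVersion("hervscape")),
              unname(tools::md5sum(cfg_file)), unname(sums)),
    stringsAsFactors = FALSE)
  write_tsv(prov, outp("provenance.tsv"))
  res$provenance <- prov
  say("done: %s", out_dir)
  invisible(res)
}
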