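# Median-calibrated 2^-delta-delta-Ct relative quantification and the
# accompanying group statistics (two-way ANOVA, Tukey HSD).

#' Per-sample delta-Ct against a reference gene
#'
#' Technical replicates are collapsed first by the arithmetic mean of Ct per
#' (sample, gene); then `delta_ct = mean Ct_target - mean Ct_reference` per
#' sample and target gene. Wells with missing Ct are dropped with a warning;
#' a sample lacking the reference gene is an error.
#'
#' @param ct a `ct_table` (or data.frame) with columns `sample_id`,
#'   `cell_line`, `medium`, `bio_rep`, `tech_rep`, `gene`, `ct`.
#' @param reference_gene the normalization gene (default the HPRT1
#'   housekeeping transcript).
#' @return data.frame of class `delta_ct_table` with columns `sample_id`,
#'   `cell_line`, `medium`, `bio_rep`, `gene`, `delta_ct`.
#' @export
delta_ct <- function(ct, reference_gene = "HPRT1") {
  req <- c("sample_id", "cell_line", "medium", "bio_rep", "tech_rep", "gene", "ct")
  miss <- setdiff(req, names(ct))
  if (length(miss)) stopf("ct table is missing column(s): %s", paste(miss, collapse = ", "))
  ct <- as.data.frame(ct)
  n_na <- sum(!is.finite(ct$ct))
  if (n_na) {
    warning(sprintf("dropping %d well(s) with missing Ct", n_na), call. = FALSE)
    ct <- ct[is.finite(ct$ct), , drop = FALSE]
  }
  if (!reference_gene %in% ct$gene)
    stopf("reference gene %s not present in the Ct table", reference_gene)
  targets <- setdiff(unique(ct$gene), reference_gene)
  if (!length(targets))
    stopf("Ct table contains only reference-gene measurements")

  means <- stats::aggregate(ct ~ sample_id + gene, data = ct, FUN = mean)
  meta <- unique(ct[, c("sample_id", "cell_line", "medium", "bio_rep")])
  ref <- means[means$gene == reference_gene, c("sample_id", "ct")]
  names(ref)[2] <- "ct_ref"
  no_ref <- setdiff(unique(ct$sample_id), ref$sample_id)
  if (length(no_ref))
    stopf("sample(s) missing the reference gene %s: %s", reference_gene,
          paste(no_ref, collapse = ", "))

  tg <- means[means$gene != reference_gene, ]
  tg <- merge(tg, ref, by = "sample_id")
  tg$delta_ct <- tg$ct - tg$ct_ref
  out <- merge(meta, tg[, c("sample_id", "gene", "delta_ct")], by = "sample_id")
  out <- out[order(out$gene, out$cell_line, out$medium, out$bio_rep), ]
  rownames(out) <- NULL
  class(out) <- c("delta_ct_table", "data.frame")
  out
}

#' Median-calibrated relative expression (2^-delta-delta-Ct)
#'
#' Per gene, the calibrator is chosen so that the median relative expression
#' across all samples equals 1: `rel_expr = 2^-delta_ct /
#' median(2^-delta_ct)`, equivalently `2^-(delta_ct - c)` with
#' `c = -log2(median(2^-delta_ct))`. Calibrating on the linear scale makes
#' the median exactly 1 for any sample count (for odd counts it coincides
#' with taking the median delta-Ct).
#'
#' @param dct a `delta_ct_table` from [delta_ct()].
#' @return data.frame of class `rel_expression_table`: the input plus
#'   columns `rel_expr` and `calibrator` (the per-gene calibrator on the Ct
#'   scale).
#' @export
rel_expression <- function(dct) {
  stopifnot(all(c("sample_id", "gene", "delta_ct") %in% names(dct)))
  out <- as.data.frame(dct)
  out$rel_expr <- NA_real_
  out$calibrator <- NA_real_
  for (g in unique(out$gene)) {
    idx <- out$gene == g
    lin <- 2^(-out$delta_ct[idx])
    cal <- -log2(stats::median(lin))
    out$rel_expr[idx] <- lin / stats::median(lin)
    out$calibrator[idx] <- cal
  }
  class(out) <- c("rel_expression_table", "data.frame")
  out
}

#' Two-way fixed-effects ANOVA on relative expression
#'
#' Fits `transform(rel_expr) ~ factor_a * factor_b` for one gene on a
#' balanced design (equal replicates in every cell; unbalanced designs are
#' rejected) and returns the standard ANOVA decomposition. The default
#' response is log2 relative expression, which stabilizes the variance of
#' fold-change-scale data.
#'
#' @param rel a `rel_expression_table`.
#' @param gene gene to test.
#' @param factor_a,factor_b column names of the two factors.
#' @param response_transform function applied to `rel_expr` (default
#'   `log2`); use `identity` for the raw scale.
#' @return data.frame with columns `term`, `df`, `sum_sq`, `mean_sq`,
#'   `statistic`, `p_value` (terms: factor_a, factor_b, interaction,
#'   residuals). F statistics are `NA` when the residual variance is 0.
#' @export
two_way_anova <- function(rel, gene, factor_a = "cell_line",
                          factor_b = "medium", response_transform = log2) {
  d <- anova_frame(rel, gene, factor_a, factor_b, response_transform)
  fit <- stats::aov(y ~ A * B, data = d)
  s <- summary(fit)[[1]]
  out <- data.frame(
    term = c(factor_a, factor_b, paste0(factor_a, ":", factor_b), "residuals"),
    df = s[["Df"]],
    sum_sq = s[["Sum Sq"]],
    mean_sq = s[["Mean Sq"]],
    statistic = c(s[["F value"]][1:3], NA),
    p_value = c(s[["Pr(>F)"]][1:3], NA),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (isTRUE(all.equal(out$mean_sq[4], 0))) {
    out$statistic[1:3] <- NA_real_
    out$p_value[1:3] <- NA_real_
  }
  out
}

# Shared validation: one gene, two crossed factors, balanced with >= 2
# replicates per cell.
anova_frame <- function(rel, gene, factor_a, factor_b, response_transform) {
  stopifnot(all(c("gene", "rel_expr", factor_a, factor_b) %in% names(rel)))
  d <- rel[rel$gene == gene, , drop = FALSE]
  if (!nrow(d)) stopf("gene %s not present in the table", gene)
  d <- data.frame(A = factor(d[[factor_a]]), B = factor(d[[factor_b]]),
                  y = response_transform(d$rel_expr))
  if (nlevels(d$A) < 2 || nlevels(d$B) < 2)
    stopf("both factors need at least 2 levels")
  tab <- table(d$A, d$B)
  if (any(tab == 0)) stopf("empty design cell(s); unbalanced designs are rejected")
  if (length(unique(as.vector(tab))) != 1)
    stopf("unequal cell sizes; unbalanced designs are rejected")
  if (tab[1] < 2) stopf("at least 2 replicates per cell are required")
  d
}

#' Tukey HSD comparisons within strata
#'
#' Pairwise comparisons of `factor` levels within each level of `within`
#' (e.g. media within each cell line), using the pooled residual mean square
#' and error degrees of freedom of the full two-way model and studentized
#' range p-values. Significance tiers follow the `*` convention of
#' [significance_stars()].
#'
#' @inheritParams two_way_anova
#' @param factor factor whose levels are compared (default `medium`).
#' @param within stratifying factor (default `cell_line`).
#' @return data.frame with columns `within`, `comparison`, `diff` (on the
#'   transformed scale), `se`, `q`, `p_adj`, `stars`.
#' @export
tukey_hsd <- function(rel, gene, factor = "medium", within = "cell_line",
                      response_transform = log2) {
  d <- anova_frame(rel, gene, within, factor, response_transform)
  # d$A = within, d$B = compared factor
  fit <- stats::aov(y ~ A * B, data = d)
  s <- summary(fit)[[1]]
  mse <- s[["Mean Sq"]][4]
  df_err <- s[["Df"]][4]
  n_cell <- as.vector(table(d$A, d$B))[1]
  k <- nlevels(d$B)
  lev_b <- levels(d$B)
  rows <- list()
  for (w in levels(d$A)) {
    cm <- tapply(d$y[d$A == w], d$B[d$A == w], mean)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      diff <- cm[[lev_b[j]]] - cm[[lev_b[i]]]
      se <- sqrt(mse / n_cell)
      if (se == 0) {
        q <- if (abs(diff) == 0) 0 else Inf
        p <- if (abs(diff) == 0) 1 else 0
      } else {
        q <- abs(diff) / se
        p <- stats::ptukey(q, nmeans = k, df = df_err, lower.tail = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        within = w, comparison = paste(lev_b[j], "-", lev_b[i]),
        diff = diff, se = se, q = q, p_adj = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$stars <- significance_stars(out$p_adj)
  rownames(out) <- NULL
  out
}
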