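# Anchor-gene correlation screen: select transcripts whose expression
# profile tracks a qPCR anchor (e.g. a HERV-K GAG relative-expression
# profile) with |Pearson r| above a cutoff AND a serum-free fold change
# above a cutoff; plus row Z-scores for heatmap display and family ranking.

#' Pearson correlation with validity checks
#'
#' @param x,y numeric vectors of equal length >= 3, both non-constant.
#' @return The sample Pearson correlation coefficient in [-1, 1].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 3) stopf("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("correlation undefined for a constant vector")
  stats::cor(x, y)
}

#' Screen configuration
#'
#' @param r_threshold minimal |Pearson r| (default 0.7).
#' @param fc_threshold minimal fold change, expressed >= 1 (default 1.4).
#' @param pseudocount added to group means before ratios (expression units;
#'   default 0.01) to guard zero-expression genes.
#' @return Object of class `screen_config`.
#' @export
screen_config <- function(r_threshold = 0.7, fc_threshold = 1.4,
                          pseudocount = 0.01) {
  stopifnot(r_threshold > 0, r_threshold <= 1, fc_threshold >= 1,
            pseudocount >= 0)
  structure(list(r_threshold = r_threshold, fc_threshold = fc_threshold,
                 pseudocount = pseudocount), class = "screen_config")
}

#' Expand condition-level anchor values to per-sample values
#'
#' qPCR anchors are measured per (cell line, medium) condition; RNA-seq
#' samples of the same condition share the anchor value.
#'
#' @param anchor data.frame with columns `cell_line`, `medium`, `value`.
#' @param metadata per-sample metadata with columns `cell_line`, `medium`
#'   (row order = sample order).
#' @return Numeric vector, one anchor value per metadata row.
#' @export
expand_anchor <- function(anchor, metadata) {
  stopifnot(all(c("cell_line", "medium", "value") %in% names(anchor)),
            all(c("cell_line", "medium") %in% names(metadata)))
  key <- function(cl, md) paste(cl, md, sep = "\r")
  map <- stats::setNames(anchor$value, key(anchor$cell_line, anchor$medium))
  wanted <- key(metadata$cell_line, metadata$medium)
  missing <- !(wanted %in% names(map))
  if (any(missing)) {
    mk <- unique(metadata[missing, c("cell_line", "medium")])
    stopf("anchor value missing for condition(s): %s",
          paste(sprintf("(%s, %s)", mk$cell_line, mk$medium), collapse = ", "))
  }
  as.numeric(map[wanted])
}

#' Serum-free versus serum-supplemented fold change
#'
#' `m1` is the mean over serum-free samples and `m0` over the remaining
#' (serum-supplemented) samples, both plus the pseudocount; the fold change
#' is reported as `max(m1/m0, m0/m1) >= 1` with `direction` carrying the
#' sign (`up` when the serum-free mean is larger; ties are `up` with fold
#' change 1 by convention).
#'
#' @param expr numeric matrix, features x samples.
#' @param gene feature id (row of `expr`).
#' @param serum_free logical vector per sample (TRUE = serum-free group).
#' @param pseudocount added to both group means.
#' @return List with `fc` (>= 1) and `direction` (`"up"` or `"down"`).
#' @export
fold_change <- function(expr, gene, serum_free, pseudocount = 0.01) {
  if (!gene %in% rownames(expr)) stopf("gene %s not present", gene)
  stopifnot(length(serum_free) == ncol(expr))
  if (!any(serum_free) || all(serum_free)) stopf("both groups must be non-empty")
  x <- expr[gene, ]
  m1 <- mean(x[serum_free]) + pseudocount
  m0 <- mean(x[!serum_free]) + pseudocount
  if (m1 == m0) return(list(fc = 1, direction = "up"))
  list(fc = max(m1 / m0, m0 / m1),
       direction = if (m1 > m0) "up" else "down")
}

#' Anchor-correlation + fold-change gene screen
#'
#' For every gene, computes the Pearson correlation of its expression
#' profile with the per-sample anchor vector and its serum-free fold
#' change; a gene passes iff `|r| >= r_threshold` and
#' `fc >= fc_threshold`. Constant genes are excluded (counted, never
#' assigned r = 0). Passing genes are partitioned into up- and
#' down-regulated sets by fold-change direction, each sorted by |r|
#' descending (ties: fold change descending, then gene id).
#'
#' @param expr numeric matrix, features x samples (e.g. FPKM).
#' @param metadata per-sample metadata with columns `cell_line`, `medium`,
#'   `serum_free` (rows aligned with `expr` columns).
#' @param anchor_vector per-sample anchor values (see [expand_anchor()]).
#' @param config a [screen_config()].
#' @param log2_expr correlate on log2(expr + pseudocount) instead of the
#'   raw scale.
#' @return Object of class `screen_result`: list with `table` (gene,
#'   pearson_r, fold_change, direction, passes), `up`/`down` (ordered gene
#'   ids), `n_constant_excluded`, `z_matrix` (row Z-scores of `expr`), and
#'   `config`.
#' @export
screen <- function(expr, metadata, anchor_vector, config = screen_config(),
                   log2_expr = FALSE) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  if (anyDuplicated(rownames(expr))) stopf("duplicate feature ids")
  if (!is.null(colnames(expr)) && anyDuplicated(colnames(expr)))
    stopf("duplicate sample ids")
  if (length(anchor_vector) != ncol(expr))
    stopf("anchor vector length (%d) != sample count (%d)",
          length(anchor_vector), ncol(expr))
  stopifnot(nrow(metadata) == ncol(expr), "serum_free" %in% names(metadata))
  if (stats::sd(anchor_vector) == 0) stopf("anchor vector is constant")

  cx <- if (log2_expr) log2(expr + config$pseudocount) else expr
  genes <- rownames(expr)
  const <- apply(cx, 1, function(v) stats::sd(v) == 0)
  r <- rep(NA_real_, length(genes))
  r[!const] <- as.vector(stats::cor(t(cx[!const, , drop = FALSE]), anchor_vector))
  fc <- numeric(length(genes)); dir <- character(length(genes))
  for (i in seq_along(genes)) {
    f <- fold_change(expr, genes[i], metadata$serum_free, config$pseudocount)
    fc[i] <- f$fc; dir[i] <- f$direction
  }
  dir[const] <- "excluded"
  passes <- !const & abs(r) >= config$r_threshold & fc >= config$fc_threshold
  tab <- data.frame(gene = genes, pearson_r = r, fold_change = fc,
                    direction = dir, passes = passes,
                    stringsAsFactors = FALSE, row.names = NULL)
  ord <- function(d) {
    d <- d[order(-abs(d$pearson_r), -d$fold_change, d$gene), ]
    d$gene
  }
  up <- ord(tab[tab$passes & tab$direction == "up", , drop = FALSE])
  down <- ord(tab[tab$passes & tab$direction == "down", , drop = FALSE])
  out <- list(table = tab, up = up, down = down,
              n_constant_excluded = sum(const),
              z_matrix = zscore_rows(expr), config = config)
  class(out) <- "screen_result"
  out
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("screen_result: %d genes tested (|r| >= %g, fc >= %g)\n",
              nrow(x$table), x$config$r_threshold, x$config$fc_threshold))
  cat(sprintf("  passing: %d (%d up, %d down)\n",
              sum(x$table$passes), length(x$up), length(x$down)))
  if (x$n_constant_excluded)
    cat(sprintf("  constant genes excluded: %d\n", x$n_constant_excluded))
  invisible(x)
}

#' Row Z-scores for heatmap display
#'
#' Per row: `(x - row mean) / row sd` (sd with n-1 denominator). Constant
#' rows become all-zero and are flagged in the `"constant_rows"` attribute.
#'
#' @param expr numeric matrix with >= 2 columns.
#' @return Matrix of the same shape; attribute `constant_rows` holds the
#'   flagged row names (character(0) if none).
#' @export
zscore_rows <- function(expr) {
  stopifnot(is.matrix(expr))
  if (ncol(expr) < 2) stopf("row Z-scores need at least 2 samples")
  mu <- rowMeans(expr)
  sdv <- apply(expr, 1, stats::sd)
  const <- sdv == 0
  sdv[const] <- 1
  z <- (expr - mu) / sdv
  z[const, ] <- 0
  attr(z, "constant_rows") <- rownames(expr)[const]
  z
}

#' Rank virus families by serum-free differential expression
#'
#' Per family, the differential is the signed log2 ratio of the serum-free
#' mean to the serum-supplemented mean (pseudocount-guarded); families are
#' ordered from strongest up-regulation to strongest down-regulation (ties
#' broken by family name).
#'
#' @param family_fpkm numeric matrix, families x samples.
#' @param serum_free logical vector per sample.
#' @param pseudocount added to both group means.
#' @return data.frame with columns `family`, `mean_serum_free`,
#'   `mean_serum`, `log2_differential`, `rank`, ordered by rank.
#' @export
rank_families <- function(family_fpkm, serum_free, pseudocount = 0.01) {
  stopifnot(is.matrix(family_fpkm), !is.null(rownames(family_fpkm)),
            nrow(family_fpkm) >= 1, length(serum_free) == ncol(family_fpkm))
  if (!any(serum_free) || all(serum_free)) stopf("both groups must be non-empty")
  m1 <- rowMeans(family_fpkm[, serum_free, drop = FALSE]) + pseudocount
  m0 <- rowMeans(family_fpkm[, !serum_free, drop = FALSE]) + pseudocount
  d <- log2(m1 / m0)
  out <- data.frame(family = rownames(family_fpkm),
                    mean_serum_free = m1 - pseudocount,
                    mean_serum = m0 - pseudocount,
                    log2_differential = d,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$log2_differential, out$family), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Minimal Z-score heatmap
#'
#' Convenience image of a row-Z-scored matrix (values above the row mean in
#' yellow, below in blue), for a quick look at screen output; use a
#' dedicated heatmap tool for figures.
#'
#' @param z matrix of row Z-scores (see [zscore_rows()]).
#' @param ... passed to [graphics::image()].
#' @return Invisibly, `z`.
#' @export
plot_zscore_heatmap <- function(z, ...) {
  pal <- grDevices::colorRampPalette(c("blue", "black", "yellow"))(101)
  lim <- max(abs(range(z, finite = TRUE)), 1e-9)
  graphics::image(t(z[rev(seq_len(nrow(z))), , drop = FALSE]),
                  col = pal, zlim = c(-lim, lim), axes = FALSE, ...)
  invisible(z)
}
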