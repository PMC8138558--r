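# delta-Ct, median-calibrated relative expression, ANOVA, Tukey HSD.

make_ct <- function(df) {
  # df: sample_id, gene, ct (tech reps as repeated rows); metadata filled in
  df$cell_line <- "A"; df$medium <- "M"; df$bio_rep <- 1L
  df$tech_rep <- stats::ave(seq_len(nrow(df)),
                            df$sample_id, df$gene, FUN = seq_along)
  class(df) <- c("ct_table", "data.frame")
  df
}

test_that("delta_ct averages technical replicates before subtracting", {
  ct <- make_ct(data.frame(
    sample_id = "s1",
    gene = c("T", "T", "HPRT1", "HPRT1"),
    ct = c(25, 25, 20, 20), stringsAsFactors = FALSE))
  expect_equal(delta_ct(ct)$delta_ct, 5)

  ct2 <- make_ct(data.frame(
    sample_id = "s1",
    gene = c("T", "T", "HPRT1", "HPRT1"),
    ct = c(24, 26, 20, 20), stringsAsFactors = FALSE))
  expect_equal(delta_ct(ct2)$delta_ct, 5)  # mean(24, 26) = 25

  # a sample without the reference gene is an error naming the sample
  ct3 <- make_ct(data.frame(
    sample_id = c("s1", "s1", "s2"),
    gene = c("T", "HPRT1", "T"),
    ct = c(25, 20, 24), stringsAsFactors = FALSE))
  expect_error(delta_ct(ct3), "s2")
})

test_that("delta_ct matches a per-record hand-rolled recomputation", {
  set.seed(61)
  d <- study_design(n_bio_replicates = 2)
  conds <- expand.grid(cell_line = d$cell_lines, medium = d$media,
                       stringsAsFactors = FALSE)
  lv <- rbind(cbind(conds, gene = "G1", level = runif(nrow(conds), 0.5, 4)),
              cbind(conds, gene = "G2", level = runif(nrow(conds), 0.5, 4)))
  ct <- simulate_ct(d, lv, noise_sd = 0.3, seed = 62)
  got <- delta_ct(ct)
  for (i in sample(nrow(got), 10)) {
    s <- got$sample_id[i]; g <- got$gene[i]
    manual <- mean(ct$ct[ct$sample_id == s & ct$gene == g]) -
      mean(ct$ct[ct$sample_id == s & ct$gene == "HPRT1"])
    expect_equal(got$delta_ct[i], manual)
  }
})

test_that("relative expression is median-calibrated powers of two", {
  dct <- data.frame(sample_id = c("a", "b", "c"), gene = "G",
                    delta_ct = c(4, 5, 6), stringsAsFactors = FALSE)
  rel <- rel_expression(dct)
  expect_equal(rel$rel_expr, c(2, 1, 0.5))

  flat <- data.frame(sample_id = letters[1:4], gene = "G",
                     delta_ct = rep(5, 4), stringsAsFactors = FALSE)
  expect_equal(rel_expression(flat)$rel_expr, rep(1, 4))
})

test_that("per-gene median of relative expression is exactly 1", {
  set.seed(63)
  for (n in c(5, 6, 9, 12)) {   # odd and even sample counts
    dct <- data.frame(sample_id = paste0("s", 1:n),
                      gene = rep(c("G1", "G2"), each = n),
                      delta_ct = rnorm(2 * n, 5, 2), stringsAsFactors = FALSE)
    rel <- rel_expression(dct)
    for (g in c("G1", "G2"))
      expect_equal(median(rel$rel_expr[rel$gene == g]), 1, tolerance = 1e-12)
  }
})

test_that("relative expression is invariant to per-sample Ct shifts", {
  # adding a constant to both target and reference Ct of one sample
  # (e.g. a loading difference) leaves rel_expr unchanged
  base <- data.frame(
    sample_id = rep(c("s1", "s2", "s3"), each = 4),
    cell_line = "A", medium = "M",
    bio_rep = rep(1:3, each = 4),
    tech_rep = rep(c(1, 2, 1, 2), 3),
    gene = rep(c("T", "T", "HPRT1", "HPRT1"), 3),
    ct = c(25, 25.4, 20, 20.2, 26, 26.2, 21, 20.8, 24, 24.2, 19.5, 19.7),
    stringsAsFactors = FALSE)
  shifted <- base
  shifted$ct[shifted$sample_id == "s2"] <- shifted$ct[shifted$sample_id == "s2"] + 3
  r1 <- rel_expression(delta_ct(base))
  r2 <- rel_expression(delta_ct(shifted))
  expect_equal(r1$rel_expr, r2$rel_expr)
})

test_that("two-way ANOVA matches the textbook closed form", {
  set.seed(64)
  for (rep in 1:5) {
    d <- expand.grid(cell_line = c("A", "B", "C"),
                     medium = c("m1", "m2", "m3"),
                     bio_rep = 1:3, stringsAsFactors = FALSE)
    d$gene <- "G"
    d$rel_expr <- 2^rnorm(nrow(d), 0, 0.6)
    an <- two_way_anova(d, "G")
    or <- oracle_anova(log2(d$rel_expr), d$cell_line, d$medium)
    expect_equal(an$sum_sq, or$sum_sq, tolerance = 1e-10)
    expect_equal(an$df, or$df)
    expect_equal(an$statistic, or$statistic, tolerance = 1e-10)
    expect_equal(an$p_value, or$p_value, tolerance = 1e-10)
  }
})

test_that("degenerate and orthogonal designs decompose as expected", {
  d <- expand.grid(cell_line = c("A", "B"), medium = c("m1", "m2"),
                   bio_rep = 1:2, stringsAsFactors = FALSE)
  d$gene <- "G"
  d$rel_expr <- 1
  an <- two_way_anova(d, "G")
  expect_equal(an$sum_sq[1:3], rep(0, 3))
  expect_true(all(is.na(an$statistic[1:3])))  # 0/0: F undefined

  # additive shift on medium only: cell-line and interaction SS vanish
  d2 <- d
  d2$rel_expr <- ifelse(d2$medium == "m2", 4, 1)
  an2 <- two_way_anova(d2, "G")
  expect_equal(an2$sum_sq[c(1, 3)], c(0, 0))
  expect_gt(an2$sum_sq[2], 0)

  # unbalanced designs are rejected
  d3 <- rbind(d, d[1, ])
  expect_error(two_way_anova(d3, "G"), "unbalanced")
})

test_that("Tukey HSD flags only genuinely separated groups", {
  # two identical groups: q = 0, p = 1
  d <- expand.grid(cell_line = c("A", "B"), medium = c("m1", "m2"),
                   bio_rep = 1:3, stringsAsFactors = FALSE)
  d$gene <- "G"
  d$rel_expr <- 2
  tk <- tukey_hsd(d, "G")
  expect_equal(tk$q, rep(0, nrow(tk)))
  expect_equal(tk$p_adj, rep(1, nrow(tk)))

  # one medium shifted far beyond within-group spread: its comparisons are
  # the most significant
  set.seed(65)
  d2 <- expand.grid(cell_line = c("A", "B"), medium = c("m1", "m2", "m3"),
                    bio_rep = 1:3, stringsAsFactors = FALSE)
  d2$gene <- "G"
  d2$rel_expr <- 2^(rnorm(nrow(d2), 0, 0.05) + ifelse(d2$medium == "m3", 5, 0))
  tk2 <- tukey_hsd(d2, "G")
  has_m3 <- grepl("m3", tk2$comparison)
  expect_lt(max(tk2$p_adj[has_m3]), min(tk2$p_adj[!has_m3]))
  expect_true(all(tk2$stars[has_m3] == "****"))
})

test_that("Tukey adjusted p agrees with the studentized-range integral", {
  set.seed(66)
  d <- expand.grid(cell_line = c("A", "B"), medium = c("m1", "m2", "m3"),
                   bio_rep = 1:3, stringsAsFactors = FALSE)
  d$gene <- "G"
  d$rel_expr <- 2^rnorm(nrow(d), 0, 0.5)
  tk <- tukey_hsd(d, "G")
  # error df of the 2 x 3 model with 3 replicates: 18 - 6 = 12
  for (i in seq_len(nrow(tk))) {
    expect_equal(tk$p_adj[i], oracle_ptukey_upper(tk$q[i], k = 3, df = 12),
                 tolerance = 1e-6)
  }
})

test_that("noisy planted qPCR ratios are recovered across seeds", {
  # planted ratio 4 between serum-free and supplemented conditions,
  # noise_sd 0.2, 3 biological replicates; the recovered ratio of mean
  # rel_expr should land within a factor [3, 5.3] in >= 95% of 200 seeds
  d <- study_design(cell_lines = "A", media = c("serum", "free"),
                    serum_free_media = "free", n_bio_replicates = 3)
  conds <- expand.grid(cell_line = d$cell_lines, medium = d$media,
                       stringsAsFactors = FALSE)
  lv <- cbind(conds, gene = "G", level = ifelse(conds$medium == "free", 4, 1))
  ok <- vapply(1:200, function(s) {
    ct <- simulate_ct(d, lv, noise_sd = 0.2, seed = 7000 + s)
    rel <- rel_expression(delta_ct(ct))
    ratio <- mean(rel$rel_expr[rel$medium == "free"]) /
      mean(rel$rel_expr[rel$medium == "serum"])
    ratio >= 3 && ratio <= 5.3
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
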