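# Independent oracles and fixture builders used across the suite. These
# deliberately re-derive results along different code paths than the
# package: exhaustive pattern scans, textbook sums-of-squares formulas, and
# direct numerical integration of the studentized-range distribution.

rc_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

# ---- exhaustive-scan fragment assignment oracle -------------------------

# All gapless in-bounds placements of `rd` on `subj` with at most max_mm
# mismatches, found by an exhaustive pattern scan.
oracle_hits <- function(rd, subj, max_mm) {
  len <- nchar(rd)
  m <- Biostrings::matchPattern(Biostrings::DNAString(rd), subj,
                                max.mismatch = max_mm, with.indels = FALSE)
  st <- Biostrings::start(m)
  keep <- st >= 1 & (st + len - 1L) <= length(subj)
  st <- st[keep]
  if (!length(st)) return(NULL)
  subj_chr <- as.character(subj)
  mm <- vapply(st, function(p) {
    sum(charToRaw(substr(subj_chr, p, p + len - 1L)) != charToRaw(rd))
  }, numeric(1))
  cbind(pos = st, mm = mm)
}

# Per-fragment calls (element id, "ambiguous" or "unassigned") under the
# same uniqueness contract as assign_fragments, derived by scanning every
# read against every element position.
oracle_assign <- function(r1, r2, seqs, max_mm = 2, max_frag = 1000) {
  subs <- lapply(seqs, Biostrings::DNAString)
  r1r <- rc_chr(r1); r2r <- rc_chr(r2)
  n <- length(r1)
  calls <- character(n)
  for (i in seq_len(n)) {
    scores <- rep(Inf, length(seqs))
    for (e in seq_along(seqs)) {
      h1f <- oracle_hits(r1[i], subs[[e]], max_mm)
      h1r <- oracle_hits(r1r[i], subs[[e]], max_mm)
      h2f <- oracle_hits(r2[i], subs[[e]], max_mm)
      h2r <- oracle_hits(r2r[i], subs[[e]], max_mm)
      comb <- function(fwd, rev, len_rev) {
        if (is.null(fwd) || is.null(rev)) return(Inf)
        b <- Inf
        for (a in seq_len(nrow(fwd))) for (d in seq_len(nrow(rev))) {
          if (rev[d, "pos"] >= fwd[a, "pos"] &&
              rev[d, "pos"] + len_rev - fwd[a, "pos"] <= max_frag)
            b <- min(b, fwd[a, "mm"] + rev[d, "mm"])
        }
        b
      }
      scores[e] <- min(comb(h1f, h2r, nchar(r2[i])),
                       comb(h2f, h1r, nchar(r1[i])))
    }
    if (!any(is.finite(scores))) {
      calls[i] <- "unassigned"
    } else {
      w <- which(scores == min(scores))
      calls[i] <- if (length(w) == 1L) names(seqs)[w] else "ambiguous"
    }
  }
  calls
}

# ---- random small metagenomes -------------------------------------------

random_metagenome <- function(n_elem, len_range = c(400L, 900L),
                              n_families = max(2L, n_elem %/% 2L)) {
  fams <- paste0("FAM", seq_len(n_families))
  man <- data.frame(
    element_id = sprintf("el%02d", seq_len(n_elem)),
    accession_label = sprintf("ACC%02d.1", seq_len(n_elem)),
    family = sample(fams, n_elem, replace = TRUE),
    category = "endogenous_human",
    stringsAsFactors = FALSE)
  lens <- sample(len_range[1]:len_range[2], n_elem, replace = TRUE)
  seqs <- stats::setNames(vapply(lens, function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
    character(1)), man$element_id)
  build_metagenome(man, seqs)
}

# ---- closed-form balanced two-way ANOVA ---------------------------------

# Textbook sums-of-squares for a balanced a x b design with r replicates.
oracle_anova <- function(y, A, B) {
  A <- factor(A); B <- factor(B)
  a <- nlevels(A); b <- nlevels(B); r <- length(y) / (a * b)
  g <- mean(y)
  mA <- tapply(y, A, mean); mB <- tapply(y, B, mean)
  mAB <- tapply(y, interaction(A, B), mean)
  ss_a <- r * b * sum((mA - g)^2)
  ss_b <- r * a * sum((mB - g)^2)
  cell_mean <- mAB[paste(A, B, sep = ".")]
  ss_e <- sum((y - cell_mean)^2)
  ss_ab <- sum((y - g)^2) - ss_a - ss_b - ss_e
  df <- c(a - 1, b - 1, (a - 1) * (b - 1), a * b * (r - 1))
  ss <- c(ss_a, ss_b, ss_ab, ss_e)
  ms <- ss / df
  f <- c(ms[1:3] / ms[4], NA)
  p <- c(stats::pf(f[1:3], df[1:3], df[4], lower.tail = FALSE), NA)
  data.frame(df = df, sum_sq = ss, mean_sq = ms, statistic = f, p_value = p)
}

# ---- studentized-range distribution by direct integration ----------------

# P(Q > q) for k means and df error degrees of freedom, via the classical
# double integral (outer: scaled chi density of s; inner: range of k
# standard normals).
oracle_ptukey_upper <- function(q, k, df) {
  prange <- function(w) {
    if (w <= 0) return(0)
    stats::integrate(function(z)
      k * stats::dnorm(z) * (stats::pnorm(z) - stats::pnorm(z - w))^(k - 1),
      -Inf, Inf, rel.tol = 1e-11)$value
  }
  fs <- function(s)
    df^(df / 2) / (gamma(df / 2) * 2^(df / 2 - 1)) *
      s^(df - 1) * exp(-df * s^2 / 2)
  val <- stats::integrate(Vectorize(function(s) fs(s) * prange(q * s)),
                          0, Inf, rel.tol = 1e-9)$value
  1 - val
}

# ---- misc ---------------------------------------------------------------

oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  sxy / (sqrt(sum((x - mean(x))^2) / (n - 1)) *
           sqrt(sum((y - mean(y))^2) / (n - 1)))
}

# Tiny three-element manifest used in several tests.
toy_manifest <- function() {
  man <- data.frame(
    element_id = c("k1", "k2", "sp1"),
    accession_label = c("AB000001.1", "AB000002.1", "SP000001.1"),
    family = c("HERV-K(HML-2)", "HERV-K(HML-2)", "spacer"),
    category = c("endogenous_human", "endogenous_human", "spacer"),
    stringsAsFactors = FALSE)
  seqs <- c(k1 = strrep("ACGT", 100), k2 = strrep("GGCA", 100),
            sp1 = strrep("TTAGC", 80))
  list(manifest = man, sequences = seqs)
}
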