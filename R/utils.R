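# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-stage seed derived from a master seed and a stage label,
# so adding a stage never perturbs another stage's draws. Kept below 2^31.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

# Reverse complement for plain character vectors of A/C/G/T/N.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count1 <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)

#' Significance tiers as asterisks
#'
#' Maps p-values to the conventional GraphPad-style tiers used when reporting
#' group comparisons: `****` p < 0.0001, `***` p < 0.001, `**` p < 0.01,
#' `*` p < 0.05, `ns` otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector of the same length.
#' @export
significance_stars <- function(p) {
  out <- rep("ns", length(p))
  out[!is.na(p) & p < 0.05]   <- "*"
  out[!is.na(p) & p < 0.01]   <- "**"
  out[!is.na(p) & p < 0.001]  <- "***"
  out[!is.na(p) & p < 0.0001] <- "****"
  out[is.na(p)] <- NA_character_
  out
}
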