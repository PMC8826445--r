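# Shared fixtures: tiny models, calibration curves and rank tables built in
# code at test time.

zero_model <- function(allele = "ZERO*01:01") {
  allele_model(allele, matrix(0, 9, 20))
}

# weights[i, "A"] = 1 for all positions: scores count alanines in a window
ala_model <- function(allele = "ALA*01:01") {
  w <- matrix(0, 9, 20)
  w[, 1] <- 1
  allele_model(allele, w)
}

random_model <- function(allele = "RND*01:01") {
  allele_model(allele, matrix(stats::runif(180, -3, 3), 9, 20))
}

# Hand-made calibration curve with known background scores.
manual_curve <- function(scores, allele = "X*01:01") {
  structure(
    list(allele = allele, background_scores = sort(as.numeric(scores)),
         n_bg = length(scores), length_range = c(9L, 9L), seed = NULL),
    class = "calibration_curve"
  )
}

# Long-format rank data frame from a peptide x allele matrix of ranks.
rank_df <- function(ranks, peptides = rownames(ranks),
                    alleles = colnames(ranks), sample_id = "s1") {
  df <- expand.grid(peptide = peptides, allele = alleles,
                    stringsAsFactors = FALSE)
  df$sample_id <- sample_id
  df$rank_percent <- ranks[cbind(match(df$peptide, peptides),
                                 match(df$allele, alleles))]
  df$raw_score <- -df$rank_percent
  df$core <- ifelse(nchar(df$peptide) >= 9, substr(df$peptide, 1, 9), NA)
  df$core_offset <- ifelse(nchar(df$peptide) >= 9, 0L, NA_integer_)
  df[, c("sample_id", "peptide", "allele", "raw_score", "rank_percent",
         "core", "core_offset")]
}

# n random peptides of random lengths in [lmin, lmax], uniform residues.
random_test_peptides <- function(n, lmin = 9, lmax = 18) {
  vapply(seq_len(n), function(i) {
    paste(sample(AMINO_ACIDS, sample(lmin:lmax, 1), replace = TRUE),
          collapse = "")
  }, character(1))
}

# Brute-force window-scoring oracle, independent of score_peptides().
brute_force_score <- function(weights, peptide) {
  L <- nchar(peptide)
  if (L < 9) return(list(raw_score = -Inf, core_offset = NA_integer_))
  ch <- strsplit(peptide, "")[[1]]
  best <- -Inf
  best_o <- NA_integer_
  for (o in 0:(L - 9)) {
    s <- 0
    for (j in 1:9) s <- s + weights[j, match(ch[o + j], AMINO_ACIDS)]
    if (s > best) {
      best <- s
      best_o <- o
    }
  }
  list(raw_score = best, core_offset = best_o)
}

# Independent MCC oracle: Pearson correlation of expanded binary vectors.
mcc_cor_oracle <- function(tp, fp, fn, tn) {
  truth <- c(rep(1, tp), rep(0, fp), rep(1, fn), rep(0, tn))
  pred <- c(rep(1, tp), rep(1, fp), rep(0, fn), rep(0, tn))
  if (stats::sd(truth) == 0 || stats::sd(pred) == 0) return(0)
  stats::cor(truth, pred)
}

lex_order_test <- function(...) order(..., method = "radix")

# aliases for package internals exercised directly in tests
with_seed <- function(seed, code) motifdecon:::with_seed(seed, code)
random_peptides <- motifdecon:::random_peptides
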