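#' Binding-core frequency matrix
#'
#' Position-wise relative residue frequencies of a set of 9-mer binding
#' cores: `freq[i, a]` is the fraction of cores with residue `a` at core
#' position `i`. No pseudocounts or sequence weighting are applied, so
#' zero-count cells are exactly 0 and every row sums to 1.
#'
#' @param cores Character vector of 9-mers (canonical residues).
#' @return 9x20 numeric matrix, rows `P1..P9`, columns [AMINO_ACIDS].
#' @examples
#' core_frequency_matrix(c("AAAAAAAAA", "CCCCCCCCC"))[1, c("A", "C")]
#' @export
core_frequency_matrix <- function(cores) {
  if (length(cores) == 0L) stop("empty core list", call. = FALSE)
  if (any(nchar(cores) != 9L))
    stop("all cores must be 9-mers", call. = FALSE)
  idx <- peptide_index_matrix(cores, 9L)
  freq <- matrix(0, nrow = 9L, ncol = 20L,
                 dimnames = list(paste0("P", 1:9), AMINO_ACIDS))
  for (i in 1:9)
    freq[i, ] <- tabulate(idx[, i], nbins = 20L) / length(cores)
  freq
}

#' Kullback-Leibler sequence-logo data
#'
#' Per-position information content in bits,
#' `info_i = sum_a p_ia log2(p_ia / q_a)` with `0 log 0 = 0`, and
#' frequency-weighted letter heights `h_ia = p_ia * info_i` (non-negative
#' rendering). The raw frequencies and background are returned alongside so
#' alternative renderings (e.g. showing depleted residues below the axis)
#' can be layered on.
#'
#' @param freq 9x20 (or any Nx20) frequency matrix with rows summing to 1.
#' @param background Length-20 background frequencies, strictly positive
#'   (default uniform 1/20).
#' @return List with `info` (per-position KL information, bits), `heights`
#'   (plot-ready data frame: `position`, `residue`, `freq`, `height`),
#'   `freq` and `background`.
#' @examples
#' f <- core_frequency_matrix(rep("AAAAAAAAA", 5))
#' kl_logo_data(f)$info[1]  # log2(20) for a point mass vs uniform
#' @export
kl_logo_data <- function(freq, background = aa_background("uniform")) {
  background <- check_frequencies(background, "logo background")
  freq <- as.matrix(freq)
  if (ncol(freq) != 20L) stop("freq must have 20 columns", call. = FALSE)
  kl_term <- function(p, q) ifelse(p > 0, p * log2(p / q), 0)
  info <- apply(freq, 1L, function(p) sum(kl_term(p, background)))
  heights <- data.frame(
    position = rep(seq_len(nrow(freq)), each = 20L),
    residue = rep(AMINO_ACIDS, nrow(freq)),
    freq = as.vector(t(freq)),
    height = as.vector(t(freq * info)),
    stringsAsFactors = FALSE
  )
  list(info = unname(info), heights = heights, freq = freq,
       background = background)
}

#' Length distribution of a cluster
#'
#' Histogram of peptide lengths within one cluster of a deconvolution
#' result, over the configured length range (zero counts included for
#' empty lengths, so histograms from different clusters are comparable).
#'
#' @param result A `deconvolution_result`.
#' @param cluster Cluster name: an allele of the sample or `TRASH`.
#' @return Named integer vector, names = lengths `length_min..length_max`.
#' @export
length_distribution <- function(result, cluster) {
  stopifnot(inherits(result, "deconvolution_result"))
  if (!cluster %in% names(result$cluster_counts))
    stop("unknown cluster: ", cluster, call. = FALSE)
  rng <- seq.int(result$config$length_min, result$config$length_max)
  peps <- result$assignments$peptide[result$assignments$assigned == cluster]
  counts <- table(factor(nchar(peps), levels = rng))
  stats::setNames(as.integer(counts), rng)
}

#' Motif summary for one cluster
#'
#' Gathers, for a single cluster of a deconvolution result, the peptide
#' count, the 9x20 binding-core frequency matrix, the per-position KL
#' information, and the length histogram. When the cluster holds fewer than
#' `config$min_logo_peptides` peptides the motif is flagged `suppressed`
#' (a logo should not be rendered) but counts are still reported; the trash
#' cluster of an all-trash run has no cores and an all-zero frequency
#' matrix.
#'
#' @param result A `deconvolution_result`.
#' @param cluster Cluster name (allele or `TRASH`).
#' @param background Logo background (default uniform).
#' @return A `motif_summary`: list with `cluster`, `n_peptides`, `freq`,
#'   `info`, `length_hist`, `suppressed`.
#' @export
motif_summary <- function(result, cluster,
                          background = aa_background("uniform")) {
  stopifnot(inherits(result, "deconvolution_result"))
  asn <- result$assignments
  if (!cluster %in% names(result$cluster_counts))
    stop("unknown cluster: ", cluster, call. = FALSE)
  cores <- asn$best_core[asn$assigned == cluster & !is.na(asn$best_core)]
  n <- sum(asn$assigned == cluster)
  if (length(cores)) {
    freq <- core_frequency_matrix(cores)
    info <- kl_logo_data(freq, background)$info
  } else {
    freq <- matrix(0, 9L, 20L, dimnames = list(paste0("P", 1:9), AMINO_ACIDS))
    info <- rep(0, 9L)
  }
  structure(
    list(cluster = cluster, n_peptides = n, freq = freq, info = info,
         length_hist = length_distribution(result, cluster),
         suppressed = n < result$config$min_logo_peptides),
    class = "motif_summary"
  )
}

# Flatten a 9x20 frequency matrix position-major (P1 A..Y, P2 A..Y, ...):
# the fixed 180-element order used for motif-consistency correlations.
flatten_motif <- function(freq) as.vector(t(as.matrix(freq)))

#' Cross-sample motif consistency matrix
#'
#' For one allele deconvoluted in several samples, each sample's 9x20
#' core frequency matrix is flattened to a 180-vector (position-major,
#' fixed order) and pairwise Pearson correlation coefficients (PCC) are
#' computed. A pair involving a constant vector has undefined PCC and is
#' reported as `NA` and excluded from the mean. `mean_pcc` averages the
#' off-diagonal upper triangle.
#'
#' @param freqs Named list (>= 2 entries, names = sample ids) of 9x20
#'   frequency matrices or `motif_summary` objects for the same allele.
#' @param allele Optional allele name recorded in the output.
#' @return A `consistency_matrix`: list with `allele`, `sample_ids`, `pcc`
#'   (symmetric matrix, unit diagonal) and `mean_pcc`.
#' @export
consistency_matrix <- function(freqs, allele = NA_character_) {
  if (length(freqs) < 2L)
    stop("need motif summaries from at least 2 samples", call. = FALSE)
  mats <- lapply(freqs, function(f) {
    if (inherits(f, "motif_summary")) f$freq else as.matrix(f)
  })
  vecs <- vapply(mats, flatten_motif, numeric(180L))
  ids <- names(freqs)
  if (is.null(ids)) ids <- paste0("sample", seq_along(freqs))
  n <- length(freqs)
  pcc <- diag(1, n)
  dimnames(pcc) <- list(ids, ids)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    v <- if (stats::sd(vecs[, i]) == 0 || stats::sd(vecs[, j]) == 0)
      NA_real_ else stats::cor(vecs[, i], vecs[, j])
    pcc[i, j] <- pcc[j, i] <- v
  }
  upper <- pcc[upper.tri(pcc)]
  structure(
    list(allele = allele, sample_ids = ids, pcc = pcc,
         mean_pcc = mean(upper, na.rm = TRUE)),
    class = "consistency_matrix"
  )
}

#' Frequencies implied by a PSSM model
#'
#' Converts a log-odds allele model back to the positional residue
#' frequencies it implies (`p = q * 2^w`, renormalised per position), so a
#' sample's deconvoluted motif can be correlated against the model itself
#' in the same 180-vector space as [consistency_matrix()].
#'
#' @param model An [allele_model()].
#' @return 9x20 frequency matrix with rows summing to 1.
#' @export
model_frequency_matrix <- function(model) {
  stopifnot(inherits(model, "allele_model"))
  p <- sweep(2^model$weights, 2L, model$background, `*`)
  sweep(p, 1L, rowSums(p), `/`)
}

#' Write a frequency matrix, logo table or consistency matrix as TSV
#'
#' @param x A 9x20 frequency matrix, the `heights` data frame of
#'   [kl_logo_data()], or a `consistency_matrix`.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_report_table <- function(x, path) {
  if (inherits(x, "consistency_matrix")) x <- x$pcc
  if (is.matrix(x)) {
    utils::write.table(data.frame(position = rownames(x), x,
                                  check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
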