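#' Construct a PSSM allele model
#'
#' The built-in scoring backend: a 9x20 position-specific scoring matrix of
#' log-odds weights (bits) over the 9-residue binding core, rows P1..P9,
#' columns in canonical amino-acid order, plus the background frequencies
#' the log-odds refer to. A peptide's raw score is the maximum over all
#' 9-mer windows of the summed per-position weights; the arg-max window is
#' the predicted binding core.
#'
#' @param allele Allele name.
#' @param weights 9x20 numeric matrix (finite), rows P1..P9, columns
#'   [AMINO_ACIDS].
#' @param background Length-20 frequency vector, strictly positive, sums
#'   to 1. Default [aa_background()] (natural composition).
#' @return An `allele_model` object.
#' @examples
#' m <- allele_model("MOCK*01:01", matrix(0, 9, 20))
#' score_peptide(m, "AAKMNPQRS")$raw_score  # 0 under the zero matrix
#' @export
allele_model <- function(allele, weights, background = aa_background()) {
  stopifnot(is.character(allele), length(allele) == 1L)
  weights <- as.matrix(weights)
  if (!all(dim(weights) == c(9L, 20L)))
    stop("weights must be a 9x20 matrix", call. = FALSE)
  if (!all(is.finite(weights)))
    stop("weights must be finite", call. = FALSE)
  background <- check_frequencies(background)
  dimnames(weights) <- list(paste0("P", 1:9), AMINO_ACIDS)
  structure(list(allele = allele, weights = weights, background = background),
            class = "allele_model")
}

#' @export
print.allele_model <- function(x, ...) {
  cat("allele_model '", x$allele, "': 9x20 log-odds PSSM, weight range [",
      sprintf("%.2f", min(x$weights)), ", ", sprintf("%.2f", max(x$weights)),
      "] bits\n", sep = "")
  invisible(x)
}

#' Score peptides against a PSSM model
#'
#' `score_peptides()` is vectorised; `score_peptide()` scores one peptide.
#' The raw score is the maximum over all 9-mer windows of the summed
#' position weights; ties go to the leftmost window. Peptides shorter than
#' 9 residues cannot place a core and receive raw score `-Inf` (mapping to
#' rank 100 under any calibration curve).
#'
#' @param model An [allele_model()].
#' @param peptides,peptide Character vector / single peptide (canonical
#'   residues only).
#' @return `score_peptides()`: data frame with `peptide`, `raw_score`,
#'   `core`, `core_offset` (0-based). `score_peptide()`: list with
#'   `raw_score`, `core`, `core_offset`.
#' @export
score_peptides <- function(model, peptides) {
  stopifnot(inherits(model, "allele_model"), is.character(peptides))
  n <- length(peptides)
  raw <- rep(-Inf, n)
  core <- rep(NA_character_, n)
  off <- rep(NA_integer_, n)
  len <- nchar(peptides)
  W <- model$weights
  for (L in unique(len[len >= 9L])) {
    sel <- which(len == L)
    idx <- peptide_index_matrix(peptides[sel], L)
    nw <- L - 8L
    sc <- matrix(0, nrow = length(sel), ncol = nw)
    for (o in seq_len(nw)) {
      s <- W[1L, idx[, o]]
      for (j in 2:9) s <- s + W[j, idx[, o + j - 1L]]
      sc[, o] <- s
    }
    best <- max.col(sc, ties.method = "first")
    raw[sel] <- sc[cbind(seq_along(sel), best)]
    off[sel] <- best - 1L
    core[sel] <- substr(peptides[sel], best, best + 8L)
  }
  if (any(len < 9L)) {
    short <- which(len < 9L)
    # validate residues even when unscoreable
    invisible(validate_or_stop(peptides[short]))
  }
  data.frame(peptide = peptides, raw_score = raw, core = core,
             core_offset = off, stringsAsFactors = FALSE)
}

validate_or_stop <- function(peptides) {
  bad <- peptides[!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", peptides)]
  if (length(bad))
    stop("non-canonical residue in peptide(s): ",
         paste(utils::head(bad, 3L), collapse = ", "), call. = FALSE)
  invisible(peptides)
}

#' @rdname score_peptides
#' @export
score_peptide <- function(model, peptide) {
  stopifnot(length(peptide) == 1L)
  df <- score_peptides(model, peptide)
  list(raw_score = df$raw_score, core = df$core, core_offset = df$core_offset)
}

#' Calibrate percentile ranks against random natural peptides
#'
#' Draws `n_bg` random peptides with residues i.i.d. from `bg_frequencies`
#' and lengths uniform over `length_range`, scores each with the model, and
#' stores the sorted raw scores. The percentile rank of a query score is
#' then the percentage of these background scores greater than or equal to
#' it ([rank_of()]), so rank 0 is a score exceeding every random natural
#' peptide and rank 100 a score below all of them.
#'
#' @param model An [allele_model()].
#' @param n_bg Number of background peptides (>= 1000; default 100000).
#' @param length_range Integer vector `c(min, max)`; peptide lengths are
#'   pooled uniformly over this range.
#' @param bg_frequencies Background residue frequencies (default: the
#'   model's own background).
#' @param seed Integer seed; the curve is fully reproducible from it.
#' @return A `calibration_curve` (allele, sorted `background_scores`,
#'   `n_bg`, `length_range`, `seed`).
#' @export
calibrate_ranks <- function(model, n_bg = 100000L, length_range,
                            bg_frequencies = NULL, seed = NULL) {
  stopifnot(inherits(model, "allele_model"))
  if (n_bg < 1000L) stop("n_bg must be >= 1000", call. = FALSE)
  stopifnot(length(length_range) == 2L, length_range[1] <= length_range[2])
  bg <- check_frequencies(
    if (is.null(bg_frequencies)) model$background else bg_frequencies
  )
  peps <- with_seed(seed, random_peptides(
    n_bg, lengths = seq.int(length_range[1], length_range[2]), bg = bg
  ))
  scores <- sort(score_peptides(model, peps)$raw_score)
  structure(
    list(allele = model$allele, background_scores = scores,
         n_bg = as.integer(n_bg), length_range = as.integer(length_range),
         seed = seed),
    class = "calibration_curve"
  )
}

#' Percentile rank of a raw score
#'
#' `rank = 100 * #\{background scores >= raw\} / n_bg`. Total and
#' monotonically non-increasing in the raw score; `-Inf` (unscoreable
#' peptides shorter than 9) maps to 100.
#'
#' @param curve A `calibration_curve` from [calibrate_ranks()].
#' @param raw_score Numeric vector of raw scores.
#' @return Numeric vector of ranks in \[0, 100\].
#' @export
rank_of <- function(curve, raw_score) {
  stopifnot(inherits(curve, "calibration_curve"))
  # findInterval(..., left.open = TRUE) counts background scores < raw
  n_lt <- findInterval(raw_score, curve$background_scores, left.open = TRUE)
  100 * (curve$n_bg - n_lt) / curve$n_bg
}

#' Predict a sample's peptides against all of its alleles
#'
#' Collapses duplicate peptides (keeping first-occurrence order, logging
#' the multiplicity), scores every unique peptide against every allele the
#' sample expresses, and converts raw scores to percentile ranks.
#'
#' @param sample A [peptidome_sample()].
#' @param models Named list of [allele_model()]s covering `sample$alleles`.
#' @param curves Named list of calibration curves, same names as `models`.
#' @return A complete [rank_table()] with one record per unique peptide x
#'   allele; the number of collapsed duplicates is in
#'   `attr(, "n_duplicates")`.
#' @export
predict_sample <- function(sample, models, curves) {
  stopifnot(inherits(sample, "peptidome_sample"))
  missing_m <- setdiff(sample$alleles, names(models))
  if (length(missing_m))
    stop("no model for allele(s): ", paste(missing_m, collapse = ", "),
         call. = FALSE)
  missing_c <- setdiff(sample$alleles, names(curves))
  if (length(missing_c))
    stop("no calibration curve for allele(s): ",
         paste(missing_c, collapse = ", "), call. = FALSE)
  peps <- unique(sample$peptides)
  n_dup <- length(sample$peptides) - length(peps)
  recs <- lapply(sample$alleles, function(a) {
    df <- score_peptides(models[[a]], peps)
    data.frame(
      sample_id = sample$sample_id, peptide = df$peptide, allele = a,
      raw_score = df$raw_score,
      rank_percent = rank_of(curves[[a]], df$raw_score),
      core = df$core, core_offset = df$core_offset,
      stringsAsFactors = FALSE
    )
  })
  out <- rank_table(do.call(rbind, recs))
  attr(out, "n_duplicates") <- n_dup
  out
}

#' Read and write allele model files
#'
#' Models are stored as JSON: allele name, 9x20 weight matrix (row-major,
#' canonical column order) and background vector, optionally the
#' calibration seed and `n_bg` used with the model.
#'
#' @param models Named list of [allele_model()]s.
#' @param path JSON file path.
#' @return `write_allele_models()`: the path, invisibly.
#'   `read_allele_models()`: named list of models.
#' @export
write_allele_models <- function(models, path) {
  payload <- lapply(models, function(m) {
    list(allele = m$allele,
         weights = unname(m$weights),
         background = unname(m$background))
  })
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_allele_models
#' @export
read_allele_models <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  models <- lapply(payload, function(p) {
    w <- matrix(vapply(unlist(p$weights, recursive = FALSE),
                       as.numeric, numeric(1)),
                nrow = 9, byrow = TRUE)
    allele_model(as.character(p$allele), w,
                 vapply(p$background, as.numeric, numeric(1)))
  })
  stats::setNames(models, vapply(models, `[[`, "", "allele"))
}
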