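#' Deconvolution configuration
#'
#' Bundles the tunable parameters of a deconvolution run. Length defaults
#' follow the MHC class: 8-14 residues for class I and 13-21 for class II
#' (12-21 is also reasonable for class II when short-length specificities
#' are of interest). The trash threshold is a percentile rank: a peptide
#' whose rank exceeds it for every declared allele is called a contaminant;
#' setting it to 101 disables the trash cluster entirely.
#'
#' @param mhc_class `"I"` or `"II"`.
#' @param length_min,length_max Inclusive peptide length bounds; defaults
#'   by class as above.
#' @param trash_threshold Percent rank in (0, 101]; default 20.
#' @param min_logo_peptides Minimum peptides in a cluster before its motif
#'   logo is rendered (default 10); smaller clusters still report counts.
#' @param class_i_prefilter_threshold Percent rank at or below which a
#'   peptide counts as a class I binder in [exclude_class_i_binders()]
#'   (default 2).
#' @return A `deconv_config` list.
#' @examples
#' deconv_config("II")$length_min  # 13
#' @export
deconv_config <- function(mhc_class = c("I", "II"), length_min = NULL,
                          length_max = NULL, trash_threshold = 20,
                          min_logo_peptides = 10,
                          class_i_prefilter_threshold = 2) {
  mhc_class <- match.arg(mhc_class)
  if (is.null(length_min)) length_min <- if (mhc_class == "I") 8L else 13L
  if (is.null(length_max)) length_max <- if (mhc_class == "I") 14L else 21L
  length_min <- as.integer(length_min)
  length_max <- as.integer(length_max)
  stopifnot(length_min >= 1L, length_min <= length_max)
  if (!(trash_threshold > 0 && trash_threshold <= 101))
    stop("trash_threshold must be in (0, 101]; 101 disables the trash cluster",
         call. = FALSE)
  structure(
    list(mhc_class = mhc_class, length_min = length_min,
         length_max = length_max, trash_threshold = trash_threshold,
         min_logo_peptides = as.integer(min_logo_peptides),
         class_i_prefilter_threshold = class_i_prefilter_threshold),
    class = "deconv_config"
  )
}

#' Length-filter and deduplicate peptides
#'
#' Retains peptides with `length_min <= length <= length_max`, then
#' collapses duplicates (first-occurrence order). The counts removed by
#' each rule are attached as attributes (`n_input`, `n_length_removed`,
#' `n_duplicates_removed`).
#'
#' @param peptides Character vector of validated peptides.
#' @param config A [deconv_config()].
#' @return Filtered unique peptides (character vector with count
#'   attributes). Errors if nothing survives filtering.
#' @export
prepare_peptides <- function(peptides, config) {
  stopifnot(inherits(config, "deconv_config"), is.character(peptides))
  len <- nchar(peptides)
  keep <- peptides[len >= config$length_min & len <= config$length_max]
  out <- unique(keep)
  if (length(out) == 0L)
    stop("no peptides left after length filtering (", config$length_min, "-",
         config$length_max, ")", call. = FALSE)
  structure(out,
            n_input = length(peptides),
            n_length_removed = length(peptides) - length(keep),
            n_duplicates_removed = length(keep) - length(out))
}

#' Assign each peptide to its best-ranked allele or to the trash cluster
#'
#' Each unique peptide is assigned to the allele with the minimum
#' percentile rank, provided that rank is at or below
#' `config$trash_threshold`; when every allele's rank is strictly above the
#' threshold, the peptide is a presumed co-immunoprecipitated contaminant
#' and goes to the trash cluster. Equal best ranks are broken by
#' lexicographic (C-locale) allele order, so assignment does not depend on
#' input order. Cluster counts always partition the peptide set.
#'
#' @param rtab A complete [rank_table()] for a single sample.
#' @param config A [deconv_config()].
#' @return A `deconvolution_result`: list with `assignments` (data frame
#'   `sample_id`, `peptide`, `assigned`, `best_rank`, `best_core`),
#'   `cluster_counts` (named vector over alleles and `TRASH`),
#'   `rank_table`, `config` and `log`.
#' @export
assign_peptides <- function(rtab, config) {
  stopifnot(inherits(config, "deconv_config"))
  if (!inherits(rtab, "rank_table")) rtab <- rank_table(rtab)
  if (length(unique(rtab$sample_id)) != 1L)
    stop("assign_peptides() handles one sample at a time; see deconvolute()",
         call. = FALSE)
  alleles <- lex_sort(unique(rtab$allele))
  # best record per peptide: minimum rank, ties to lexicographically first
  # allele; ordering is peptide-major so the choice is order-free
  o <- lex_order(rtab$peptide, rtab$rank_percent, rtab$allele)
  d <- rtab[o, ]
  first <- !duplicated(d$peptide)
  best <- d[first, ]
  trash <- best$rank_percent > config$trash_threshold
  asn <- data.frame(
    sample_id = best$sample_id,
    peptide = best$peptide,
    assigned = ifelse(trash, TRASH, best$allele),
    best_rank = best$rank_percent,
    best_core = ifelse(trash, NA_character_, best$core),
    stringsAsFactors = FALSE
  )
  counts <- table(factor(asn$assigned, levels = c(alleles, TRASH)))
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(
    list(assignments = asn, cluster_counts = counts, rank_table = rtab,
         config = config,
         log = list(n_peptides = nrow(asn), n_trash = sum(trash))),
    class = "deconvolution_result"
  )
}

#' @export
print.deconvolution_result <- function(x, ...) {
  cat("deconvolution_result: ", x$log$n_peptides, " peptides\n", sep = "")
  print(x$cluster_counts)
  invisible(x)
}

#' Exclude peptides with predicted class I restriction
#'
#' Contaminants in class II immunoprecipitates are predominantly
#' co-purified HLA class I ligands. This prefilter removes peptides whose
#' best class I percentile rank (minimum over the sample's class I
#' alleles) is at or below `threshold` (default 2, the conventional class I
#' binder cutoff), returning both partitions.
#'
#' @param peptides Character vector of peptides to filter.
#' @param class_i_rank_table A [rank_table()] of class I predictions
#'   covering every peptide against at least one class I allele.
#' @param threshold Percent rank; best class I rank <= threshold is
#'   excluded.
#' @return List with `retained`, `excluded`, `n_retained`, `n_excluded`.
#' @export
exclude_class_i_binders <- function(peptides, class_i_rank_table,
                                    threshold = 2) {
  rt <- class_i_rank_table
  if (!inherits(rt, "rank_table")) rt <- rank_table(rt)
  if (length(unique(rt$allele)) < 1L || nrow(rt) == 0L)
    stop("class I rank table has no alleles", call. = FALSE)
  missing <- setdiff(peptides, rt$peptide)
  if (length(missing))
    stop("missing class I predictions for peptide(s): ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  best <- tapply(rt$rank_percent, rt$peptide, min)
  is_binder <- best[peptides] <= threshold
  list(retained = peptides[!is_binder], excluded = peptides[is_binder],
       n_retained = sum(!is_binder), n_excluded = sum(is_binder))
}

#' Per-cluster contribution summary
#'
#' Reports, for every cluster (allele or trash), the peptide count and its
#' percentage of two denominators: all assigned peptides including trash
#' (`percent_total`) and allele-assigned peptides excluding trash
#' (`percent_assigned`). Display columns round half-up to the nearest
#' integer percent; full-precision values are retained alongside.
#'
#' @param x A `deconvolution_result`, or a named numeric vector of cluster
#'   counts (may include a `TRASH` element).
#' @return Data frame with `cluster`, `count`, `percent_total`,
#'   `percent_assigned`, `percent_total_display`,
#'   `percent_assigned_display`. Percentages with a zero denominator are
#'   `NA` (undefined), not 0.
#' @examples
#' contribution_summary(c("DRB1*15:01" = 1501, "DRB5*01:01" = 1490))
#' @export
contribution_summary <- function(x) {
  counts <- if (inherits(x, "deconvolution_result")) x$cluster_counts
            else x
  if (is.null(names(counts)) || !is.numeric(counts))
    stop("need a deconvolution_result or a named numeric count vector",
         call. = FALSE)
  if (sum(counts) == 0L) stop("empty result", call. = FALSE)
  total <- sum(counts)
  assigned <- sum(counts[names(counts) != TRASH])
  pt <- if (total > 0) 100 * counts / total else rep(NA_real_, length(counts))
  pa <- ifelse(names(counts) == TRASH, NA_real_,
               if (assigned > 0) 100 * counts / assigned else NA_real_)
  data.frame(
    cluster = names(counts),
    count = as.integer(counts),
    percent_total = as.numeric(pt),
    percent_assigned = as.numeric(pa),
    percent_total_display = round_half_up(as.numeric(pt)),
    percent_assigned_display = round_half_up(as.numeric(pa)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Peptide repertoire overlap between two alleles
#'
#' Classifies every peptide in the table as a binder of allele A, allele B,
#' both (overlapping) or neither, using a stringent percentile-rank binder
#' threshold (default 1). This intentionally uses a tighter cutoff than the
#' trash threshold: overlap is asked of high-confidence repertoires, not of
#' the contaminant filter.
#'
#' @param rtab A [rank_table()] containing both alleles.
#' @param allele_a,allele_b Allele names present in the table.
#' @param binder_threshold Percent rank at or below which a peptide counts
#'   as a binder (default 1).
#' @return List with counts `unique_a`, `unique_b`, `overlap`, `neither`
#'   and the corresponding peptide vectors `peptides_a`, `peptides_b`,
#'   `peptides_overlap`, `peptides_neither`.
#' @export
repertoire_overlap <- function(rtab, allele_a, allele_b,
                               binder_threshold = 1) {
  if (!inherits(rtab, "rank_table")) rtab <- rank_table(rtab)
  for (a in c(allele_a, allele_b))
    if (!a %in% rtab$allele)
      stop("allele not in rank table: ", a, call. = FALSE)
  da <- rtab[rtab$allele == allele_a, ]
  db <- rtab[rtab$allele == allele_b, ]
  peps <- unique(rtab$peptide)
  ra <- stats::setNames(da$rank_percent, da$peptide)[peps]
  rb <- stats::setNames(db$rank_percent, db$peptide)[peps]
  ba <- ra <= binder_threshold
  bb <- rb <= binder_threshold
  list(
    unique_a = sum(ba & !bb), unique_b = sum(!ba & bb),
    overlap = sum(ba & bb), neither = sum(!ba & !bb),
    peptides_a = peps[ba & !bb], peptides_b = peps[!ba & bb],
    peptides_overlap = peps[ba & bb], peptides_neither = peps[!ba & !bb]
  )
}

#' Run the full deconvolution pipeline for one sample
#'
#' Convenience orchestration: length-filter and deduplicate the sample's
#' peptides, optionally exclude predicted class I binders, predict ranks
#' with the PSSM backend (or use a supplied prediction table), and assign
#' every peptide to its best allele or the trash cluster.
#'
#' @param sample A [peptidome_sample()].
#' @param models,curves Named lists covering `sample$alleles` (ignored when
#'   `predictions` is given). If `curves` is `NULL` they are calibrated on
#'   the fly over the configured length range with `calibration_seed`.
#' @param config A [deconv_config()]; defaults to the class defaults for
#'   the sample's class.
#' @param predictions Optional precomputed [rank_table()] for this sample.
#' @param class_i_rank_table Optional class I [rank_table()]; when given,
#'   peptides with best class I rank at or below
#'   `config$class_i_prefilter_threshold` are excluded before class II
#'   deconvolution.
#' @param calibration_seed,n_bg Calibration parameters used when `curves`
#'   is `NULL`.
#' @return A `deconvolution_result` whose `log` records the counts removed
#'   at every stage.
#' @export
deconvolute <- function(sample, models = NULL, curves = NULL, config = NULL,
                        predictions = NULL, class_i_rank_table = NULL,
                        calibration_seed = 1L, n_bg = 100000L) {
  stopifnot(inherits(sample, "peptidome_sample"))
  if (is.null(config)) config <- deconv_config(sample$mhc_class)
  peps <- prepare_peptides(sample$peptides, config)
  log <- list(
    n_input = attr(peps, "n_input"),
    n_length_removed = attr(peps, "n_length_removed"),
    n_duplicates_removed = attr(peps, "n_duplicates_removed"),
    n_class_i_excluded = 0L
  )
  if (!is.null(class_i_rank_table)) {
    ex <- exclude_class_i_binders(as.character(peps), class_i_rank_table,
                                  config$class_i_prefilter_threshold)
    log$n_class_i_excluded <- ex$n_excluded
    peps <- ex$retained
    if (length(peps) == 0L)
      stop("no peptides left after class I exclusion", call. = FALSE)
  }
  rtab <- if (!is.null(predictions)) {
    if (!inherits(predictions, "rank_table"))
      predictions <- rank_table(predictions)
    keep <- predictions$sample_id == sample$sample_id &
      predictions$peptide %in% as.character(peps)
    rank_table(as.data.frame(predictions[keep, ]))
  } else {
    if (is.null(models)) stop("need either models or predictions", call. = FALSE)
    if (is.null(curves)) {
      curves <- lapply(seq_along(sample$alleles), function(i) {
        calibrate_ranks(models[[sample$alleles[i]]], n_bg = n_bg,
                        length_range = c(config$length_min, config$length_max),
                        seed = calibration_seed + i - 1L)
      })
      names(curves) <- sample$alleles
    }
    filtered <- sample
    filtered$peptides <- as.character(peps)
    predict_sample(filtered, models, curves)
  }
  res <- assign_peptides(rtab, config)
  res$log <- c(log, res$log)
  res
}
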