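#' Confusion matrix of true labels versus assigned clusters
#'
#' Rows are the true labels (allele of origin, or `CONTAMINANT` for
#' injected contaminants), columns the assigned clusters (allele names or
#' anonymous cluster ids, plus a `TRASH` column, always present). Row sums
#' equal the per-label dataset sizes and the grand total equals the number
#' of peptides.
#'
#' @param true_labels Character vector of true labels, one per peptide.
#' @param assigned Character vector of assigned clusters, same length.
#' @return Integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(true_labels, assigned) {
  if (length(true_labels) != length(assigned))
    stop("true_labels and assigned must have the same length", call. = FALSE)
  rows <- lex_sort(unique(true_labels))
  cols <- c(lex_sort(setdiff(unique(assigned), TRASH)), TRASH)
  m <- table(factor(true_labels, rows), factor(assigned, cols))
  m <- matrix(as.integer(m), nrow = length(rows),
              dimnames = list(true = rows, cluster = cols))
  class(m) <- c("confusion_matrix", class(m))
  m
}

#' Map anonymous clusters to alleles by majority vote
#'
#' For deconvolution methods that return unnamed clusters, each allele is
#' associated with the (non-trash) cluster holding the majority of its
#' peptides. When an allele's majority cluster is already claimed by
#' another allele, the allele takes the remaining unclaimed cluster with
#' the most of its peptides. Resolution is deterministic: alleles are
#' processed by descending dataset size, remaining ties lexicographically;
#' cluster ties within an allele also resolve lexicographically.
#'
#' @param cm A [confusion_matrix()]. At most `nrow + 1` clusters (including
#'   trash) are allowed.
#' @param alleles Rows to map (default: all rows except `CONTAMINANT`).
#' @return Named character vector: `mapping[allele] = cluster` (`NA` when
#'   there are fewer clusters than alleles).
#' @export
map_clusters_to_alleles <- function(cm, alleles = NULL) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (is.null(alleles)) alleles <- setdiff(rownames(cm), "CONTAMINANT")
  clusters <- setdiff(colnames(cm), TRASH)
  if (length(clusters) > length(alleles))
    stop("more non-trash clusters (", length(clusters), ") than alleles (",
         length(alleles), ")", call. = FALSE)
  sizes <- rowSums(cm)[alleles]
  ord <- alleles[lex_order(-sizes, alleles)]
  mapping <- stats::setNames(rep(NA_character_, length(alleles)), alleles)
  claimed <- character(0)
  for (a in ord) {
    counts <- cm[a, clusters, drop = TRUE]
    # majority cluster for this allele, lexicographic on ties
    pick_from <- function(cl) {
      if (!length(cl)) return(NA_character_)
      cnt <- cm[a, cl]
      cl <- cl[cnt == max(cnt)]
      lex_sort(cl)[1]
    }
    best <- pick_from(clusters)
    if (!is.na(best) && !(best %in% claimed)) {
      mapping[a] <- best
    } else {
      mapping[a] <- pick_from(setdiff(clusters, claimed))
    }
    if (!is.na(mapping[a])) claimed <- c(claimed, mapping[a])
  }
  mapping
}

#' Matthews correlation coefficient from binary counts
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with the
#' standard convention MCC = 0 when any denominator factor is zero.
#' Vectorised.
#'
#' @param tp,fp,fn,tn Non-negative counts.
#' @return Numeric vector of MCC values in \[-1, 1\].
#' @examples
#' mcc_from_counts(8, 2, 2, 88)  # 700/900
#' @export
mcc_from_counts <- function(tp, fp, fn, tn) {
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  fn <- as.numeric(fn); tn <- as.numeric(tn)
  num <- tp * tn - fp * fn
  den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  ifelse(den == 0, 0, num / den)
}

#' Per-allele MCC report from a confusion matrix
#'
#' For each allele X with mapped cluster C_X: TP is the number of X's
#' peptides assigned to C_X; FP the peptides of other origins assigned to
#' C_X (the trash cluster is never a mapped cluster, so trash-assigned
#' peptides are never false positives); FN the peptides of X assigned to
#' any other cluster, trash included; TN the peptides of other origins not
#' assigned to C_X, trash included. The median over alleles is the
#' headline comparison statistic.
#'
#' @param cm A [confusion_matrix()].
#' @param mapping Named vector `allele -> cluster` (default: identity where
#'   allele names appear among the cluster names, as produced by the
#'   supervised deconvolution; `NA` otherwise).
#' @param alleles Alleles to score (default: all rows except
#'   `CONTAMINANT`).
#' @return An `mcc_report`: list with `per_allele` (named numeric),
#'   `median`, `counts` (per-allele TP/FP/FN/TN data frame).
#' @export
mcc_scores <- function(cm, mapping = NULL, alleles = NULL) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (is.null(alleles)) alleles <- setdiff(rownames(cm), "CONTAMINANT")
  if (is.null(mapping)) {
    mapping <- stats::setNames(
      ifelse(alleles %in% colnames(cm), alleles, NA_character_), alleles
    )
  }
  total <- sum(cm)
  counts <- lapply(alleles, function(a) {
    cl <- mapping[[a]]
    row_a <- sum(cm[a, ])
    if (is.na(cl) || !cl %in% colnames(cm)) {
      tp <- 0; fp <- 0
    } else {
      tp <- cm[a, cl]
      fp <- sum(cm[, cl]) - tp
    }
    fn <- row_a - tp
    tn <- total - row_a - fp
    data.frame(allele = a, tp = tp, fp = fp, fn = fn, tn = tn)
  })
  counts <- do.call(rbind, counts)
  per <- stats::setNames(
    mcc_from_counts(counts$tp, counts$fp, counts$fn, counts$tn), alleles
  )
  structure(
    list(per_allele = per, median = stats::median(per), counts = counts,
         mapping = mapping),
    class = "mcc_report"
  )
}

#' @export
print.mcc_report <- function(x, ...) {
  cat("mcc_report: median MCC =", sprintf("%.4f", x$median), "\n")
  print(round(x$per_allele, 4))
  if (!is.null(x$bootstrap_ci))
    cat("bootstrap ", x$n_boot, "x percentile CI: [",
        sprintf("%.4f", x$bootstrap_ci[1]), ", ",
        sprintf("%.4f", x$bootstrap_ci[2]), "]\n", sep = "")
  invisible(x)
}

#' Bootstrap confidence interval for the median per-allele MCC
#'
#' Resamples peptides with replacement `n_boot` times; each replicate
#' rebuilds the confusion matrix, recomputes per-allele MCCs (optionally
#' re-deriving the cluster-to-allele mapping) and records the median. The
#' 2.5/97.5 percentile interval of the replicate medians is reported.
#' Fully reproducible from `seed`.
#'
#' @param true_labels,assigned Per-peptide labels as in
#'   [confusion_matrix()] (>= 2 peptides).
#' @param n_boot Number of bootstrap replicates (default 100, >= 2).
#' @param seed Integer seed.
#' @param remap Recompute the cluster mapping per replicate (default
#'   `FALSE`: use the full-data mapping).
#' @param mapping Optional fixed mapping passed to [mcc_scores()].
#' @return An `mcc_report` with additional fields `bootstrap_ci`,
#'   `bootstrap_medians`, `n_boot`, `seed`.
#' @export
bootstrap_median_mcc <- function(true_labels, assigned, n_boot = 100L,
                                 seed = NULL, remap = FALSE, mapping = NULL) {
  if (length(true_labels) < 2L) stop("need >= 2 peptides", call. = FALSE)
  if (n_boot < 2L) stop("n_boot must be >= 2", call. = FALSE)
  cm0 <- confusion_matrix(true_labels, assigned)
  if (is.null(mapping) && remap) mapping0 <- NULL
  else if (is.null(mapping)) mapping0 <- NULL
  else mapping0 <- mapping
  point <- mcc_scores(cm0, mapping = mapping0)
  n <- length(true_labels)
  meds <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    cmb <- confusion_matrix(true_labels[idx], assigned[idx])
    mb <- if (remap) map_clusters_to_alleles(cmb) else mapping0
    mcc_scores(cmb, mapping = mb)$median
  }, numeric(1)))
  point$bootstrap_medians <- meds
  point$bootstrap_ci <- unname(stats::quantile(meds, c(0.025, 0.975),
                                               type = 7))
  point$n_boot <- as.integer(n_boot)
  point$seed <- seed
  point
}

#' Write an MCC report
#'
#' @param report An `mcc_report`.
#' @param path Output path; `.json` writes JSON, anything else TSV.
#' @return The path, invisibly.
#' @export
write_mcc_report <- function(report, path) {
  stopifnot(inherits(report, "mcc_report"))
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(
      list(per_allele = as.list(report$per_allele), median = report$median,
           bootstrap_ci = report$bootstrap_ci, n_boot = report$n_boot,
           seed = report$seed),
      path, digits = NA, auto_unbox = TRUE, null = "null"
    )
  } else {
    df <- data.frame(allele = names(report$per_allele),
                     mcc = as.numeric(report$per_allele),
                     median = report$median)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
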