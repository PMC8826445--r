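#' Validate peptide sequences against the canonical alphabet
#'
#' Upper-cases sequences and partitions them into peptides made only of the
#' 20 canonical one-letter codes and rejected sequences (anything containing
#' B, J, O, U, X, Z, or any non-letter). Validation is total: every input
#' lands in exactly one of the two partitions.
#'
#' @param peptides Character vector of peptide sequences.
#' @return List with `kept` (upper-cased canonical peptides, input order,
#'   duplicates retained), `rejected` (offending inputs) and `n_rejected`.
#' @examples
#' validate_peptides(c("aakmnpqrst", "PEPTIDEBX"))
#' @export
validate_peptides <- function(peptides) {
  stopifnot(is.character(peptides))
  up <- toupper(peptides)
  ok <- grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", up)
  list(kept = up[ok], rejected = peptides[!ok], n_rejected = sum(!ok))
}

#' Construct an immunopeptidome sample
#'
#' Bundles a sample identifier, its peptide sequences, the HLA alleles the
#' sample expresses, and the MHC class. Peptides are validated against the
#' canonical alphabet (non-canonical sequences are dropped with a logged
#' count); duplicates are retained here and collapsed at prediction time.
#'
#' @param sample_id Length-1 character identifier.
#' @param peptides Character vector of peptide sequences.
#' @param alleles Character vector of allele names, unique, at least one
#'   (e.g. `"HLA-A*02:02"`, `"DRB1*13:01"`, `"DRB4*01:03N"`).
#' @param mhc_class `"I"` or `"II"`.
#' @return A `peptidome_sample` object (list with fields `sample_id`,
#'   `peptides`, `alleles`, `mhc_class`, `log`).
#' @examples
#' s <- peptidome_sample("9060", c("AAKMNPQRSTVWY"),
#'                       c("DRB1*13:01", "DRB3*02:02"), "II")
#' s$alleles
#' @export
peptidome_sample <- function(sample_id, peptides, alleles, mhc_class = c("I", "II")) {
  mhc_class <- match.arg(mhc_class)
  stopifnot(is.character(sample_id), length(sample_id) == 1L, nzchar(sample_id))
  if (length(alleles) < 1L) stop("at least one allele is required", call. = FALSE)
  if (anyDuplicated(alleles))
    stop("duplicate allele in sample '", sample_id, "': ",
         paste(unique(alleles[duplicated(alleles)]), collapse = ", "),
         call. = FALSE)
  v <- validate_peptides(peptides)
  structure(
    list(
      sample_id = sample_id,
      peptides = v$kept,
      alleles = as.character(alleles),
      mhc_class = mhc_class,
      log = list(n_input = length(peptides), n_rejected_alphabet = v$n_rejected)
    ),
    class = "peptidome_sample"
  )
}

#' @export
print.peptidome_sample <- function(x, ...) {
  cat("peptidome_sample '", x$sample_id, "' (class ", x$mhc_class, ")\n",
      "  ", length(x$peptides), " peptides (", length(unique(x$peptides)),
      " unique), ", x$log$n_rejected_alphabet, " rejected\n",
      "  alleles: ", paste(x$alleles, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read peptides from a plain list or FASTA file
#'
#' List format is one peptide per line. FASTA is parsed with
#' `Biostrings::readAAStringSet`. Peptides are upper-cased and returned in
#' input order with duplicates retained; lines containing non-canonical
#' residues are excluded and counted in the `"n_skipped"` attribute.
#'
#' @param path Readable text file.
#' @param format `"auto"` (default, FASTA iff the first non-blank character
#'   is `>`), `"list"`, or `"fasta"`.
#' @return Character vector of peptides with attributes `n_skipped` and
#'   `skipped`.
#' @export
read_peptide_input <- function(path, format = c("auto", "list", "fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read peptide input: ", path, call. = FALSE)
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (length(first) && startsWith(trimws(first), ">")) "fasta" else "list"
  }
  raw <- if (format == "fasta") {
    as.character(Biostrings::readAAStringSet(path))
  } else {
    x <- trimws(readLines(path, warn = FALSE))
    x[nzchar(x)]
  }
  if (length(raw) == 0L) stop("no peptides in input: ", path, call. = FALSE)
  v <- validate_peptides(unname(raw))
  if (length(v$kept) == 0L)
    stop("no peptides left after alphabet validation: ", path, call. = FALSE)
  structure(v$kept, n_skipped = v$n_rejected, skipped = v$rejected)
}

# Allele-name syntax: optional HLA- prefix, locus, '*', two-field code,
# optional trailing N for null alleles (accepted verbatim).
.ALLELE_RE <- "^(HLA-)?[A-Z][A-Z0-9]*\\*[0-9]+:[0-9]+N?$"

#' Read a sample sheet
#'
#' Tab-separated with header columns `sample_id`, `mhc_class`, `alleles`
#' (comma-separated), `peptide_file`. Returns one sample stub per row;
#' allele-name syntax is validated (locus, `*`, two-field code; a trailing
#' `N` marks a null allele and is accepted verbatim as a distinct name).
#'
#' @param path Sample sheet TSV.
#' @return List of stubs, each a list with `sample_id`, `mhc_class`,
#'   `alleles`, `peptide_file`.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("sample_id", "mhc_class", "alleles", "peptide_file")
  if (!all(need %in% names(df)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in sample sheet: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    alleles <- trimws(strsplit(df$alleles[i], ",", fixed = TRUE)[[1]])
    alleles <- alleles[nzchar(alleles)]
    bad <- alleles[!grepl(.ALLELE_RE, alleles)]
    if (length(bad))
      stop("row ", i, " (sample '", df$sample_id[i], "'): malformed allele name ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (anyDuplicated(alleles))
      stop("row ", i, " (sample '", df$sample_id[i], "'): duplicate allele ",
           paste(unique(alleles[duplicated(alleles)]), collapse = ", "),
           call. = FALSE)
    if (length(alleles) < 1L)
      stop("row ", i, " (sample '", df$sample_id[i], "'): no alleles", call. = FALSE)
    if (!df$mhc_class[i] %in% c("I", "II"))
      stop("row ", i, ": mhc_class must be 'I' or 'II'", call. = FALSE)
    list(sample_id = df$sample_id[i], mhc_class = df$mhc_class[i],
         alleles = alleles, peptide_file = df$peptide_file[i])
  })
}

#' Construct a rank table
#'
#' A rank table is a long-format data frame with one row per
#' (sample, peptide, allele) combination: columns `sample_id`, `peptide`,
#' `allele`, `raw_score`, `rank_percent`, `core`, `core_offset` (0-based).
#' The table must be complete: within each sample, every unique peptide has
#' exactly one row per allele of that sample.
#'
#' @param df Data frame with the columns above (`core`/`core_offset` may be
#'   `NA`).
#' @return The validated data frame with class `rank_table`.
#' @export
rank_table <- function(df) {
  need <- c("sample_id", "peptide", "allele", "raw_score", "rank_percent",
            "core", "core_offset")
  if (!all(need %in% names(df)))
    stop("rank table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  df <- df[, need]
  df$rank_percent <- as.numeric(df$rank_percent)
  df$raw_score <- as.numeric(df$raw_score)
  bad_rank <- which(!is.finite(df$rank_percent) | df$rank_percent < 0 |
                      df$rank_percent > 100)
  if (length(bad_rank))
    stop("rank_percent outside [0,100] at row(s) ",
         paste(utils::head(bad_rank, 5L), collapse = ", "), call. = FALSE)
  has_core <- !is.na(df$core) & nzchar(df$core)
  if (any(has_core)) {
    off <- as.integer(df$core_offset[has_core])
    sub <- substr(df$peptide[has_core], off + 1L, off + 9L)
    bad <- which(nchar(df$core[has_core]) != 9L | sub != df$core[has_core])
    if (length(bad))
      stop("core is not the 9-mer at core_offset for row(s) ",
           paste(utils::head(which(has_core)[bad], 5L), collapse = ", "),
           call. = FALSE)
  }
  check_rank_table_complete(df)
  class(df) <- c("rank_table", "data.frame")
  df
}

# Completeness invariant: within each sample, peptides x alleles fully
# crossed, one row each.
check_rank_table_complete <- function(df) {
  for (sid in unique(df$sample_id)) {
    d <- df[df$sample_id == sid, ]
    peps <- unique(d$peptide)
    alls <- unique(d$allele)
    tab <- table(factor(d$peptide, peps), factor(d$allele, alls))
    if (any(tab != 1L)) {
      miss <- which(tab == 0L, arr.ind = TRUE)
      msg <- if (nrow(miss)) {
        paste0("missing (peptide, allele) pair(s): ",
               paste(utils::head(
                 paste0("(", peps[miss[, 1]], ", ", alls[miss[, 2]], ")"), 5L),
                 collapse = ", "))
      } else "duplicated (peptide, allele) rows"
      stop("incomplete rank table for sample '", sid, "': ", msg, call. = FALSE)
    }
  }
  invisible(df)
}

#' Read a long-format prediction table
#'
#' Adapter for externally computed predictions (e.g. a neural predictor's
#' output exported to TSV). Expects a header `sample_id`, `peptide`,
#' `allele`, `raw_score`, `rank_percent`, `core`, `core_offset`;
#' `core`/`core_offset` may be empty. Enforces the rank-table completeness
#' invariant and the rank range.
#'
#' @param path Prediction table TSV.
#' @return A [rank_table()].
#' @export
read_prediction_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = list(sample_id = "character",
                                            peptide = "character",
                                            allele = "character",
                                            core = "character"))
  df$core[is.na(df$core) | !nzchar(df$core)] <- NA_character_
  df$core_offset <- suppressWarnings(as.integer(df$core_offset))
  rank_table(df)
}

#' Write deconvolution output tables
#'
#' Writes two TSVs into `dir`: `peptide_allele_scores.tsv`, the full
#' peptide-by-allele score table (one row per peptide-allele combination
#' with raw and rank scores and the 9-mer binding core), and
#' `peptide_assignments.tsv`, the per-peptide assignment
#' (`sample_id`, `peptide`, `assigned`, `best_rank`, `best_core`).
#' Column order is fixed and ranks are printed with 4 decimals, so a
#' write/read round-trip through [read_prediction_table()] reproduces ranks
#' to printed precision.
#'
#' @param result A `deconvolution_result` from [assign_peptides()] or
#'   [deconvolute()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_assignment_table <- function(result, dir) {
  stopifnot(inherits(result, "deconvolution_result"))
  if (nrow(result$assignments) == 0L) stop("empty result", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scores_path <- file.path(dir, "peptide_allele_scores.tsv")
  assign_path <- file.path(dir, "peptide_assignments.tsv")

  sc <- as.data.frame(result$rank_table)
  sc$raw_score <- sprintf("%.4f", sc$raw_score)
  sc$rank_percent <- sprintf("%.4f", sc$rank_percent)
  sc$core[is.na(sc$core)] <- ""
  sc$core_offset[is.na(sc$core_offset)] <- ""
  utils::write.table(sc, scores_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  asn <- result$assignments
  asn$best_rank <- sprintf("%.4f", asn$best_rank)
  asn$best_core[is.na(asn$best_core)] <- ""
  utils::write.table(asn, assign_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(scores = scores_path, assignments = assign_path))
}
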