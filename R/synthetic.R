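#' Specify a mock allele motif
#'
#' A mock allele is defined by anchor positions (a subset of core positions
#' 1..9) with per-position preferred-residue frequency maps; non-anchor
#' positions follow the background. Together with a length distribution
#' this fully specifies a ground-truth generative motif for synthetic
#' peptidomes.
#'
#' @param allele Allele name (used as the ground-truth label).
#' @param anchors Named list; names are core positions (`"1"`..`"9"`),
#'   values are named numeric frequency maps over residues, each summing
#'   to 1 (residues not named get frequency 0 at that position).
#' @param length_dist Named numeric vector mapping peptide length to
#'   probability (sums to 1); default [default_length_dist()] for the
#'   class.
#' @param mhc_class `"I"` or `"II"`.
#' @return A `mock_allele_spec`.
#' @examples
#' sp <- mock_allele_spec("MOCKDR*01:01", list(`1` = c(Y = 0.5, F = 0.5)))
#' @export
mock_allele_spec <- function(allele, anchors, length_dist = NULL,
                             mhc_class = c("II", "I")) {
  mhc_class <- match.arg(mhc_class)
  stopifnot(is.list(anchors))
  if (length(anchors)) {
    pos <- as.integer(names(anchors))
    if (anyNA(pos) || any(pos < 1L | pos > 9L))
      stop("anchor positions must be in 1..9", call. = FALSE)
    for (p in names(anchors)) {
      m <- anchors[[p]]
      if (is.null(names(m)) || !all(names(m) %in% AMINO_ACIDS))
        stop("anchor map at P", p, " must be named by canonical residues",
             call. = FALSE)
      if (any(m < 0) || abs(sum(m) - 1) > 1e-6)
        stop("anchor map at P", p, " must be non-negative and sum to 1",
             call. = FALSE)
    }
  } else {
    warning("empty anchor set: mock allele '", allele,
            "' will have a flat motif")
  }
  if (is.null(length_dist)) length_dist <- default_length_dist(mhc_class)
  if (abs(sum(length_dist) - 1) > 1e-6 || is.null(names(length_dist)))
    stop("length_dist must be a named probability vector summing to 1",
         call. = FALSE)
  lens <- as.integer(names(length_dist))
  rng <- if (mhc_class == "I") c(8L, 14L) else c(12L, 25L)
  if (any(lens < rng[1] | lens > rng[2]))
    stop("length support ", min(lens), "-", max(lens),
         " incompatible with class ", mhc_class, " range ",
         rng[1], "-", rng[2], call. = FALSE)
  structure(list(allele = allele, anchors = anchors,
                 length_dist = length_dist, mhc_class = mhc_class),
            class = "mock_allele_spec")
}

#' Default synthetic length distributions
#'
#' Class II ligands peak at 15 residues over 12-21; class I ligands peak at
#' 9 over 8-14, echoing the canonical eluted-ligand length profiles.
#'
#' @param mhc_class `"I"` or `"II"`.
#' @return Named probability vector over lengths.
#' @export
default_length_dist <- function(mhc_class = c("II", "I")) {
  mhc_class <- match.arg(mhc_class)
  if (mhc_class == "I") {
    stats::setNames(c(0.05, 0.70, 0.14, 0.07, 0.02, 0.01, 0.01), 8:14)
  } else {
    stats::setNames(c(0.03, 0.07, 0.20, 0.30, 0.18, 0.10, 0.06, 0.03,
                      0.02, 0.01), 12:21)
  }
}

# Target positional frequencies implied by a spec: anchor maps at anchor
# positions (unnamed residues at 0), background elsewhere.
target_frequencies <- function(spec, background = aa_background()) {
  background <- check_frequencies(background)
  p <- matrix(rep(background, each = 9L), nrow = 9L,
              dimnames = list(paste0("P", 1:9), AMINO_ACIDS))
  for (pos in names(spec$anchors)) {
    row <- stats::setNames(rep(0, 20L), AMINO_ACIDS)
    row[names(spec$anchors[[pos]])] <- spec$anchors[[pos]]
    p[as.integer(pos), ] <- row
  }
  p
}

#' Build a PSSM model from a mock allele specification
#'
#' Weights are `log2(p_target / q)` where `p_target` is the spec's anchor
#' map at anchor positions and the background at the rest; target
#' frequencies are floored at 1e-3 before the log so weights stay finite
#' for residues the anchor map excludes.
#'
#' @param spec A [mock_allele_spec()].
#' @param background Background frequencies `q` (default natural).
#' @return An [allele_model()].
#' @examples
#' sp <- mock_allele_spec("MOCKDR*01:01", list(`1` = c(A = 1)))
#' m <- make_mock_allele(sp, aa_background("uniform"))
#' m$weights["P1", "A"]  # log2(1 / 0.05)
#' @export
make_mock_allele <- function(spec, background = aa_background()) {
  stopifnot(inherits(spec, "mock_allele_spec"))
  background <- check_frequencies(background)
  p <- target_frequencies(spec, background)
  w <- log2(pmax(p, 1e-3) / rep(background, each = 9L))
  allele_model(spec$allele, w, background)
}

#' Sample a ground-truth labeled peptidome from one mock allele
#'
#' Per peptide: a length is drawn from the spec's length distribution and a
#' 9-mer core from the spec's target positional frequencies. Class II
#' peptides embed the core in background flanks at a uniformly drawn
#' offset. Class I peptides of length 9 are the core itself; length 8
#' deletes core position 5; lengths above 9 insert background residues
#' between core positions 5 and 6 (central bulge convention). Fully
#' reproducible from `seed`.
#'
#' @param spec A [mock_allele_spec()].
#' @param n Number of peptides (>= 1).
#' @param seed Integer seed.
#' @param background Background frequencies for flanks/insertions.
#' @return A `labeled_peptidome` (see [build_artificial_benchmark()]) with
#'   a single true label.
#' @export
sample_peptidome <- function(spec, n, seed = NULL,
                             background = aa_background()) {
  stopifnot(inherits(spec, "mock_allele_spec"), n >= 1L)
  background <- check_frequencies(background)
  peps <- with_seed(seed, draw_motif_peptides(spec, n, background))
  labeled_peptidome(peps, rep(spec$allele, n), alleles = spec$allele,
                    mhc_class = spec$mhc_class, seed = seed)
}

# RNG-using internals; callers control the seed.
draw_motif_peptides <- function(spec, n, background) {
  p_target <- target_frequencies(spec, background)
  lens <- as.integer(names(spec$length_dist))
  L <- if (length(lens) == 1L) rep(lens, n)
       else sample(lens, n, replace = TRUE, prob = spec$length_dist)
  cores <- draw_cores(n, p_target)
  if (spec$mhc_class == "II") embed_core_class2(cores, L, background)
  else reshape_core_class1(cores, L, background)
}

draw_cores <- function(n, p_target) {
  cols <- lapply(1:9, function(i)
    AMINO_ACIDS[sample.int(20L, n, replace = TRUE, prob = p_target[i, ])])
  do.call(paste0, cols)
}

embed_core_class2 <- function(cores, L, background) {
  n <- length(cores)
  ft <- L - 9L
  if (any(ft < 0L)) stop("class II lengths must be >= 9", call. = FALSE)
  off <- integer(n)
  pos <- ft > 0L
  # uniform offset 0..ft for the core within the peptide
  off[pos] <- floor(stats::runif(sum(pos)) * (ft[pos] + 1L))
  off <- pmin(off, ft)
  flank <- character(n)
  for (l in unique(ft[ft > 0L])) {
    sel <- which(ft == l)
    flank[sel] <- random_peptides(length(sel), l, background)
  }
  paste0(substring(flank, 1L, off), cores,
         substring(flank, off + 1L, ft))
}

reshape_core_class1 <- function(cores, L, background) {
  n <- length(cores)
  out <- character(n)
  out[L == 9L] <- cores[L == 9L]
  del <- L == 8L
  out[del] <- paste0(substr(cores[del], 1L, 4L), substr(cores[del], 6L, 9L))
  for (l in unique(L[L > 9L])) {
    sel <- which(L == l)
    ins <- random_peptides(length(sel), l - 9L, background)
    out[sel] <- paste0(substr(cores[sel], 1L, 5L), ins,
                       substr(cores[sel], 6L, 9L))
  }
  if (any(L < 8L)) stop("class I lengths must be >= 8", call. = FALSE)
  out
}

#' Ground-truth labeled peptidome
#'
#' Container pairing peptides with the allele that generated them (or
#' `CONTAMINANT`), plus the sample's allele list, class and generation
#' seed.
#'
#' @param peptides,true_label Equal-length character vectors.
#' @param alleles The declared allele list of the synthetic sample.
#' @param mhc_class `"I"` or `"II"`.
#' @param seed Generation seed (recorded).
#' @return A `labeled_peptidome` list with fields `peptides`, `true_label`,
#'   `alleles`, `mhc_class`, `seed`.
#' @export
labeled_peptidome <- function(peptides, true_label, alleles, mhc_class,
                              seed = NULL) {
  stopifnot(length(peptides) == length(true_label))
  structure(list(peptides = as.character(peptides),
                 true_label = as.character(true_label),
                 alleles = as.character(alleles),
                 mhc_class = mhc_class, seed = seed),
            class = "labeled_peptidome")
}

#' @export
print.labeled_peptidome <- function(x, ...) {
  cat("labeled_peptidome: ", length(x$peptides), " peptides, class ",
      x$mhc_class, "\n", sep = "")
  print(table(x$true_label))
  invisible(x)
}

# Preferred-residue map blended with a uniform floor so every residue keeps
# some mass: sharp enough to anchor, smooth enough that scores are
# effectively continuous.
blend_map <- function(prefs, blend = 0.10) {
  prefs <- prefs / sum(prefs)
  full <- stats::setNames(rep(blend / 20, 20L), AMINO_ACIDS)
  full[names(prefs)] <- full[names(prefs)] + (1 - blend) * prefs
  full
}

#' Built-in mock allele panels
#'
#' Two panels of ground-truth motif specifications used by the artificial
#' benchmarks. `"classI_benchmark"`: six class I mock alleles with anchors
#' at P2 and P9 - four with sharp motifs (A/B-like) and two with weaker,
#' flatter motifs (C-like, emulating the less-defined HLA-C specificity).
#' `"classII_benchmark"`: four class II mock DR alleles with pairwise
#' disjoint preferred residues at P1/P4/P6/P9 and length support 13-21.
#' Anchor preferences are loose caricatures of published DR motif
#' chemistry (aromatic vs aliphatic P1, charged P4/P9, etc.); the labels
#' are synthetic.
#'
#' @param preset `"classI_benchmark"` or `"classII_benchmark"`.
#' @return Named list of [mock_allele_spec()]s.
#' @export
mock_allele_panel <- function(preset = c("classII_benchmark",
                                         "classI_benchmark")) {
  preset <- match.arg(preset)
  if (preset == "classII_benchmark") {
    len2 <- stats::setNames(c(0.08, 0.20, 0.30, 0.18, 0.10, 0.06, 0.04,
                              0.02, 0.02), 13:21)
    specs <- list(
      mock_allele_spec("MOCKDR*01:01", list(
        `1` = blend_map(c(Y = 0.5, W = 0.25, F = 0.25)),
        `4` = blend_map(c(D = 0.6, E = 0.4)),
        `6` = blend_map(c(K = 0.5, R = 0.5)),
        `9` = blend_map(c(L = 0.5, I = 0.3, V = 0.2))
      ), len2, "II"),
      mock_allele_spec("MOCKDR*02:01", list(
        `1` = blend_map(c(L = 0.5, I = 0.3, V = 0.2)),
        `4` = blend_map(c(Q = 0.6, N = 0.4)),
        `6` = blend_map(c(A = 0.4, S = 0.35, G = 0.25)),
        `9` = blend_map(c(K = 0.6, R = 0.4))
      ), len2, "II"),
      mock_allele_spec("MOCKDR*03:01", list(
        `1` = blend_map(c(D = 0.5, E = 0.5)),
        `4` = blend_map(c(Y = 0.5, F = 0.3, W = 0.2)),
        `6` = blend_map(c(L = 0.5, V = 0.5)),
        `9` = blend_map(c(D = 0.6, E = 0.4))
      ), len2, "II"),
      mock_allele_spec("MOCKDR*04:01", list(
        `1` = blend_map(c(K = 0.5, R = 0.5)),
        `4` = blend_map(c(L = 0.4, I = 0.3, V = 0.3)),
        `6` = blend_map(c(D = 0.5, E = 0.5)),
        `9` = blend_map(c(Y = 0.4, F = 0.4, W = 0.2))
      ), len2, "II")
    )
  } else {
    # Class I mocks anchor at P2 / auxiliary P3 / C-terminal P9. The P3
    # auxiliary keeps two of three anchors inside one contiguous window for
    # middle-bulged length variants, which a window-maximising PSSM can
    # still detect. "C-like" alleles are flat at P2/P3 but keep a fairly
    # sharp C-terminal anchor, emulating their less defined motifs with one
    # prominent anchor.
    len1 <- default_length_dist("I")
    strong <- function(allele, p2, p3, p9)
      mock_allele_spec(allele, list(`2` = blend_map(p2, 0.10),
                                    `3` = blend_map(p3, 0.10),
                                    `9` = blend_map(p9, 0.10)),
                       len1, "I")
    weak <- function(allele, p2, p3, p9)
      mock_allele_spec(allele, list(`2` = blend_map(p2, 0.45),
                                    `3` = blend_map(p3, 0.45),
                                    `9` = blend_map(p9, 0.10)),
                       len1, "I")
    specs <- list(
      strong("MOCKA*01:01", c(L = 0.6, M = 0.4), c(F = 0.6, Y = 0.4),
             c(V = 0.6, I = 0.4)),
      strong("MOCKA*02:01", c(S = 0.6, T = 0.4), c(K = 0.6, R = 0.4),
             c(Y = 0.6, F = 0.4)),
      strong("MOCKB*01:01", c(E = 0.6, D = 0.4), c(I = 0.6, V = 0.4),
             c(L = 0.6, M = 0.4)),
      strong("MOCKB*02:01", c(K = 0.6, R = 0.4), c(D = 0.6, E = 0.4),
             c(A = 0.6, G = 0.4)),
      weak("MOCKC*01:01", c(A = 0.5, V = 0.5), c(L = 0.5, P = 0.5),
           c(F = 0.5, W = 0.5)),
      weak("MOCKC*02:01", c(Y = 0.5, W = 0.5), c(G = 0.5, S = 0.5),
           c(K = 0.5, R = 0.5))
    )
  }
  stats::setNames(specs, vapply(specs, `[[`, "", "allele"))
}

# Class II contaminant model: co-purified contaminants in class II
# immunoprecipitates are predominantly short class I-type ligands, so the
# default contaminant length profile is class I-like (8-11, peaked at 9).
default_contaminant_length_dist <- function(mhc_class) {
  if (mhc_class == "II")
    stats::setNames(c(0.08, 0.60, 0.20, 0.12), 8:11)
  else
    stats::setNames(rep(1 / 11, 11L), 15:25)
}

#' Build a merged artificial benchmark dataset
#'
#' Samples a labeled peptidome from each mock allele, injects random
#' contaminant peptides, merges and shuffles deterministically. Peptides
#' are unique within and across origins (cross-origin duplicates would
#' have ambiguous truth and are dropped with a logged count). Presets
#' reproduce the published benchmark designs: `"classI_benchmark"` mixes
#' four high-abundance alleles at 1000 peptides each with two
#' low-abundance weak-motif alleles at 200 each (the 5:1 A/B-to-C
#' expression ratio), giving 4400 labeled ligands;
#' `"classII_benchmark"` mixes 800 unique peptides of length 13-21 from
#' each of four mock DR alleles.
#'
#' @param specs Named list of [mock_allele_spec()]s (default: from
#'   `preset`).
#' @param per_allele_counts Named integer vector allele -> n (default:
#'   preset design).
#' @param contaminant_n Number of contaminant peptides to inject
#'   (default 0).
#' @param seed Integer seed; the whole benchmark is reproducible from it.
#' @param preset Optional `"classI_benchmark"` / `"classII_benchmark"`.
#' @param background Background frequencies.
#' @param contaminant_length_dist Named probability vector for contaminant
#'   lengths; the class II default is a class I-like short profile
#'   (8-11, peaked at 9) emulating co-purified class I ligands.
#' @return A `labeled_peptidome` with labels = generating allele or
#'   `CONTAMINANT`, plus `models` (the true [allele_model()]s) attached.
#' @export
build_artificial_benchmark <- function(specs = NULL, per_allele_counts = NULL,
                                       contaminant_n = 0L, seed = 1L,
                                       preset = NULL,
                                       background = aa_background(),
                                       contaminant_length_dist = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("classI_benchmark", "classII_benchmark"))
    if (is.null(specs)) specs <- mock_allele_panel(preset)
    if (is.null(per_allele_counts)) {
      per_allele_counts <- if (preset == "classI_benchmark") {
        stats::setNames(c(1000L, 1000L, 1000L, 1000L, 200L, 200L),
                        names(specs))
      } else {
        stats::setNames(rep(800L, 4L), names(specs))
      }
    }
  }
  if (is.null(specs)) specs <- list()
  if (is.null(per_allele_counts))
    per_allele_counts <- stats::setNames(integer(0), character(0))
  if (length(per_allele_counts) &&
      !all(names(per_allele_counts) %in% names(specs)))
    stop("per_allele_counts names must match spec names", call. = FALSE)
  if (any(per_allele_counts < 0L) || contaminant_n < 0L)
    stop("counts must be >= 0", call. = FALSE)
  mhc_class <- if (length(specs)) specs[[1]]$mhc_class else "II"
  background <- check_frequencies(background)
  if (is.null(contaminant_length_dist))
    contaminant_length_dist <- default_contaminant_length_dist(mhc_class)

  out <- with_seed(seed, {
    pep <- character(0); lab <- character(0)
    for (a in names(per_allele_counts)) {
      n <- per_allele_counts[[a]]
      if (n == 0L) next
      got <- character(0)
      while (length(got) < n) {
        batch <- draw_motif_peptides(specs[[a]],
                                     max(2L * (n - length(got)), 32L),
                                     background)
        got <- unique(c(got, batch))
      }
      pep <- c(pep, got[seq_len(n)])
      lab <- c(lab, rep(a, n))
    }
    if (contaminant_n > 0L) {
      lens <- as.integer(names(contaminant_length_dist))
      got <- character(0)
      while (length(got) < contaminant_n) {
        batch <- random_peptides(max(2L * (contaminant_n - length(got)), 32L),
                                 lens, background,
                                 length_probs = contaminant_length_dist)
        got <- unique(c(got, batch))
      }
      pep <- c(pep, got[seq_len(contaminant_n)])
      lab <- c(lab, rep("CONTAMINANT", contaminant_n))
    }
    # cross-origin duplicates have ambiguous ground truth: drop all copies
    dup <- pep %in% pep[duplicated(pep)]
    n_ambiguous <- sum(dup)
    pep <- pep[!dup]; lab <- lab[!dup]
    o <- sample.int(length(pep))
    list(pep = pep[o], lab = lab[o], n_ambiguous = n_ambiguous)
  })
  lp <- labeled_peptidome(out$pep, out$lab, alleles = names(per_allele_counts),
                          mhc_class = mhc_class, seed = seed)
  lp$models <- lapply(specs, make_mock_allele, background = background)
  lp$n_ambiguous_dropped <- out$n_ambiguous
  lp
}

#' Remove peptides sharing a k-mer with an exclusion set
#'
#' Benchmark hygiene: any peptide sharing a contiguous k-mer with any
#' exclusion peptide is removed (e.g. excluding overlap with a predictor's
#' training data; k = 8 for class I, 9 for class II in the published
#' protocol). Implemented via a k-mer index of the exclusion set.
#'
#' @param peptides Character vector to filter.
#' @param exclusion_set Character vector of excluded peptides.
#' @param k Overlap length (>= 1).
#' @return List with `retained`, `removed`.
#' @export
kmer_overlap_filter <- function(peptides, exclusion_set, k) {
  stopifnot(k >= 1L)
  if (length(exclusion_set) == 0L || all(nchar(exclusion_set) < k)) {
    if (length(exclusion_set))
      warning("k = ", k, " exceeds every exclusion peptide length; ",
              "nothing removed")
    return(list(retained = peptides, removed = character(0)))
  }
  index <- unique(all_kmers(exclusion_set, k))
  hit <- vapply(peptides, function(p) {
    n <- nchar(p)
    if (n < k) return(FALSE)
    any(substring(p, 1:(n - k + 1L), k:n) %in% index)
  }, logical(1), USE.NAMES = FALSE)
  list(retained = peptides[!hit], removed = peptides[hit])
}

all_kmers <- function(x, k) {
  x <- x[nchar(x) >= k]
  unlist(lapply(x, function(p) {
    n <- nchar(p)
    substring(p, 1:(n - k + 1L), k:n)
  }), use.names = FALSE)
}

#' Scrambled-peptide null dataset
#'
#' Each input peptide is scrambled `n_scrambles` times (uniform random
#' permutations of its residues, preserving amino-acid composition); every
#' scramble is scored with `rank_fn` and its best (lowest) rank over the
#' sample's alleles recorded. A subsample of the scrambles matching the
#' original length histogram exactly (per-length sampling without
#' replacement when possible, with replacement otherwise) provides a
#' length-matched null for the original dataset.
#'
#' @param peptides Character vector of source peptides.
#' @param rank_fn Function: character vector of peptides -> numeric vector
#'   of best percentile ranks (minimum over the relevant alleles).
#' @param n_scrambles Scrambles per peptide (default 100, >= 1).
#' @param seed Integer seed.
#' @return List with `scrambles` (data frame `source`, `scramble`, `rank`),
#'   `per_peptide` (data frame `peptide`, `best_rank`: minimum over that
#'   peptide's scrambles) and `subsample` (length-matched rows of
#'   `scrambles`).
#' @export
scramble_peptides <- function(peptides, rank_fn, n_scrambles = 100L,
                              seed = NULL) {
  if (n_scrambles < 1L) stop("n_scrambles must be >= 1", call. = FALSE)
  stopifnot(is.function(rank_fn))
  with_seed(seed, {
    chars <- strsplit(peptides, "", fixed = TRUE)
    scr <- unlist(lapply(chars, function(ch) {
      vapply(seq_len(n_scrambles),
             function(i) paste(sample(ch), collapse = ""), character(1))
    }), use.names = FALSE)
    src <- rep(peptides, each = n_scrambles)
    ranks <- rank_fn(scr)
    if (length(ranks) != length(scr))
      stop("rank_fn must return one rank per peptide", call. = FALSE)
    df <- data.frame(source = src, scramble = scr, rank = as.numeric(ranks),
                     stringsAsFactors = FALSE)
    grp <- rep(seq_along(peptides), each = n_scrambles)
    per <- data.frame(
      peptide = peptides,
      best_rank = as.numeric(tapply(df$rank, grp, min)),
      stringsAsFactors = FALSE
    )
    # exact length-histogram match against the originals
    want <- table(nchar(peptides))
    pool_len <- nchar(df$scramble)
    rows <- unlist(lapply(names(want), function(l) {
      pool <- which(pool_len == as.integer(l))
      k <- want[[l]]
      if (length(pool) >= k) sample(pool, k)
      else sample(pool, k, replace = TRUE)
    }), use.names = FALSE)
    list(scrambles = df, per_peptide = per, subsample = df[rows, ])
  })
}

#' Merge peptide lists from several samples
#'
#' Concatenates per-sample peptide lists and reports both the total and
#' the unique peptide counts (merged datasets are routinely quoted either
#' way).
#'
#' @param peptide_lists List of character vectors.
#' @return List with `n_total`, `n_unique`, `peptides` (unique, first
#'   occurrence order).
#' @export
merge_peptidomes <- function(peptide_lists) {
  stopifnot(is.list(peptide_lists))
  all <- unlist(peptide_lists, use.names = FALSE)
  list(n_total = length(all), n_unique = length(unique(all)),
       peptides = unique(all))
}

#' Write a synthetic benchmark to disk
#'
#' Emits the files a deconvolution run consumes: per-sample peptide list
#' (`peptides.txt`), ground-truth labels (`truth.tsv`), the true model
#' JSONs (`models.json`) and a one-row sample sheet (`sample_sheet.tsv`).
#'
#' @param lp A `labeled_peptidome` from [build_artificial_benchmark()].
#' @param dir Output directory.
#' @param sample_id Sample identifier used in the sheet (default
#'   `"synthetic"`).
#' @return Invisibly, the file paths.
#' @export
write_benchmark <- function(lp, dir, sample_id = "synthetic") {
  stopifnot(inherits(lp, "labeled_peptidome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pep_path <- file.path(dir, "peptides.txt")
  writeLines(lp$peptides, pep_path)
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(
    data.frame(peptide = lp$peptides, true_label = lp$true_label),
    truth_path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  sheet_path <- file.path(dir, "sample_sheet.tsv")
  utils::write.table(
    data.frame(sample_id = sample_id, mhc_class = lp$mhc_class,
               alleles = paste(lp$alleles, collapse = ","),
               peptide_file = pep_path),
    sheet_path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  paths <- c(peptides = pep_path, truth = truth_path, sheet = sheet_path)
  if (!is.null(lp$models)) {
    model_path <- file.path(dir, "models.json")
    write_allele_models(lp$models, model_path)
    paths <- c(paths, models = model_path)
  }
  invisible(paths)
}
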