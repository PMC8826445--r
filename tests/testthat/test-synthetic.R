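test_that("mock models follow the log-odds construction", {
  q <- aa_background("uniform")
  # anchor map equal to the background gives an all-zero weight matrix
  sp_flat <- mock_allele_spec("MOCKDR*09:01",
                              list(`1` = q, `5` = q), mhc_class = "II")
  m_flat <- make_mock_allele(sp_flat, q)
  expect_equal(max(abs(m_flat$weights)), 0)

  # point-mass anchor vs uniform background: log2(1 / 0.05)
  sp <- mock_allele_spec("MOCKDR*09:02", list(`1` = c(A = 1)),
                         mhc_class = "II")
  m <- make_mock_allele(sp, q)
  expect_equal(m$weights["P1", "A"], log2(1 / 0.05), tolerance = 1e-12)
  # excluded residues are floored at 1e-3 before the log
  expect_equal(m$weights["P1", "C"], log2(1e-3 / 0.05), tolerance = 1e-12)
  expect_equal(unname(m$weights["P2", ]), rep(0, 20))

  # disjoint anchors give dissimilar implied motifs
  panel <- mock_allele_panel("classII_benchmark")
  f1 <- model_frequency_matrix(make_mock_allele(panel[[1]]))
  f2 <- model_frequency_matrix(make_mock_allele(panel[[2]]))
  pcc <- stats::cor(as.vector(t(f1)), as.vector(t(f2)))
  expect_lt(pcc, 0.5)

  expect_warning(mock_allele_spec("MOCKDR*09:03", list(), mhc_class = "II"),
                 "flat motif")
  expect_error(mock_allele_spec("X*01:01", list(`1` = c(A = 0.5))),
               "sum to 1")
})

test_that("sampled peptidomes are seeded, in-range, and reproduce anchor maps", {
  sp <- mock_allele_panel("classII_benchmark")[[1]]
  lp1 <- sample_peptidome(sp, 100, seed = 5)
  lp2 <- sample_peptidome(sp, 100, seed = 5)
  expect_identical(lp1$peptides, lp2$peptides)
  expect_true(all(nchar(lp1$peptides) %in% 13:21))
  expect_equal(unique(lp1$true_label), sp$allele)

  # P1 anchor usage in generated cores matches the spec map within 0.05
  big <- sample_peptidome(sp, 5000, seed = 6)
  m <- make_mock_allele(sp)
  cur <- calibrate_ranks(m, n_bg = 1000L, length_range = c(13, 21), seed = 7)
  cores <- score_peptides(m, big$peptides)$core
  p1 <- substr(cores, 1, 1)
  p1_map <- sp$anchors[["1"]]
  for (a in names(p1_map)[p1_map > 0.05])
    expect_lt(abs(mean(p1 == a) - p1_map[[a]]), 0.05)

  # class I length variants stay inside the class range
  sp1 <- mock_allele_panel("classI_benchmark")[[1]]
  lpc1 <- sample_peptidome(sp1, 500, seed = 8)
  expect_true(all(nchar(lpc1$peptides) %in% 8:14))
})

test_that("benchmark presets reproduce the published designs", {
  b1 <- build_artificial_benchmark(preset = "classI_benchmark", seed = 1)
  expect_length(b1$peptides, 4400L)
  tab1 <- table(b1$true_label)
  expect_equal(sort(as.integer(tab1)),
               c(200L, 200L, 1000L, 1000L, 1000L, 1000L))

  b2 <- build_artificial_benchmark(preset = "classII_benchmark", seed = 1)
  tab2 <- table(b2$true_label)
  expect_length(tab2, 4L)
  expect_true(all(tab2 == 800L))
  expect_true(all(nchar(b2$peptides) %in% 13:21))
  expect_equal(anyDuplicated(b2$peptides), 0L)

  # contaminants only
  b3 <- build_artificial_benchmark(contaminant_n = 50, seed = 2)
  expect_length(b3$peptides, 50L)
  expect_true(all(b3$true_label == "CONTAMINANT"))

  # determinism
  b2b <- build_artificial_benchmark(preset = "classII_benchmark", seed = 1)
  expect_identical(b2$peptides, b2b$peptides)
})

test_that("k-mer overlap filtering is sharp in k", {
  # shared 9-mer stretch: removed at k = 9
  out9 <- kmer_overlap_filter("AAAAAAAAARKL", "GGGAAAAAAAAA", k = 9)
  expect_equal(out9$removed, "AAAAAAAAARKL")

  # disjoint alphabets: everything retained
  out_dis <- kmer_overlap_filter(c("AAAAAAAAA", "CCCCCCCCC"),
                                 "GGGGGGGGGGGG", k = 8)
  expect_length(out_dis$removed, 0L)

  # longest shared stretch exactly 8: k = 8 removes, k = 9 retains
  pep <- "KLMNAAAAAAAAW"
  excl <- "GGGAAAAAAAAGG"
  expect_equal(kmer_overlap_filter(pep, excl, k = 8)$removed, pep)
  expect_length(kmer_overlap_filter(pep, excl, k = 9)$removed, 0L)

  expect_warning(out <- kmer_overlap_filter("AAAAAAAAA", "AAAA", k = 9),
                 "exceeds every exclusion peptide")
  expect_equal(out$retained, "AAAAAAAAA")
})

test_that("scrambles preserve composition and track best ranks", {
  m <- ala_model()
  cur <- manual_curve(0:9)
  rank_fn <- function(p) rank_of(cur, score_peptides(m, p)$raw_score)
  peps <- c("AAKMNPQRSTVWY", "AAAAAAAAAAAAA", "CCDEFGHIKLMNP")
  sc <- scramble_peptides(peps, rank_fn, n_scrambles = 20, seed = 11)

  # composition invariance
  comp <- function(x) vapply(strsplit(x, ""), function(ch)
    paste(sort(ch), collapse = ""), character(1))
  expect_equal(comp(sc$scrambles$scramble), comp(sc$scrambles$source))

  # homopolymer scrambles are the source itself
  homo <- sc$scrambles$scramble[sc$scrambles$source == peps[2]]
  expect_true(all(homo == peps[2]))

  # per-peptide best rank is the minimum over that peptide's scrambles
  indep <- rank_fn(sc$scrambles$scramble)
  best <- tapply(indep, sc$scrambles$source, min)
  expect_equal(sc$per_peptide$best_rank,
               as.numeric(best[sc$per_peptide$peptide]), tolerance = 1e-12)
  expect_true(all(sc$per_peptide$best_rank <=
                    as.numeric(tapply(indep, sc$scrambles$source, max)[
                      sc$per_peptide$peptide])))

  # the subsample matches the original length histogram exactly
  expect_equal(table(nchar(sc$subsample$scramble)), table(nchar(peps)))

  # determinism
  sc2 <- scramble_peptides(peps, rank_fn, n_scrambles = 20, seed = 11)
  expect_identical(sc$scrambles$scramble, sc2$scrambles$scramble)
  expect_error(scramble_peptides(peps, rank_fn, n_scrambles = 0), ">= 1")
})

test_that("scrambling destroys informative motifs but not flat ones", {
  sp <- mock_allele_panel("classII_benchmark")[[1]]
  m <- make_mock_allele(sp)
  cur <- calibrate_ranks(m, n_bg = 5000L, length_range = c(13, 21), seed = 13)
  rank_fn <- function(p) rank_of(cur, score_peptides(m, p)$raw_score)

  src <- sample_peptidome(sp, 80, seed = 14)$peptides
  src_ranks <- rank_fn(src)
  sc <- scramble_peptides(src, rank_fn, n_scrambles = 10, seed = 15)
  # strong motif: scrambles rank stochastically worse than their sources
  w <- stats::wilcox.test(sc$scrambles$rank, src_ranks,
                          alternative = "greater", exact = FALSE)
  expect_lt(w$p.value, 1e-6)

  # flat motif: scrambling changes nothing about the score distribution
  z <- zero_model()
  curz <- calibrate_ranks(z, n_bg = 1000L, length_range = c(13, 21), seed = 16)
  rank_fn_z <- function(p) rank_of(curz, score_peptides(z, p)$raw_score)
  scz <- scramble_peptides(src, rank_fn_z, n_scrambles = 5, seed = 17)
  expect_equal(unique(scz$scrambles$rank), unique(rank_fn_z(src)))
})

test_that("merged peptidomes report both total and unique counts", {
  m <- merge_peptidomes(list(c("AAA", "CCC"), c("CCC", "GGG"), "AAA"))
  expect_equal(m$n_total, 5L)
  expect_equal(m$n_unique, 3L)
  expect_equal(m$peptides, c("AAA", "CCC", "GGG"))
})

test_that("low-abundance weak-motif alleles are still recovered", {
  b1 <- build_artificial_benchmark(preset = "classI_benchmark", seed = 1)
  s1 <- peptidome_sample("c1", b1$peptides, b1$alleles, "I")
  r1 <- deconvolute(s1, models = b1$models, config = deconv_config("I"),
                    calibration_seed = 51L, n_bg = 100000L)
  tl <- stats::setNames(b1$true_label, b1$peptides)[r1$assignments$peptide]
  rep1 <- mcc_scores(confusion_matrix(tl, r1$assignments$assigned))
  minority <- grep("MOCKC", names(rep1$per_allele), value = TRUE)
  expect_length(minority, 2L)
  expect_true(all(rep1$per_allele[minority] >= 0.75))
  expect_true(all(rep1$per_allele >= 0.75))
})

test_that("benchmarks round-trip to disk as CLI-consumable files", {
  b <- build_artificial_benchmark(
    specs = mock_allele_panel("classII_benchmark")[1:2],
    per_allele_counts = c("MOCKDR*01:01" = 30, "MOCKDR*02:01" = 30),
    contaminant_n = 10, seed = 3
  )
  dir <- withr::local_tempdir()
  paths <- write_benchmark(b, dir, sample_id = "syn1")
  expect_true(all(file.exists(paths)))
  peps <- read_peptide_input(paths["peptides"], "list")
  expect_equal(as.character(peps), b$peptides)
  stub <- read_sample_sheet(paths["sheet"])[[1]]
  expect_equal(stub$alleles, b$alleles)
  mods <- read_allele_models(paths["models"])
  expect_equal(names(mods), names(b$models))
})
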