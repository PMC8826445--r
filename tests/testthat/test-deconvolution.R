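test_that("length filtering and deduplication follow the class defaults", {
  cfg2 <- deconv_config("II")
  expect_equal(c(cfg2$length_min, cfg2$length_max), c(13L, 21L))
  out <- prepare_peptides(c(strrep("A", 12), strrep("C", 15)), cfg2)
  expect_equal(as.character(out), strrep("C", 15))
  expect_equal(attr(out, "n_length_removed"), 1L)

  cfg1 <- deconv_config("I")
  expect_equal(c(cfg1$length_min, cfg1$length_max), c(8L, 14L))
  out1 <- prepare_peptides(c(strrep("A", 7), strrep("C", 9)), cfg1)
  expect_equal(as.character(out1), strrep("C", 9))

  dup <- rep("AAKMNPQRS", 2)
  out_dup <- prepare_peptides(dup, cfg1)
  expect_length(out_dup, 1L)
  expect_equal(attr(out_dup, "n_duplicates_removed"), 1L)

  expect_error(prepare_peptides(strrep("A", 30), cfg1), "no peptides left")
  expect_error(deconv_config("I", trash_threshold = 0), "trash_threshold")
  expect_error(deconv_config("I", trash_threshold = 102), "trash_threshold")
})

test_that("peptides go to the minimum-rank allele, the trash boundary is strict >", {
  peps <- c("AAKMNPQRSTVWY", "CCKMNPQRSTVWY", "DDKMNPQRSTVWY",
            "EEKMNPQRSTVWY")
  ranks <- matrix(c(0.5, 25, 20.0, 1.0,
                    10, 30, 50, 1.0),
                  ncol = 2, dimnames = list(peps, c("A*01:01", "B*08:01")))
  res <- assign_peptides(rank_table(rank_df(ranks)), deconv_config("II"))
  asn <- stats::setNames(res$assignments$assigned, res$assignments$peptide)
  expect_equal(asn[[peps[1]]], "A*01:01")       # plain argmin
  expect_equal(asn[[peps[2]]], TRASH)           # 25 and 30 both above 20
  expect_equal(asn[[peps[3]]], "A*01:01")       # rank == threshold stays assignable
  expect_equal(asn[[peps[4]]], "A*01:01")       # tie -> lexicographically first
  expect_true(is.na(
    res$assignments$best_core[res$assignments$assigned == TRASH]
  ))

  # threshold 101 disables the trash cluster
  res_no_trash <- assign_peptides(
    rank_table(rank_df(ranks)), deconv_config("II", trash_threshold = 101)
  )
  expect_equal(res_no_trash$cluster_counts[[TRASH]], 0L)
})

test_that("cluster counts partition the peptides and ignore input order", {
  set.seed(13)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    peps <- unique(random_test_peptides(n, 13, 21))
    alleles <- c("DRB1*11:01", "DRB3*02:02", "DRB5*01:01")
    ranks <- matrix(runif(length(peps) * 3, 0, 100), ncol = 3,
                    dimnames = list(peps, alleles))
    rt <- rank_table(rank_df(ranks))
    res <- assign_peptides(rt, deconv_config("II"))
    expect_equal(sum(res$cluster_counts), length(peps))

    shuffled <- rank_table(rank_df(ranks)[sample(nrow(rt)), ])
    res2 <- assign_peptides(shuffled, deconv_config("II"))
    o1 <- lex_order_test(res$assignments$peptide)
    o2 <- lex_order_test(res2$assignments$peptide)
    expect_equal(res$assignments$assigned[o1], res2$assignments$assigned[o2])
  }
})

test_that("raising the trash threshold never moves peptides into trash", {
  set.seed(17)
  peps <- unique(random_test_peptides(60, 13, 21))
  ranks <- matrix(runif(length(peps) * 2, 0, 100), ncol = 2,
                  dimnames = list(peps, c("DRB1*04:01", "DRB4*01:03")))
  rt <- rank_table(rank_df(ranks))
  prev_trash <- NULL
  for (thr in c(5, 20, 50, 101)) {
    res <- assign_peptides(rt, deconv_config("II", trash_threshold = thr))
    trash_set <- res$assignments$peptide[res$assignments$assigned == TRASH]
    if (!is.null(prev_trash)) expect_true(all(trash_set %in% prev_trash))
    prev_trash <- trash_set
  }
})

test_that("the class I prefilter removes predicted class I binders", {
  peps <- c("AAKMNPQRSTVWY", "CCKMNPQRSTVWY", "DDKMNPQRSTVWY")
  ci_ranks <- matrix(c(1.5, 10, 2.0,
                       80, 50, 60),
                     ncol = 2,
                     dimnames = list(peps, c("HLA-A*01:01", "HLA-B*15:01")))
  ci <- rank_table(rank_df(ci_ranks))
  out <- exclude_class_i_binders(peps, ci, threshold = 2)
  expect_equal(sort(out$excluded), sort(peps[c(1, 3)]))  # best rank <= 2
  expect_equal(out$retained, peps[2])

  expect_error(exclude_class_i_binders(c(peps, "EEKMNPQRSTVWY"), ci),
               "missing class I predictions")
})

test_that("contribution percentages match worked examples with half-up rounding", {
  # DR51-type samples: secondary DR contributions of 50% and 64% of the
  # total DR peptidome
  s9013 <- contribution_summary(c("DRB1*15:01" = 1501, "DRB5*01:01" = 1490))
  expect_equal(
    s9013$percent_total_display[s9013$cluster == "DRB5*01:01"], 50
  )
  s9084 <- contribution_summary(c("DRB1*16:01" = 570, "DRB5*02:02" = 1010))
  expect_equal(
    s9084$percent_total_display[s9084$cluster == "DRB5*02:02"], 64
  )
  # null-allele sample: 53 of 2597 DR-annotated peptides (trash excluded
  # from the assigned denominator)
  s9052 <- contribution_summary(
    c("DRB1*07:01" = 2544, "DRB4*01:03N" = 53, TRASH = 121)
  )
  expect_equal(
    s9052$percent_assigned_display[s9052$cluster == "DRB4*01:03N"], 2
  )
  expect_true(is.na(s9052$percent_assigned[s9052$cluster == TRASH]))

  # all-trash: allele percentages of total are 0, assigned denominators NA
  all_trash <- contribution_summary(c("DRB1*01:01" = 0, TRASH = 10))
  expect_equal(all_trash$percent_total[all_trash$cluster == TRASH], 100)
  expect_equal(all_trash$percent_total[all_trash$cluster == "DRB1*01:01"], 0)
  expect_true(is.na(
    all_trash$percent_assigned[all_trash$cluster == "DRB1*01:01"]
  ))
})

test_that("repertoire overlap classifies binder combinations at 1% rank", {
  peps <- c("AAKMNPQRSTVWY", "CCKMNPQRSTVWY", "DDKMNPQRSTVWY",
            "EEKMNPQRSTVWY")
  ranks <- matrix(c(0.5, 0.5, 2, 2,
                    0.5, 2, 0.5, 2),
                  ncol = 2,
                  dimnames = list(peps, c("DRB1*15:01", "DRB5*01:01")))
  rt <- rank_table(rank_df(ranks))
  ov <- repertoire_overlap(rt, "DRB1*15:01", "DRB5*01:01")
  expect_equal(ov$overlap, 1)
  expect_equal(ov$unique_a, 1)
  expect_equal(ov$unique_b, 1)
  expect_equal(ov$neither, 1)
  expect_equal(ov$peptides_overlap, peps[1])
  expect_error(repertoire_overlap(rt, "DRB1*15:01", "DQB1*06:02"),
               "allele not in rank table")
})

test_that("the pipeline logs every filtering stage and composes the steps", {
  models <- list("DRB1*13:01" = ala_model("DRB1*13:01"),
                 "DRB3*02:02" = zero_model("DRB3*02:02"))
  peps <- c(strrep("A", 15), strrep("A", 15), strrep("C", 15),
            strrep("G", 10), "AAKMNPQRSTVWYAC")
  samp <- peptidome_sample("cb6b", peps, names(models), "II")
  res <- deconvolute(samp, models = models,
                     config = deconv_config("II"),
                     calibration_seed = 9L, n_bg = 1000L)
  expect_equal(res$log$n_length_removed, 1L)     # the 10-mer
  expect_equal(res$log$n_duplicates_removed, 1L)
  expect_equal(sum(res$cluster_counts), 3L)

  # class I prefilter drops peptides before class II assignment
  ci_ranks <- matrix(c(1, 50, 50), ncol = 1,
                     dimnames = list(c(strrep("A", 15), strrep("C", 15),
                                       "AAKMNPQRSTVWYAC"),
                                     "HLA-A*01:01"))
  res_ci <- deconvolute(samp, models = models,
                        config = deconv_config("II"),
                        class_i_rank_table = rank_table(rank_df(ci_ranks)),
                        calibration_seed = 9L, n_bg = 1000L)
  expect_equal(res_ci$log$n_class_i_excluded, 1L)
  expect_equal(sum(res_ci$cluster_counts), 2L)
})
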