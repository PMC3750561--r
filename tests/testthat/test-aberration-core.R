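test_that("rank_genes sorts descending with deterministic tie-breaks", {
  expect_identical(rank_genes(c(A = 2.0, B = -1.0, C = 0.5)),
                   c("A", "C", "B"))
  expect_identical(rank_genes(c(B = 1.0, A = 1.0)), c("A", "B"))
  expect_identical(rank_genes(c(A = NA, B = 0, C = -1)), c("B", "C"))
  expect_error(rank_genes(c(A = NA, B = NA)), "2 genes")
})

test_that("enrichment AUC matches hand-derived values and edge geometries", {
  r <- ranked_letters(6)
  expect_equal(enrichment_auc(r, c("A", "B"))$auc, 1.0)
  expect_equal(enrichment_auc(r, c("E", "F"))$auc, 0.0)
  expect_equal(enrichment_auc(r, c("A", "C"))$auc, 0.875)
  expect_equal(enrichment_auc(r, c("A", "C"))$m, 2)
  # members absent from the list don't count toward m
  expect_equal(enrichment_auc(r, c("A", "C", "ZZZ"))$m, 2)
  expect_error(enrichment_auc(r, c("X", "Y")), "1 <= m < n")
  expect_error(enrichment_auc(r, r), "1 <= m < n")
})

test_that("depletion AUC is the reversed walk and complements enrichment", {
  r <- ranked_letters(6)
  expect_equal(depletion_auc(r, c("A", "B"))$auc, 0.0)
  expect_equal(depletion_auc(r, c("E", "F"))$auc, 1.0)
  expect_equal(depletion_auc(r, c("A", "C"))$auc, 0.125)
  # strict-order complement, property over random subsets
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(3:12, 1)
    m <- sample(seq_len(n - 1), 1)
    members <- sample(LETTERS[1:n], m)
    expect_equal(enrichment_auc(LETTERS[1:n], members)$auc +
                   depletion_auc(LETTERS[1:n], members)$auc, 1)
  }
})

test_that("AUC equals the pairwise-concordance oracle on exhaustive small cases", {
  for (n in 2:6) {
    r <- ranked_letters(n)
    for (m in seq_len(n - 1)) {
      subsets <- utils::combn(n, m)
      for (j in seq_len(ncol(subsets))) {
        pos <- subsets[, j]
        expect_equal(enrichment_auc(r, r[pos])$auc,
                     oracle_concordance_auc(pos, n))
      }
    }
  }
})

test_that("exact null tail probabilities match subset enumeration", {
  expect_equal(exact_null_pvalue(1.0, 4, 2), 1 / 6)
  expect_equal(exact_null_pvalue(0.5, 4, 2), 4 / 6)
  expect_equal(exact_null_pvalue(0.0, 7, 3), 1.0)
  expect_equal(exact_null_pvalue(1.0, 5, 2), 1 / 10)
  expect_error(exact_null_pvalue(0.5, 500, 10), "1e6")
})

test_that("permutation p-values converge to the exact null and hit the bounds", {
  # maximum AUC at (5, 2): exact tail 1/10; average over independent
  # streams so the Monte-Carlo band is tight
  p_bar <- mean(vapply(1:10, function(s)
    permutation_pvalue(1.0, n = 5, m = 2, B = 5000, seed = s),
    numeric(1)))
  expect_lt(abs(p_bar - 0.1),
            4 * sqrt(0.1 * 0.9 / (5000 * 10)) + 2 / 5001)
  # nothing beats AUC 0: p = 1 exactly
  expect_equal(permutation_pvalue(0.0, n = 8, m = 3, B = 200, seed = 1), 1)
  # top of a long list: add-one floor
  expect_equal(permutation_pvalue(1.0, n = 5000, m = 5, B = 1000, seed = 2),
               1 / 1001)
  # deterministic given seed
  expect_identical(permutation_pvalue(0.7, 50, 5, B = 500, seed = 33),
                   permutation_pvalue(0.7, 50, 5, B = 500, seed = 33))
})

test_that("combine_scores signs and ties follow the log2 convention", {
  expect_equal(combine_scores(0.001, 0.9), log2(0.001))
  expect_equal(combine_scores(0.9, 0.001), -log2(0.001))
  expect_equal(combine_scores(0.5, 0.5), -1.0)    # tie -> enrichment
  expect_error(combine_scores(0, 0.5), "positive")
})

scored_fixture <- function(B = 300, seed = 5) {
  set.seed(2)
  n_genes <- 120
  genes <- sprintf("G%03d", 1:n_genes)
  values <- matrix(rnorm(n_genes * 6), nrow = n_genes,
                   dimnames = list(genes, paste0("s", 1:6)))
  coll <- tiny_collection(list(TOP = genes[1:10], MID = genes[51:70],
                               ODD = genes[seq(1, 40, by = 2)]))
  list(values = values, coll = coll, B = B, seed = seed)
}

test_that("score_cohort composes ranking, AUC and permutation confidence", {
  n_genes <- 200
  genes <- sprintf("G%03d", 1:n_genes)
  v <- seq(n_genes, 1)                  # strictly decreasing values
  values <- matrix(v, ncol = 1, dimnames = list(genes, "s1"))
  coll <- tiny_collection(list(TOPSET = genes[1:12]))
  pr <- score_cohort(values, coll, B = 1000, seed = 4)
  expect_equal(pr$auc_enrichment["TOPSET", "s1"], 1)
  expect_equal(pr$p_enrichment["TOPSET", "s1"], 1 / 1001)
  expect_equal(pr$combined["TOPSET", "s1"], log2(1 / 1001))
  expect_equal(pr$m["TOPSET", "s1"], 12)

  bad <- tiny_collection(list(ABSENT = c("NOPE1", "NOPE2", "NOPE3")))
  expect_error(score_cohort(values, bad, B = 100, seed = 1), "effective size")
})

test_that("score_cohort is deterministic and order/transform invariant", {
  fx <- scored_fixture()
  a <- score_cohort(fx$values, fx$coll, B = fx$B, seed = fx$seed)
  b <- score_cohort(fx$values, fx$coll, B = fx$B, seed = fx$seed)
  expect_identical(a, b)

  # sample column permutation: identical up to relabeling
  perm <- c(4, 1, 6, 2, 3, 5)
  c2 <- score_cohort(fx$values[, perm], fx$coll, B = fx$B, seed = fx$seed)
  expect_equal(c2$combined[, colnames(a$combined)], a$combined)

  # strictly monotone per-sample transform leaves everything unchanged
  warped <- fx$values
  warped[, 2] <- exp(warped[, 2]); warped[, 5] <- warped[, 5]^3 + 2
  c3 <- score_cohort(warped, fx$coll, B = fx$B, seed = fx$seed)
  expect_equal(c3$combined, a$combined)

  # different master seed gives a different (but valid) answer
  c4 <- score_cohort(fx$values, fx$coll, B = fx$B, seed = fx$seed + 1)
  expect_false(identical(c4$combined, a$combined))
})

test_that("profile matrices respect the score bounds and sign convention", {
  fx <- scored_fixture()
  pr <- score_cohort(fx$values, fx$coll, B = fx$B, seed = fx$seed)
  expect_true(all(pr$p_enrichment >= 1 / (fx$B + 1) & pr$p_enrichment <= 1))
  expect_true(all(pr$p_depletion >= 1 / (fx$B + 1) & pr$p_depletion <= 1))
  enr_dom <- pr$p_enrichment <= pr$p_depletion
  expect_true(all(pr$combined[enr_dom] <= 0))
  expect_true(all(pr$combined[!enr_dom] >= 0))
  expect_equal(pr$combined[enr_dom], log2(pr$p_enrichment)[enr_dom])
  expect_equal(pr$combined[!enr_dom], -log2(pr$p_depletion)[!enr_dom])
})

test_that("write_profiles emits parseable TSV matrices and a manifest", {
  fx <- scored_fixture(B = 120)
  pr <- score_cohort(fx$values, fx$coll, B = fx$B, seed = 1)
  dir <- withr::local_tempdir()
  write_profiles(pr, dir)
  comb <- utils::read.delim(file.path(dir, "combined.tsv"),
                            check.names = FALSE)
  expect_equal(comb$pathway, rownames(pr$combined))
  expect_equal(as.matrix(comb[, -1]), pr$combined,
               ignore_attr = TRUE)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$B, 120)
})
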