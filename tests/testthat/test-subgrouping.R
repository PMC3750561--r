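test_that("aberration calls are mutually exclusive with the smaller score winning", {
  pe <- matrix(c(0.01, 0.2, 0.04, 0.5), 2, 2,
               dimnames = list(c("P1", "P2"), c("s1", "s2")))
  pd <- matrix(c(0.8, 0.3, 0.03, 0.5), 2, 2, dimnames = dimnames(pe))
  calls <- call_aberrations(fake_profiles(pe, pd), alpha = 0.05)
  expect_equal(calls$calls["P1", "s1"], "E")
  expect_equal(calls$calls["P2", "s1"], "N")
  expect_equal(calls$calls["P1", "s2"], "D")   # both significant, dep smaller
  expect_equal(calls$calls["P2", "s2"], "N")
  expect_true(all(calls$calls %in% c("E", "D", "N")))
  expect_equal(calls$counts$enriched, c(1, 0))
})

test_that("alpha boundary is strict and calls partition all pairs (property)", {
  set.seed(21)
  pe <- matrix(runif(300), 30, 10,
               dimnames = list(paste0("P", 1:30), paste0("s", 1:10)))
  pd <- matrix(runif(300), 30, 10, dimnames = dimnames(pe))
  calls <- call_aberrations(fake_profiles(pe, pd), alpha = 0.05)
  expect_equal(sum(calls$calls == "E") + sum(calls$calls == "D") +
                 sum(calls$calls == "N"), 300)
  expect_true(all((calls$calls == "E") == (pe < 0.05 & pe <= pd)))
  expect_true(all((calls$calls == "D") == (pd < 0.05 & pd < pe)))
})

test_that("aberration frequencies count enriched and depleted fractions", {
  calls_mat <- matrix(c("E", "E", "N", "D"), nrow = 1,
                      dimnames = list("P1", paste0("s", 1:4)))
  calls <- structure(list(calls = calls_mat, alpha = 0.05),
                     class = "aberration_calls")
  fr <- aberration_frequencies(calls, setNames(rep("g1", 4), paste0("s", 1:4)))
  expect_equal(fr$enr_freq["P1", "g1"], 0.5)
  expect_equal(fr$dep_freq["P1", "g1"], 0.25)
  expect_equal(unname(fr$group_size["g1"]), 4L)

  # all-neutral group and a singleton enriched group
  calls2 <- structure(list(calls = matrix(c("N", "N", "E"), nrow = 1,
                                          dimnames = list("P1", c("a", "b", "c"))),
                           alpha = 0.05), class = "aberration_calls")
  fr2 <- aberration_frequencies(calls2, c(a = "g1", b = "g1", c = "g2"))
  expect_equal(unname(fr2$enr_freq["P1", ]), c(0, 1))
  expect_equal(unname(fr2$dep_freq["P1", ]), c(0, 0))
  expect_error(aberration_frequencies(calls2, c(a = "g1", b = "g1")),
               "missing sample")
  # invariant: enr + dep <= 1 per pathway/group
  expect_true(all(fr2$enr_freq + fr2$dep_freq <= 1))
})

test_that("Ward clustering merges the closest 1-D pair first, height 0 for twins", {
  feats <- matrix(c(0, 1, 5), ncol = 1,
                  dimnames = list(c("a", "b", "c"), "f"))
  tree <- hierarchical_cluster(feats)
  expect_identical(sort(tree$merge[1, ]), c(-2L, -1L))   # {0, 1} first

  twins <- matrix(c(3, 3, 9), ncol = 1,
                  dimnames = list(c("a", "b", "c"), "f"))
  expect_equal(hierarchical_cluster(twins)$height[1], 0)
  expect_error(hierarchical_cluster(feats[1, , drop = FALSE]), "2 items")
})

test_that("clustering is invariant to item order up to relabeling", {
  set.seed(8)
  feats <- matrix(rnorm(40), nrow = 10,
                  dimnames = list(paste0("it", 1:10), paste0("f", 1:4)))
  t1 <- hierarchical_cluster(feats)
  perm <- sample(10)
  t2 <- hierarchical_cluster(feats[perm, ])
  c1 <- as.matrix(stats::cophenetic(t1))
  c2 <- as.matrix(stats::cophenetic(t2))[rownames(c1), colnames(c1)]
  expect_equal(c1, c2)
})

two_blob_tree <- function(n_per = 30, sep = 10, sd = 0.5, seed = 14) {
  set.seed(seed)
  feats <- rbind(matrix(rnorm(n_per * 2, 0, sd), ncol = 2),
                 matrix(rnorm(n_per * 2, sep, sd), ncol = 2))
  rownames(feats) <- sprintf("s%02d", seq_len(2 * n_per))
  list(feats = feats, tree = hierarchical_cluster(feats))
}

test_that("well-separated blobs are recovered as subgroups within bounds", {
  tb <- two_blob_tree()
  asg <- extract_subgroups(tb$tree, min_size = 20, max_size = 30)
  expect_equal(length(asg$sizes), 2)
  expect_setequal(unname(asg$sizes), c(30L, 30L))
  # each recovered subgroup is exactly one planted blob
  blob <- rep(1:2, each = 30)
  expect_equal(length(unique(asg$assignment[blob == 1])), 1)
  expect_equal(length(unique(asg$assignment[blob == 2])), 1)
})

test_that("k_override cuts to exactly k and matches the standard tree cut", {
  tb <- two_blob_tree()
  for (k in c(2, 5, 12)) {
    asg <- extract_subgroups(tb$tree, k_override = k)
    expect_equal(length(asg$sizes), k)
    expect_equal(unname(asg$assignment), unname(stats::cutree(tb$tree, k = k)))
  }
})

test_that("subgroup extraction always partitions the samples", {
  # cannot split below the bounds: single subgroup
  set.seed(5)
  feats <- matrix(rnorm(25 * 3), nrow = 25,
                  dimnames = list(sprintf("s%02d", 1:25), paste0("f", 1:3)))
  tree <- hierarchical_cluster(feats)
  asg <- extract_subgroups(tree, min_size = 20, max_size = 30)
  expect_equal(unname(asg$sizes), 25L)

  # forced splits with stragglers still assign every sample exactly once
  set.seed(6)
  feats2 <- rbind(matrix(rnorm(32 * 2, 0, 0.5), ncol = 2),
                  matrix(rnorm(3 * 2, 8, 0.5), ncol = 2),
                  matrix(rnorm(28 * 2, 16, 0.5), ncol = 2))
  rownames(feats2) <- sprintf("s%02d", 1:63)
  tree2 <- hierarchical_cluster(feats2)
  asg2 <- extract_subgroups(tree2, min_size = 10, max_size = 30)
  expect_equal(sum(asg2$sizes), 63L)
  expect_equal(sort(unique(unname(asg2$assignment))),
               seq_along(asg2$sizes))
  expect_error(extract_subgroups(tree2, min_size = 100, max_size = 200),
               "exceeds")
})

test_that("cross-group features concatenate frequencies and cluster twins at 0", {
  mk_fp <- function(enr, dep, groups) {
    structure(list(enr_freq = matrix(enr, nrow = 3,
                                     dimnames = list(paste0("P", 1:3), groups)),
                   dep_freq = matrix(dep, nrow = 3,
                                     dimnames = list(paste0("P", 1:3), groups)),
                   group_size = setNames(rep(5L, length(groups)), groups)),
              class = "frequency_profiles")
  }
  fp <- mk_fp(c(1, 0, 0.4, 1, 0, 0.4), c(0, 0.6, 0.2, 0, 0.6, 0.2),
              c("A.1", "B.1"))
  feats <- cross_group_features(fp)
  expect_equal(dim(feats), c(2L, 6L))
  expect_equal(unname(feats["A.1", ]), c(1, 0, 0.4, 0, 0.6, 0.2))
  # identical frequency patterns from different cohorts merge at height 0
  tree <- hierarchical_cluster(feats)
  expect_equal(tree$height[1], 0)

  fp_bad <- mk_fp(rep(0, 6), rep(0, 6), c("C.1", "C.2"))
  rownames(fp_bad$enr_freq) <- paste0("Q", 1:3)
  rownames(fp_bad$dep_freq) <- paste0("Q", 1:3)
  expect_error(cross_group_features(list(fp, fp_bad)), "pathway lists differ")
})

test_that("newick export round-trips through ape with positive branch lengths", {
  tb <- two_blob_tree(n_per = 5)
  nwk <- write_newick(tb$tree)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, rownames(tb$feats))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tb$tree, path)
  expect_true(file.exists(path))
})
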