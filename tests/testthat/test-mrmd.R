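test_that("Pearson correlation matches the textbook formula and edge rules", {
  expect_equal(pearson_correlation(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pearson_correlation(c(1, 2, 3), c(3, 2, 1)), -1)
  x <- c(1, 2, 3, 4); y <- c(1, 3, 2, 4)
  expect_equal(pearson_correlation(x, y), naive_pcc(x, y), tolerance = 1e-14)
  expect_warning(r0 <- pearson_correlation(c(1, 1, 1), c(1, 2, 3)),
                 "zero-variance")
  expect_equal(r0, 0)
  expect_error(pearson_correlation(1:3, 1:4), "equal length")
  expect_error(pearson_correlation(1, 2), "at least 2")
})

test_that("MR scores: relevance magnitude with zero-variance rule", {
  labels <- c(1L, 0L, 1L, 0L, 1L)
  x <- cbind(same = as.numeric(labels),
             anti = 1 - as.numeric(labels),
             const = rep(2, 5))
  rownames(x) <- paste0("s", 1:5)
  mr <- mr_scores(feature_matrix(x, labels))
  expect_equal(unname(mr), c(1, 1, 0))
  expect_error(mr_scores(feature_matrix(x)), "labeled")
})

test_that("MD scores: hand-computed distances, duplicates, scaling", {
  x <- cbind(a = c(0, 0), b = c(3, 4))
  rownames(x) <- c("s1", "s2")
  fm <- feature_matrix(x, c(1L, 0L))
  expect_equal(unname(md_scores(fm, scale = "none")), c(5, 5))

  # duplicated column contributes zero distance to its twin
  x3 <- cbind(x, a2 = c(0, 0))
  md <- md_scores(feature_matrix(x3, c(1L, 0L)), scale = "none")
  expect_equal(unname(md[["a"]]), 5 / 2)   # (0 + 5)/2
  expect_equal(unname(md[["a2"]]), 5 / 2)

  # all-identical features: MD uniformly zero
  xid <- matrix(1:4, 4, 3, dimnames = list(NULL, c("u", "v", "w")))
  expect_equal(unname(md_scores(feature_matrix(xid), scale = "none")),
               rep(0, 3))
  expect_error(md_scores(feature_matrix(x[, 1, drop = FALSE])), "2 features")
})

test_that("MR/MD/score match a naive double-loop oracle to 1e-12", {
  withr::with_seed(2024, {
    for (i in 1:20) {
      x <- matrix(runif(10 * 8), 10, 8,
                  dimnames = list(NULL, paste0("f", 1:8)))
      labels <- c(rep(1L, 5), rep(0L, 5))[sample(10)]
      fm <- feature_matrix(x, labels)
      for (sc in c("minmax", "none")) {
        oracle <- naive_mrmd(x, labels, scale = sc == "minmax")
        tab <- mrmd_rank(fm, scale = sc)
        ord <- match(colnames(x), tab$name)
        expect_equal(tab$MR[ord], oracle$MR, tolerance = 1e-12)
        expect_equal(tab$MD[ord], oracle$MD, tolerance = 1e-12)
        expect_equal(tab$score[ord], oracle$score, tolerance = 1e-12)
      }
      expect_equal(sort(tab$rank), 1:8)
    }
  })
})

test_that("ranking is stable under ties and invariant to row permutation", {
  x <- cbind(f1 = c(0, 1, 0, 1), f2 = c(0, 1, 0, 1),  # identical twins
             f3 = c(0.9, 0.1, 0.8, 0.2))
  rownames(x) <- paste0("s", 1:4)
  fm <- feature_matrix(x, c(0L, 1L, 0L, 1L))
  tab <- mrmd_rank(fm)
  # identical columns tie exactly; original column order breaks the tie
  r1 <- tab$rank[tab$name == "f1"]
  r2 <- tab$rank[tab$name == "f2"]
  expect_equal(r2, r1 + 1)

  # permuting samples leaves every score unchanged
  perm <- c(3, 1, 4, 2)
  tab_p <- mrmd_rank(feature_matrix(x[perm, ], fm$labels[perm]))
  expect_equal(tab_p[order(tab_p$name), c("MR", "MD", "score")],
               tab[order(tab$name), c("MR", "MD", "score")],
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("MR is invariant to increasing affine transforms of a feature", {
  fm <- toy_feature_matrix()
  mr <- mr_scores(fm)
  x2 <- fm$x
  x2[, "sig1"] <- 3 * x2[, "sig1"] + 7
  mr2 <- mr_scores(feature_matrix(x2, fm$labels))
  expect_equal(mr2, mr, tolerance = 1e-12)
})

test_that("planted informative features outrank noise features on average", {
  fm <- toy_feature_matrix(n_pos = 30, n_neg = 30, n_noise = 10, seed = 88)
  tab <- mrmd_rank(fm)
  sig_rank <- tab$rank[grepl("^sig", tab$name)]
  noise_rank <- tab$rank[grepl("^noise", tab$name)]
  expect_lt(mean(sig_rank), mean(noise_rank))
})

test_that("incremental selection applies the max-accuracy, fewest-features rule", {
  fm <- toy_feature_matrix(n_pos = 25, n_neg = 25, n_noise = 6, seed = 11)
  tab <- mrmd_rank(fm)
  sel <- incremental_select(fm, tab, folds = 3, step = 1, trees = 60,
                            seed = 13)
  expect_equal(sel$sizes, 1:8)
  expect_equal(sel$chosen_accuracy, max(sel$accuracy))
  expect_equal(sel$chosen_size,
               min(sel$sizes[sel$accuracy == sel$chosen_accuracy]))
  expect_equal(sel$chosen_features, tab$name[seq_len(sel$chosen_size)])
  # the curve maximum includes the full set, so the chosen accuracy can
  # never fall below the full-feature accuracy on the same folds
  expect_gte(sel$chosen_accuracy, sel$accuracy[length(sel$accuracy)])

  # step coarsening still ends at the full size
  sel10 <- incremental_select(fm, tab, folds = 3, step = 5, trees = 60,
                              seed = 13)
  expect_equal(sel10$sizes, c(5, 8))

  expect_error(incremental_select(fm, tab, folds = 3, step = 0), "step")
  expect_error(incremental_select(fm, tab[-1, ], folds = 3), "exactly")
  expect_error(incremental_select(fm, tab, folds = 30), "fewer samples")
})
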