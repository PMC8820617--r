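make_candidates <- function(rf, svm) {
  tibble::tibble(
    id = sprintf("c%03d", seq_along(rf)),
    rf_positive = rf, svm_positive = svm,
    consensus = rf & svm
  )
}

random_profiles <- function(ids, lo = -12, hi = -4) {
  out <- tibble::tibble(id = ids)
  for (cf in cyp_conformations()) out[[cf]] <- runif(length(ids), lo, hi)
  out
}

test_that("consensus is the intersection of the two models' positives", {
  fx <- make_fixture(40, 10, effect = 3, seed = 71)
  g <- default_hyper_grid(15, ntree = 50, mtry = 3, cost = 2, sigma_mult = 1)
  rf <- train_rf(fx$matrix, fx$labels, g, cv_control(5, 1), seed = 4)
  st <- standardize(fx$matrix)
  svm <- train_svm_rbf(st$matrix, fx$labels, st$params, g, cv_control(5, 1),
                       seed = 4)
  cand <- consensus_predict(rf, svm, fx$matrix)
  rf_pos <- cand$id[cand$rf_positive]
  svm_pos <- cand$id[cand$svm_positive]
  expect_setequal(cand$id[cand$consensus], intersect(rf_pos, svm_pos))
  expect_equal(cand$consensus, cand$rf_positive & cand$svm_positive)
})

test_that("prioritization is the conjunction of consensus and the IE filter", {
  set.seed(15)
  cand <- make_candidates(rf = runif(50) < 0.6, svm = runif(50) < 0.6)
  prof <- random_profiles(cand$id, lo = -10, hi = -7)
  out <- prioritize(cand, prof, threshold = -8.5)
  # brute-force row-by-row oracle
  for (i in seq_len(50)) {
    scores <- as.numeric(prof[prof$id == out$id[i], cyp_conformations()])
    expect_identical(out$prioritized[i],
                     out$consensus[i] && all(scores < -8.5))
  }
  # non-consensus never prioritized even with excellent energies
  strong <- random_profiles(cand$id, lo = -12, hi = -11.5)
  out2 <- prioritize(cand, strong)
  expect_true(all(!out2$prioritized[!out2$consensus]))

  # permutation invariance of the prioritized set
  perm <- sample(50)
  out3 <- prioritize(cand[perm, ], prof)
  expect_setequal(out3$id[out3$prioritized], out$id[out$prioritized])

  # raising the threshold toward zero never shrinks the set
  sets <- lapply(c(-9, -8.5, -8, -7.5), function(t) {
    o <- prioritize(cand, prof, threshold = t)
    o$id[o$prioritized]
  })
  for (k in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[k]] %in% sets[[k + 1]]))
  }

  # a consensus candidate without a complete profile is an error
  prof_missing <- prof[-which(prof$id == cand$id[cand$consensus][1]), ]
  expect_error(prioritize(cand, prof_missing), "no complete IE profile")
})

test_that("two-stage clustering keys then paths, re-clustering only centroids", {
  hits <- head(fixture_valid(), 25)
  cl <- cluster_hits(hits, stage1_cutoff = 0.80, stage2_cutoff = 0.70)
  expect_setequal(cl$stage1$id, hits$id)
  # stage 2 clusters exactly the stage-1 centroids
  expect_setequal(cl$stage2$id, unique(cl$stage1$centroid_id))
  expect_equal(attr(cl$stage1, "fingerprint"), "maccs")
  expect_equal(attr(cl$stage2, "fingerprint"), "fp2")
  # every hit maps to a stage-2 cluster through its centroid
  expect_false(any(is.na(cl$hit_map$stage2_cluster)))

  # all-identical hits collapse to one cluster at both stages
  same <- tibble::tibble(id = c("x1", "x2", "x3"),
                         smiles = rep("CC(=O)Oc1ccccc1C(=O)O", 3))
  cl2 <- cluster_hits(same)
  expect_equal(max(cl2$stage1$cluster_id), 1L)
  expect_equal(max(cl2$stage2$cluster_id), 1L)
  expect_error(cluster_hits(same[0, ]), "empty")
})

test_that("candidate selection takes centroids plus max-min diverse extras", {
  hits <- head(fixture_valid(), 24)
  cl <- cluster_hits(hits, stage1_cutoff = 0.99, stage2_cutoff = 0.99)
  # near-1.0 cutoffs make every molecule its own cluster: one pick each
  picks <- select_candidates(cl, hits)
  expect_equal(nrow(picks), nrow(cl$stage2))
  expect_true(all(picks$pick_rank == 1L))

  # force one big stage-2 cluster: extra picks by ceiling(size / 15)
  cl_all <- cluster_hits(hits, stage1_cutoff = 0.99, stage2_cutoff = 0.01)
  expect_equal(max(cl_all$stage2$cluster_id), 1L)
  n <- nrow(cl_all$stage2)
  picks2 <- select_candidates(cl_all, hits)
  expect_equal(nrow(picks2), ceiling(n / 15))
  # centroid is always the first pick
  expect_equal(picks2$id[1], unique(cl_all$stage2$centroid_id))
  # extras disabled
  picks3 <- select_candidates(cl_all, hits, extra_min_size = Inf)
  expect_equal(nrow(picks3), 1L)
  # reference sizes: 18 -> 2 picks, 37 -> 3 picks
  expect_equal(ceiling(18 / 15), 2)
  expect_equal(ceiling(37 / 15), 3)
})

test_that("screen_library runs the cascade with monotone counts and exclusions", {
  fx <- make_fixture(40, 10, effect = 3, seed = 81)
  mols <- fixture_valid()
  # give each fixture row a real structure (recycled) for clustering
  lib <- tibble::tibble(
    id = fx$matrix$id,
    smiles = rep_len(mols$smiles, nrow(fx$matrix))
  )
  prof <- gen_ie_profiles(fx$matrix$id, fx$labels,
                          fixture_spec(ie_active_mean = -10, ie_sd = 0.5, seed = 81))
  g <- default_hyper_grid(15, ntree = 50, mtry = 3, cost = 2, sigma_mult = 1)
  rf <- train_rf(fx$matrix, fx$labels, g, cv_control(5, 1), seed = 4)
  st <- standardize(fx$matrix)
  svm <- train_svm_rbf(st$matrix, fx$labels, st$params, g, cv_control(5, 1),
                       seed = 4)
  rep <- screen_library(lib, fx$matrix, prof, rf, svm)
  counts <- setNames(rep$counts$n, rep$counts$stage)
  expect_lte(counts["consensus"], counts["library"])
  expect_lte(counts["prioritized"], counts["consensus"])
  expect_gte(counts["prioritized"], 1)
  expect_true(all(rep$selected$id %in% rep$candidates$id[rep$candidates$prioritized]))

  # exclusion list removes molecules before the cascade
  excl <- lib$id[1:5]
  rep2 <- screen_library(lib, fx$matrix, prof, rf, svm, exclude = excl)
  expect_equal(rep2$counts$n[1], nrow(lib) - 5L)
  expect_false(any(excl %in% rep2$candidates$id))

  # report writer produces the three delimited artifacts
  dir <- tempfile()
  write_screen_report(rep, dir)
  expect_true(all(file.exists(file.path(dir, c("candidates.csv",
                                               "cascade_counts.csv",
                                               "selected.csv")))))
  expect_s3_class(glance(rep), "tbl_df")
})
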