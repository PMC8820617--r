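write_activity_csv <- function(df, path = tempfile(fileext = ".csv")) {
  readr::write_csv(df, path)
  path
}

test_that("activity tables parse with rejects reported, never dropped", {
  path <- write_activity_csv(tibble::tibble(
    id = c("a", "b", "c"),
    smiles = c("CCO", "c1ccccc1", "CC(=O)O"),
    source = "pubchem", ac50_um = c(5, NA, 20),
    pct_inhib_at_50um = c(NA, 4, NA)
  ))
  res <- parse_activity_table(path)
  expect_equal(nrow(res$records), 3L)
  expect_equal(nrow(res$rejects), 0L)

  path2 <- write_activity_csv(tibble::tibble(
    id = c("a", "bad"), smiles = c("CCO", "not_a_molecule"),
    ac50_um = c(5, 5), pct_inhib_at_50um = NA_real_
  ))
  res2 <- parse_activity_table(path2)
  expect_equal(res2$rejects$id, "bad")
  expect_equal(res2$rejects$reason, "smiles_parse")

  path3 <- write_activity_csv(tibble::tibble(id = "a", ac50_um = 5))
  expect_error(parse_activity_table(path3), "schema error")
  path4 <- write_activity_csv(tibble::tibble(id = character(),
                                             smiles = character()))
  expect_error(parse_activity_table(path4), "empty")
})

test_that("labeling thresholds: AC50 <= 10 uM inclusive, %inhib < 10 exclusive", {
  recs <- tibble::tibble(
    id = c("in1", "in_boundary", "noninhib", "ambig"),
    ac50_um = c(5, 10, NA, 25),
    pct_inhib_at_50um = c(NA, NA, 8, 40)
  )
  out <- assign_labels(recs)
  expect_equal(out$label,
               c("inhibitor", "inhibitor", "non_inhibitor", "ambiguous"))

  # a record matching both rules is contradictory evidence
  expect_error(
    assign_labels(tibble::tibble(id = "x", ac50_um = 5, pct_inhib_at_50um = 2)),
    "conflict"
  )
  expect_error(
    assign_labels(tibble::tibble(id = "x", ac50_um = NA_real_,
                                 pct_inhib_at_50um = NA_real_)),
    "without any activity"
  )
})

test_that("labeling is total over random activity evidence", {
  set.seed(2022)
  n <- 10000
  recs <- tibble::tibble(
    id = as.character(seq_len(n)),
    ac50_um = ifelse(runif(n) < 0.5, NA, runif(n, 0.01, 100)),
    pct_inhib_at_50um = ifelse(runif(n) < 0.5, NA, runif(n, 0, 100))
  )
  recs <- recs[!(is.na(recs$ac50_um) & is.na(recs$pct_inhib_at_50um)), ]
  # drop the genuinely contradictory ones; the rest must all be labeled
  conflict <- !is.na(recs$ac50_um) & recs$ac50_um <= 10 &
    !is.na(recs$pct_inhib_at_50um) & recs$pct_inhib_at_50um < 10
  out <- assign_labels(recs[!conflict, ])
  expect_true(all(out$label %in% c("inhibitor", "non_inhibitor", "ambiguous")))
  expect_false(any(is.na(out$label)))
})

test_that("soft drug-like filter keeps in-bounds molecules and lists every violation", {
  valid <- fixture_valid()
  res <- soft_druglike_filter(valid)
  expect_true("aspirin" %in% res$kept$id)   # MW 180, logP ~1: inside all bounds
  expect_true(all(lengths(res$kept$filter_flags) == 0L))
  poly <- res$rejects[res$rejects$id == "big_polyether", ]
  expect_true(all(c("mw_max", "hba_max") %in% poly$filter_flags[[1]]))
  alk <- res$rejects[res$rejects$id == "long_alkane", ]
  expect_true(all(c("logp_max", "rotb_max") %in% alk$filter_flags[[1]]))

  # tightened config pulls more molecules out
  strict <- soft_druglike_filter(valid, filter_config(mw_max = 200))
  expect_gt(nrow(strict$rejects), nrow(res$rejects))
  expect_true(all(vapply(strict$rejects$filter_flags,
                         function(f) length(f) > 0, logical(1))))
  expect_error(filter_config(mw_min = 900, mw_max = 800), "mw_min")
})

test_that("deduplication merges matching labels, drops conflicts, and is idempotent", {
  valid <- head(fixture_valid(), 6)
  base <- dplyr::mutate(valid, source = "pubchem", label = "inhibitor")
  # same structure under a different id and source
  dup <- dplyr::mutate(base[1, ], id = "dup1", source = "chembl")
  res <- deduplicate(dplyr::bind_rows(base, dup))
  expect_equal(nrow(res$records), nrow(base))
  expect_equal(res$records$source[1], "chembl,pubchem")
  expect_equal(res$log$action, "merged")

  # conflicting labels: compound dropped entirely, conflict logged
  con <- dplyr::mutate(dup, label = "non_inhibitor")
  res2 <- deduplicate(dplyr::bind_rows(base, con))
  expect_equal(nrow(res2$records), nrow(base) - 1L)
  expect_false(base$id[1] %in% res2$records$id)
  expect_equal(res2$log$action, "dropped_conflicting_labels")

  # all-distinct input is the identity; dedup o dedup = dedup
  res3 <- deduplicate(base)
  expect_equal(res3$records$id, base$id)
  res4 <- deduplicate(res3$records)
  expect_equal(res4$records, res3$records)
})

test_that("stratified split conserves class proportions and is seed-reproducible", {
  recs <- tibble::tibble(
    id = sprintf("m%02d", 1:20),
    label = rep(c("inhibitor", "non_inhibitor"), each = 10)
  )
  sp <- stratified_split(recs, fraction = 0.8, seed = 4)
  counts <- table(sp$label, sp$split)
  expect_equal(unname(counts["inhibitor", "train"]), 8)
  expect_equal(unname(counts["non_inhibitor", "train"]), 8)
  expect_identical(sp, stratified_split(recs, fraction = 0.8, seed = 4))
  expect_false(identical(sp$split, stratified_split(recs, 0.8, seed = 5)$split))
  expect_error(stratified_split(recs, fraction = 1.2), "fraction")
  expect_error(stratified_split(recs[1:10, ], 0.8), "both classes")

  # reference dataset arithmetic: 4840 + 3301 compounds at 80%
  big <- tibble::tibble(
    id = as.character(1:8141),
    label = rep(c("inhibitor", "non_inhibitor"), c(4840, 3301))
  )
  sp2 <- stratified_split(big, fraction = 0.8, seed = 1)
  tab <- table(sp2$label, sp2$split)
  expect_equal(unname(tab["inhibitor", c("train", "test")]), c(3872, 968))
  expect_equal(unname(tab["non_inhibitor", c("train", "test")]), c(2641, 660))
})

test_that("diversity clustering satisfies the leader-cluster contract", {
  valid <- head(fixture_valid(), 20)
  cl <- diversity_cluster(valid, cutoff = 0.85)
  # partition
  expect_setequal(cl$id, valid$id)
  expect_true(all(cl$centroid_id %in% cl$id))
  # every member similar to its centroid; centroids pairwise dissimilar
  fp <- compute_fingerprints(valid, "fp2")
  sim <- tanimoto_matrix(fp)
  for (k in unique(cl$cluster_id)) {
    members <- cl$id[cl$cluster_id == k]
    cent <- unique(cl$centroid_id[cl$cluster_id == k])
    expect_length(cent, 1L)
    expect_true(all(sim[cent, members] >= 0.85))
  }
  cents <- unique(cl$centroid_id)
  if (length(cents) > 1L) {
    off <- sim[cents, cents]; diag(off) <- 0
    expect_true(all(off < 0.85))
  }
  # identical molecules cluster together, dissimilar ones apart
  trio <- tibble::tibble(
    id = c("a", "b", "c"),
    smiles = c("CC(=O)Oc1ccccc1C(=O)O", "CC(=O)Oc1ccccc1C(=O)O", "CCCCCCCC")
  )
  expect_equal(max(diversity_cluster(trio, cutoff = 0.85)$cluster_id), 2L)
  expect_error(diversity_cluster(trio[0, ]), "empty")
})

test_that("lowering the similarity cutoff never increases the cluster count", {
  mols <- fixture_valid()
  counts <- vapply(seq(0.9, 0.5, by = -0.1), function(ct) {
    max(diversity_cluster(mols, cutoff = ct)$cluster_id)
  }, integer(1))
  expect_true(all(diff(counts) <= 0L))
})
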