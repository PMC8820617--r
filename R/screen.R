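## Screening cascade: consensus RF-AND-SVM prediction, the
## per-conformation interaction-energy filter, two-stage diversity
## clustering of the prioritized hits, and per-cluster candidate
## selection.

#' Consensus prediction over the forest and SVM bundles
#'
#' A molecule is consensus-positive iff BOTH models call it an
#' inhibitor; each model's call is recorded.
#'
#' @param rf_bundle,svm_bundle Trained `cyp_model` bundles.
#' @param matrix Descriptor tibble satisfying both bundles' column
#'   requirements (raw scale; the SVM bundle scales internally).
#' @return Tibble `id`, `rf_positive`, `svm_positive`, `consensus`.
#' @export
consensus_predict <- function(rf_bundle, svm_bundle, matrix) {
  pos <- cyp_labels()[1]
  rf <- predict(rf_bundle, matrix)
  svm <- predict(svm_bundle, matrix)
  tibble::tibble(
    id = matrix$id,
    rf_positive = rf$.pred_label == pos,
    svm_positive = svm$.pred_label == pos,
    consensus = rf$.pred_label == pos & svm$.pred_label == pos
  )
}

#' Apply the interaction-energy filter to consensus candidates
#'
#' Marks as `prioritized` the candidates that are consensus-positive
#' AND whose docking score is strictly below `threshold` for every
#' conformation. Non-consensus candidates are never prioritized, no
#' matter their energies. Every consensus candidate must have a
#' complete IE profile; a missing or incomplete profile is an error,
#' so absent docking runs surface instead of being masked.
#'
#' @param candidates Tibble from [consensus_predict()].
#' @param profiles IE tibble covering (at least) the consensus ids.
#' @param threshold Cutoff in kcal/mol (default
#'   [ie_default_threshold()]).
#' @return `candidates` with `ie_pass` and `prioritized` columns.
#' @export
prioritize <- function(candidates, profiles, threshold = ie_default_threshold()) {
  stopifnot(all(c("id", "consensus") %in% names(candidates)))
  need <- candidates$id[candidates$consensus]
  complete <- ie_completeness(profiles)
  have <- profiles$id[complete]
  missing_ids <- setdiff(need, have)
  if (length(missing_ids) > 0L) {
    abort(sprintf("no complete IE profile for consensus candidate(s): %s",
                  paste(missing_ids, collapse = ", ")))
  }
  prof <- profiles[complete, , drop = FALSE]
  pass <- ie_pass_filter(prof, threshold)
  pass_of <- stats::setNames(pass, prof$id)
  out <- candidates
  out$ie_pass <- unname(pass_of[out$id])
  out$prioritized <- out$consensus & !is.na(out$ie_pass) & out$ie_pass
  out
}

#' Two-stage diversity clustering of prioritized hits
#'
#' Stage 1 clusters all hits with a 166-key structural-key fingerprint
#' at `stage1_cutoff` (default 0.80); stage 2 re-clusters only the
#' stage-1 centroids with a path-based fingerprint at `stage2_cutoff`
#' (default 0.70). Both stages use deterministic leader clustering
#' (see [diversity_cluster()]).
#'
#' @param records Tibble with `id` and `smiles` for the prioritized
#'   hits.
#' @param stage1_cutoff,stage2_cutoff Tanimoto cutoffs.
#' @return List with `stage1` and `stage2` cluster assignments;
#'   `stage2` additionally maps every hit to its stage-2 cluster via
#'   its stage-1 centroid (`hit_map`).
#' @export
cluster_hits <- function(records, stage1_cutoff = 0.80, stage2_cutoff = 0.70) {
  if (nrow(records) == 0L) abort("empty input: no prioritized hits to cluster.")
  stage1 <- diversity_cluster(records, fingerprint = "maccs",
                              cutoff = stage1_cutoff)
  centroids <- records[records$id %in% stage1$centroid_id, , drop = FALSE]
  stage2 <- diversity_cluster(centroids, fingerprint = "fp2",
                              cutoff = stage2_cutoff)
  s2_of_centroid <- stats::setNames(stage2$cluster_id, stage2$id)
  hit_map <- tibble::tibble(
    id = stage1$id,
    stage1_cluster = stage1$cluster_id,
    stage2_cluster = unname(s2_of_centroid[stage1$centroid_id])
  )
  list(stage1 = stage1, stage2 = stage2, hit_map = hit_map)
}

#' Select diverse representatives from the stage-2 clusters
#'
#' By default one pick per stage-2 cluster (its centroid). Clusters
#' with more than `extra_min_size` members yield
#' `ceiling(size / extra_per)` picks: after the centroid, each further
#' pick greedily maximizes the minimum Tanimoto distance to the picks
#' so far (max-min diversity).
#'
#' @param clusters Result of [cluster_hits()].
#' @param records Tibble with `id` and `smiles` covering the stage-2
#'   members.
#' @param picks_per_cluster Baseline picks per cluster (default 1).
#' @param extra_min_size Size above which a cluster earns extra picks
#'   (default 10); `Inf` disables extra picks.
#' @param extra_per Members per pick for large clusters (default 15).
#' @param fingerprint Fingerprint used for the diversity picks
#'   (default the stage-2 path fingerprint).
#' @return Tibble `id`, `stage2_cluster`, `pick_rank`.
#' @export
select_candidates <- function(clusters, records, picks_per_cluster = 1,
                              extra_min_size = 10, extra_per = 15,
                              fingerprint = "fp2") {
  s2 <- clusters$stage2
  if (nrow(s2) == 0L) abort("empty cluster assignment.")
  fp <- compute_fingerprints(records[records$id %in% s2$id, , drop = FALSE],
                             fingerprint)
  sim <- tanimoto_matrix(fp)
  picks <- list()
  for (cl in sort(unique(s2$cluster_id))) {
    members <- s2$id[s2$cluster_id == cl]
    centroid <- unique(s2$centroid_id[s2$cluster_id == cl])
    n_picks <- picks_per_cluster
    if (is.finite(extra_min_size) && length(members) > extra_min_size) {
      n_picks <- max(picks_per_cluster, ceiling(length(members) / extra_per))
    }
    n_picks <- min(n_picks, length(members))
    chosen <- centroid
    while (length(chosen) < n_picks) {
      rest <- setdiff(members, chosen)
      ## max-min: farthest (least similar) from current picks; ties by id
      worst <- vapply(rest, function(m) max(sim[m, chosen]), numeric(1))
      chosen <- c(chosen, rest[order(worst, rest)][1])
    }
    picks[[length(picks) + 1L]] <- tibble::tibble(
      id = chosen, stage2_cluster = cl, pick_rank = seq_along(chosen)
    )
  }
  dplyr::bind_rows(picks)
}

#' Run the full screening cascade on a drug library
#'
#' Consensus prediction, interaction-energy filtering, two-stage
#' diversity clustering and per-cluster candidate selection, with an
#' optional exclusion list (e.g. drugs already known to inhibit the
#' enzyme).
#'
#' @param records Library tibble with `id` and `smiles`.
#' @param matrix Descriptor tibble for the library (raw scale,
#'   including the `ie.*` columns both bundles were trained with, if
#'   any).
#' @param profiles IE tibble covering the library.
#' @param rf_bundle,svm_bundle Trained `cyp_model` bundles.
#' @param threshold IE cutoff in kcal/mol.
#' @param exclude Character vector of ids to drop before screening.
#' @param stage1_cutoff,stage2_cutoff Clustering cutoffs.
#' @return A `screen_report`: list with `candidates` (per-molecule
#'   flags and cluster ids), `counts` (cascade stage sizes), `clusters`
#'   and `selected`.
#' @export
screen_library <- function(records, matrix, profiles, rf_bundle, svm_bundle,
                           threshold = ie_default_threshold(),
                           exclude = character(0),
                           stage1_cutoff = 0.80, stage2_cutoff = 0.70) {
  records <- records[!(records$id %in% exclude), , drop = FALSE]
  matrix <- matrix[!(matrix$id %in% exclude), , drop = FALSE]
  cand <- consensus_predict(rf_bundle, svm_bundle, matrix)
  cand <- prioritize(cand, profiles, threshold)
  hits <- records[records$id %in% cand$id[cand$prioritized], , drop = FALSE]
  clusters <- NULL
  selected <- tibble::tibble(id = character(), stage2_cluster = integer(),
                             pick_rank = integer())
  if (nrow(hits) > 0L) {
    clusters <- cluster_hits(hits, stage1_cutoff, stage2_cutoff)
    selected <- select_candidates(clusters, hits)
    cand <- dplyr::left_join(cand, clusters$hit_map, by = "id")
  } else {
    cand$stage1_cluster <- NA_integer_
    cand$stage2_cluster <- NA_integer_
  }
  counts <- tibble::tibble(
    stage = c("library", "consensus", "prioritized", "stage1_clusters",
              "stage2_clusters", "selected"),
    n = c(nrow(cand), sum(cand$consensus), sum(cand$prioritized),
          if (is.null(clusters)) 0L else max(clusters$stage1$cluster_id),
          if (is.null(clusters)) 0L else max(clusters$stage2$cluster_id),
          nrow(selected))
  )
  stopifnot(counts$n[2] <= counts$n[1], counts$n[3] <= counts$n[2])
  structure(
    list(candidates = cand, counts = counts, clusters = clusters,
         selected = selected, threshold = threshold,
         stage1_cutoff = stage1_cutoff, stage2_cutoff = stage2_cutoff),
    class = "screen_report"
  )
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report>\n")
  print(x$counts)
  invisible(x)
}

#' Write a screening report to disk
#'
#' Writes the per-candidate table (id, model flags, cluster ids,
#' picked) and the cascade counts as CSV files under `dir`.
#'
#' @param report A `screen_report`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_screen_report <- function(report, dir) {
  stopifnot(inherits(report, "screen_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cand <- report$candidates
  cand$picked <- cand$id %in% report$selected$id
  readr::write_csv(cand, file.path(dir, "candidates.csv"))
  readr::write_csv(report$counts, file.path(dir, "cascade_counts.csv"))
  readr::write_csv(report$selected, file.path(dir, "selected.csv"))
  invisible(dir)
}
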