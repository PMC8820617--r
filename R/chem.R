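## Thin chemistry layer over ChemmineR/ChemmineOB and the obabel CLI.
## Everything downstream works on tibbles of (id, smiles) plus binary
## fingerprint matrices; this file is the only place that touches SDF
## objects directly.

#' Parse SMILES into an SDF set, reporting failures
#'
#' Attempts to parse each SMILES independently so that a single bad
#' structure never aborts a batch. Open Babel's parser is used via
#' ChemmineOB.
#'
#' @param records Tibble with `id` and `smiles` columns.
#' @return List with `sdf` (a `ChemmineR::SDFset` of the molecules that
#'   parsed, named by id), `valid` (the parsed rows) and `rejects`
#'   (tibble `id`, `smiles`, `reason`).
#' @export
parse_smiles <- function(records) {
  stopifnot(all(c("id", "smiles") %in% names(records)))
  if (anyDuplicated(records$id)) abort("compound ids must be unique.")
  ok <- vapply(seq_len(nrow(records)), function(i) {
    smi <- records$smiles[[i]]
    !is.null(suppressWarnings(tryCatch(
      {
        s <- ChemmineR::smiles2sdf(stats::setNames(smi, records$id[[i]]))
        if (length(s) != 1L) stop("parse failed")
        s
      },
      error = function(e) NULL
    )))
  }, logical(1))
  rejects <- tibble::tibble(
    id = records$id[!ok],
    smiles = records$smiles[!ok],
    reason = rep("smiles_parse", sum(!ok))
  )
  sdf <- NULL
  if (any(ok)) {
    sdf <- suppressWarnings(ChemmineR::smiles2sdf(
      stats::setNames(records$smiles[ok], records$id[ok])
    ))
    ChemmineR::cid(sdf) <- records$id[ok]
  }
  list(sdf = sdf, valid = records[ok, , drop = FALSE], rejects = rejects)
}

## Supported fingerprint kinds. "maccs" is a 166-key structural-key set,
## "fp2" a path-based (linear fragment) fingerprint; both computed by
## Open Babel. These stand in for the proprietary MACCS/FragFp
## descriptors used with commercial tools.
FP_KINDS <- c("fp2", "maccs")

#' Compute binary fingerprints for a set of molecules
#'
#' @param records Tibble with `id` and `smiles`; all SMILES must parse.
#' @param kind `"fp2"` (path-based, 1024 bits) or `"maccs"`
#'   (166-key structural keys).
#' @return A logical/0-1 matrix, one row per molecule, rownames = ids.
#' @export
compute_fingerprints <- function(records, kind = c("fp2", "maccs")) {
  kind <- match.arg(kind)
  parsed <- parse_smiles(records)
  if (nrow(parsed$rejects) > 0L) {
    abort(sprintf(
      "unparseable SMILES for ids: %s",
      paste(parsed$rejects$id, collapse = ", ")
    ))
  }
  fpset <- ChemmineR::fingerprintOB(parsed$sdf, switch(kind, fp2 = "FP2", maccs = "MACCS"))
  m <- fpset@fpma
  rownames(m) <- records$id
  m
}

#' Pairwise Tanimoto similarity from a binary fingerprint matrix
#'
#' Tanimoto(A, B) = |A AND B| / |A OR B|. Molecules with empty
#' fingerprints get similarity 1 with each other and 0 with everything
#' else (the 0/0 convention is similarity 1 only on the diagonal).
#'
#' @param fp Binary matrix (rows = molecules).
#' @return Symmetric numeric matrix of similarities in \[0, 1\].
#' @export
tanimoto_matrix <- function(fp) {
  fp <- matrix(as.numeric(fp > 0), nrow = nrow(fp), dimnames = dimnames(fp))
  inter <- fp %*% t(fp)
  ones <- rowSums(fp)
  uni <- outer(ones, ones, "+") - inter
  s <- ifelse(uni == 0, 0, inter / pmax(uni, 1e-300))
  diag(s) <- 1
  s
}

## Leader (sphere-exclusion) clustering on a precomputed similarity
## matrix. Molecules are processed in descending neighbour-count order
## (neighbours = similarity >= cutoff), ties broken by ascending id;
## each unassigned molecule in the leader's sphere joins its cluster.
## Centroids are pairwise dissimilar (< cutoff) by construction.
leader_cluster_sim <- function(sim, ids, cutoff) {
  n <- length(ids)
  stopifnot(nrow(sim) == n)
  neigh <- rowSums(sim >= cutoff) - 1L
  ord <- order(-neigh, ids)
  cluster <- integer(n)
  centroid <- character(n)
  next_id <- 0L
  for (i in ord) {
    if (cluster[i] != 0L) next
    next_id <- next_id + 1L
    members <- which(cluster == 0L & sim[i, ] >= cutoff)
    cluster[members] <- next_id
    centroid[members] <- ids[i]
  }
  tibble::tibble(
    id = ids,
    cluster_id = cluster,
    centroid_id = centroid,
    is_centroid = ids == centroid
  )
}

#' Diversity clustering by Tanimoto leader (sphere-exclusion) clustering
#'
#' Greedy clustering in which every member is within `cutoff` Tanimoto
#' similarity of its cluster centroid and centroids are pairwise less
#' similar than `cutoff`. Molecules are processed in descending
#' neighbour-count order with ties broken by ascending id, which makes
#' the partition deterministic for a given input.
#'
#' @param records Tibble with `id` and `smiles`.
#' @param fingerprint Fingerprint kind, see [compute_fingerprints()].
#' @param cutoff Tanimoto similarity cutoff in (0, 1).
#' @return Tibble `id`, `cluster_id`, `centroid_id`, `is_centroid` with
#'   attributes `similarity_cutoff` and `fingerprint`.
#' @export
#' @examples
#' mols <- head(fixture_molecules(), 12)
#' diversity_cluster(mols, cutoff = 0.85)
diversity_cluster <- function(records, fingerprint = c("fp2", "maccs"), cutoff = 0.85) {
  fingerprint <- match.arg(fingerprint)
  if (nrow(records) == 0L) abort("empty input: no molecules to cluster.")
  if (!(cutoff > 0 && cutoff < 1)) abort("`cutoff` must be in (0, 1).")
  fp <- compute_fingerprints(records, fingerprint)
  sim <- tanimoto_matrix(fp)
  out <- leader_cluster_sim(sim, records$id, cutoff)
  attr(out, "similarity_cutoff") <- cutoff
  attr(out, "fingerprint") <- fingerprint
  out
}
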