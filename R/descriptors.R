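## Descriptor engine: open 2D/3D physicochemical descriptors, pruning
## of correlated and near-constant columns, and standardization for
## kernel models. A descriptor matrix is a tibble whose first column is
## `id`; every transform appends to a provenance attribute so the
## processed matrix can be replayed from the raw one.

new_descriptor_tbl <- function(x, provenance = list()) {
  stopifnot(names(x)[1] == "id")
  if (anyDuplicated(x$id)) abort("descriptor matrix row ids must be unique.")
  if (anyDuplicated(names(x))) abort("descriptor column names must be unique.")
  vals <- as.matrix(x[, -1, drop = FALSE])
  if (ncol(vals) > 0 && any(!is.finite(vals))) {
    abort("descriptor matrix must contain only finite values.")
  }
  attr(x, "provenance") <- provenance
  class(x) <- unique(c("descriptor_tbl", class(x)))
  x
}

#' Transform provenance of a descriptor matrix
#'
#' @param matrix A descriptor tibble.
#' @return List of recorded transform steps.
#' @export
provenance <- function(matrix) attr(matrix, "provenance") %||% list()

`%||%` <- function(a, b) if (is.null(a)) b else a

append_provenance <- function(matrix, step) {
  prov <- c(provenance(matrix), list(step))
  attr(matrix, "provenance") <- prov
  matrix
}

#' Replay recorded transforms on a raw descriptor matrix
#'
#' Applies the provenance of a processed matrix (column removals and
#' scaling) to the raw matrix it came from, reproducing the processed
#' matrix exactly.
#'
#' @param raw The untransformed descriptor tibble.
#' @param prov A provenance list, from [provenance()].
#' @return The re-processed descriptor tibble.
#' @export
replay_provenance <- function(raw, prov) {
  out <- raw
  for (step in prov) {
    out <- switch(step$step,
      prune_correlated = ,
      prune_low_variance = out[, !(names(out) %in% step$removed), drop = FALSE],
      standardize = standardize(out, params = step$params)$matrix,
      abort(sprintf("unknown provenance step '%s'", step$step))
    )
    if (!inherits(out, "descriptor_tbl")) out <- new_descriptor_tbl(out)
  }
  attr(out, "provenance") <- prov
  out
}

## ---- descriptor computation -------------------------------------------

## Basic physicochemical properties needed by the soft filter:
## MW, logP, HBD, HBA, rotatable bonds, TPSA. Open Babel via ChemmineOB.
molecular_properties <- function(records) {
  parsed <- parse_smiles(records)
  if (nrow(parsed$rejects) > 0L) {
    abort(sprintf("unparseable SMILES for ids: %s",
                  paste(parsed$rejects$id, collapse = ", ")))
  }
  sdf <- parsed$sdf
  p <- ChemmineR::propOB(sdf)
  rotb <- ChemmineR::smartsSearchOB(sdf, "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]",
                                    uniqueMatches = TRUE)
  tibble::tibble(
    id = records$id,
    mw = as.numeric(p$MW),
    logp = as.numeric(p$logP),
    hbd = as.numeric(p$HBD),
    hba = as.numeric(p$HBA1),
    rotb = as.numeric(rotb),
    tpsa = as.numeric(p$TPSA),
    mr = as.numeric(p$MR)
  )
}

## Gasteiger partial charges per molecule, via `obabel -omol2`.
## Returns a list of numeric vectors (one per molecule, input order).
gasteiger_charges <- function(smiles) {
  obabel <- Sys.which("obabel")
  if (!nzchar(obabel)) abort("the `obabel` executable is required but not on PATH.")
  smi_file <- tempfile(fileext = ".smi")
  mol2_file <- tempfile(fileext = ".mol2")
  on.exit(unlink(c(smi_file, mol2_file)), add = TRUE)
  writeLines(paste(smiles, sprintf("m%06d", seq_along(smiles))), smi_file)
  system2(obabel, c("-ismi", smi_file, "-omol2", "-O", mol2_file,
                    "--partialcharge", "gasteiger"),
          stdout = FALSE, stderr = FALSE)
  lines <- readLines(mol2_file)
  mol_starts <- grep("^@<TRIPOS>MOLECULE", lines)
  if (length(mol_starts) != length(smiles)) {
    abort("charge calculation failed for at least one molecule.")
  }
  atom_starts <- grep("^@<TRIPOS>ATOM", lines)
  bond_starts <- grep("^@<TRIPOS>BOND", lines)
  purrr::map2(atom_starts, bond_starts, function(a, b) {
    block <- lines[(a + 1):(b - 1)]
    vapply(strsplit(trimws(block), "\\s+"), function(f) as.numeric(f[[9]]),
           numeric(1))
  })
}

## 3D conformer coordinates via `obabel --gen3d`; returns per-molecule
## tibbles of (element, x, y, z), or NULL where embedding failed.
embed_3d <- function(smiles) {
  obabel <- Sys.which("obabel")
  if (!nzchar(obabel)) abort("the `obabel` executable is required but not on PATH.")
  out <- vector("list", length(smiles))
  for (i in seq_along(smiles)) {
    sdf_file <- tempfile(fileext = ".sdf")
    status <- suppressWarnings(system2(
      obabel, c(paste0("-:", shQuote(smiles[[i]])), "-osdf", "-O", sdf_file, "--gen3d"),
      stdout = FALSE, stderr = FALSE
    ))
    txt <- tryCatch(readLines(sdf_file), error = function(e) character(0))
    unlink(sdf_file)
    counts_line <- txt[4]
    if (length(txt) < 5L || is.na(counts_line) || !grepl("V2000", counts_line)) next
    n_atoms <- as.integer(substr(counts_line, 1, 3))
    if (is.na(n_atoms) || n_atoms < 1L) next
    atom_block <- txt[5:(4 + n_atoms)]
    coords <- do.call(rbind, lapply(atom_block, function(l) {
      f <- strsplit(trimws(l), "\\s+")[[1]]
      data.frame(x = as.numeric(f[1]), y = as.numeric(f[2]),
                 z = as.numeric(f[3]), element = f[4])
    }))
    if (all(abs(coords$z) < 1e-8) && all(abs(coords$y) < 1e-8)) next # embedding failed
    out[[i]] <- coords
  }
  out
}

ATOMIC_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
                 P = 30.974, S = 32.06, Cl = 35.45, Br = 79.904, I = 126.904,
                 B = 10.81, Si = 28.085)

## Shape descriptors from 3D coordinates: principal moments of inertia,
## normalized ratios, mass-weighted radius of gyration, span,
## asphericity.
shape_descriptors <- function(coords) {
  m <- ATOMIC_MASS[coords$element]
  m[is.na(m)] <- 12.011
  xyz <- as.matrix(coords[, c("x", "y", "z")])
  com <- colSums(xyz * m) / sum(m)
  c_xyz <- sweep(xyz, 2, com)
  ## inertia tensor
  ixx <- sum(m * (c_xyz[, 2]^2 + c_xyz[, 3]^2))
  iyy <- sum(m * (c_xyz[, 1]^2 + c_xyz[, 3]^2))
  izz <- sum(m * (c_xyz[, 1]^2 + c_xyz[, 2]^2))
  ixy <- -sum(m * c_xyz[, 1] * c_xyz[, 2])
  ixz <- -sum(m * c_xyz[, 1] * c_xyz[, 3])
  iyz <- -sum(m * c_xyz[, 2] * c_xyz[, 3])
  tensor <- matrix(c(ixx, ixy, ixz, ixy, iyy, iyz, ixz, iyz, izz), 3, 3)
  pmi <- sort(eigen(tensor, symmetric = TRUE, only.values = TRUE)$values)
  pmi <- pmax(pmi, 0)
  rg <- sqrt(sum(m * rowSums(c_xyz^2)) / sum(m))
  dists <- sqrt(rowSums(c_xyz^2))
  ## gyration-tensor eigenvalues for asphericity
  gt <- crossprod(c_xyz * sqrt(m)) / sum(m)
  ev <- sort(eigen(gt, symmetric = TRUE, only.values = TRUE)$values, decreasing = TRUE)
  asph <- ev[1] - 0.5 * (ev[2] + ev[3])
  c(
    pmi1 = pmi[1],
    npr1 = if (pmi[3] > 0) pmi[1] / pmi[3] else 0,
    npr2 = if (pmi[3] > 0) pmi[2] / pmi[3] else 0,
    rgyr = rg,
    span = max(dists),
    asphericity = asph
  )
}

D2_NAMES <- c(
  "d2.mw", "d2.logp", "d2.tpsa", "d2.hbd", "d2.hba", "d2.mr",
  "d2.n_heavy", "d2.n_c", "d2.n_n", "d2.n_o", "d2.n_s", "d2.n_hal",
  "d2.n_rot", "d2.n_rings", "d2.n_arom_rings", "d2.n_arom_atoms",
  "d2.n_arom_bonds", "d2.frac_csp3",
  "d2.q_max", "d2.q_min", "d2.q_pos", "d2.q_neg", "d2.n_q_neg"
)
D3_NAMES <- c("d3.pmi1", "d3.npr1", "d3.npr2", "d3.rgyr", "d3.span",
              "d3.asphericity")

#' Compute the open 2D/3D descriptor set
#'
#' An open substitute for commercial descriptor sets, covering the
#' categories that drive CYP2C9 inhibition models: lipophilicity
#' (logP, molar refractivity), aromatic bond/atom counts, Gasteiger
#' partial-charge statistics (including negative-charge surface
#' proxies), polar surface area, and 3D shape (inertia-moment ratios,
#' radius of gyration, span, asphericity). Descriptor names are
#' namespaced `d2.*` / `d3.*`. The full column set for a configuration
#' is fixed: any molecule that cannot yield it is moved to a rejects
#' table instead of producing partial rows.
#'
#' @param records Tibble with `id` and `smiles`.
#' @param include_3d Compute the 3D shape block (requires single-
#'   conformer embedding; default `TRUE`).
#' @param conformer_seed Accepted for interface stability; the bundled
#'   embedding backend is deterministic and ignores it.
#' @return List with `matrix` (descriptor tibble: 23 `d2.*` columns,
#'   plus 6 `d3.*` columns when `include_3d`) and `rejects` (tibble
#'   `id`, `reason` with reasons `"smiles_parse"` or `"embed_fail"`).
#' @export
#' @examples
#' \donttest{
#' compute_descriptors(tibble::tibble(id = "bz", smiles = "c1ccccc1"),
#'                     include_3d = FALSE)$matrix
#' }
compute_descriptors <- function(records, include_3d = TRUE, conformer_seed = 2022) {
  parsed <- parse_smiles(records)
  rejects <- tibble::tibble(id = parsed$rejects$id,
                            reason = rep("smiles_parse", nrow(parsed$rejects)))
  recs <- parsed$valid
  if (nrow(recs) == 0L) {
    abort("no valid structures to compute descriptors for.")
  }
  sdf <- parsed$sdf
  p <- ChemmineR::propOB(sdf)
  counts <- ChemmineR::atomcountMA(sdf, addH = FALSE)
  cnt <- function(el) if (el %in% colnames(counts)) as.numeric(counts[, el]) else numeric(nrow(recs))
  rings <- ChemmineR::rings(sdf, type = "count", arom = TRUE)
  if (is.null(dim(rings))) {
    rings <- matrix(rings, nrow = 1, dimnames = list(NULL, names(rings)))
  }
  smarts_count <- function(pat) {
    as.numeric(ChemmineR::smartsSearchOB(sdf, pat, uniqueMatches = TRUE))
  }
  n_rot <- smarts_count("[!$(*#*)&!D1]-!@[!$(*#*)&!D1]")
  n_arom_atoms <- smarts_count("[a]")
  n_arom_bonds <- smarts_count("[a]:[a]")
  n_csp3 <- smarts_count("[CX4]")
  n_c <- cnt("C")
  charges <- gasteiger_charges(recs$smiles)
  q_max <- vapply(charges, max, numeric(1))
  q_min <- vapply(charges, min, numeric(1))
  q_pos <- vapply(charges, function(q) sum(q[q > 0]), numeric(1))
  q_neg <- vapply(charges, function(q) sum(q[q < 0]), numeric(1))
  n_q_neg <- vapply(charges, function(q) sum(q < -0.2), numeric(1))
  n_heavy <- as.numeric(rowSums(counts))
  d2 <- cbind(
    `d2.mw` = as.numeric(p$MW), `d2.logp` = as.numeric(p$logP),
    `d2.tpsa` = as.numeric(p$TPSA), `d2.hbd` = as.numeric(p$HBD),
    `d2.hba` = as.numeric(p$HBA1), `d2.mr` = as.numeric(p$MR),
    `d2.n_heavy` = n_heavy, `d2.n_c` = n_c, `d2.n_n` = cnt("N"),
    `d2.n_o` = cnt("O"), `d2.n_s` = cnt("S"),
    `d2.n_hal` = cnt("F") + cnt("Cl") + cnt("Br") + cnt("I"),
    `d2.n_rot` = n_rot, `d2.n_rings` = as.numeric(rings[, "RINGS"]),
    `d2.n_arom_rings` = as.numeric(rings[, "AROMATIC"]),
    `d2.n_arom_atoms` = n_arom_atoms, `d2.n_arom_bonds` = n_arom_bonds,
    `d2.frac_csp3` = ifelse(n_c > 0, n_csp3 / n_c, 0),
    `d2.q_max` = q_max, `d2.q_min` = q_min, `d2.q_pos` = q_pos,
    `d2.q_neg` = q_neg, `d2.n_q_neg` = n_q_neg
  )
  keep <- rep(TRUE, nrow(recs))
  d3 <- NULL
  if (include_3d) {
    coords <- embed_3d(recs$smiles)
    ok3d <- !vapply(coords, is.null, logical(1))
    d3 <- matrix(NA_real_, nrow(recs), length(D3_NAMES),
                 dimnames = list(NULL, D3_NAMES))
    for (i in which(ok3d)) d3[i, ] <- shape_descriptors(coords[[i]])
    keep <- keep & ok3d
    if (any(!ok3d)) {
      rejects <- dplyr::bind_rows(rejects, tibble::tibble(
        id = recs$id[!ok3d], reason = rep("embed_fail", sum(!ok3d))
      ))
    }
  }
  vals <- if (is.null(d3)) d2 else cbind(d2, d3)
  mat <- dplyr::bind_cols(
    tibble::tibble(id = recs$id[keep]),
    tibble::as_tibble(vals[keep, , drop = FALSE])
  )
  list(matrix = new_descriptor_tbl(mat), rejects = rejects)
}

## ---- pruning -----------------------------------------------------------

#' Remove highly correlated descriptor columns
#'
#' Scans columns left-to-right against the surviving set; whenever a
#' pair has |Pearson r| at or above `r_cut`, the member with the lower
#' variance is removed (ties broken by removing the alphabetically
#' later name). The surviving matrix has no pair at or above the
#' cutoff, and the operation is idempotent.
#'
#' @param matrix Descriptor tibble (id column first, >= 2 rows).
#' @param r_cut Absolute Pearson correlation cutoff (default 0.85).
#' @return List with `matrix` (pruned) and `report` (tibble: `column`,
#'   `reason`, `partner`, `r`).
#' @export
prune_correlated <- function(matrix, r_cut = 0.85) {
  vals <- as.matrix(matrix[, -1, drop = FALSE])
  if (nrow(vals) < 2L) abort("correlation is undefined for a single-row matrix.")
  cols <- colnames(vals)
  vars <- apply(vals, 2, var)
  removed <- character(0)
  report <- list()
  repeat {
    surv <- setdiff(cols, removed)
    if (length(surv) < 2L) break
    cm <- suppressWarnings(abs(cor(vals[, surv, drop = FALSE])))
    cm[is.na(cm)] <- 0
    diag(cm) <- 0
    hit <- NULL
    for (i in seq_along(surv)) {
      js <- which(cm[i, ] >= r_cut)
      js <- js[js > i]
      if (length(js) > 0L) {
        hit <- c(i, js[1])
        break
      }
    }
    if (is.null(hit)) break
    a <- surv[hit[1]]; b <- surv[hit[2]]
    drop_col <- if (vars[a] < vars[b]) a
    else if (vars[b] < vars[a]) b
    else max(a, b) # tie: alphabetically later goes
    partner <- setdiff(c(a, b), drop_col)
    r_val <- suppressWarnings(cor(vals[, a], vals[, b]))
    removed <- c(removed, drop_col)
    report[[length(report) + 1L]] <- tibble::tibble(
      column = drop_col, reason = "correlation", partner = partner,
      r = r_val
    )
  }
  out <- matrix[, !(names(matrix) %in% removed), drop = FALSE]
  out <- new_descriptor_tbl(tibble::as_tibble(out), provenance(matrix))
  out <- append_provenance(out, list(step = "prune_correlated",
                                     removed = removed, r_cut = r_cut))
  rep_tbl <- if (length(report)) dplyr::bind_rows(report) else
    tibble::tibble(column = character(), reason = character(),
                   partner = character(), r = numeric())
  list(matrix = out, report = rep_tbl)
}

#' Remove near-zero-variance descriptor columns
#'
#' Constant columns are always removed. A non-constant column is
#' removed when the ratio of its most frequent to second most frequent
#' value exceeds `freq_ratio` AND the fraction of distinct values is
#' below `unique_cut` (the conventional two-part near-zero-variance
#' rule).
#'
#' @param matrix Descriptor tibble (>= 2 rows).
#' @param freq_ratio Frequency-ratio threshold (default 19, i.e. 95/5).
#' @param unique_cut Distinct-value fraction threshold (default 0.1).
#' @return List with `matrix` and `report` (columns `column`, `reason`).
#' @export
prune_low_variance <- function(matrix, freq_ratio = 19, unique_cut = 0.1) {
  vals <- as.matrix(matrix[, -1, drop = FALSE])
  if (nrow(vals) < 2L) abort("need at least 2 rows.")
  n <- nrow(vals)
  drop <- vapply(colnames(vals), function(cn) {
    x <- vals[, cn]
    if (var(x) == 0) return(TRUE)
    tab <- sort(table(x), decreasing = TRUE)
    fr <- if (length(tab) >= 2L) tab[[1]] / tab[[2]] else Inf
    uq <- length(tab) / n
    fr > freq_ratio && uq < unique_cut
  }, logical(1))
  removed <- names(drop)[drop]
  out <- matrix[, !(names(matrix) %in% removed), drop = FALSE]
  out <- new_descriptor_tbl(tibble::as_tibble(out), provenance(matrix))
  out <- append_provenance(out, list(step = "prune_low_variance",
                                     removed = removed,
                                     freq_ratio = freq_ratio,
                                     unique_cut = unique_cut))
  list(matrix = out,
       report = tibble::tibble(column = removed,
                               reason = rep("near_zero_variance", length(removed))))
}

## ---- standardization ---------------------------------------------------

#' Center and scale descriptor columns
#'
#' With `params = NULL`, fits per-column mean and standard deviation
#' (denominator n-1) on the given matrix and returns both the scaled
#' matrix and the fitted parameters. With `params` supplied (e.g. from
#' the training set), the stored means/sds are applied unchanged —
#' test or screening data are never re-fit.
#'
#' @param matrix Descriptor tibble; no constant columns when fitting.
#' @param params Optional scaling parameters (tibble `column`, `mean`,
#'   `sd`) from a previous fit.
#' @return List with `matrix` (scaled) and `params`.
#' @export
#' @examples
#' m <- new_descriptor_tbl(tibble::tibble(id = c("a", "b", "c"), x = c(1, 2, 3)))
#' standardize(m)$matrix$x
standardize <- function(matrix, params = NULL) {
  vals <- as.matrix(matrix[, -1, drop = FALSE])
  if (is.null(params)) {
    mu <- colMeans(vals)
    sds <- apply(vals, 2, sd)
    if (any(sds == 0)) {
      abort(sprintf("constant column(s) must be pruned before scaling: %s",
                    paste(colnames(vals)[sds == 0], collapse = ", ")))
    }
    params <- tibble::tibble(column = colnames(vals), mean = unname(mu),
                             sd = unname(sds))
  } else {
    missing_cols <- setdiff(params$column, colnames(vals))
    if (length(missing_cols) > 0L) {
      abort(sprintf("matrix lacks scaled column(s): %s",
                    paste(missing_cols, collapse = ", ")))
    }
    if (any(params$sd <= 0)) abort("scaling parameters must have sd > 0.")
    vals <- vals[, params$column, drop = FALSE]
  }
  scaled <- sweep(sweep(vals, 2, params$mean[match(colnames(vals), params$column)]),
                  2, params$sd[match(colnames(vals), params$column)], "/")
  out <- dplyr::bind_cols(matrix[, "id", drop = FALSE], tibble::as_tibble(scaled))
  out <- new_descriptor_tbl(out, provenance(matrix))
  out <- append_provenance(out, list(step = "standardize", params = params))
  list(matrix = out, params = params)
}
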