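## Dataset curation: activity parsing, labeling, soft drug-like
## filtering, deduplication, diversity clustering to centroids, and the
## stratified train/test split.

#' Read an activity table into compound records
#'
#' Reads a delimited text file (comma or tab, auto-detected from the
#' header line) of assay results and returns one record per row.
#' Rows whose SMILES do not parse are returned in a rejects table with
#' a reason, never silently dropped.
#'
#' @param path Path to the delimited file (header required).
#' @param schema Named list mapping record fields to column names; must
#'   name at least `id` and `smiles`. Optional entries: `source`,
#'   `ac50_um`, `pct_inhib_at_50um`.
#' @return List with `records` (tibble: `id`, `smiles`, `source`,
#'   `ac50_um`, `pct_inhib_at_50um`, `label`, `filter_flags`) and
#'   `rejects` (tibble: `id`, `smiles`, `reason`).
#' @export
parse_activity_table <- function(path,
                                 schema = list(id = "id", smiles = "smiles",
                                               source = "source", ac50_um = "ac50_um",
                                               pct_inhib_at_50um = "pct_inhib_at_50um")) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (is.null(schema$id) || is.null(schema$smiles)) {
    abort("schema must name the `id` and `smiles` columns.")
  }
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) abort("empty input: activity file has no rows.")
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (nrow(raw) == 0L) abort("empty input: activity file has no data rows.")
  mandatory <- c(schema$id, schema$smiles)
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols) > 0L) {
    abort(sprintf("schema error: missing column(s) %s",
                  paste(missing_cols, collapse = ", ")))
  }
  get_col <- function(field, default) {
    nm <- schema[[field]]
    if (!is.null(nm) && nm %in% names(raw)) raw[[nm]] else default
  }
  records <- tibble::tibble(
    id = as.character(raw[[schema$id]]),
    smiles = as.character(raw[[schema$smiles]]),
    source = as.character(get_col("source", rep("other", nrow(raw)))),
    ac50_um = as.numeric(get_col("ac50_um", rep(NA_real_, nrow(raw)))),
    pct_inhib_at_50um = as.numeric(get_col("pct_inhib_at_50um", rep(NA_real_, nrow(raw))))
  )
  bad_ac50 <- !is.na(records$ac50_um) & records$ac50_um <= 0
  if (any(bad_ac50)) {
    abort(sprintf("AC50 must be positive; offending ids: %s",
                  paste(records$id[bad_ac50], collapse = ", ")))
  }
  parsed <- parse_smiles(records)
  records <- parsed$valid |>
    dplyr::mutate(
      label = NA_character_,
      filter_flags = list(character(0))
    )
  list(records = records, rejects = parsed$rejects)
}

#' Assign inhibitor / non-inhibitor labels from activity evidence
#'
#' A compound is an `inhibitor` when its AC50 (or IC50) is at most
#' 10 uM (boundary inclusive); a `non_inhibitor` when it shows less
#' than 10% inhibition at 50 uM and has no qualifying AC50; otherwise
#' `ambiguous`. A record satisfying both rules at once is contradictory
#' evidence and raises an error.
#'
#' @param records Tibble with `ac50_um` and `pct_inhib_at_50um`
#'   columns (NA = not measured).
#' @param ac50_max Inhibitor AC50 cutoff in uM (default 10).
#' @param pct_max Non-inhibitor %-inhibition cutoff at 50 uM
#'   (default 10, exclusive).
#' @return `records` with the `label` column filled.
#' @export
#' @examples
#' assign_labels(tibble::tibble(id = "a", ac50_um = 5, pct_inhib_at_50um = NA))
assign_labels <- function(records, ac50_max = 10, pct_max = 10) {
  stopifnot(all(c("ac50_um", "pct_inhib_at_50um") %in% names(records)))
  no_evidence <- is.na(records$ac50_um) & is.na(records$pct_inhib_at_50um)
  if (any(no_evidence)) {
    abort(sprintf("record(s) without any activity field: %s",
                  paste(records$id[no_evidence], collapse = ", ")))
  }
  bad_pct <- !is.na(records$pct_inhib_at_50um) &
    (records$pct_inhib_at_50um < 0 | records$pct_inhib_at_50um > 100)
  if (any(bad_pct)) {
    abort("`pct_inhib_at_50um` must lie in [0, 100].")
  }
  inhib <- !is.na(records$ac50_um) & records$ac50_um <= ac50_max
  noninhib <- !is.na(records$pct_inhib_at_50um) & records$pct_inhib_at_50um < pct_max
  conflict <- inhib & noninhib
  if (any(conflict)) {
    abort(sprintf(
      "conflicting activity evidence (AC50 <= %g and %%inhib < %g) for: %s",
      ac50_max, pct_max, paste(records$id[conflict], collapse = ", ")
    ))
  }
  records$label <- dplyr::case_when(
    inhib ~ "inhibitor",
    noninhib ~ "non_inhibitor",
    TRUE ~ "ambiguous"
  )
  records
}

#' Soft drug-like filter configuration
#'
#' Bounds intentionally looser than Lipinski-style rules, so that
#' diverse drug-like chemistry (including reactive or PAINS-flagged
#' compounds, which can still be CYP inhibitors) is retained.
#'
#' @param mw_min,mw_max Molecular weight bounds (Da).
#' @param logp_min,logp_max logP bounds.
#' @param hbd_max Max H-bond donors.
#' @param hba_max Max H-bond acceptors.
#' @param rotb_max Max rotatable bonds.
#' @param tpsa_max Max topological polar surface area (A^2).
#' @param remove_pains Reserved; PAINS/toxicophores are never removed
#'   when `FALSE` (the default) and no pattern library is bundled.
#' @return A `filter_config` list.
#' @export
filter_config <- function(mw_min = 100, mw_max = 800,
                          logp_min = -4, logp_max = 8,
                          hbd_max = 7, hba_max = 14,
                          rotb_max = 20, tpsa_max = 250,
                          remove_pains = FALSE) {
  if (mw_min > mw_max) abort("mw_min must be <= mw_max.")
  if (logp_min > logp_max) abort("logp_min must be <= logp_max.")
  if (isTRUE(remove_pains)) {
    abort("PAINS/toxicophore removal is not implemented (kept by design).")
  }
  structure(
    list(mw_min = mw_min, mw_max = mw_max, logp_min = logp_min,
         logp_max = logp_max, hbd_max = hbd_max, hba_max = hba_max,
         rotb_max = rotb_max, tpsa_max = tpsa_max,
         remove_pains = FALSE),
    class = "filter_config"
  )
}

#' Apply the soft drug-like filter
#'
#' Keeps a record iff every configured physicochemical bound holds;
#' rejected records carry the full list of violated rule names in
#' `filter_flags`.
#'
#' @param records Tibble with `id` and `smiles` (all SMILES must parse).
#' @param config A [filter_config()].
#' @return List with `kept` and `rejects` tibbles; both gain a
#'   `filter_flags` list-column, and `rejects` lists every violated
#'   rule (e.g. `"mw_max"`, `"rotb_max"`).
#' @export
soft_druglike_filter <- function(records, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  props <- molecular_properties(records)
  flags <- purrr::pmap(props, function(mw, logp, hbd, hba, rotb, tpsa, ...) {
    f <- character(0)
    if (mw < config$mw_min) f <- c(f, "mw_min")
    if (mw > config$mw_max) f <- c(f, "mw_max")
    if (logp < config$logp_min) f <- c(f, "logp_min")
    if (logp > config$logp_max) f <- c(f, "logp_max")
    if (hbd > config$hbd_max) f <- c(f, "hbd_max")
    if (hba > config$hba_max) f <- c(f, "hba_max")
    if (rotb > config$rotb_max) f <- c(f, "rotb_max")
    if (tpsa > config$tpsa_max) f <- c(f, "tpsa_max")
    f
  })
  out <- records
  out$filter_flags <- flags
  keep <- lengths(flags) == 0L
  list(kept = out[keep, , drop = FALSE], rejects = out[!keep, , drop = FALSE])
}

#' Deduplicate compound records by canonical structure
#'
#' Collapses records that share the same canonical SMILES. Duplicates
#' with identical labels merge their provenance (comma-joined sources);
#' duplicates with conflicting labels are dropped entirely and logged,
#' so that label noise is never injected.
#'
#' @param records Tibble with `id`, `smiles`, `source` and `label`.
#' @return List with `records` (unique) and `log` (tibble of merge and
#'   conflict events: `canonical_smiles`, `ids`, `action`).
#' @export
deduplicate <- function(records) {
  parsed <- parse_smiles(records)
  if (nrow(parsed$rejects) > 0L) {
    abort(sprintf("unparseable SMILES for ids: %s",
                  paste(parsed$rejects$id, collapse = ", ")))
  }
  canon <- canonical_smiles(records$smiles)
  recs <- records
  recs$.canon <- canon
  grouped <- recs |>
    dplyr::group_by(.data$.canon) |>
    dplyr::group_split()
  keep <- list()
  log <- list()
  for (g in grouped) {
    if (nrow(g) == 1L) {
      keep[[length(keep) + 1L]] <- g
      next
    }
    labs <- unique(g$label)
    if (length(labs) == 1L) {
      merged <- g[1L, , drop = FALSE]
      merged$source <- paste(sort(unique(g$source)), collapse = ",")
      keep[[length(keep) + 1L]] <- merged
      log[[length(log) + 1L]] <- tibble::tibble(
        canonical_smiles = g$.canon[[1]],
        ids = paste(g$id, collapse = ","),
        action = "merged"
      )
    } else {
      log[[length(log) + 1L]] <- tibble::tibble(
        canonical_smiles = g$.canon[[1]],
        ids = paste(g$id, collapse = ","),
        action = "dropped_conflicting_labels"
      )
    }
  }
  out <- dplyr::bind_rows(keep)
  ## preserve original row order among survivors
  out <- out[order(match(out$id, records$id)), , drop = FALSE]
  out$.canon <- NULL
  list(
    records = out,
    log = if (length(log)) dplyr::bind_rows(log) else
      tibble::tibble(canonical_smiles = character(), ids = character(),
                     action = character())
  )
}

## Canonical SMILES via Open Babel (batch, order-preserving).
canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    out <- suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", paste0(s, "\n")))
    s2 <- strsplit(out, "[\t\n ]")[[1]][1]
    if (is.na(s2) || !nzchar(s2)) abort(sprintf("cannot canonicalize SMILES '%s'", s))
    s2
  }, character(1), USE.NAMES = FALSE)
}

#' Stratified train/test split
#'
#' Draws `round(fraction * class size)` training compounds from each
#' class independently, so class proportions are conserved to within
#' one compound; reproducible for a given seed.
#'
#' @param records Tibble with `id` and `label` (both classes present).
#' @param fraction Training fraction in (0, 1); default 0.8.
#' @param seed Integer seed.
#' @return Tibble `id`, `label`, `split` (factor train/test), with
#'   attributes `fraction` and `seed`.
#' @export
#' @examples
#' fx <- gen_descriptor_table(fixture_spec(n_active = 10, n_inactive = 10))
#' recs <- tibble::tibble(id = names(fx$labels), label = as.character(fx$labels))
#' table(stratified_split(recs, 0.8, seed = 1)[c("label", "split")])
stratified_split <- function(records, fraction = 0.8, seed = 2022) {
  if (!(fraction > 0 && fraction < 1)) abort("`fraction` must be in (0, 1).")
  stopifnot(all(c("id", "label") %in% names(records)))
  classes <- unique(records$label)
  if (length(classes) < 2L) abort("both classes must be present for a stratified split.")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  split <- rep("test", nrow(records))
  for (cl in sort(classes)) {
    idx <- which(records$label == cl)
    n_train <- round(fraction * length(idx))
    train_idx <- sample(idx, n_train)
    split[train_idx] <- "train"
  }
  out <- tibble::tibble(
    id = records$id,
    label = records$label,
    split = factor(split, levels = c("train", "test"))
  )
  attr(out, "fraction") <- fraction
  attr(out, "seed") <- seed
  out
}
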