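## Interaction-energy descriptors over the seven CYP2C9 receptor
## conformations: docking-output parsing, IE tables, merging onto
## descriptor matrices, the quantile-derived threshold, and the
## per-conformation energy filter. All energies are kcal/mol; more
## negative means stronger predicted binding.

.CONFORMATIONS <- c("1R9O", "5XXI", "MD1", "MD2", "MD3", "MD4", "MD5")

#' The CYP2C9 conformation ensemble
#'
#' Two crystal structures (PDB ids 1R9O, 5XXI) and five molecular-
#' dynamics-derived conformations (MD1-MD5), in their canonical order.
#'
#' @return Character vector of the 7 conformation names.
#' @export
#' @examples
#' cyp_conformations()
cyp_conformations <- function() .CONFORMATIONS

#' Default interaction-energy cutoff (kcal/mol)
#'
#' The screening filter requires the docking score against every
#' conformation to be strictly below this value. The default, -8.5,
#' corresponds to the 75% quantile of training-set inhibitor scores;
#' see [ie_threshold_from_inhibitors()] to re-derive it from data.
#'
#' @return A single number, -8.5.
#' @export
ie_default_threshold <- function() -8.5

#' Origin of each conformation
#'
#' @return Tibble `conformation`, `origin` (crystal or md).
#' @export
conformation_set <- function() {
  tibble::tibble(
    conformation = .CONFORMATIONS,
    origin = c("crystal", "crystal", rep("md", 5))
  )
}

#' Docking grid / job bookkeeping for a conformation
#'
#' Returns the docking-engine settings used for the CYP2C9 binding
#' pocket: grid centered at (8.208, 32.219, -1.923) with a
#' 25 x 25 x 25 A search box around the pocket of 1R9O, grid
#' resolution 1 A, exhaustiveness 8, up to 10 output binding modes.
#' This is bookkeeping for an external docking engine; no docking is
#' executed by this package.
#'
#' @param conformation A name from [cyp_conformations()].
#' @param overrides Named list of settings to override.
#' @return A `docking_job_spec` list.
#' @export
#' @examples
#' default_job_spec("1R9O")$box_size
default_job_spec <- function(conformation, overrides = list()) {
  if (!conformation %in% .CONFORMATIONS) {
    abort(sprintf("unknown conformation '%s'; expected one of %s.",
                  conformation, paste(.CONFORMATIONS, collapse = ", ")))
  }
  spec <- list(
    receptor = conformation,
    grid_center = c(x = 8.208, y = 32.219, z = -1.923),
    box_size = c(25, 25, 25),
    grid_resolution = 1,
    exhaustiveness = 8L,
    max_modes = 10L
  )
  for (nm in names(overrides)) spec[[nm]] <- overrides[[nm]]
  if (any(spec$box_size <= 0)) abort("box sizes must be positive.")
  if (spec$exhaustiveness < 1) abort("exhaustiveness must be >= 1.")
  structure(spec, class = "docking_job_spec")
}

#' Extract the best score from docking-engine output
#'
#' Parses the result text of a docking run and returns the best (most
#' negative) binding-mode score in kcal/mol. Two dialects are
#' recognized: `RESULT:`-prefixed lines with the score as the first
#' number, and the mode table (`mode | affinity | ...`) in which the
#' score is the second column. 1-10 modes are expected; all are read.
#'
#' @param text Character vector (lines) or single string of engine
#'   output.
#' @return The minimum mode score.
#' @export
#' @examples
#' parse_docking_output(c("RESULT:  -9.1  0.0 0.0", "RESULT:  -8.7 1.2 2.0"))
parse_docking_output <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  scores <- numeric(0)
  res_lines <- grep("^\\s*RESULT:", lines, value = TRUE)
  if (length(res_lines) > 0L) {
    scores <- vapply(res_lines, function(l) {
      m <- regmatches(l, regexpr("-?[0-9]+\\.?[0-9]*", l))
      as.numeric(m[[1]])
    }, numeric(1), USE.NAMES = FALSE)
  } else {
    ## generic mode table: lines starting with a mode index then a score
    tab_lines <- grep("^\\s*[0-9]+[\\s,]+-?[0-9]", lines, value = TRUE, perl = TRUE)
    scores <- vapply(tab_lines, function(l) {
      f <- strsplit(trimws(l), "[\\s,]+", perl = TRUE)[[1]]
      as.numeric(f[[2]])
    }, numeric(1), USE.NAMES = FALSE)
  }
  scores <- scores[is.finite(scores)]
  if (length(scores) == 0L) abort("no parsable docking score line found.")
  min(scores)
}

#' Read an interaction-energy table
#'
#' Expects delimited text with an `id` column plus one kcal/mol column
#' per conformation in [cyp_conformations()]. Missing cells are
#' permitted but flag the profile incomplete.
#'
#' @param path File path.
#' @return Tibble `id`, the 7 conformation columns, and `complete`
#'   (logical).
#' @export
read_ie_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  missing_cols <- setdiff(c("id", .CONFORMATIONS), names(raw))
  if (length(missing_cols) > 0L) {
    abort(sprintf("schema error: IE table lacks column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  out <- tibble::tibble(id = as.character(raw$id))
  for (cf in .CONFORMATIONS) out[[cf]] <- as.numeric(raw[[cf]])
  if (anyDuplicated(out$id)) abort("duplicate ids in IE table.")
  out$complete <- stats::complete.cases(out[.CONFORMATIONS])
  out
}

ie_completeness <- function(profiles) {
  if ("complete" %in% names(profiles)) profiles$complete
  else stats::complete.cases(profiles[.CONFORMATIONS])
}

#' Merge interaction energies onto a descriptor matrix
#'
#' Adds the seven per-conformation docking scores as structure-based
#' descriptor columns `ie.<conformation>`.
#'
#' @param matrix Descriptor tibble.
#' @param profiles IE tibble (`id` + conformation columns).
#' @param drop_incomplete Drop matrix rows without a complete profile
#'   (logged via message) instead of raising an error.
#' @return The widened descriptor tibble.
#' @export
merge_ie_descriptors <- function(matrix, profiles, drop_incomplete = FALSE) {
  if (anyDuplicated(profiles$id)) abort("duplicate profile ids.")
  complete <- ie_completeness(profiles)
  prof_ok <- profiles[complete, c("id", .CONFORMATIONS)]
  missing_ids <- setdiff(matrix$id, prof_ok$id)
  if (length(missing_ids) > 0L && !drop_incomplete) {
    abort(sprintf("no complete IE profile for id(s): %s",
                  paste(missing_ids, collapse = ", ")))
  }
  keep <- matrix$id %in% prof_ok$id
  if (length(missing_ids) > 0L) {
    message(sprintf("dropping %d molecule(s) without complete IE profiles.",
                    sum(!keep)))
  }
  out <- matrix[keep, , drop = FALSE]
  ord <- match(out$id, prof_ok$id)
  for (cf in .CONFORMATIONS) out[[paste0("ie.", cf)]] <- prof_ok[[cf]][ord]
  new_descriptor_tbl(tibble::as_tibble(out), provenance(matrix))
}

#' Derive the IE cutoff from training-set inhibitors
#'
#' Pools every (inhibitor x conformation) docking score and returns
#' the q-quantile of the pooled distribution, i.e. the value below
#' which a fraction q of inhibitor scores lie (scores are negative, so
#' "below" means stronger binding). With the default q = 0.75 this
#' reproduces the rationale behind the -8.5 kcal/mol screening cutoff.
#'
#' @param profiles IE tibble of training inhibitors (complete rows).
#' @param q Quantile in (0, 1\]; default 0.75.
#' @return The threshold in kcal/mol.
#' @export
ie_threshold_from_inhibitors <- function(profiles, q = 0.75) {
  if (nrow(profiles) == 0L) abort("need at least one inhibitor profile.")
  pooled <- unlist(profiles[.CONFORMATIONS], use.names = FALSE)
  pooled <- pooled[is.finite(pooled)]
  if (length(pooled) == 0L) abort("no finite scores in profiles.")
  unname(quantile(pooled, probs = q, type = 7))
}

#' Per-conformation interaction-energy filter
#'
#' A molecule passes iff its score is strictly below `threshold` for
#' EVERY conformation (a score exactly at the threshold fails).
#'
#' @param profiles IE tibble.
#' @param threshold Cutoff in kcal/mol (default [ie_default_threshold()]).
#' @return Logical vector, one per profile row.
#' @export
#' @examples
#' prof <- tibble::tibble(id = "a", `1R9O` = -9, `5XXI` = -9, MD1 = -9,
#'                        MD2 = -9, MD3 = -9, MD4 = -9, MD5 = -9)
#' ie_pass_filter(prof)
ie_pass_filter <- function(profiles, threshold = ie_default_threshold()) {
  complete <- ie_completeness(profiles)
  if (any(!complete)) {
    abort(sprintf("incomplete IE profile(s) for id(s): %s",
                  paste(profiles$id[!complete], collapse = ", ")))
  }
  vals <- as.matrix(profiles[.CONFORMATIONS])
  unname(apply(vals < threshold, 1, all))
}
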