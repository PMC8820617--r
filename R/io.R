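## Delimited-text readers and writers shared across the pipeline.

#' Write a curated compound set
#'
#' Columns: id, smiles, label, source, filter_flags (semicolon-joined).
#'
#' @param records Curated tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_curated_set <- function(records, path) {
  out <- records |>
    dplyr::mutate(filter_flags = purrr::map_chr(
      .data$filter_flags %||% list(character(0)),
      ~ paste(.x, collapse = ";")
    )) |>
    dplyr::select(dplyr::any_of(c("id", "smiles", "label", "source",
                                  "filter_flags")))
  readr::write_csv(out, path)
  invisible(path)
}

#' Read / write a descriptor matrix
#'
#' Delimited text with the id column first. The transform provenance
#' is written as a JSON sidecar (`<path>.provenance.json`) and
#' restored on read when present (scaling steps keep their fitted
#' parameters).
#'
#' @param matrix Descriptor tibble.
#' @param path CSV path.
#' @return `write_descriptor_matrix`: `path` invisibly;
#'   `read_descriptor_matrix`: the descriptor tibble.
#' @export
write_descriptor_matrix <- function(matrix, path) {
  readr::write_csv(tibble::as_tibble(matrix), path)
  prov <- provenance(matrix)
  if (length(prov) > 0L) {
    jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  }
  invisible(path)
}

#' @rdname write_descriptor_matrix
#' @export
read_descriptor_matrix <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  names(raw)[1] <- "id"
  raw$id <- as.character(raw$id)
  prov_path <- paste0(path, ".provenance.json")
  prov <- list()
  if (file.exists(prov_path)) {
    prov <- jsonlite::read_json(prov_path, simplifyVector = TRUE,
                                simplifyDataFrame = FALSE)
    prov <- lapply(prov, function(step) {
      if (!is.null(step$params)) step$params <- tibble::as_tibble(step$params)
      if (!is.null(step$removed)) {
        step$removed <- as.character(unlist(step$removed))
      }
      step
    })
  }
  new_descriptor_tbl(raw, prov)
}

#' Write an interaction-energy table
#'
#' Header `id,1R9O,5XXI,MD1,MD2,MD3,MD4,MD5`; kcal/mol.
#'
#' @param profiles IE tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ie_table <- function(profiles, path) {
  readr::write_csv(profiles[, c("id", cyp_conformations())], path)
  invisible(path)
}

#' Read molecules from a SMILES or SDF file
#'
#' SMILES files hold one molecule per line (`SMILES [id]`, whitespace
#' separated; missing ids are numbered). SDF files are parsed with
#' ChemmineR and ids taken from the molecule title block.
#'
#' @param path File path; format chosen by extension (`.smi`/`.smiles`
#'   vs `.sdf`).
#' @return Tibble `id`, `smiles`.
#' @export
read_molecules <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("smi", "smiles", "txt")) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "\\s+")
    tibble::tibble(
      id = purrr::imap_chr(parts, ~ if (length(.x) > 1) .x[[2]] else sprintf("mol%04d", .y)),
      smiles = purrr::map_chr(parts, 1)
    )
  } else if (ext == "sdf") {
    sdf <- ChemmineR::read.SDFset(path)
    ids <- ChemmineR::sdfid(sdf)
    smi <- ChemmineR::sdf2smiles(sdf)
    tibble::tibble(id = as.character(ids), smiles = as.character(smi))
  } else {
    abort(sprintf("unsupported molecule file extension '%s'.", ext))
  }
}
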