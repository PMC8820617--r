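## Seeded synthetic fixtures: descriptor tables with planted class
## signal, matched interaction-energy profiles, and a small embedded
## molecule set, so the whole pipeline is testable with no downloads.

#' Specification for a synthetic two-class benchmark
#'
#' Describes the statistical structure the pipeline assumes in real
#' data: a handful of class-separating descriptors buried in noise, and
#' actives whose docking interaction energies are shifted toward more
#' negative (stronger) values.
#'
#' @param n_active,n_inactive Class sizes.
#' @param n_informative Number of planted class-separating descriptors.
#' @param n_noise Number of pure-noise descriptors.
#' @param effect_size Standardized mean class separation per informative
#'   descriptor (class means at +/- effect_size/2, unit variance).
#' @param ie_active_mean,ie_inactive_mean Per-conformation mean
#'   interaction energy (kcal/mol) for actives / inactives.
#' @param ie_sd Interaction-energy standard deviation (kcal/mol).
#' @param ie_cor Between-conformation correlation of a molecule's
#'   interaction energies (compound symmetry; default 0, independent).
#' @param seed Integer seed; all fixture randomness flows through it.
#' @return A `fixture_spec` list.
#' @export
#' @examples
#' fixture_spec(n_active = 50, n_inactive = 50, effect_size = 3)
fixture_spec <- function(n_active = 300, n_inactive = 300,
                         n_informative = 5, n_noise = 100,
                         effect_size = 1.5,
                         ie_active_mean = -9.5, ie_inactive_mean = -7.0,
                         ie_sd = 1.0, ie_cor = 0, seed = 2022) {
  stopifnot(
    n_active >= 0, n_inactive >= 0, n_informative >= 0, n_noise >= 0,
    effect_size >= 0, ie_sd > 0, ie_cor >= 0, ie_cor < 1
  )
  structure(
    list(
      n_active = as.integer(n_active), n_inactive = as.integer(n_inactive),
      n_informative = as.integer(n_informative), n_noise = as.integer(n_noise),
      effect_size = effect_size,
      ie_active_mean = ie_active_mean, ie_inactive_mean = ie_inactive_mean,
      ie_sd = ie_sd, ie_cor = ie_cor, seed = as.integer(seed)
    ),
    class = "fixture_spec"
  )
}

#' Generate a two-class descriptor table with planted signal
#'
#' Informative columns are drawn Normal(+effect_size/2, 1) for actives
#' and Normal(-effect_size/2, 1) for inactives; noise columns are
#' standard normal for everyone. Column names mark the planted ground
#' truth (`inf.*`, `noise.*`).
#'
#' @param spec A [fixture_spec()].
#' @return List with `matrix` (tibble: `id` then descriptor columns) and
#'   `labels` (factor named by id, levels [cyp_labels()]).
#' @export
#' @examples
#' fx <- gen_descriptor_table(fixture_spec(n_active = 20, n_inactive = 20))
#' dim(fx$matrix)
gen_descriptor_table <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_active + spec$n_inactive
  p <- spec$n_informative + spec$n_noise
  if (n < 4L) abort("degenerate spec: need at least 4 molecules.")
  if (p < 1L) abort("degenerate spec: need at least 1 descriptor.")
  withr_seed <- derive_seed(spec$seed, 0L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(withr_seed)
  ids <- sprintf("mol%04d", seq_len(n))
  labels <- factor(
    rep(cyp_labels(), c(spec$n_active, spec$n_inactive)),
    levels = cyp_labels()
  )
  names(labels) <- ids
  shift <- ifelse(labels == "inhibitor", spec$effect_size / 2, -spec$effect_size / 2)
  cols <- c(
    if (spec$n_informative > 0) paste0("inf.", seq_len(spec$n_informative)),
    if (spec$n_noise > 0) paste0("noise.", seq_len(spec$n_noise))
  )
  x <- matrix(rnorm(n * p), n, p, dimnames = list(ids, cols))
  if (spec$n_informative > 0) {
    x[, seq_len(spec$n_informative)] <- x[, seq_len(spec$n_informative)] + shift
  }
  mat <- dplyr::bind_cols(tibble::tibble(id = ids), tibble::as_tibble(x))
  list(matrix = new_descriptor_tbl(mat), labels = labels)
}

#' Generate matched interaction-energy profiles
#'
#' Active molecules get per-conformation scores from
#' Normal(`ie_active_mean`, `ie_sd`), inactives from
#' Normal(`ie_inactive_mean`, `ie_sd`); a compound-symmetry correlation
#' across the seven conformations is available via `spec$ie_cor`
#' (default 0, independent). All profiles are complete.
#'
#' @param ids Unique molecule ids.
#' @param labels Factor/character vector of class labels aligned with
#'   `ids`.
#' @param spec A [fixture_spec()].
#' @return IE tibble: `id` plus one kcal/mol column per conformation in
#'   [cyp_conformations()].
#' @export
gen_ie_profiles <- function(ids, labels, spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (anyDuplicated(ids)) abort("ids must be unique.")
  if (length(ids) != length(labels)) abort("id/label length mismatch.")
  confs <- cyp_conformations()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(spec$seed, 7L))
  n <- length(ids)
  mu <- ifelse(as.character(labels) == "inhibitor",
    spec$ie_active_mean, spec$ie_inactive_mean
  )
  rho <- spec$ie_cor
  shared <- rnorm(n)
  scores <- sapply(confs, function(cf) {
    eps <- rnorm(n)
    mu + spec$ie_sd * (sqrt(rho) * shared + sqrt(1 - rho) * eps)
  })
  out <- dplyr::bind_cols(
    tibble::tibble(id = ids),
    tibble::as_tibble(matrix(scores, n, length(confs), dimnames = list(NULL, confs)))
  )
  out
}

#' Embedded drug-like molecule set for tests and demos
#'
#' Returns a fixed table of diverse, public-domain drug-like structures
#' spanning the default soft-filter bounds, plus two deliberately
#' out-of-bounds molecules (`big_polyether`, oversized with an excess
#' of H-bond acceptors; `long_alkane`,
#' over-lipophilic with an excess of rotatable bonds) and one invalid
#' SMILES (`bad_smiles`) for negative tests. The table is a constant:
#' repeated calls return byte-identical values.
#'
#' @return Tibble with `id` and `smiles`.
#' @export
#' @examples
#' nrow(fixture_molecules())
fixture_molecules <- function() {
  tibble::tribble(
    ~id, ~smiles,
    "aspirin", "CC(=O)Oc1ccccc1C(=O)O",
    "paracetamol", "CC(=O)Nc1ccc(O)cc1",
    "ibuprofen", "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
    "naproxen", "COc1ccc2cc(ccc2c1)C(C)C(=O)O",
    "caffeine", "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
    "theophylline", "Cn1c2c(c(=O)n(C)c1=O)[nH]cn2",
    "nicotine", "CN1CCCC1c1cccnc1",
    "warfarin", "CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O",
    "diclofenac", "OC(=O)Cc1ccccc1Nc1c(Cl)cccc1Cl",
    "flurbiprofen", "CC(C(=O)O)c1ccc(c(c1)F)-c1ccccc1",
    "celecoxib", "Cc1ccc(cc1)-c1cc(nn1-c1ccc(cc1)S(N)(=O)=O)C(F)(F)F",
    "sulfamethoxazole", "Cc1cc(no1)NS(=O)(=O)c1ccc(N)cc1",
    "trimethoprim", "COc1cc(Cc2cnc(N)nc2N)cc(OC)c1OC",
    "metronidazole", "Cc1ncc(n1CCO)[N+](=O)[O-]",
    "fluconazole", "OC(Cn1cncn1)(Cn1cncn1)c1ccc(F)cc1F",
    "omeprazole", "COc1ccc2[nH]c(nc2c1)S(=O)Cc1ncc(C)c(OC)c1C",
    "lansoprazole", "Cc1c(OCC(F)(F)F)ccnc1CS(=O)c1nc2ccccc2[nH]1",
    "cimetidine", "CC1=C(N=CN1)CSCCNC(=NC)NC#N",
    "ranitidine", "CNC(=C[N+](=O)[O-])NCCSCc1ccc(CN(C)C)o1",
    "propranolol", "CC(C)NCC(O)COc1cccc2ccccc12",
    "atenolol", "CC(C)NCC(O)COc1ccc(CC(N)=O)cc1",
    "metoprolol", "CC(C)NCC(O)COc1ccc(CCOC)cc1",
    "lidocaine", "CCN(CC)CC(=O)Nc1c(C)cccc1C",
    "procaine", "CCN(CC)CCOC(=O)c1ccc(N)cc1",
    "benzocaine", "CCOC(=O)c1ccc(N)cc1",
    "diazepam", "CN1c2ccc(Cl)cc2C(=NCC1=O)c1ccccc1",
    "oxazepam", "OC1N=C(c2ccccc2)c2cc(Cl)ccc2NC1=O",
    "phenytoin", "O=C1NC(=O)C(N1)(c1ccccc1)c1ccccc1",
    "carbamazepine", "NC(=O)N1c2ccccc2C=Cc2ccccc21",
    "valproic_acid", "CCCC(CCC)C(=O)O",
    "gabapentin", "NCC1(CC(=O)O)CCCCC1",
    "losartan", "CCCCc1nc(Cl)c(CO)n1Cc1ccc(cc1)-c1ccccc1-c1nnn[nH]1",
    "hydrochlorothiazide", "NS(=O)(=O)c1cc2c(cc1Cl)NCNS2(=O)=O",
    "furosemide", "NS(=O)(=O)c1cc(C(=O)O)c(NCc2ccco2)cc1Cl",
    "allopurinol", "O=c1[nH]cnc2[nH]ncc12",
    "methotrexate_frag", "CN(Cc1cnc2nc(N)nc(N)c2n1)c1ccc(C(=O)O)cc1",
    "quinine", "COc1ccc2nccc(C(O)C3CC4CCN3CC4C=C)c2c1",
    "ketoconazole_frag", "CC(=O)N1CCN(CC1)c1ccc(OC)cc1",
    "sertraline", "CNC1CCC(c2ccc(Cl)c(Cl)c2)c2ccccc12",
    "fluoxetine", "CNCCC(Oc1ccc(cc1)C(F)(F)F)c1ccccc1",
    "amitriptyline", "CN(C)CCC=C1c2ccccc2CCc2ccccc21",
    "haloperidol", "OC1(CCN(CCCC(=O)c2ccc(F)cc2)CC1)c1ccc(Cl)cc1",
    "chlorpromazine", "CN(C)CCCN1c2ccccc2Sc2ccc(Cl)cc21",
    "tamoxifen", "CCC(=C(c1ccccc1)c1ccc(OCCN(C)C)cc1)c1ccccc1",
    "simvastatin_frag", "CCC(C)(C)C(=O)OC1CC(C)C=C2C=CC(C)C(CC[C@@H]3C[C@H](O)CC(=O)O3)C21",
    "big_polyether", paste0(
      "OCCOCCOCCOCCOCCOCCOCCOCCOCCOCCOCCOCCOCCOCCOCCOCCOCCOCCOCCOCCO"
    ),
    "long_alkane", "CCCCCCCCCCCCCCCCCCCCCCCCCCCCCC",
    "bad_smiles", "not_a_molecule"
  )
}

#' Deterministic mock docking scorer
#'
#' Hash-seeded stand-in for a docking engine: maps (molecule,
#' conformation, seed) to a reproducible score uniform on
#' \[-12, -4\] kcal/mol. For tests and demos only; scores carry no
#' physical meaning.
#'
#' @param smiles A single SMILES string (must parse).
#' @param conformation A conformation name from [cyp_conformations()].
#' @param seed Integer seed.
#' @return A single score in kcal/mol.
#' @export
#' @examples
#' mock_docking_scorer("CC(=O)Oc1ccccc1C(=O)O", "1R9O", seed = 1)
mock_docking_scorer <- function(smiles, conformation, seed = 2022) {
  if (!conformation %in% cyp_conformations()) {
    abort(sprintf("unknown conformation '%s'.", conformation))
  }
  parsed <- parse_smiles(tibble::tibble(id = "x", smiles = smiles))
  if (nrow(parsed$rejects) > 0L) abort("invalid structure: SMILES does not parse.")
  h <- str_hash32(paste(smiles, conformation, seed, sep = "|"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(h)
  runif(1, min = -12, max = -4)
}

## Save/restore the global RNG state so generators are seeded without
## disturbing the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
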