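# Fingerprint computation: E-state atom-type counts and SMARTS fragment
# counts per molecule, assembled into the 319-long feature vector that feeds
# the regression network.

#' Assign E-state atom types
#'
#' Classifies every heavy atom of a molecule into at most one Hall-Kier
#' electrotopological atom type (first matching type in vocabulary order
#' wins) and returns the per-type counts. Only the type counts are used as
#' features; the E-state index values themselves are not computed.
#'
#' @param molecule A SMILES string or `fl_mol` from [parse_smiles()].
#' @param registry Registry whose `estate_atom_type` rows define the
#'   vocabulary; default built-in.
#' @return Named integer vector of counts over the atom-type vocabulary,
#'   with attribute `"unmatched"`: the number of heavy atoms outside the
#'   vocabulary (e.g. noble gases).
#' @examples
#' assign_estate_atom_types("CCO")[c("sCH3", "ssCH2", "sOH")]
#' @export
assign_estate_atom_types <- function(molecule, registry = load_registry()) {
  mol <- fl_as_mol(molecule)
  es <- registry[registry$kind == "estate_atom_type", ]
  counts <- fl_classify_atoms(list(mol$ref), es$pattern)[, 1]
  names(counts) <- es$name
  counts <- as.integer(round(counts))
  names(counts) <- es$name
  unmatched <- mol$n_heavy - sum(counts)
  if (unmatched > 0L) {
    message("assign_estate_atom_types: ", unmatched,
            " heavy atom(s) outside the atom-type vocabulary")
  }
  structure(counts, unmatched = unmatched)
}

#' Count substructure matches of a SMARTS pattern
#'
#' Number of distinct substructure matches of `pattern` in the molecule,
#' deduplicated by matched-atom set: symmetry-equivalent mappings onto the
#' same atoms count once (so benzene matches `"c1ccccc1"` once, not 12
#' times).
#'
#' @param molecule A SMILES string or `fl_mol`.
#' @param pattern SMARTS pattern.
#' @return Integer match count.
#' @examples
#' count_fragment("c1ccccc1", "c1ccccc1")  # 1
#' count_fragment("CCO", "[OX2H]")         # 1
#' @export
count_fragment <- function(molecule, pattern) {
  if (!fl_smarts_valid(pattern)) {
    stop("invalid SMARTS pattern: ", pattern, call. = FALSE)
  }
  mol <- fl_as_mol(molecule)
  as.integer(fl_smarts_count(list(mol$ref), pattern, unique_sets = TRUE))
}

fl_featurize_refs <- function(refs, registry) {
  n_mol <- length(refs)
  mat <- matrix(0, nrow = n_mol, ncol = nrow(registry),
                dimnames = list(NULL, registry$name))
  if (n_mol == 0L) {
    return(mat)
  }
  is_es <- registry$kind == "estate_atom_type"
  if (any(is_es)) {
    es_counts <- fl_classify_atoms(refs, registry$pattern[is_es])
    mat[, which(is_es)] <- t(es_counts)
  }
  for (j in which(!is_es)) {
    mat[, j] <- fl_smarts_count(refs, registry$pattern[j], unique_sets = TRUE)
  }
  boolean <- registry$value_mode == "boolean"
  if (any(boolean)) {
    mat[, boolean] <- pmin(mat[, boolean, drop = FALSE], 1)
  }
  mat
}

#' Compute the feature vector of one molecule
#'
#' Fills `estate_atom_type` entries from [assign_estate_atom_types()] and
#' `smarts_fragment` entries from [count_fragment()]; boolean-mode features
#' are clipped to 0/1. Deterministic: the same molecule always yields the
#' same vector.
#'
#' @param molecule A SMILES string or `fl_mol`.
#' @param registry Feature registry (default built-in, 319 features).
#' @return Named numeric vector of length `nrow(registry)` with attribute
#'   `"registry_version"`.
#' @examples
#' v <- featurize("c1ccccc1")
#' length(v)     # 319
#' v[v > 0][1:5]
#' @export
featurize <- function(molecule, registry = load_registry()) {
  mol <- fl_as_mol(molecule)
  v <- fl_featurize_refs(list(mol$ref), registry)[1, ]
  structure(v, registry_version = registry_version(registry))
}

#' Featurize a batch of molecule records
#'
#' Computes the feature matrix for a molecule-record data frame (or a
#' character vector of SMILES). Row order matches the input; molecules that
#' fail to parse are reported in the `failures` element, not silently
#' dropped.
#'
#' @param records Molecule-record data frame (see [molecule_record()]) or a
#'   character vector of SMILES.
#' @param registry Feature registry.
#' @param strip_salt Keep the largest fragment of multi-fragment SMILES.
#' @return A list with `features` (matrix, one row per successfully parsed
#'   record, rownames = record ids), `failures` (data frame of row, id,
#'   smiles, reason) and `row_index` (input row of each feature row).
#' @export
featurize_batch <- function(records, registry = load_registry(),
                            strip_salt = TRUE) {
  if (is.character(records)) {
    records <- data.frame(id = paste0("mol_", seq_along(records)),
                          smiles_raw = records, stringsAsFactors = FALSE)
  }
  n <- nrow(records)
  mols <- vector("list", n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    mols[[i]] <- tryCatch(
      parse_smiles(records$smiles_raw[i], strip_salt = strip_salt),
      error = function(e) {
        reason[i] <<- conditionMessage(e)
        NULL
      }
    )
  }
  ok <- !vapply(mols, is.null, logical(1))
  mat <- fl_featurize_refs(fl_refs(mols[ok]), registry)
  rownames(mat) <- records$id[ok]
  failures <- data.frame(row = which(!ok), id = records$id[!ok],
                         smiles = records$smiles_raw[!ok],
                         reason = reason[!ok], stringsAsFactors = FALSE)
  if (nrow(failures)) {
    message("featurize_batch: ", nrow(failures), " of ", n,
            " molecule(s) failed to parse")
  }
  list(features = mat, failures = failures, row_index = which(ok))
}
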