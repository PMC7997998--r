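# Wildman-Crippen SLogP: the one baseline descriptor recomputed from
# scratch (all other comparison descriptors enter as precomputed columns).
#
# Every heavy atom is assigned to the first contribution class in the
# published table whose pattern it heads; implicit hydrogens are typed by
# their heavy-atom anchor.  The SMARTS engine reports match counts but not
# matched atoms, so per-class counts are recovered by cumulative-union
# counting (see fl_classify_atoms).

# Hydrogen classes of the published table, reformulated as patterns on the
# hydrogen-bearing heavy atom (order preserved; [#1][#1] molecular hydrogen
# is not representable with implicit hydrogens and is out of scope).
FL_WC_H_RULES <- data.frame(
  class = c("H1", "H2", "H2", "H2", "H3", "H3", "H4", "H4", "HS"),
  anchor = c(
    "[#6;!H0]",
    "[O;!H0;$(O[CX4,c])]",
    "[O;!H0;$(O[!#6;!#7;!#8;!#16])]",
    "[!#6;!#7;!#8;!#1;!H0]",
    "[#7;!H0]",
    "[O;!H0;$(O[#7])]",
    "[O;!H0;$(OC=[#6,#7,O,S])]",
    "[O;!H0;$(O[O,S])]",
    "[!#1;!H0]"
  ),
  stringsAsFactors = FALSE
)

fl_load_crippen <- function() {
  if (!is.null(.fl_env$crippen)) {
    return(.fl_env$crippen)
  }
  path <- system.file("extdata", "wildman_crippen_1999.tsv",
                      package = "fraglogp", mustWork = TRUE)
  tab <- fl_read_tsv_hash_safe(path)
  tab$is_h <- startsWith(tab$smarts, "[#1]")
  contrib <- tapply(tab$logp, tab$class, function(x) x[[1]])
  .fl_env$crippen <- list(heavy = tab[!tab$is_h, ],
                          h_contrib = contrib[FL_WC_H_RULES$class])
  .fl_env$crippen
}

#' Wildman-Crippen SLogP
#'
#' Atomic-contribution estimate of the octanol/water partition coefficient:
#' each heavy atom contributes the increment of the first class in the
#' published contribution table (Wildman & Crippen 1999) that matches it,
#' and each implicit hydrogen contributes according to the atom it is
#' attached to. Purely additive and deterministic; two SMILES spellings of
#' the same molecule give the same value.
#'
#' @param molecule A SMILES string or `fl_mol`, or a list/vector of these.
#' @return Numeric SLogP value(s).
#' @examples
#' slogp("c1ccccc1")  # benzene
#' slogp("CCO")
#' @export
slogp <- function(molecule) {
  if (is.character(molecule) && length(molecule) > 1L) {
    mols <- lapply(molecule, parse_smiles)
  } else if (is.list(molecule) && !inherits(molecule, "fl_mol")) {
    mols <- lapply(molecule, fl_as_mol)
  } else {
    mols <- list(fl_as_mol(molecule))
  }
  refs <- fl_refs(mols)
  cr <- fl_load_crippen()
  heavy_counts <- fl_classify_atoms(refs, cr$heavy$smarts)
  typed <- colSums(heavy_counts)
  n_heavy <- vapply(mols, function(m) m$n_heavy, numeric(1))
  if (any(typed < n_heavy)) {
    i <- which(typed < n_heavy)[1]
    stop(n_heavy[i] - typed[i], " heavy atom(s) of '", mols[[i]]$smiles,
         "' match no contribution class", call. = FALSE)
  }
  h_counts <- fl_classify_atoms(refs, FL_WC_H_RULES$anchor, h_weighted = TRUE)
  out <- as.numeric(crossprod(heavy_counts, cr$heavy$logp) +
                      crossprod(h_counts, cr$h_contrib))
  unname(out)
}
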