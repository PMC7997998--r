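# Internal molecule backend built on ChemmineOB (OpenBabel).
#
# Molecules are kept as OpenBabel molecule references (external pointers)
# wrapped in a light "fl_mol" list so that SMARTS evaluation can reuse the
# parsed structure across the hundreds of patterns a featurization touches.

.fl_env <- new.env(parent = emptyenv())

# OpenBabel accepts some malformed strings (e.g. "C(" parses as methane), so
# reject obviously unbalanced input before handing it over.
fl_lexical_ok <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(trimws(smiles))) {
    return(FALSE)
  }
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  depth_paren <- cumsum((chars == "(") - (chars == ")"))
  depth_brack <- cumsum((chars == "[") - (chars == "]"))
  !(any(depth_paren < 0) || any(depth_brack < 0) ||
      utils::tail(depth_paren, 1) != 0L || utils::tail(depth_brack, 1) != 0L)
}

fl_parse_one <- function(smiles) {
  if (!fl_lexical_ok(smiles)) {
    return(NULL)
  }
  refs <- tryCatch(
    suppressWarnings(
      ChemmineOB::forEachMol("SMILES", paste0(smiles, "\n"), identity)
    ),
    error = function(e) NULL
  )
  if (is.null(refs) || length(refs) != 1L) {
    return(NULL)
  }
  n_heavy <- tryCatch(
    as.integer(ChemmineOB::smartsSearch_OB(refs, "[!#1]", uniqueMatches = TRUE)),
    error = function(e) NA_integer_
  )
  if (is.na(n_heavy) || n_heavy < 1L) {
    return(NULL)
  }
  list(ref = refs[[1]], n_heavy = n_heavy)
}

#' Parse a SMILES string into an internal molecule handle
#'
#' Parses with OpenBabel (aromaticity perceived, hydrogens implicit) and
#' optionally keeps only the largest covalent fragment of a multi-fragment
#' SMILES, the usual pre-processing step for salt forms of probes.
#'
#' @param smiles Single SMILES string.
#' @param strip_salt Keep only the largest fragment (by heavy-atom count) of a
#'   dotted multi-fragment SMILES. A message is emitted when stripping occurs.
#' @return An object of class `fl_mol`: a list with elements `smiles_raw`,
#'   `smiles` (the fragment actually parsed), `ref` (OpenBabel molecule
#'   reference) and `n_heavy`.
#' @examples
#' m <- parse_smiles("CCO")
#' m$n_heavy
#' @export
parse_smiles <- function(smiles, strip_salt = TRUE) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  used <- smiles
  if (strip_salt && grepl(".", smiles, fixed = TRUE) && fl_lexical_ok(smiles)) {
    frags <- strsplit(smiles, ".", fixed = TRUE)[[1]]
    frags <- frags[nzchar(frags)]
    sizes <- vapply(frags, function(f) {
      p <- fl_parse_one(f)
      if (is.null(p)) -1L else p$n_heavy
    }, integer(1))
    if (all(sizes < 0L)) {
      stop("unparseable SMILES: ", smiles, call. = FALSE)
    }
    used <- frags[[which.max(sizes)]]
    if (length(frags) > 1L) {
      message("salt stripping: kept largest fragment '", used,
              "' of '", smiles, "'")
    }
  }
  parsed <- fl_parse_one(used)
  if (is.null(parsed)) {
    stop("unparseable SMILES: ", smiles, call. = FALSE)
  }
  structure(
    list(smiles_raw = smiles, smiles = used, ref = parsed$ref,
         n_heavy = parsed$n_heavy),
    class = "fl_mol"
  )
}

fl_as_mol <- function(x, strip_salt = TRUE) {
  if (inherits(x, "fl_mol")) x else parse_smiles(x, strip_salt = strip_salt)
}

fl_refs <- function(mols) {
  lapply(mols, function(m) m$ref)
}

# Count of unique-atom-set SMARTS matches for a list of OBMol references.
fl_smarts_count <- function(refs, pattern, unique_sets = TRUE) {
  res <- tryCatch(
    ChemmineOB::smartsSearch_OB(refs, pattern, uniqueMatches = unique_sets),
    error = function(e) {
      stop("SMARTS evaluation failed for pattern '", pattern, "': ",
           conditionMessage(e), call. = FALSE)
    }
  )
  as.numeric(res)
}

fl_smarts_valid <- function(pattern) {
  if (is.null(.fl_env$probe_ref)) {
    .fl_env$probe_ref <- fl_parse_one("C")$ref
  }
  ok <- tryCatch({
    ChemmineOB::smartsSearch_OB(list(.fl_env$probe_ref), pattern,
                                uniqueMatches = TRUE)
    TRUE
  }, error = function(e) FALSE)
  isTRUE(ok)
}

# First-match-wins single-atom classification over an ordered pattern table.
#
# Each pattern must be interpretable as the environment of its first (head)
# atom.  OpenBabel reports match counts but not matched atom indices, so
# per-class counts are recovered from cumulative counts of the ordered unions
# [$(P1)], [$(P1),$(P2)], ...: the k-th difference is the number of atoms
# whose first matching pattern is P_k.  With `h_weighted = TRUE` the count of
# each class is replaced by the total number of (implicit) hydrogens carried
# by its atoms, obtained by intersecting the unions with exact H-count
# primitives.
fl_classify_atoms <- function(refs, patterns, h_weighted = FALSE,
                              max_h = 4L) {
  n_pat <- length(patterns)
  n_mol <- length(refs)
  counts <- matrix(0, nrow = n_pat, ncol = n_mol)
  terms <- sprintf("$(%s)", patterns)
  if (!h_weighted) {
    prev <- numeric(n_mol)
    for (k in seq_len(n_pat)) {
      union_pat <- paste0("[", paste(terms[seq_len(k)], collapse = ","), "]")
      cum <- fl_smarts_count(refs, union_pat)
      counts[k, ] <- cum - prev
      prev <- cum
    }
  } else {
    prev <- matrix(0, nrow = max_h, ncol = n_mol)
    for (k in seq_len(n_pat)) {
      inner <- paste(terms[seq_len(k)], collapse = ",")
      for (h in seq_len(max_h)) {
        union_pat <- paste0("[", inner, ";H", h, "]")
        cum <- fl_smarts_count(refs, union_pat)
        counts[k, ] <- counts[k, ] + h * (cum - prev[h, ])
        prev[h, ] <- cum
      }
    }
  }
  counts
}

#' Canonicalize SMILES strings
#'
#' Maps any SMILES spelling of a molecule to OpenBabel's canonical form, so
#' that canonical-SMILES equality can serve as the molecular identity key
#' (used e.g. by the train/validation deduplication rule). Canonicalization
#' is idempotent.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES.
#' @examples
#' canonicalize(c("OCC", "CCO"))  # same molecule, one spelling
#' @export
canonicalize <- function(smiles) {
  stopifnot(is.character(smiles))
  vapply(smiles, function(s) {
    if (!fl_lexical_ok(s)) {
      stop("unparseable SMILES: ", s, call. = FALSE)
    }
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", paste0(s, "\n"))),
      error = function(e) ""
    )
    out <- sub("[ \t].*$", "", sub("\n.*$", "", out))
    if (!nzchar(out)) {
      stop("unparseable SMILES: ", s, call. = FALSE)
    }
    out
  }, character(1), USE.NAMES = FALSE)
}
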