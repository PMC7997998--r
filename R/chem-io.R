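# Reading and writing molecule tables (CSV/TSV/.smi/SDF) as molecule-record
# data frames.

FL_LOGP_KINDS <- c("LogP", "LogD", "none")
FL_PERMEABILITY <- c("permeant", "impermeant", "unknown")
FL_SOURCES <- c("opera_train", "opera_valid", "auxiliary", "probe_test", "user")

#' Construct a molecule-record table
#'
#' A molecule record carries an identifier, the raw and canonical SMILES, an
#' optional experimental partition coefficient (LogP, or LogD for ionizable
#' compounds), an optional permeability label, and a provenance tag.
#'
#' @param id Character identifiers.
#' @param smiles Raw SMILES strings.
#' @param exp_logp Experimental LogP/LogD values (`NA` if absent).
#' @param logp_kind One of `"LogP"`, `"LogD"`, `"none"` per record.
#' @param permeability One of `"permeant"`, `"impermeant"`, `"unknown"`.
#' @param source Provenance: `"opera_train"`, `"opera_valid"`, `"auxiliary"`,
#'   `"probe_test"` or `"user"`.
#' @param canonical Pre-computed canonical SMILES; computed when `NULL`.
#' @return A `data.frame` with columns `id`, `smiles_raw`, `smiles_canonical`,
#'   `exp_logp`, `logp_kind`, `permeability`, `source`.
#' @export
molecule_record <- function(id, smiles, exp_logp = NA_real_,
                            logp_kind = "none", permeability = "unknown",
                            source = "user", canonical = NULL) {
  n <- length(smiles)
  id <- as.character(rep_len(id, n))
  exp_logp <- as.numeric(rep_len(exp_logp, n))
  logp_kind <- rep_len(as.character(logp_kind), n)
  permeability <- rep_len(as.character(permeability), n)
  source <- rep_len(as.character(source), n)
  check_enum <- function(x, choices, what) {
    bad <- !x %in% choices
    if (any(bad)) {
      stop("invalid ", what, ": ", paste(unique(x[bad]), collapse = ", "),
           call. = FALSE)
    }
    x
  }
  logp_kind <- check_enum(logp_kind, FL_LOGP_KINDS, "logp_kind")
  permeability <- check_enum(permeability, FL_PERMEABILITY, "permeability")
  source <- check_enum(source, FL_SOURCES, "source")
  if (is.null(canonical)) {
    canonical <- canonicalize(smiles)
  }
  data.frame(
    id = id, smiles_raw = as.character(smiles),
    smiles_canonical = as.character(canonical),
    exp_logp = exp_logp,
    logp_kind = rep_len(logp_kind, n),
    permeability = rep_len(permeability, n),
    source = rep_len(source, n),
    stringsAsFactors = FALSE
  )
}

fl_read_raw_table <- function(path, format) {
  switch(format,
    csv = utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE),
    tsv = utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE),
    smi = {
      lines <- readLines(path, warn = FALSE)
      lines <- lines[nzchar(trimws(lines))]
      parts <- strsplit(trimws(lines), "[ \t]+")
      data.frame(
        smiles = vapply(parts, `[`, character(1), 1L),
        id = vapply(parts, function(p) {
          if (length(p) >= 2L) p[[2]] else NA_character_
        }, character(1)),
        stringsAsFactors = FALSE
      )
    },
    sdf = {
      sdfset <- ChemmineR::read.SDFset(path)
      smi <- as.character(ChemmineR::sdf2smiles(sdfset))
      data.frame(smiles = smi, id = ChemmineR::sdfid(sdfset),
                 stringsAsFactors = FALSE)
    },
    stop("unsupported format: ", format, call. = FALSE)
  )
}

#' Read a molecule table from CSV/TSV/.smi/SDF
#'
#' Loads a tabular molecule file into a molecule-record data frame,
#' canonicalizing SMILES on the way in. Rows whose SMILES do not parse are
#' skipped (lenient mode, default) or abort the read (`strict = TRUE`); the
#' number of records and skips is reported via [message()].
#'
#' @param path File path.
#' @param format `"csv"`, `"tsv"`, `"smi"` or `"sdf"`. `.smi` files are
#'   whitespace-delimited SMILES-then-identifier.
#' @param column_map Named list mapping record fields to column names in the
#'   file, e.g. `list(id = "Name", smiles = "SMILES", permeability = "label",
#'   exp_logp = "logp_exp", logp_kind = "kind")`. Only `smiles` is required
#'   for CSV/TSV; `.smi`/SDF inputs ignore it.
#' @param strict Abort on the first unparseable SMILES instead of skipping.
#' @param source Provenance tag stored on every record.
#' @return Molecule-record `data.frame` (see [molecule_record()]) with an
#'   attribute `"skipped"`: a data frame of row numbers, offending SMILES and
#'   reasons.
#' @export
read_molecule_table <- function(path, format = c("csv", "tsv", "smi", "sdf"),
                                column_map = list(id = "id", smiles = "smiles"),
                                strict = FALSE, source = "user") {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  raw <- fl_read_raw_table(path, format)
  if (format %in% c("csv", "tsv")) {
    needed <- unlist(column_map[!vapply(column_map, is.null, logical(1))])
    missing_cols <- setdiff(needed, names(raw))
    if (length(missing_cols)) {
      stop("mapped column(s) not in file: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    get_col <- function(field, default) {
      if (!is.null(column_map[[field]])) raw[[column_map[[field]]]] else default
    }
    smiles <- as.character(get_col("smiles", stop("column_map$smiles required",
                                                  call. = FALSE)))
    ids <- as.character(get_col("id", paste0("mol_", seq_len(nrow(raw)))))
    exp_logp <- suppressWarnings(as.numeric(get_col("exp_logp",
                                                    rep(NA_real_, nrow(raw)))))
    logp_kind <- as.character(get_col("logp_kind",
                                      ifelse(is.na(exp_logp), "none", "LogP")))
    permeability <- as.character(get_col("permeability",
                                         rep("unknown", nrow(raw))))
  } else {
    smiles <- raw$smiles
    ids <- ifelse(is.na(raw$id) | !nzchar(raw$id),
                  paste0("mol_", seq_len(nrow(raw))), raw$id)
    exp_logp <- rep(NA_real_, nrow(raw))
    logp_kind <- rep("none", nrow(raw))
    permeability <- rep("unknown", nrow(raw))
  }
  permeability[is.na(permeability) | !nzchar(permeability)] <- "unknown"
  permeability <- tolower(permeability)
  bad_label <- !permeability %in% FL_PERMEABILITY
  if (any(bad_label)) {
    stop("unrecognized permeability label(s): ",
         paste(unique(permeability[bad_label]), collapse = ", "),
         call. = FALSE)
  }
  logp_kind[is.na(logp_kind) | !nzchar(logp_kind)] <- "none"

  canonical <- rep(NA_character_, length(smiles))
  reason <- rep(NA_character_, length(smiles))
  for (i in seq_along(smiles)) {
    canonical[i] <- tryCatch(canonicalize(smiles[i]), error = function(e) {
      reason[i] <<- conditionMessage(e)
      NA_character_
    })
  }
  bad <- is.na(canonical)
  if (strict && any(bad)) {
    first <- which(bad)[1]
    stop("row ", first, ": ", reason[first], call. = FALSE)
  }
  skipped <- data.frame(row = which(bad), smiles = smiles[bad],
                        reason = reason[bad], stringsAsFactors = FALSE)
  keep <- !bad
  records <- molecule_record(
    id = ids[keep], smiles = smiles[keep], exp_logp = exp_logp[keep],
    logp_kind = logp_kind[keep], permeability = permeability[keep],
    source = source, canonical = canonical[keep]
  )
  message("read_molecule_table: ", nrow(records), " record(s), ",
          nrow(skipped), " skipped")
  attr(records, "skipped") <- skipped
  records
}

#' Write a prediction table
#'
#' Writes the fixed output schema `id, smiles, deepfl_logp,
#' predicted_permeability` as CSV, preserving row order.
#'
#' @param records Molecule-record data frame.
#' @param predictions Numeric LogP predictions, one per record.
#' @param labels Predicted permeability classes, one per record.
#' @param path Output CSV path.
#' @return Invisibly, the written data frame.
#' @export
write_prediction_table <- function(records, predictions, labels, path) {
  if (nrow(records) != length(predictions) ||
      nrow(records) != length(labels)) {
    stop("records, predictions and labels must have equal length",
         call. = FALSE)
  }
  out <- data.frame(
    id = records$id,
    smiles = records$smiles_raw,
    deepfl_logp = as.numeric(predictions),
    predicted_permeability = as.character(labels),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(out)
}
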