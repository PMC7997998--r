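# Training/validation set assembly: reference training data plus auxiliary
# molecules, with the rule that an auxiliary molecule already present in the
# validation set is removed from validation (never from training), so the
# two splits stay disjoint by canonical SMILES.

#' Assemble the training/validation split
#'
#' `train = opera_train + auxiliary`; any validation record whose canonical
#' SMILES also occurs among the auxiliary molecules is dropped from the
#' validation set. Duplicates *within* a source table are left untouched.
#' Every record must carry an experimental LogP/LogD value.
#'
#' @param opera_train,opera_valid Molecule-record data frames of the
#'   experimental-LogP reference collection (user-supplied files; see
#'   [read_molecule_table()]).
#' @param auxiliary Molecule-record data frame of additional molecules
#'   appended to the training set (`source` is forced to `"auxiliary"`).
#' @param n_bins Histogram bins for the per-split distribution summaries.
#' @return A list of class `fl_dataset_split`: `train`, `valid` (record
#'   data frames), `provenance_counts`, `removed` (the deduplicated
#'   validation records, with both SMILES spellings), and `stats` (per-split
#'   [distribution_stats()] of the experimental values).
#' @export
assemble_split <- function(opera_train, opera_valid, auxiliary = NULL,
                           n_bins = 20L) {
  if (is.null(auxiliary)) {
    auxiliary <- opera_train[0, ]
  }
  for (nm in c("opera_train", "opera_valid", "auxiliary")) {
    tab <- get(nm)
    if (nrow(tab) && anyNA(tab$exp_logp)) {
      stop(nm, " contains record(s) without an experimental LogP value",
           call. = FALSE)
    }
  }
  if (nrow(opera_train)) opera_train$source <- "opera_train"
  if (nrow(opera_valid)) opera_valid$source <- "opera_valid"
  if (nrow(auxiliary)) auxiliary$source <- "auxiliary"
  train <- rbind(opera_train, auxiliary)
  dup <- opera_valid$smiles_canonical %in% auxiliary$smiles_canonical
  removed <- opera_valid[dup, , drop = FALSE]
  if (nrow(removed)) {
    message("assemble_split: removed ", nrow(removed), " validation ",
            "record(s) that also occur among the auxiliary molecules")
  }
  valid <- opera_valid[!dup, , drop = FALSE]
  overlap <- intersect(train$smiles_canonical, valid$smiles_canonical)
  structure(
    list(
      train = train, valid = valid,
      provenance_counts = c(
        opera_train = nrow(opera_train),
        auxiliary = nrow(auxiliary),
        opera_valid = nrow(valid),
        removed_from_valid = nrow(removed)
      ),
      removed = removed,
      residual_overlap = overlap,
      stats = list(
        train = if (nrow(train)) distribution_stats(train$exp_logp, n_bins),
        valid = if (nrow(valid)) distribution_stats(valid$exp_logp, n_bins)
      )
    ),
    class = "fl_dataset_split"
  )
}

#' Descriptive statistics with a histogram
#'
#' Mean, min, max and an equal-width histogram over `[min, max]` -- the
#' summary used to compare the LogP distributions of the training and
#' validation sets.
#'
#' @param values Non-empty numeric vector.
#' @param n_bins Number of equal-width bins.
#' @return List of class `fl_distribution_stats`: `n`, `mean`, `min`,
#'   `max`, and `histogram` (data frame `bin_low`, `bin_high`, `count`).
#' @export
distribution_stats <- function(values, n_bins = 20L) {
  values <- as.numeric(values)
  if (!length(values) || anyNA(values)) {
    stop("values must be non-empty and free of NA", call. = FALSE)
  }
  lo <- min(values)
  hi <- max(values)
  if (lo == hi) {
    histogram <- data.frame(bin_low = lo, bin_high = hi,
                            count = length(values))
  } else {
    edges <- seq(lo, hi, length.out = n_bins + 1L)
    h <- graphics::hist(values, breaks = edges, plot = FALSE,
                        include.lowest = TRUE, right = TRUE)
    histogram <- data.frame(bin_low = utils::head(edges, -1L),
                            bin_high = edges[-1L], count = h$counts)
  }
  structure(
    list(n = length(values), mean = mean(values), min = lo, max = hi,
         histogram = histogram),
    class = "fl_distribution_stats"
  )
}
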