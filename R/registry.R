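# The feature registry: the ordered vocabulary of fingerprint features.
#
# The registry is data, not code: a TSV with one row per feature
# (index, name, kind, pattern, value_mode).  The built-in default combines
# the 79 Hall-Kier E-state atom types with a 240-fragment SMARTS vocabulary,
# 319 features in total -- the input width of the regression network.

FL_DEFAULT_REGISTRY_SIZE <- 319L
FL_FEATURE_KINDS <- c("estate_atom_type", "smarts_fragment")
FL_VALUE_MODES <- c("count", "boolean")

#' Load a feature registry
#'
#' Reads an ordered feature-definition table and validates it: unique names,
#' contiguous 0-based indices, known kinds/value modes, and (optionally)
#' that every SMARTS pattern compiles. The built-in default registry has
#' exactly 319 features.
#'
#' @param path Path to a registry TSV, or `NULL` for the built-in default.
#' @param validate_patterns Compile-check every pattern against the SMARTS
#'   engine (adds about a second for the full default registry).
#' @return A `data.frame` of class `fl_registry` with columns `index`,
#'   `name`, `kind`, `pattern`, `value_mode` and attribute `version`.
#' @examples
#' reg <- load_registry()
#' nrow(reg)  # 319
#' @export
load_registry <- function(path = NULL, validate_patterns = TRUE) {
  default <- is.null(path)
  if (default) {
    if (!is.null(.fl_env$default_registry)) {
      return(.fl_env$default_registry)
    }
    path <- system.file("extdata", "feature_registry.tsv",
                        package = "fraglogp", mustWork = TRUE)
  }
  reg <- fl_read_tsv_hash_safe(path)
  required <- c("index", "name", "kind", "pattern", "value_mode")
  if (!all(required %in% names(reg))) {
    stop("registry file must have columns: ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  dup <- reg$name[duplicated(reg$name)]
  if (length(dup)) {
    stop("duplicate feature name(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (!identical(as.integer(reg$index), seq_len(nrow(reg)) - 1L)) {
    stop("feature indices must be contiguous from 0", call. = FALSE)
  }
  bad_kind <- setdiff(unique(reg$kind), FL_FEATURE_KINDS)
  if (length(bad_kind)) {
    stop("unknown feature kind(s): ", paste(bad_kind, collapse = ", "),
         call. = FALSE)
  }
  bad_mode <- setdiff(unique(reg$value_mode), FL_VALUE_MODES)
  if (length(bad_mode)) {
    stop("unknown value_mode(s): ", paste(bad_mode, collapse = ", "),
         call. = FALSE)
  }
  if (default && nrow(reg) != FL_DEFAULT_REGISTRY_SIZE) {
    stop("default registry must have exactly ", FL_DEFAULT_REGISTRY_SIZE,
         " features, found ", nrow(reg), call. = FALSE)
  }
  if (validate_patterns) {
    eval_pattern <- ifelse(reg$kind == "estate_atom_type",
                           sprintf("[$(%s)]", reg$pattern), reg$pattern)
    ok <- vapply(eval_pattern, fl_smarts_valid, logical(1))
    if (any(!ok)) {
      stop("invalid SMARTS pattern(s) for feature(s): ",
           paste(reg$name[!ok], collapse = ", "), call. = FALSE)
    }
  }
  attr(reg, "version") <- if (default) "fraglogp-default-1.0" else
    paste0("custom-", basename(path))
  class(reg) <- c("fl_registry", "data.frame")
  if (default) {
    .fl_env$default_registry <- reg
  }
  reg
}

#' Save a feature registry
#'
#' Writes a registry back to TSV; `load_registry()` on the result reproduces
#' order, names and patterns exactly.
#'
#' @param registry An `fl_registry`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
save_registry <- function(registry, path) {
  stopifnot(inherits(registry, "fl_registry"))
  utils::write.table(as.data.frame(registry), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

registry_version <- function(registry) {
  v <- attr(registry, "version")
  if (is.null(v)) "unversioned" else v
}
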