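# Synthetic data generators: download-free stand-ins with known ground
# truth, so the featurize -> train -> classify pipeline is testable end to
# end.  Regression sets are generated directly in feature space (exact
# linear ground truth); probe sets emulate a labelled test panel whose two
# classes have Gaussian descriptor distributions on either side of the
# permeability threshold.

#' Generate a synthetic LogP regression dataset
#'
#' Integer count features are drawn per molecule from a truncated Poisson
#' (emulating sparse fragment counts), and the target is an exact sparse
#' linear function of the features plus Gaussian noise:
#' `y = X w + N(0, noise_sd)`. The true weight vector is returned so
#' parameter-recovery tests have an oracle. With the defaults the targets
#' span a realistic partition-coefficient range (roughly -4 to 8, s.d.
#' about 1.8).
#'
#' @param n Number of molecules.
#' @param n_features Feature-space width (default 319, the registry size).
#' @param k Number of nonzero entries of the true weight vector.
#' @param weights Optional explicit weight vector (length `n_features`),
#'   overriding the sparse random draw.
#' @param noise_sd Gaussian noise standard deviation on the target.
#' @param feature_count_range Inclusive integer bounds for the counts.
#' @param poisson_mean Mean of the (pre-truncation) Poisson counts.
#' @param seed Integer seed; the same spec and seed give an identical
#'   dataset.
#' @return List: `features` (n x n_features integer matrix), `targets`
#'   (length n), `truth` (the weight vector used).
#' @export
generate_regression_set <- function(n, n_features = 319L, k = 20L,
                                    weights = NULL, noise_sd = 0.1,
                                    feature_count_range = c(0L, 4L),
                                    poisson_mean = 1, seed = 1L) {
  stopifnot(n >= 1, n_features >= 1, noise_sd >= 0,
            length(feature_count_range) == 2L,
            feature_count_range[1] <= feature_count_range[2])
  fl_with_seed(seed, {
    if (is.null(weights)) {
      stopifnot(k >= 1, k <= n_features)
      weights <- numeric(n_features)
      weights[sample.int(n_features, k)] <- stats::rnorm(k, 0, 0.4)
    } else {
      stopifnot(length(weights) == n_features)
    }
    counts <- stats::rpois(n * n_features, poisson_mean)
    counts <- pmin(pmax(counts, feature_count_range[1]),
                   feature_count_range[2])
    X <- matrix(as.integer(counts), nrow = n, ncol = n_features,
                dimnames = list(NULL, paste0("f", seq_len(n_features))))
    y <- as.numeric(X %*% weights)
    if (noise_sd > 0) {
      y <- y + stats::rnorm(n, 0, noise_sd)
    }
    list(features = X, targets = y, truth = weights)
  })
}

#' Generate a synthetic labelled probe panel
#'
#' Emulates a curated test set of fluorescent probes: descriptor values of
#' the permeant class are drawn from `N(1 + separation, 1)` and of the
#' impermeant class from `N(1 - separation, 1)`, so the two classes sit
#' symmetric around the LogP >= 1 decision threshold. An optional fraction
#' of labels is flipped to emulate curation noise. Rows also carry simple
#' generated SMILES so table-parsing code paths can run on the output.
#'
#' The default class sizes mirror a 99 permeant / 25 impermeant panel and
#' the default separation of 1.75 puts about 96% of each class on its
#' correct side of the threshold.
#'
#' @param n_permeant,n_impermeant Class sizes (>= 1).
#' @param separation Class mean offset from the threshold, in s.d. units.
#' @param label_noise Fraction of labels flipped, in `[0, 1)`.
#' @param seed Integer seed.
#' @return A `data.frame`: `id`, `smiles`, `descriptor` (the synthetic LogP
#'   value), `permeability` (the possibly noisy label), `true_class`.
#' @export
generate_probe_set <- function(n_permeant = 99L, n_impermeant = 25L,
                               separation = 1.75, label_noise = 0,
                               seed = 1L) {
  stopifnot(n_permeant >= 1, n_impermeant >= 1,
            label_noise >= 0, label_noise < 1)
  fl_with_seed(seed, {
    n <- n_permeant + n_impermeant
    true_class <- c(rep("permeant", n_permeant),
                    rep("impermeant", n_impermeant))
    descriptor <- c(stats::rnorm(n_permeant, 1 + separation, 1),
                    stats::rnorm(n_impermeant, 1 - separation, 1))
    labels <- true_class
    if (label_noise > 0) {
      flip <- stats::runif(n) < label_noise
      labels[flip] <- ifelse(true_class[flip] == "permeant",
                             "impermeant", "permeant")
    }
    # simple valid alkane/alcohol/arene SMILES so parsing paths can run
    motif <- sample(3L, n, replace = TRUE)
    len <- sample(1:6, n, replace = TRUE)
    smiles <- vapply(seq_len(n), function(i) {
      switch(motif[i],
             strrep("C", len[i] + 1L),
             paste0(strrep("C", len[i]), "O"),
             paste0("c1ccccc1", strrep("C", len[i])))
    }, character(1))
    data.frame(
      id = sprintf("probe_%03d", seq_len(n)),
      smiles = smiles,
      descriptor = descriptor,
      permeability = labels,
      true_class = true_class,
      stringsAsFactors = FALSE
    )
  })
}
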