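# Feature-vector assembly: fingerprint bits first, min-max scaled descriptors
# second, with an explicit layout map. Scaling statistics always come from the
# training partition; test-time values outside the training range are clipped
# into [0, 1] so every entry is a valid grayscale intensity.

#' Ablation feature strategies
#'
#' The five feature configurations of the ablation harness: descriptor panels
#' of size 3, 6 or 12, the fingerprint alone, or fingerprint plus the full
#' descriptor panel.
#' @export
FEATURE_STRATEGIES <- c("D3", "D6", "D12", "MORGAN", "MORGAN_D12")

strategy_components <- function(strategy) {
  strategy <- match.arg(strategy, FEATURE_STRATEGIES)
  list(
    use_fp = strategy %in% c("MORGAN", "MORGAN_D12"),
    descriptor_set = switch(strategy, D3 = "D3", D6 = "D6", D12 = "D12",
                            MORGAN = NULL, MORGAN_D12 = "D12")
  )
}

#' Fit per-descriptor min-max scaling statistics
#'
#' @param desc_matrix Numeric matrix, one row per (training) molecule, one
#'   column per descriptor.
#' @return A list with `min` and `max` named vectors. Constant columns get a
#'   unit range so they scale to 0 rather than NaN.
#' @export
fit_descriptor_scaling <- function(desc_matrix) {
  stopifnot(is.matrix(desc_matrix), nrow(desc_matrix) >= 1)
  mins <- apply(desc_matrix, 2, min)
  maxs <- apply(desc_matrix, 2, max)
  degenerate <- maxs - mins <= 0
  maxs[degenerate] <- mins[degenerate] + 1
  list(min = mins, max = maxs)
}

scale_descriptors <- function(values, scaling) {
  scaled <- (values - scaling$min) / (scaling$max - scaling$min)
  pmin(pmax(scaled, 0), 1)
}

#' Merge fingerprint and descriptors into a feature vector
#'
#' Concatenates the fingerprint bit segment (first) and the min-max scaled
#' descriptor segment (second). Descriptor scaling statistics must have been
#' fitted on training data only; out-of-range values are clipped to [0, 1].
#'
#' @param fp A `fingerprint_vector` or NULL.
#' @param desc A `descriptor_vector` or NULL.
#' @param scaling Per-descriptor scaling from [fit_descriptor_scaling()]
#'   (required when `desc` is given).
#' @return An object of class `feature_vector`: list with `values` (numeric in
#'   [0, 1]), `layout` (data.frame: start, end, segment) and `scaling`.
#' @export
build_feature_vector <- function(fp = NULL, desc = NULL, scaling = NULL) {
  if (is.null(fp) && is.null(desc)) {
    stop(ddimage_config_error(
      "build_feature_vector needs at least one of fingerprint/descriptors"))
  }
  values <- numeric(0)
  layout <- data.frame(start = integer(0), end = integer(0),
                       segment = character(0))
  if (!is.null(fp)) {
    stopifnot(inherits(fp, "fingerprint_vector"))
    values <- c(values, as.numeric(fp$bits))
    layout <- rbind(layout, data.frame(start = 1L, end = fp$n_bits,
                                       segment = "fp"))
  }
  if (!is.null(desc)) {
    stopifnot(inherits(desc, "descriptor_vector"))
    if (is.null(scaling)) {
      stop(ddimage_config_error(
        "descriptor segment requires training-partition scaling statistics"))
    }
    scaled <- scale_descriptors(desc$values, scaling)
    off <- length(values)
    values <- c(values, unname(scaled))
    layout <- rbind(layout, data.frame(start = off + 1L,
                                       end = off + length(scaled),
                                       segment = "desc"))
  }
  structure(list(values = values, layout = layout, scaling = scaling),
            class = "feature_vector")
}

ddimage_config_error <- function(message) {
  structure(class = c("ddimage_config_error", "ddimage_error",
                      "error", "condition"),
            list(message = message, call = NULL))
}

# -- batch featurization -----------------------------------------------------

#' Fit a featurizer on the training drugs
#'
#' Computes fingerprints/descriptors for all molecules and fits descriptor
#' scaling on the subset named in `train_ids` only, so no test-set statistics
#' leak into the features.
#'
#' @param mols Named list of `mol_record` (names are drug ids).
#' @param strategy One of [FEATURE_STRATEGIES].
#' @param train_ids Drug ids forming the training set (defaults to all).
#' @param radius,n_bits Fingerprint parameters.
#' @return A `featurizer` object; apply with [featurize_drugs()].
#' @export
fit_featurizer <- function(mols, strategy, train_ids = names(mols),
                           radius = 2L, n_bits = 2048L) {
  comp <- strategy_components(strategy)
  scaling <- NULL
  if (!is.null(comp$descriptor_set)) {
    train_ids <- intersect(train_ids, names(mols))
    stopifnot(length(train_ids) >= 1)
    dm <- t(vapply(mols[train_ids], function(m)
      descriptors(m, comp$descriptor_set)$values,
      numeric(length(switch(comp$descriptor_set, D3 = 1:3, D6 = 1:6,
                            D12 = 1:12)))))
    scaling <- fit_descriptor_scaling(dm)
  }
  structure(list(strategy = strategy, components = comp, scaling = scaling,
                 radius = as.integer(radius), n_bits = as.integer(n_bits)),
            class = "featurizer")
}

#' Feature vectors for a set of molecules
#'
#' @param ftz A `featurizer` from [fit_featurizer()].
#' @param mols Named list of `mol_record`.
#' @return Named list of `feature_vector`.
#' @export
featurize_drugs <- function(ftz, mols) {
  stopifnot(inherits(ftz, "featurizer"))
  lapply(mols, function(m) {
    fp <- if (ftz$components$use_fp)
      morgan_fingerprint(m, ftz$radius, ftz$n_bits) else NULL
    desc <- if (!is.null(ftz$components$descriptor_set))
      descriptors(m, ftz$components$descriptor_set) else NULL
    build_feature_vector(fp, desc, ftz$scaling)
  })
}

#' Feature matrix (rows = drugs) for the logistic-regression baseline
#'
#' @inheritParams featurize_drugs
#' @return Numeric matrix with one row per molecule.
#' @export
feature_matrix <- function(ftz, mols) {
  fvs <- featurize_drugs(ftz, mols)
  out <- t(vapply(fvs, function(fv) fv$values,
                  numeric(length(fvs[[1]]$values))))
  rownames(out) <- names(mols)
  out
}
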