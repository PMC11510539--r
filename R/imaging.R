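# Feature-to-image codec: a feature vector in [0,1]^L is laid out row-major on
# the smallest square grid covering L, on a white (255) background, with
# pixel = round(255 * (1 - value)) so an active feature is a dark point on a
# blank white image. The decoder inverts the first n_features cells, which
# makes the codec round-trip testable: binary entries are exact (0 and 1 are
# representable 8-bit levels), continuous entries recover within 1/255.

#' Render a feature vector as a grayscale feature image
#'
#' @param fv A `feature_vector` (all values must lie in [0, 1]).
#' @return An object of class `feature_image`: list with `pixels`
#'   (grid_side x grid_side integer matrix, 0-255), `grid_side`, `n_features`,
#'   `background` (255).
#' @details Feature i (1-based) lands at row `(i-1) %/% grid_side + 1`,
#'   column `(i-1) %% grid_side + 1`; cells beyond `n_features` keep the
#'   background value and carry no information.
#' @export
feature_to_image <- function(fv) {
  values <- if (inherits(fv, "feature_vector")) fv$values else as.numeric(fv)
  if (any(!is.finite(values)) || any(values < 0) || any(values > 1)) {
    stop(ddimage_contract_error(
      "feature values must be finite and within [0, 1]"))
  }
  L <- length(values)
  stopifnot(L >= 1)
  side <- ceiling(sqrt(L))
  px <- matrix(255L, side, side)
  idx <- seq_len(L) - 1L
  px[cbind(idx %/% side + 1L, idx %% side + 1L)] <-
    as.integer(round(255 * (1 - values)))
  structure(list(pixels = px, grid_side = side, n_features = L,
                 background = 255L),
            class = "feature_image")
}

ddimage_contract_error <- function(message) {
  structure(class = c("ddimage_contract_error", "ddimage_error",
                      "error", "condition"),
            list(message = message, call = NULL))
}

#' Decode a feature image back to feature values
#'
#' Inverse of [feature_to_image()] up to 8-bit quantization: reads the first
#' `n_features` grid cells row-major and maps pixel p to value 1 - p/255.
#' Padding cells are ignored.
#'
#' @param img A `feature_image`.
#' @return Numeric vector of length `img$n_features`.
#' @export
image_decode <- function(img) {
  stopifnot(inherits(img, "feature_image"))
  side <- img$grid_side
  idx <- seq_len(img$n_features) - 1L
  p <- img$pixels[cbind(idx %/% side + 1L, idx %% side + 1L)]
  1 - p / 255
}

#' Image tensor specification
#'
#' Target side, channel count and per-channel normalization applied before
#' the image enters the network. The conventional backbone input side is 224;
#' tests and the synthetic benchmark use smaller sides (the encoder accepts
#' any side >= 32).
#'
#' @param target_side Output side in pixels.
#' @param channels Channel count (the encoder is single-channel grayscale).
#' @param mean,sd Normalization applied as (pixel/255 - mean) / sd.
#' @export
image_tensor_spec <- function(target_side = 224L, channels = 1L,
                              mean = 0.5, sd = 0.5) {
  stopifnot(target_side >= 1L, channels == 1L, sd > 0)
  structure(list(target_side = as.integer(target_side),
                 channels = as.integer(channels), mean = mean, sd = sd),
            class = "image_tensor_spec")
}

#' Resize and normalize a feature image for the network
#'
#' Nearest-neighbor resize to `spec$target_side` (keeps binary fingerprint
#' pixels crisp; no new gray levels are invented), then per-channel
#' normalization `(pixel/255 - mean) / sd`.
#'
#' @param img A `feature_image`.
#' @param spec An [image_tensor_spec()].
#' @return Numeric `target_side` x `target_side` matrix.
#' @export
resize_normalize <- function(img, spec) {
  stopifnot(inherits(img, "feature_image"), inherits(spec, "image_tensor_spec"))
  src <- img$pixels
  S <- img$grid_side
  Tn <- spec$target_side
  if (Tn == S) {
    out <- src
  } else {
    map <- pmin(pmax(floor(((seq_len(Tn) - 0.5) * S) / Tn) + 1L, 1L), S)
    out <- src[map, map, drop = FALSE]
  }
  (out / 255 - spec$mean) / spec$sd
}

#' Write a feature image as an ASCII PGM (P2) file
#'
#' Plain-text grayscale export for visual inspection with standard tools.
#'
#' @param img A `feature_image`.
#' @param path Output file path.
#' @export
write_pgm <- function(img, path) {
  stopifnot(inherits(img, "feature_image"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", img$grid_side, img$grid_side), "255"),
             con)
  apply(img$pixels, 1, function(row)
    writeLines(paste(row, collapse = " "), con))
  invisible(path)
}

#' Featurize molecules into normalized network-ready images
#'
#' Convenience wrapper: feature vectors ([featurize_drugs()]) rendered as
#' feature images and resized/normalized per `spec`. The returned list is
#' the `images` argument expected by [train()], [evaluate()] and
#' [predict_proba()] workflows.
#'
#' @param ftz A `featurizer` from [fit_featurizer()].
#' @param mols Named list of `mol_record`.
#' @param spec An [image_tensor_spec()].
#' @return Named list (drug id -> side x side numeric matrix).
#' @export
prepare_images <- function(ftz, mols, spec) {
  fvs <- featurize_drugs(ftz, mols)
  lapply(fvs, function(fv) resize_normalize(feature_to_image(fv), spec))
}
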