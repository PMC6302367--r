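#' Construct a float MLP
#'
#' An ordered stack of dense layers. Layer `i` holds a `rows x cols`
#' weight matrix and a length-`rows` bias vector; its `cols` must equal
#' the previous layer's `rows` (the first layer's `cols` is the input
#' size). Evaluation is weighted sum + bias, ReLU between layers, argmax
#' at the output.
#'
#' @param layers List of `list(weights = <matrix>, bias = <numeric>)`.
#' @return Object of class `float_mlp` with a `dims` attribute
#'   `c(input_size, neurons_layer1, ..., neurons_layerK)`.
#' @examples
#' float_mlp(list(list(weights = diag(2), bias = c(0, 0))))
#' @export
float_mlp <- function(layers) {
  if (length(layers) < 1) stop("a model needs at least one layer")
  layers <- lapply(seq_along(layers), function(i) {
    l <- layers[[i]]
    w <- as.matrix(l$weights)
    b <- as.numeric(l$bias)
    if (!is.numeric(w) || anyNA(w) || any(!is.finite(w)))
      stop(sprintf("layer %d: weights must be finite numeric", i))
    if (length(b) != nrow(w))
      stop(sprintf("layer %d: bias length %d != rows %d", i, length(b), nrow(w)))
    list(weights = w, bias = b)
  })
  for (i in seq_along(layers)[-1]) {
    if (ncol(layers[[i]]$weights) != nrow(layers[[i - 1]]$weights))
      stop(sprintf("layer %d: cols (%d) must equal layer %d rows (%d)",
                   i, ncol(layers[[i]]$weights),
                   i - 1, nrow(layers[[i - 1]]$weights)))
  }
  dims <- c(ncol(layers[[1]]$weights),
            vapply(layers, function(l) nrow(l$weights), numeric(1)))
  structure(list(layers = layers, dims = as.integer(dims)),
            class = "float_mlp")
}

#' @export
print.float_mlp <- function(x, ...) {
  cat("float_mlp:", paste(x$dims, collapse = " x "),
      sprintf("(%d layers)\n", length(x$layers)))
  invisible(x)
}

#' Model dimensions
#'
#' @param model A `float_mlp` or `quantized_mlp`.
#' @return Integer vector `c(input_size, layer_sizes...)`.
#' @export
model_dims <- function(model) model$dims

#' Load a float MLP from a JSON model file
#'
#' The file holds `{"layers": [{"rows", "cols", "weights", "bias",
#' "dtype": "float"}, ...]}` with weights as a rows-by-cols nested array.
#' Chained dimensions are validated on load.
#'
#' @param path Path to the JSON model file.
#' @return A [float_mlp()].
#' @export
load_float_model <- function(path) {
  raw <- read_model_json(path)
  layers <- lapply(seq_along(raw), function(i) {
    l <- raw[[i]]
    if (!is.null(l$dtype) && !identical(l$dtype, "float"))
      stop(sprintf("layer %d: expected dtype 'float', found '%s'", i, l$dtype))
    list(weights = l$weights, bias = l$bias)
  })
  float_mlp(layers)
}

#' Save a float MLP to a JSON model file
#'
#' @param model A [float_mlp()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_float_model <- function(model, path) {
  stopifnot(inherits(model, "float_mlp"))
  layers <- lapply(model$layers, function(l) {
    list(rows = nrow(l$weights), cols = ncol(l$weights),
         weights = unname(l$weights), bias = l$bias, dtype = "float")
  })
  jsonlite::write_json(list(layers = layers), path,
                       auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

read_model_json <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  parsed <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = TRUE),
    error = function(e) stop("malformed model file '", path, "': ",
                             conditionMessage(e)))
  if (is.null(parsed$layers)) stop("model file '", path, "' has no 'layers'")
  lay <- parsed$layers
  # read_json with simplifyVector returns either a data.frame-like or a list
  if (is.data.frame(lay)) {
    lay <- lapply(seq_len(nrow(lay)), function(i) as.list(lay[i, , drop = FALSE]))
    lay <- lapply(lay, function(l) {
      l$weights <- l$weights[[1]]
      l$bias <- l$bias[[1]]
      if (!is.null(l$dtype)) l$dtype <- l$dtype[[1]]
      l
    })
  }
  for (i in seq_along(lay)) {
    l <- lay[[i]]
    if (is.null(l$weights) || is.null(l$bias))
      stop(sprintf("malformed model file: layer %d lacks weights or bias", i))
    w <- as.matrix(l$weights)
    if (!is.null(l$rows) && (nrow(w) != l$rows || ncol(w) != l$cols))
      stop(sprintf("layer %d: declared %dx%d but weights are %dx%d",
                   i, l$rows, l$cols, nrow(w), ncol(w)))
    lay[[i]]$weights <- w
  }
  lay
}

#' Quantize a trained float MLP to 8-bit weights / 32-bit biases
#'
#' Post-training conversion to the fixed-point representation consumed by
#' the datapath. Per layer, weights are scaled symmetrically by the
#' layer's maximum absolute weight so the extremes land on +/-127
#' (`qw = round(w * 127 / max|w|)`, round half away from zero), and
#' biases are scaled into the 32-bit accumulator domain
#' (`qb = round(b * weight_scale * input_scale)`), saturating at the
#' signed 32-bit limits with a warning.
#'
#' The first layer's `input_scale` is the factor mapping the float input
#' to the 8-bit integers fed to the datapath (127 when inputs in
#' \[0, 1\] are quantized with [quantize_input_vector()]). Deeper layers
#' see activations whose scale depends on the truncation shift chosen at
#' run time; when `calibration` rows are supplied, the expected shift per
#' layer is estimated from the float activation maxima over those rows
#' and propagated, otherwise activations are assumed to fill the 7-bit
#' range of a unit-scale float activation.
#'
#' @param model A [float_mlp()].
#' @param input_scale Scale of the quantized input fed to layer 1.
#' @param calibration Optional numeric matrix of float inputs (rows =
#'   cases, on the same scale the model was trained on) used to estimate
#'   per-layer activation scales.
#' @return Object of class `quantized_mlp`: layers of `qweights`
#'   (integer matrix in \[-127, 127\]), `qbias` (32-bit range numeric),
#'   `weight_scale` and `input_scale`.
#' @export
calibrate_quantize <- function(model, input_scale = 127, calibration = NULL) {
  stopifnot(inherits(model, "float_mlp"))
  if (input_scale <= 0) stop("input_scale must be > 0")

  # float activation maxima per layer, for scale propagation
  act_max <- NULL
  if (!is.null(calibration)) {
    calibration <- as.matrix(calibration)
    if (ncol(calibration) != model$dims[1])
      stop("calibration has ", ncol(calibration), " columns; model input is ",
           model$dims[1])
    act_max <- layer_activation_maxima(model, calibration)
  }

  qlayers <- vector("list", length(model$layers))
  in_scale <- input_scale
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    maxabs <- max(abs(l$weights))
    if (maxabs == 0)
      stop(sprintf("layer %d: all weights are zero; quantization scale degenerates", i))
    wscale <- 127 / maxabs
    qw <- round_half_away(l$weights * wscale)
    qb <- round_half_away(l$bias * wscale * in_scale)
    if (any(qb > INT32_MAX | qb < INT32_MIN)) {
      warning(sprintf("layer %d: quantized bias saturated to 32-bit range", i))
      qb <- pmin(pmax(qb, INT32_MIN), INT32_MAX)
    }
    qlayers[[i]] <- list(qweights = qw, qbias = qb,
                         weight_scale = wscale, input_scale = in_scale)
    # accumulator scale of this layer, then estimated truncation shift
    acc_scale <- wscale * in_scale
    if (!is.null(act_max) && act_max[i] > 0) {
      est_max <- round_half_away(act_max[i] * acc_scale)
      shift <- max(leading1(min(est_max, INT32_MAX)) - 6, 0)
      in_scale <- acc_scale / 2^shift
    } else {
      in_scale <- 127
    }
  }
  structure(list(layers = qlayers, dims = model$dims),
            class = "quantized_mlp")
}

# per-layer maximum positive pre-activation over calibration rows
layer_activation_maxima <- function(model, X) {
  K <- length(model$layers)
  m <- numeric(K)
  H <- X
  for (i in seq_len(K)) {
    l <- model$layers[[i]]
    Z <- H %*% t(l$weights) + matrix(l$bias, nrow(H), length(l$bias), byrow = TRUE)
    m[i] <- max(Z, 0)
    H <- pmax(Z, 0)
  }
  m
}

#' @export
print.quantized_mlp <- function(x, ...) {
  cat("quantized_mlp:", paste(x$dims, collapse = " x "),
      "(int8 weights, int32 biases)\n")
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    cat(sprintf("  layer %d: weight_scale = %.6g, input_scale = %.6g\n",
                i, l$weight_scale, l$input_scale))
  }
  invisible(x)
}

#' Quantize a nonnegative intensity vector to the 8-bit input range
#'
#' Maps raw spectrum intensities onto \[0, 127\] by
#' `q = floor(x * 127 / max_intensity)`, the full nonnegative range the
#' datapath's activation input admits (its sign/MSB bit is always 0).
#' Intensities above `max_intensity` saturate at 127.
#'
#' @param x Nonnegative numeric vector of intensities.
#' @param max_intensity Positive scalar mapped to 127.
#' @return Integer-valued numeric vector in \[0, 127\].
#' @examples
#' quantize_input_vector(c(0, 0.5, 1), 1)
#' @export
quantize_input_vector <- function(x, max_intensity) {
  if (length(max_intensity) != 1 || max_intensity <= 0)
    stop("max_intensity must be a positive scalar")
  if (any(x < 0)) stop("intensities must be nonnegative")
  pmin(floor(x * 127 / max_intensity), 127)
}

#' Save a quantized MLP to a JSON model file
#'
#' Integer payloads are serialized as exact numbers; a save/load
#' round-trip reproduces them bit-exactly.
#'
#' @param model A `quantized_mlp`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_quantized_model <- function(model, path) {
  stopifnot(inherits(model, "quantized_mlp"))
  layers <- lapply(model$layers, function(l) {
    list(rows = nrow(l$qweights), cols = ncol(l$qweights),
         weights = unname(l$qweights), bias = l$qbias,
         dtype = "int8/int32",
         weight_scale = l$weight_scale, input_scale = l$input_scale)
  })
  jsonlite::write_json(list(layers = layers), path,
                       auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load a quantized MLP from a JSON model file
#'
#' @param path Path to a file written by [save_quantized_model()].
#' @return A `quantized_mlp`.
#' @export
load_quantized_model <- function(path) {
  raw <- read_model_json(path)
  qlayers <- lapply(seq_along(raw), function(i) {
    l <- raw[[i]]
    if (!identical(l$dtype, "int8/int32"))
      stop(sprintf("layer %d: expected dtype 'int8/int32', found '%s'",
                   i, if (is.null(l$dtype)) "<missing>" else l$dtype))
    if (any(abs(l$weights) > 127))
      stop(sprintf("layer %d: quantized weight outside [-127, 127]", i))
    check_int32(l$bias, sprintf("layer %d bias", i))
    list(qweights = l$weights, qbias = as.numeric(l$bias),
         weight_scale = as.numeric(l$weight_scale),
         input_scale = as.numeric(l$input_scale))
  })
  dims <- c(ncol(qlayers[[1]]$qweights),
            vapply(qlayers, function(l) nrow(l$qweights), numeric(1)))
  for (i in seq_along(qlayers)[-1]) {
    if (ncol(qlayers[[i]]$qweights) != nrow(qlayers[[i - 1]]$qweights))
      stop(sprintf("layer %d: cols must equal layer %d rows", i, i - 1))
  }
  structure(list(layers = qlayers, dims = as.integer(dims)),
            class = "quantized_mlp")
}

#' Audit fixed-point bit-widths of a quantized model
#'
#' Measures the signed bit-width actually needed by the integer payloads:
#' weights must fit 8 signed bits, biases 32.
#'
#' @param model A `quantized_mlp`.
#' @return List with `weight_bits` and `bias_bits`, the smallest signed
#'   widths holding every weight / bias of the model.
#' @export
audit_bit_widths <- function(model) {
  stopifnot(inherits(model, "quantized_mlp"))
  signed_bits <- function(v) {
    # smallest w with -2^(w-1) <= v <= 2^(w-1)-1 for all v
    w <- 1
    while (max(v) > 2^(w - 1) - 1 || min(v) < -2^(w - 1)) w <- w + 1
    w
  }
  ws <- unlist(lapply(model$layers, function(l) range(l$qweights)))
  bs <- unlist(lapply(model$layers, function(l) range(l$qbias)))
  list(weight_bits = signed_bits(ws), bias_bits = signed_bits(bs))
}
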