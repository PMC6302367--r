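# run expr under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification for the synthetic spectrum generator
#'
#' Describes a two-class population of SELDI-like protein mass spectra:
#' nonnegative ion-intensity vectors over `n_features` mass/charge
#' positions, built from a log-normal baseline plus Gaussian-shaped
#' peaks at class-specific locations. Presets mirror the shape of the
#' published proteomic benchmarks (15154 m/z features; 160 train / 92
#' test and 100 train / 32 test case counts) plus a reduced-feature
#' `"small"` preset for fast end-to-end runs.
#'
#' @param preset One of `"ovarian-like"`, `"jnci-like"`, `"small"`, or
#'   NULL to take the explicit arguments as given.
#' @param n_features Number of m/z features per spectrum.
#' @param n_train,n_test Total cases in each split (balanced across the
#'   two classes, odd counts giving the extra case to class 0).
#' @param n_peaks Class-specific peak count per class.
#' @param peak_amplitude Mean peak height added on top of the baseline
#'   (intensity units); 0 removes all class signal.
#' @param peak_width Gaussian peak standard deviation, in feature index units.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline parameters.
#' @param seed Integer seed; generation is bit-reproducible given the spec.
#' @return Object of class `generator_spec`.
#' @export
generator_spec <- function(preset = NULL,
                           n_features = 15154,
                           n_train = 160, n_test = 92,
                           n_peaks = 6,
                           peak_amplitude = 4,
                           peak_width = 3,
                           baseline_meanlog = 0,
                           baseline_sdlog = 0.5,
                           seed = 1) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("ovarian-like", "jnci-like", "small"))
    if (preset == "jnci-like") {
      n_train <- 100
      n_test <- 32
    } else if (preset == "small") {
      n_features <- 1024
      n_train <- 160
      n_test <- 92
    }
  }
  if (n_features < 1 || n_train < 2 || n_test < 2 || n_peaks < 1)
    stop("counts must be >= 1, with at least 2 cases per split")
  if (peak_amplitude < 0) stop("peak_amplitude must be >= 0")
  if (n_features < 2 * n_peaks)
    stop("n_features too small for ", n_peaks, " peaks per class")
  structure(list(preset = preset, n_features = as.integer(n_features),
                 n_train = as.integer(n_train), n_test = as.integer(n_test),
                 n_peaks = as.integer(n_peaks),
                 peak_amplitude = peak_amplitude, peak_width = peak_width,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

#' Generate a two-class synthetic spectrum dataset
#'
#' Each case is a log-normal baseline over all features; cases of class
#' c additionally receive Gaussian-shaped peaks (amplitude jittered
#' uniformly by +/-30% per case) centered at that class's peak
#' locations, which are drawn once per dataset, disjoint between
#' classes. Intensities are nonnegative by construction. The train/test
#' split is stratified and the whole construction is a deterministic
#' function of the spec (including its seed).
#'
#' @param spec A [generator_spec()].
#' @return Object of class `spectrum_dataset`: `X` (cases x features
#'   intensity matrix), `y` (0 = normal, 1 = cancer), `train`, `test`
#'   (row indices), `peaks` (per-class locations), `seed`.
#' @export
generate_spectra <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  with_seed(spec$seed, {
    n0 <- ceiling(spec$n_train / 2) + ceiling(spec$n_test / 2)
    n1 <- floor(spec$n_train / 2) + floor(spec$n_test / 2)
    n <- n0 + n1
    f <- spec$n_features
    y <- c(rep(0L, n0), rep(1L, n1))

    loc <- sample.int(f, 2 * spec$n_peaks)
    peaks <- list("0" = sort(loc[seq_len(spec$n_peaks)]),
                  "1" = sort(loc[spec$n_peaks + seq_len(spec$n_peaks)]))

    X <- matrix(stats::rlnorm(n * f, spec$baseline_meanlog, spec$baseline_sdlog),
                nrow = n, ncol = f)
    w <- spec$peak_width
    half <- ceiling(3 * w)
    for (ci in c(0L, 1L)) {
      rows <- which(y == ci)
      for (p in peaks[[as.character(ci)]]) {
        j <- max(1, p - half):min(f, p + half)
        kern <- exp(-((j - p)^2) / (2 * w^2))
        amp <- spec$peak_amplitude * stats::runif(length(rows), 0.7, 1.3)
        X[rows, j] <- X[rows, j] + outer(amp, kern)
      }
    }

    # stratified split: sample train rows within each class
    tr0 <- sample(which(y == 0L), ceiling(spec$n_train / 2))
    tr1 <- sample(which(y == 1L), floor(spec$n_train / 2))
    train <- sort(c(tr0, tr1))
    test <- setdiff(seq_len(n), train)
    structure(list(X = X, y = y, train = train, test = test,
                   peaks = peaks, seed = spec$seed, spec = spec),
              class = "spectrum_dataset")
  })
}

#' @export
print.spectrum_dataset <- function(x, ...) {
  cat(sprintf("spectrum_dataset: %d cases x %d features (train %d / test %d), seed %d\n",
              nrow(x$X), ncol(x$X), length(x$train), length(x$test), x$seed))
  invisible(x)
}

#' Write / read a spectrum dataset as delimited text
#'
#' The interchange format is one header row, a `label` column, and one
#' nonnegative intensity column per m/z feature.
#'
#' @param data A `spectrum_dataset` (or any list with `X` and `y`).
#' @param path File path; `.tsv` extension selects tab separation.
#' @return `path` invisibly for the writer; a list with `X` (matrix)
#'   and `y` for the reader.
#' @export
write_spectra <- function(data, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- data.frame(label = data$y, data$X, check.names = FALSE)
  colnames(df) <- c("label", paste0("mz", seq_len(ncol(data$X))))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(data$seed)) writeLines(paste0("# seed: ", data$seed), con)
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectra
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) stop("dataset not found: ", path)
  head_lines <- readLines(path, n = 10)
  first <- head_lines[!startsWith(head_lines, "#")][1]
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE)
  if (!"label" %in% colnames(df)) stop("dataset has no 'label' column")
  X <- as.matrix(df[, setdiff(colnames(df), "label"), drop = FALSE])
  if (any(X < 0)) stop("intensities must be nonnegative")
  list(X = X, y = as.integer(df$label))
}

#' Train a minimal reference MLP in floating point
#'
#' A deliberately small trainer: dense layers, ReLU hidden activations,
#' softmax cross-entropy output, plain mini-batch gradient descent with
#' He-scaled Gaussian initialization. Inputs are normalized by the
#' maximum training intensity so features lie in \[0, 1\]; the factor is
#' recorded on the returned model (`attr(, "max_intensity")`) so inference
#' and quantization use the same mapping. With `epochs = 0` the seeded
#' initialization is returned unchanged.
#'
#' @param data A `spectrum_dataset`.
#' @param dims Layer sizes `c(input_size, hidden..., 2)`; `dims[1]` must
#'   equal the dataset's feature count.
#' @param epochs Training epochs (>= 0).
#' @param lr Learning rate.
#' @param seed Integer seed for initialization and batch shuffling.
#' @param batch_size Mini-batch size.
#' @return A trained [float_mlp()] with attributes `max_intensity` and
#'   `loss` (per-epoch mean cross-entropy, starting at epoch 0).
#' @export
train_reference_mlp <- function(data, dims, epochs = 40, lr = 0.05,
                                seed = 1, batch_size = 32) {
  stopifnot(inherits(data, "spectrum_dataset"))
  dims <- as.integer(dims)
  if (dims[1] != ncol(data$X))
    stop("dims[1] = ", dims[1], " but the dataset has ", ncol(data$X), " features")
  if (dims[length(dims)] != 2) stop("the output layer must have 2 classes")
  if (epochs < 0) stop("epochs must be >= 0")

  max_intensity <- max(data$X[data$train, , drop = FALSE])
  X <- data$X[data$train, , drop = FALSE] / max_intensity
  y <- data$y[data$train]
  n <- nrow(X)
  K <- length(dims) - 1

  with_seed(seed, {
    W <- lapply(seq_len(K), function(i) {
      matrix(stats::rnorm(dims[i + 1] * dims[i], sd = sqrt(2 / dims[i])),
             dims[i + 1], dims[i])
    })
    B <- lapply(seq_len(K), function(i) numeric(dims[i + 1]))

    mean_loss <- function() {
      P <- forward_probs(W, B, X)
      -mean(log(pmax(P[cbind(seq_len(n), y + 1L)], 1e-12)))
    }
    losses <- mean_loss()

    if (epochs > 0) {
      for (e in seq_len(epochs)) {
        ord <- sample.int(n)
        for (start in seq(1, n, by = batch_size)) {
          idx <- ord[start:min(start + batch_size - 1, n)]
          Xb <- X[idx, , drop = FALSE]
          yb <- y[idx]
          m <- length(idx)
          # forward, caching activations
          H <- vector("list", K + 1)
          H[[1]] <- Xb
          Z <- vector("list", K)
          for (i in seq_len(K)) {
            Z[[i]] <- H[[i]] %*% t(W[[i]]) +
              matrix(B[[i]], m, dims[i + 1], byrow = TRUE)
            H[[i + 1]] <- if (i < K) pmax(Z[[i]], 0) else Z[[i]]
          }
          P <- softmax_rows(Z[[K]])
          G <- P
          G[cbind(seq_len(m), yb + 1L)] <- G[cbind(seq_len(m), yb + 1L)] - 1
          G <- G / m
          for (i in rev(seq_len(K))) {
            gW <- t(G) %*% H[[i]]
            gB <- colSums(G)
            if (i > 1) G <- (G %*% W[[i]]) * (Z[[i - 1]] > 0)
            W[[i]] <- W[[i]] - lr * gW
            B[[i]] <- B[[i]] - lr * gB
          }
        }
        l <- mean_loss()
        if (!is.finite(l))
          stop("training diverged (non-finite loss) at epoch ", e)
        losses <- c(losses, l)
      }
    }
    model <- float_mlp(lapply(seq_len(K), function(i)
      list(weights = W[[i]], bias = B[[i]])))
    attr(model, "max_intensity") <- max_intensity
    attr(model, "loss") <- losses
    model
  })
}

forward_probs <- function(W, B, X) {
  H <- X
  K <- length(W)
  for (i in seq_len(K)) {
    Z <- H %*% t(W[[i]]) + matrix(B[[i]], nrow(H), length(B[[i]]), byrow = TRUE)
    H <- if (i < K) pmax(Z, 0) else Z
  }
  softmax_rows(H)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Full-precision reference inference
#'
#' Forward pass of a float MLP on a single input vector: weighted sum
#' plus bias per layer, ReLU between layers, argmax decision on the raw
#' output sums (ties to the lowest class index).
#'
#' @param model A [float_mlp()].
#' @param x Numeric input vector, length equal to the model input size.
#' @return List with `class` (0-based) and `output` (final real vector).
#' @export
float_infer <- function(model, x) {
  stopifnot(inherits(model, "float_mlp"))
  if (length(x) != model$dims[1])
    stop("input length ", length(x), " != model input size ", model$dims[1])
  h <- as.numeric(x)
  K <- length(model$layers)
  for (i in seq_len(K)) {
    l <- model$layers[[i]]
    z <- as.vector(l$weights %*% h) + l$bias
    h <- if (i < K) pmax(z, 0) else z
  }
  list(class = which.max(h) - 1L, output = h)
}

#' Held-out accuracy of a float model on a spectrum dataset
#'
#' @param model A trained [float_mlp()] carrying a `max_intensity` attribute.
#' @param data A `spectrum_dataset`.
#' @param split `"test"` (default) or `"train"`.
#' @return Fraction of correctly classified cases.
#' @export
evaluate_accuracy <- function(model, data, split = c("test", "train")) {
  split <- match.arg(split)
  idx <- data[[split]]
  mi <- attr(model, "max_intensity")
  if (is.null(mi)) mi <- max(data$X[data$train, , drop = FALSE])
  pred <- vapply(idx, function(r)
    float_infer(model, data$X[r, ] / mi)$class, integer(1))
  mean(pred == data$y[idx])
}
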