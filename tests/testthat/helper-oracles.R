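# Independent oracles and fixture builders. All arithmetic here stays on
# doubles, which represent integers exactly up to 2^53; every oracle
# asserts its magnitudes stay far below that bound so the shadow
# computation is exact.

EXACT_DOUBLE_BOUND <- 2^53

# element-by-element dot product (no matrix ops)
naive_dot <- function(w_row, x) {
  s <- 0
  for (j in seq_along(x)) {
    s <- s + w_row[j] * x[j]
    stopifnot(abs(s) < EXACT_DOUBLE_BOUND)
  }
  s
}

# leading-one position via log2 with correction, independent of the
# package's divide-and-count loop
oracle_lead_pos <- function(v) {
  if (v <= 0) return(0L)
  p <- floor(log2(v))
  if (2^p > v) p <- p - 1
  if (2^(p + 1) <= v) p <- p + 1
  as.integer(p)
}

# unblocked full-precision reference inference: plain loops, floor
# division for the truncation, no tiling
naive_infer_unblocked <- function(model, qx) {
  x <- as.numeric(qx)
  K <- length(model$layers)
  out <- NULL
  for (i in seq_len(K)) {
    l <- model$layers[[i]]
    rows <- nrow(l$qweights)
    z <- numeric(rows)
    for (r in seq_len(rows)) {
      z[r] <- naive_dot(l$qweights[r, ], x) + l$qbias[r]
    }
    stopifnot(all(abs(z) < 2^31))
    gmax <- -Inf
    for (r in seq_len(rows)) if (z[r] > gmax) gmax <- z[r]
    p <- min(max(oracle_lead_pos(gmax), 6L), 30L)
    if (i < K) {
      x <- floor(pmax(z, 0) / 2^(p - 6))
    } else {
      out <- z
    }
  }
  cls <- 0L
  for (r in seq_along(out)) if (out[r] > out[cls + 1L]) cls <- r - 1L
  list(class = cls, outputs = out)
}

# random quantized model with chained dims, weights in [-127, 127]
rand_quantized_model <- function(dims, bias_range = 1000) {
  layers <- lapply(seq_len(length(dims) - 1), function(i) {
    list(qweights = matrix(sample(-127:127, dims[i + 1] * dims[i], TRUE),
                           dims[i + 1], dims[i]),
         qbias = as.numeric(sample(-bias_range:bias_range, dims[i + 1], TRUE)),
         weight_scale = 1, input_scale = 1)
  })
  structure(list(layers = layers, dims = as.integer(dims)),
            class = "quantized_mlp")
}

# random float model with chained dims
rand_float_model <- function(dims, sd = 1) {
  float_mlp(lapply(seq_len(length(dims) - 1), function(i)
    list(weights = matrix(rnorm(dims[i + 1] * dims[i], sd = sd),
                          dims[i + 1], dims[i]),
         bias = rnorm(dims[i + 1], sd = sd))))
}

rand_dims <- function(max_layers = 4, max_size = 9) {
  K <- sample(1:max_layers, 1)
  sample(2:max_size, K + 1, replace = TRUE)
}
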