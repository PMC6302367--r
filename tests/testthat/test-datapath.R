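test_that("scalar product blocks compute exact integer dot products", {
  expect_identical(scalar_product_block(matrix(1:4, 1), c(4, 3, 2, 1)), 20)
  expect_identical(scalar_product_block(matrix(0, 3, 4), rep(127, 4)),
                   c(0, 0, 0))
  # extreme admissible block: 256 terms of 127*127
  w <- matrix(127, 1, 256)
  x <- rep(127, 256)
  expect_identical(scalar_product_block(w, x), naive_dot(w[1, ], x))
  expect_identical(scalar_product_block(w, x), 4129024)

  expect_error(scalar_product_block(matrix(128, 1, 1), 1), "\\[-127, 127\\]")
  expect_error(scalar_product_block(matrix(1, 1, 1), 128), "\\[0, 127\\]")
  expect_error(scalar_product_block(matrix(1, 1, 2), 1), "columns")
})

test_that("accumulation re-initializes on first block and guards overflow", {
  expect_identical(accumulate(c(10), c(5)), 15)
  expect_identical(accumulate(c(0), c(7), bias = c(3), first_block = TRUE), 10)
  # 60-block random sequence against a running-sum shadow
  set.seed(71)
  acc <- shadow <- NULL
  bias <- sample(-100:100, 4)
  for (b in 1:60) {
    partial <- sample(-10000:10000, 4)
    if (b == 1) {
      acc <- accumulate(numeric(4), partial, bias = bias, first_block = TRUE)
      shadow <- partial + bias
    } else {
      acc <- accumulate(acc, partial)
      shadow <- shadow + partial
    }
    stopifnot(all(abs(shadow) < 2^53))
  }
  expect_identical(acc, shadow)
  expect_error(accumulate(c(2^31 - 1), c(1)), "overflow")
})

test_that("streaming max search equals the one-shot maximum", {
  expect_identical(max_search(list(c(3, -1, 7, 0))), 7)
  expect_identical(max_search(list(c(-5), c(-2))), -2)
  expect_error(max_search(list()), "at least one")
  set.seed(81)
  for (i in 1:100) {
    stream <- replicate(sample(1:8, 1),
                        sample(-10^6:10^6, sample(1:6, 1)), simplify = FALSE)
    expect_identical(max_search(stream), max(unlist(stream)))
  }
})

test_that("leading-one detection clamps to [6, 30] and is monotone", {
  expect_identical(leading1(1), 6L)
  expect_identical(leading1(2^31 - 1), 30L)
  expect_identical(leading1(1023), 9L)
  expect_identical(leading1(0), 6L)
  expect_identical(leading1(-5), 6L)
  set.seed(91)
  vs <- sort(c(2^(0:30), sample(1:(2^31 - 1), 200)))
  ps <- vapply(vs, leading1, integer(1))
  expect_true(all(ps >= 6 & ps <= 30))
  expect_true(all(diff(ps) >= 0)) # monotone within clamp bounds
  expect_identical(ps, vapply(vs, function(v)
    min(max(oracle_lead_pos(v), 6L), 30L), integer(1)))
})

test_that("requantization is ReLU followed by floor division by a power of two", {
  expect_identical(relu_requantize(100, 6), 100)
  expect_identical(relu_requantize(-12345, 6), 0)
  expect_identical(relu_requantize(-12345, 30), 0)
  expect_identical(relu_requantize(1023, 10), 63)
  expect_identical(relu_requantize(1023, 10), floor(1023 / 16))
  set.seed(101)
  for (i in 1:200) {
    v <- sample(c(-10^6:10^6), 1)
    p <- leading1(max(v, 0))
    r <- relu_requantize(v, p)
    expect_identical(r, floor(max(v, 0) / 2^(p - 6)))
    expect_true(r >= 0 && r <= 127)
  }
  expect_error(relu_requantize(1, 5), "lead1")
})

test_that("blocked inference is bit-identical across (M, N) and matches the unblocked reference", {
  set.seed(111)
  archs <- list(arch_config(1, 1), arch_config(4, 2), arch_config(256, 8))
  for (i in 1:25) {
    dims <- rand_dims()
    q <- rand_quantized_model(dims)
    qx <- sample(0:127, dims[1], replace = TRUE)
    ref <- naive_infer_unblocked(q, qx)
    for (a in archs) {
      got <- infer_quantized(q, qx, a)
      expect_identical(got$outputs, ref$outputs)
      expect_identical(got$class, ref$class)
    }
  }
})

test_that("identity and degenerate models behave as forced", {
  q <- structure(list(layers = list(list(
    qweights = diag(4), qbias = numeric(4),
    weight_scale = 1, input_scale = 1)), dims = c(4L, 4L)),
    class = "quantized_mlp")
  qx <- c(5, 100, 3, 7)
  got <- infer_quantized(q, qx, arch_config(3, 2)) # deliberately non-divisor M,N
  expect_identical(got$outputs, qx)
  expect_identical(got$class, 1L)

  z <- rand_quantized_model(c(3, 4, 2))
  for (l in seq_along(z$layers)) {
    z$layers[[l]]$qweights[] <- 0
    z$layers[[l]]$qbias[] <- 0
  }
  expect_identical(infer_quantized(z, c(1, 2, 3), arch_config(2, 2))$outputs,
                   c(0, 0))
  expect_error(infer_quantized(z, c(1, 2), arch_config(1, 1)), "input length")
})

test_that("requantized activations always fit 7 magnitude bits", {
  set.seed(121)
  for (i in 1:20) {
    dims <- rand_dims(max_layers = 3)
    q <- rand_quantized_model(dims)
    qx <- sample(0:127, dims[1], replace = TRUE)
    # follow hidden activations layer by layer
    x <- qx
    for (l in seq_len(length(q$layers) - 1)) {
      z <- as.vector(q$layers[[l]]$qweights %*% x) + q$layers[[l]]$qbias
      p <- leading1(max(max(z), 0))
      x <- relu_requantize(z, p)
      expect_true(all(x >= 0 & x <= 127))
      expect_lte(leading1(max(x)), 6)
    }
  }
})
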