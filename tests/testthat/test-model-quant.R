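test_that("float model construction validates chained dimensions", {
  m <- float_mlp(list(list(weights = matrix(1, 1, 1), bias = 0)))
  expect_s3_class(m, "float_mlp")
  expect_identical(model_dims(m), c(1L, 1L))

  ok <- float_mlp(list(
    list(weights = matrix(0.1, 4, 3), bias = numeric(4)),
    list(weights = matrix(0.1, 2, 4), bias = numeric(2))))
  expect_identical(model_dims(ok), c(3L, 4L, 2L))

  expect_error(float_mlp(list(
    list(weights = matrix(0.1, 4, 3), bias = numeric(4)),
    list(weights = matrix(0.1, 2, 5), bias = numeric(2)))),
    "cols")
  expect_error(float_mlp(list(list(weights = matrix(1, 2, 2), bias = 0))),
               "bias length")
})

test_that("model files round-trip through JSON, including the benchmark shape", {
  set.seed(11)
  m <- rand_float_model(c(5, 4, 3, 2))
  path <- withr::local_tempfile(fileext = ".json")
  save_float_model(m, path)
  m2 <- load_float_model(path)
  expect_equal(m2$layers, m$layers, tolerance = 0)
  expect_identical(model_dims(m2), model_dims(m))

  # malformed file names the offending layer
  bad <- jsonlite::read_json(path, simplifyVector = TRUE)
  bad$layers$rows[2] <- 99
  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(bad, path2, auto_unbox = TRUE, digits = NA)
  expect_error(load_float_model(path2), "layer 2")

  expect_error(load_float_model(withr::local_tempfile()), "not found")
})

test_that("weight quantization follows the symmetric max-abs rule", {
  m <- float_mlp(list(list(weights = matrix(c(0.5, -0.5, 0, 0.25), 2, 2),
                           bias = c(0, 0))))
  q <- calibrate_quantize(m)
  expect_identical(q$layers[[1]]$qweights[1, 1], 127)
  expect_identical(q$layers[[1]]$qweights[2, 1], -127)
  expect_identical(q$layers[[1]]$qweights[1, 2], 0)
  expect_identical(q$layers[[1]]$qweights[2, 2], 64) # round(63.5) away from zero

  expect_error(
    calibrate_quantize(float_mlp(list(list(weights = matrix(0, 2, 2),
                                           bias = c(1, 1))))),
    "degenerate")
})

test_that("quantization error stays within half a step and is monotone", {
  set.seed(21)
  w <- matrix(runif(64, -1, 1), 8, 8)
  m <- float_mlp(list(list(weights = w, bias = numeric(8))))
  q <- calibrate_quantize(m)
  qw <- q$layers[[1]]$qweights
  s <- q$layers[[1]]$weight_scale
  # per-element brute-force check of the stated rule
  expect_equal(qw, sign(w) * floor(abs(w) * 127 / max(abs(w)) + 0.5),
               tolerance = 0)
  expect_true(all(abs(qw) <= 127))
  expect_true(all(abs(qw / s - w) <= 0.5 / s + 1e-12))
  # monotone and sign-preserving
  ord <- order(w)
  expect_true(all(diff(qw[ord]) >= 0))
  expect_true(all(sign(qw) == sign(round(w * s))))
})

test_that("bias quantization lands in the accumulator domain and saturates", {
  m <- float_mlp(list(list(weights = matrix(c(1, -1), 1, 2), bias = 0.5)))
  q <- calibrate_quantize(m, input_scale = 127)
  # wscale = 127, bias 0.5 * 127 * 127 = 8064.5 -> 8065 away from zero
  expect_identical(q$layers[[1]]$qbias, 8065)

  big <- float_mlp(list(list(weights = matrix(c(1, -1), 1, 2), bias = 1e9)))
  expect_warning(qb <- calibrate_quantize(big, input_scale = 127),
                 "saturated")
  expect_identical(qb$layers[[1]]$qbias, 2^31 - 1)
  expect_identical(audit_bit_widths(qb)$bias_bits, 32)
})

test_that("input quantization matches the floor formula and saturates at 127", {
  expect_identical(quantize_input_vector(c(2), 2), 127)
  expect_identical(quantize_input_vector(c(0, 0), 5), c(0, 0))
  expect_error(quantize_input_vector(c(-1), 1), "nonnegative")
  expect_error(quantize_input_vector(c(1), 0), "positive")
  set.seed(31)
  for (i in 1:100) {
    mx <- runif(1, 0.5, 10)
    x <- runif(20, 0, mx)
    q <- quantize_input_vector(x, mx)
    expect_identical(q, floor(x * 127 / mx))
    expect_true(all(q >= 0 & q <= 127))
  }
  expect_identical(quantize_input_vector(c(10), 1), 127)
})

test_that("quantized models round-trip bit-exactly", {
  set.seed(41)
  for (i in 1:20) {
    q <- rand_quantized_model(rand_dims())
    path <- withr::local_tempfile(fileext = ".json")
    save_quantized_model(q, path)
    q2 <- load_quantized_model(path)
    for (l in seq_along(q$layers)) {
      expect_identical(unname(q2$layers[[l]]$qweights),
                       unname(q$layers[[l]]$qweights))
      expect_identical(q2$layers[[l]]$qbias, q$layers[[l]]$qbias)
      expect_identical(q2$layers[[l]]$weight_scale, q$layers[[l]]$weight_scale)
    }
  }
})

test_that("every calibrated model passes the 8/32-bit width audit", {
  set.seed(51)
  for (i in 1:10) {
    m <- rand_float_model(rand_dims())
    q <- calibrate_quantize(m)
    bits <- audit_bit_widths(q)
    expect_lte(bits$weight_bits, 8)
    expect_lte(bits$bias_bits, 32)
    expect_true(all(vapply(q$layers, function(l) max(abs(l$qweights)), 0) == 127))
  }
})

test_that("calibration propagates activation scales across layers", {
  set.seed(61)
  m <- rand_float_model(c(6, 5, 2), sd = 0.5)
  X <- matrix(runif(40 * 6), 40, 6)
  q <- calibrate_quantize(m, input_scale = 127, calibration = X)
  expect_identical(q$layers[[1]]$input_scale, 127)
  # layer-2 input scale follows the estimated truncation shift
  acc1 <- q$layers[[1]]$weight_scale * 127
  expect_true(q$layers[[2]]$input_scale <= acc1)
  expect_error(calibrate_quantize(m, calibration = X[, 1:3]), "columns")
})
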