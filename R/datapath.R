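#' Blocked scalar product
#'
#' One cycle's worth of the scalar-product module: an N x M block of
#' 8-bit weights against an M-element 8-bit slice of the input vector,
#' reduced through per-row adder trees into 32-bit partial sums. Exact
#' integer arithmetic; any partial sum outside the signed 32-bit range
#' is a hard error (the hardware sizes its accumulators to exclude it).
#'
#' @param w_block N x M numeric matrix with entries in \[-127, 127\].
#' @param x_block Length-M numeric vector with entries in \[0, 127\].
#' @return Length-N vector of exact partial sums.
#' @examples
#' scalar_product_block(matrix(1:4, 1), c(4, 3, 2, 1))
#' @export
scalar_product_block <- function(w_block, x_block) {
  w_block <- as.matrix(w_block)
  if (ncol(w_block) != length(x_block))
    stop("w_block has ", ncol(w_block), " columns but x_block length is ",
         length(x_block))
  if (any(abs(w_block) > 127)) stop("weights must lie in [-127, 127]")
  if (any(x_block < 0 | x_block > 127)) stop("inputs must lie in [0, 127]")
  p <- as.vector(w_block %*% x_block)
  check_int32(p, "scalar product partial sum")
  p
}

#' Accumulate partial sums
#'
#' The accumulate-register update: on a row block's first column block
#' the registers are re-initialized to the incoming partial sum plus the
#' layer bias; on subsequent column blocks the partial sum is added.
#' `last_col_block` marks the update that finalizes the row block's
#' neuron sums (it does not change the arithmetic, only signals the
#' downstream max search).
#'
#' @param acc Current accumulator contents (length N).
#' @param partial Incoming partial sums (length N).
#' @param bias Bias slice for this row block (length N); injected on the
#'   first column block only.
#' @param first_block TRUE when this is the row block's first column block.
#' @param last_col_block TRUE when this update finalizes the row block.
#' @return Updated accumulator vector.
#' @export
accumulate <- function(acc, partial, bias = 0, first_block = FALSE,
                       last_col_block = FALSE) {
  if (length(acc) != length(partial))
    stop("acc and partial lengths differ")
  out <- if (first_block) partial + bias else acc + partial
  check_int32(out, "accumulator")
  out
}

#' Streaming maximum search
#'
#' Consumes finalized neuron sums N at a time, taking a local maximum of
#' each vector and promoting it to a global-maximum register when it
#' exceeds the current value — the stall-free streaming equivalent of a
#' one-shot maximum over the whole layer.
#'
#' @param stream List of numeric vectors (finalized accumulator outputs).
#' @return The global maximum (scalar).
#' @export
max_search <- function(stream) {
  if (length(stream) == 0) stop("max_search needs at least one finalized vector")
  g <- -Inf
  for (v in stream) {
    if (length(v) == 0) stop("empty vector in max stream")
    local <- max(v)
    if (local > g) g <- local
  }
  g
}

#' Leading-one position, clamped to the requantizer's range
#'
#' Position (LSB = 0) of the most significant set bit of `max(v, 0)`,
#' clamped to \[6, 30\]: 6 means the layer maximum already fits the
#' 8-bit output (7 magnitude bits), 30 is the leading-one position of
#' the largest positive 32-bit signed value. Non-positive inputs clamp
#' to 6 (every ReLU output is 0 in that case, so any shift is exact).
#'
#' @param v 32-bit signed integer (scalar).
#' @return Integer in \[6, 30\].
#' @examples
#' leading1(1)          # 6
#' leading1(2^31 - 1)   # 30
#' @export
leading1 <- function(v) {
  if (length(v) != 1) stop("leading1 takes a scalar")
  check_int32(v, "leading1 input")
  v <- max(v, 0)
  p <- 0L
  while (v >= 2) {
    v <- v %/% 2
    p <- p + 1L
  }
  min(max(p, 6L), 30L)
}

#' ReLU activation and truncation requantization
#'
#' Applies the 32-bit ReLU (`max(v, 0)`) and compresses back to 8 bits
#' by an arithmetic right shift of `lead1 - 6` positions, so the layer
#' maximum's leading 1 lands on bit 6 and every output occupies at most
#' 7 magnitude bits with a zero MSB. Truncation replaces division, which
#' is costly in hardware; the compression context keeps the difference
#' small.
#'
#' @param v 32-bit signed integer scalar or vector.
#' @param lead1 Shift key from [leading1()], in \[6, 30\].
#' @return Requantized value(s) in \[0, 127\] whenever `lead1` is at
#'   least the leading-one position of `v`.
#' @examples
#' relu_requantize(1023, 10)   # 63
#' relu_requantize(-12345, 20) # 0
#' @export
relu_requantize <- function(v, lead1) {
  if (length(lead1) != 1 || lead1 < 6 || lead1 > 30 || lead1 != floor(lead1))
    stop("lead1 must be an integer in [6, 30]")
  check_int32(v, "requantizer input")
  pmax(v, 0) %/% 2^(lead1 - 6)
}

#' Fixed-point blocked inference
#'
#' Runs a quantized model on an 8-bit input vector exactly as the
#' blocked datapath does: each layer's weight matrix is tiled into
#' ceiling(rows/N) x ceiling(cols/M) zero-padded blocks, partial sums
#' are accumulated (bias on the first column block), finalized row
#' blocks stream through the max search, the global maximum keys the
#' leading-one shift, and requantized activations feed the next layer
#' through the buffer bank swap. The final layer's decision is the
#' argmax of its raw 32-bit sums (ties to the lowest class index); no
#' requantization is needed for the decision. The outputs are
#' bit-identical for every valid (M, N).
#'
#' @param model A `quantized_mlp`.
#' @param qx Integer-valued input vector in \[0, 127\], length equal to
#'   the model input size.
#' @param arch An [arch_config()] supplying M and N.
#' @return List with `class` (0-based class index), `outputs` (final
#'   layer's 32-bit sums) and `lead1` (per-layer shift keys).
#' @export
infer_quantized <- function(model, qx, arch) {
  stopifnot(inherits(model, "quantized_mlp"), inherits(arch, "arch_config"))
  if (length(qx) != model$dims[1])
    stop("input length ", length(qx), " != model input size ", model$dims[1])
  if (any(qx < 0 | qx > 127)) stop("quantized inputs must lie in [0, 127]")
  M <- arch$M
  N <- arch$N
  K <- length(model$layers)
  x <- as.numeric(qx)
  lead1s <- integer(K)
  acc_valid <- NULL
  for (i in seq_len(K)) {
    l <- model$layers[[i]]
    rows <- nrow(l$qweights)
    cols <- ncol(l$qweights)
    nblocks <- ceiling(rows / N)
    mblocks <- ceiling(cols / M)
    wp <- matrix(0, nblocks * N, mblocks * M)
    wp[seq_len(rows), seq_len(cols)] <- l$qweights
    xp <- c(x, numeric(mblocks * M - cols))
    bp <- c(l$qbias, numeric(nblocks * N - rows))
    acc <- numeric(nblocks * N)
    row_stream <- vector("list", nblocks)
    for (nb in seq_len(nblocks)) {
      ridx <- ((nb - 1) * N + 1):(nb * N)
      a <- numeric(N)
      for (mb in seq_len(mblocks)) {
        cidx <- ((mb - 1) * M + 1):(mb * M)
        partial <- scalar_product_block(wp[ridx, cidx, drop = FALSE], xp[cidx])
        a <- accumulate(a, partial, bias = bp[ridx],
                        first_block = mb == 1,
                        last_col_block = mb == mblocks)
      }
      acc[ridx] <- a
      row_stream[[nb]] <- a
    }
    acc_valid <- acc[seq_len(rows)]
    gmax <- max_search(row_stream)
    lead1s[i] <- leading1(max(min(gmax, INT32_MAX), INT32_MIN))
    if (i < K) {
      x <- relu_requantize(acc_valid, lead1s[i])
    }
  }
  list(class = which.max(acc_valid) - 1L, outputs = acc_valid, lead1 = lead1s)
}
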