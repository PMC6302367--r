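#' Latency tags for one layer
#'
#' The counter-driven control unit fires every trigger from hard-coded
#' cycle values ("latency tags") rather than module feedback. Each tag
#' is a combination of the module latency constants and the layer's
#' block counts: MBLOCKS = ceiling(cols/M) column blocks, NBLOCKS =
#' ceiling(rows/N) row blocks, BLOCKS their product (cycles to stream
#' the whole weight matrix). Tags 2 and 3 are reserved for external
#' connectivity and are deliberately absent from the map, so indexing
#' them fails loudly.
#'
#' @param rows,cols Layer weight-matrix dimensions.
#' @param arch An [arch_config()].
#' @return Object of class `layer_schedule`: `MBLOCKS`, `NBLOCKS`,
#'   `BLOCKS` and `tags`, a named list keyed "0","1","4"..."13".
#' @export
layer_tags <- function(rows, cols, arch) {
  stopifnot(inherits(arch, "arch_config"))
  if (!is_count(rows) || !is_count(cols)) stop("rows and cols must be >= 1")
  ml <- arch$module_lat
  MB <- ceiling(cols / arch$M)
  NB <- ceiling(rows / arch$N)
  BL <- MB * NB
  head <- ml$L_QA + ml$L_MM                 # pipeline fill to first partial sum
  tags <- list(
    "0"  = head + BL + ml$L_AC + 1 + ml$L_MX + 1 + ml$L_LO,
    "1"  = MB,
    "4"  = head,
    "5"  = MB - 1,
    "6"  = head + ml$L_AC + 1 + ml$L_MX,
    "7"  = head + BL + ml$L_AC + 1 + ml$L_MX,
    "8"  = MB - 1,
    "9"  = MB - 1,
    "10" = head + BL + ml$L_AC + 1 + ml$L_MX + 1 + ml$L_LO - 1,
    "11" = head + ml$L_AC + 1,
    "12" = head + BL + ml$L_AC + 1,
    "13" = head + BL + ml$L_AC + 1
  )
  structure(list(MBLOCKS = MB, NBLOCKS = NB, BLOCKS = BL, tags = tags,
                 rows = rows, cols = cols),
            class = "layer_schedule")
}

#' @export
print.layer_schedule <- function(x, ...) {
  cat(sprintf("layer_schedule: %d x %d -> MBLOCKS=%d NBLOCKS=%d BLOCKS=%d\n",
              x$rows, x$cols, x$MBLOCKS, x$NBLOCKS, x$BLOCKS))
  for (id in names(x$tags)) cat(sprintf("  tag %-2s = %d\n", id, x$tags[[id]]))
  invisible(x)
}

#' Build the per-cycle trigger schedule
#'
#' Emits the full stall-free trigger trace for a model shape: one
#' weight block enters the datapath per cycle; a row block's sums
#' finalize after the multiply pipeline, adder tree and accumulate
#' register drain; the last row block then flows through the max-search
#' tree and the leading-one detector; a single-cycle bank swap hands the
#' requantized activations to the next layer. The trace is a pure
#' function of (dims, arch) — no module feedback, no randomness — and
#' its final `result_ready` cycle equals the closed-form
#' [total_latency()].
#'
#' @param dims Model dimensions `c(input_size, layer_sizes...)`.
#' @param arch An [arch_config()].
#' @return Object of class `trigger_trace`: data frame with columns
#'   `cycle`, `layer`, `event` (one of accumulate_reset, accumulate,
#'   max_update, lead1_latch, bank_swap, layer_advance, result_ready)
#'   and `block` (linear block index for accumulate events, row-block
#'   index for max updates, NA otherwise), sorted by cycle.
#' @export
build_schedule <- function(dims, arch) {
  stopifnot(inherits(arch, "arch_config"))
  d <- layer_dims_from_vector(dims)
  clM <- ceil_log2(arch$M)
  clN <- ceil_log2(arch$N)
  ev <- list()
  s <- 1  # main-counter value at which the layer's first block enters
  for (i in seq_len(d$K)) {
    ls <- layer_tags(d$rows[i], d$cols[i], arch)
    MB <- ls$MBLOCKS
    NB <- ls$NBLOCKS
    BL <- ls$BLOCKS
    span <- BL + clM + clN + 8  # cycles from first block to latched shift key
    b <- seq_len(BL)
    ev[[length(ev) + 1]] <- data.frame(
      cycle = s + b - 1, layer = i,
      event = ifelse((b - 1) %% MB == 0, "accumulate_reset", "accumulate"),
      block = b)
    nb <- seq_len(NB)
    ev[[length(ev) + 1]] <- data.frame(
      cycle = s + nb * MB - 1 + clM + 2, layer = i,
      event = "max_update", block = nb)
    ev[[length(ev) + 1]] <- data.frame(
      cycle = s + span - 1, layer = i, event = "lead1_latch", block = NA_real_)
    if (i < d$K) {
      ev[[length(ev) + 1]] <- data.frame(
        cycle = s + span, layer = i,
        event = c("bank_swap", "layer_advance"), block = NA_real_)
      s <- s + span + 1
    } else {
      ev[[length(ev) + 1]] <- data.frame(
        cycle = s + span - 1, layer = i,
        event = c("bank_swap", "result_ready"), block = NA_real_)
    }
  }
  trace <- do.call(rbind, ev)
  trace <- trace[order(trace$cycle), , drop = FALSE]
  rownames(trace) <- NULL
  class(trace) <- c("trigger_trace", "data.frame")
  trace
}

#' @export
print.trigger_trace <- function(x, ...) {
  cat(sprintf("trigger_trace: %d events, result_ready at cycle %d\n",
              nrow(x), result_ready_cycle(x)))
  NextMethod()
}

#' Completion cycle of a trigger trace
#'
#' @param trace A `trigger_trace`.
#' @return The main-counter value at which the final decision is ready.
#' @export
result_ready_cycle <- function(trace) {
  rr <- trace$cycle[trace$event == "result_ready"]
  if (length(rr) != 1) stop("trace has no unique result_ready event")
  rr
}

#' Event-driven cycle simulation of quantized inference
#'
#' Replays the trigger schedule of [build_schedule()] against the
#' functional datapath: accumulate events run [scalar_product_block()]
#' and [accumulate()] on the block the counter addresses, max updates
#' stream finalized row blocks through [max_search()], the lead1 latch
#' keys the requantizer, and the bank swap enforces the two-bank buffer
#' discipline — the next layer reads only the bank written at the swap.
#' Functional results are produced by an independent code path from
#' [infer_quantized()] and must be bit-identical to it; the completion
#' cycle must equal [total_latency()].
#'
#' @param model A `quantized_mlp`.
#' @param qx Integer input vector in \[0, 127\].
#' @param arch An [arch_config()].
#' @return List with `class`, `outputs`, `trace` (the `trigger_trace`)
#'   and `result_ready` (completion cycle).
#' @export
simulate_inference <- function(model, qx, arch) {
  stopifnot(inherits(model, "quantized_mlp"), inherits(arch, "arch_config"))
  if (length(qx) != model$dims[1])
    stop("input length ", length(qx), " != model input size ", model$dims[1])
  if (any(qx < 0 | qx > 127)) stop("quantized inputs must lie in [0, 127]")
  trace <- build_schedule(model$dims, arch)
  M <- arch$M
  N <- arch$N
  K <- length(model$layers)

  out_bank <- as.numeric(qx)  # bank read by the current layer
  layer_state <- NULL
  enter_layer <- function(i) {
    l <- model$layers[[i]]
    rows <- nrow(l$qweights)
    cols <- ncol(l$qweights)
    MB <- ceiling(cols / M)
    NB <- ceiling(rows / N)
    wp <- matrix(0, NB * N, MB * M)
    wp[seq_len(rows), seq_len(cols)] <- l$qweights
    xp <- c(out_bank, numeric(MB * M - cols))
    bp <- c(l$qbias, numeric(NB * N - rows))
    list(rows = rows, MB = MB, NB = NB, wp = wp, xp = xp, bp = bp,
         acc = numeric(NB * N), gmax = -Inf, lead1 = NA_integer_)
  }
  layer_state <- enter_layer(1)
  final <- NULL

  for (r in seq_len(nrow(trace))) {
    evt <- trace$event[r]
    if (evt %in% c("accumulate", "accumulate_reset")) {
      b <- trace$block[r]
      nb <- (b - 1) %/% layer_state$MB + 1
      mb <- (b - 1) %% layer_state$MB + 1
      ridx <- ((nb - 1) * N + 1):(nb * N)
      cidx <- ((mb - 1) * M + 1):(mb * M)
      partial <- scalar_product_block(
        layer_state$wp[ridx, cidx, drop = FALSE], layer_state$xp[cidx])
      layer_state$acc[ridx] <- accumulate(
        layer_state$acc[ridx], partial, bias = layer_state$bp[ridx],
        first_block = evt == "accumulate_reset",
        last_col_block = mb == layer_state$MB)
    } else if (evt == "max_update") {
      nb <- trace$block[r]
      ridx <- ((nb - 1) * N + 1):(nb * N)
      local <- max_search(list(layer_state$acc[ridx]))
      if (local > layer_state$gmax) layer_state$gmax <- local
    } else if (evt == "lead1_latch") {
      layer_state$lead1 <- leading1(
        max(min(layer_state$gmax, INT32_MAX), INT32_MIN))
    } else if (evt == "bank_swap") {
      i <- trace$layer[r]
      valid <- layer_state$acc[seq_len(layer_state$rows)]
      if (i < K) {
        out_bank <- relu_requantize(valid, layer_state$lead1)
        layer_state <- enter_layer(i + 1)
      } else {
        final <- valid
      }
    }
  }
  if (is.null(final)) stop("internal consistency error: trace never finalized")
  list(class = which.max(final) - 1L, outputs = final,
       trace = trace, result_ready = result_ready_cycle(trace))
}
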