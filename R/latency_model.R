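layer_dims_from_vector <- function(dims) {
  dims <- as.numeric(dims)
  if (length(dims) < 2 || any(dims < 1) || any(dims != floor(dims)))
    stop("dims must be at least two positive integers: input size then layer sizes")
  K <- length(dims) - 1
  list(K = K,
       rows = dims[seq_len(K) + 1],
       cols = dims[seq_len(K)])
}

#' Variable-critical-path cycle total
#'
#' Cycles spent iterating scalar-product blocks: the sum over layers of
#' `ceiling(rows_i / N) * ceiling(cols_i / M)` — the number of M x N
#' weight blocks, one per cycle. This is the application-dependent part
#' of the latency; it shrinks as M and N grow.
#'
#' @param dims Model dimensions `c(input_size, layer_sizes...)`.
#' @param arch An [arch_config()].
#' @return Total VCP cycles.
#' @examples
#' vcp_total(c(15154, 512, 512, 2), arch_config(256, 8)) # 3970
#' @export
vcp_total <- function(dims, arch) {
  d <- layer_dims_from_vector(dims)
  sum(ceiling(d$rows / arch$N) * ceiling(d$cols / arch$M))
}

#' Persistent-critical-path cycle total
#'
#' The fixed per-layer tail — scalar-product adder tree, accumulate
#' register, max-search tree and register, and the fixed 32-bit
#' leading-one tree — summarized as
#' `K * (ceiling(log2 M) + ceiling(log2 N) + 8) - 1`. Independent of
#' layer sizes; it grows with M and N.
#'
#' @param K Number of layers (>= 1).
#' @param arch An [arch_config()].
#' @return Total PCP cycles.
#' @examples
#' pcp_total(3, arch_config(256, 8)) # 56
#' @export
pcp_total <- function(K, arch) {
  if (!is_count(K)) stop("K must be a positive integer >= 1")
  as.numeric(K * (ceil_log2(arch$M) + ceil_log2(arch$N) + 8) - 1)
}

#' Total inference latency (closed form)
#'
#' Sums, per layer, the block count plus the persistent tail —
#' `ceiling(log2 M)` for the scalar-product adder tree, one cycle for
#' the single-stage multiply pipeline, one for the accumulate register,
#' `ceiling(log2 N)` for the max-search tree, one for its register and
#' `log2(32) = 5` for the fixed leading-one tree — and adds one
#' single-cycle buffer transfer between consecutive layers. The
#' persistent portion of this total exceeds the [pcp_total()] summary by
#' exactly K cycles; the total is the quantity the explorer minimizes,
#' while [pcp_total()] is exposed as the PCP summary metric.
#'
#' @param dims Model dimensions `c(input_size, layer_sizes...)`.
#' @param arch An [arch_config()].
#' @return Object of class `latency_report`: per-layer table
#'   (rows, cols, mblocks, nblocks, blocks, persistent cycles),
#'   `vcp_total`, `pcp_total`, `interlayer` and `total`.
#' @examples
#' total_latency(c(15154, 512, 512, 2), arch_config(256, 8))
#' @export
total_latency <- function(dims, arch) {
  stopifnot(inherits(arch, "arch_config"))
  d <- layer_dims_from_vector(dims)
  clM <- ceil_log2(arch$M)
  clN <- ceil_log2(arch$N)
  mblocks <- ceiling(d$cols / arch$M)
  nblocks <- ceiling(d$rows / arch$N)
  blocks <- mblocks * nblocks
  persistent <- rep(clM + clN + 8, d$K)
  interlayer <- d$K - 1
  layers <- data.frame(layer = seq_len(d$K), rows = d$rows, cols = d$cols,
                       mblocks = mblocks, nblocks = nblocks, blocks = blocks,
                       persistent = persistent)
  structure(list(layers = layers,
                 vcp_total = sum(blocks),
                 pcp_total = pcp_total(d$K, arch),
                 persistent_total = sum(persistent) + interlayer,
                 interlayer = interlayer,
                 total = sum(blocks) + sum(persistent) + interlayer,
                 M = arch$M, N = arch$N),
            class = "latency_report")
}

#' @export
print.latency_report <- function(x, ...) {
  cat(sprintf("latency_report (M = %d, N = %d)\n", x$M, x$N))
  print(x$layers, row.names = FALSE)
  cat(sprintf("  VCP total: %d cycles\n", as.integer(x$vcp_total)))
  cat(sprintf("  PCP total: %d cycles\n", as.integer(x$pcp_total)))
  cat(sprintf("  inter-layer transfers: %d cycles\n", as.integer(x$interlayer)))
  cat(sprintf("  total: %d cycles\n", as.integer(x$total)))
  invisible(x)
}
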