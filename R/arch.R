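#' Generic per-module latency model
#'
#' Latency of one hardware module expressed as pipelined reduction trees:
#' `D * (A * ceiling(log2(B)) + C)` cycles, where `A` is the number of
#' pipeline stages per tree layer, `B` the tree fan-in (number of variables
#' reduced), `C` a constant cycle offset and `D` the number of module calls
#' (only ever > 1 for modules on the variable critical path).
#'
#' @param A Pipeline stages per tree layer (>= 0).
#' @param B Tree fan-in (>= 1).
#' @param C Constant latency offset (>= 0).
#' @param D Number of module calls (>= 1).
#' @return Cycle count (numeric scalar).
#' @examples
#' module_latency(A = 1, B = 32, C = 0, D = 1) # fixed 32-bit leading-1 tree
#' @export
module_latency <- function(A, B, C = 0, D = 1) {
  if (!is_count(B)) stop("B (tree fan-in) must be a positive integer")
  if (!is_count(D)) stop("D (call count) must be a positive integer")
  if (A < 0 || C < 0) stop("A and C must be non-negative")
  as.numeric(D * (A * ceil_log2(B) + C))
}

#' Module latency constants for a given (M, N)
#'
#' Realizes the per-module cycle counts used by the latency-tag control
#' schedule: `L_QA` (activation & requantization read stage), `L_MM`
#' (scalar-product multiply stage plus its M-input adder tree), `L_AC`
#' (accumulate), `L_MX` (N-input max-search tree) and `L_LO` (fixed
#' 32-bit leading-one tree). Any constant can be overridden to model a
#' different hardware realization of that module.
#'
#' @param M Columns of the weight matrix processed per cycle.
#' @param N Rows processed per cycle.
#' @param overrides Named list of realized latencies to override, e.g.
#'   `list(L_MX = 12)`.
#' @return Object of class `module_latency_spec`: list with entries
#'   `L_QA`, `L_MM`, `L_AC`, `L_MX`, `L_LO` and the `(A, B, C, D)`
#'   constants each was realized from.
#' @export
module_latency_spec <- function(M, N, overrides = list()) {
  if (!is_count(M) || !is_count(N)) stop("M and N must be positive integers")
  constants <- list(
    L_QA = c(A = 0, B = 1, C = 1, D = 1),
    L_MM = c(A = 1, B = M, C = 1, D = 1),
    L_AC = c(A = 0, B = 1, C = 1, D = 1),
    L_MX = c(A = 1, B = N, C = 0, D = 1),
    L_LO = c(A = 1, B = 32, C = 0, D = 1)
  )
  realized <- lapply(constants, function(k) {
    module_latency(k[["A"]], k[["B"]], k[["C"]], k[["D"]])
  })
  for (nm in names(overrides)) {
    if (!nm %in% names(realized)) stop("unknown module latency: ", nm)
    realized[[nm]] <- overrides[[nm]]
  }
  structure(c(realized, list(constants = constants, M = M, N = N)),
            class = "module_latency_spec")
}

#' Architecture configuration
#'
#' Design parameters of the blocked datapath: `M` columns and `N` rows of
#' a layer's weight matrix are consumed per cycle, so one cycle processes
#' one M-by-N block. The module latency constants and the multiplier
#' budget ride along for the latency model and explorer.
#'
#' @param M Columns processed per cycle (>= 1).
#' @param N Rows processed per cycle (>= 1).
#' @param module_lat A [module_latency_spec()]; defaults to the standard
#'   realization for this (M, N).
#' @param dsp_budget Number of DSP blocks available (two multipliers each).
#' @param alm_mult_budget Number of logic-fabric (ALM) multipliers.
#' @return Object of class `arch_config`.
#' @examples
#' arch_config(M = 256, N = 8)
#' @export
arch_config <- function(M, N, module_lat = NULL,
                        dsp_budget = 0, alm_mult_budget = 0) {
  if (!is_count(M) || !is_count(N)) stop("M and N must be positive integers")
  if (dsp_budget < 0 || alm_mult_budget < 0) stop("budgets must be >= 0")
  if (is.null(module_lat)) module_lat <- module_latency_spec(M, N)
  structure(list(M = as.integer(M), N = as.integer(N),
                 module_lat = module_lat,
                 dsp_budget = dsp_budget,
                 alm_mult_budget = alm_mult_budget),
            class = "arch_config")
}

#' @export
print.arch_config <- function(x, ...) {
  cat(sprintf("arch_config: M = %d, N = %d (one %dx%d weight block per cycle)\n",
              x$M, x$N, x$N, x$M))
  ml <- x$module_lat
  cat(sprintf("  module latencies [cycles]: QA=%d MM=%d AC=%d MX=%d LO=%d\n",
              ml$L_QA, ml$L_MM, ml$L_AC, ml$L_MX, ml$L_LO))
  invisible(x)
}
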