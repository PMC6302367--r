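#' Multiplier budget from FPGA resources
#'
#' Each DSP block hosts two multipliers (and one adder); logic-fabric
#' (ALM) multipliers add one each. The scalar-product plane needs M * N
#' multipliers, so the budget bounds the admissible (M, N) pairs.
#'
#' @param dsp_blocks Number of DSP blocks (>= 0).
#' @param alm_multipliers Number of ALM-based multipliers (>= 0).
#' @return Object of class `resource_budget` with `dsp_blocks`,
#'   `alm_multipliers` and `multipliers_total = 2 * dsp + alm`.
#' @examples
#' multiplier_budget(512, 1024) # 2048 multipliers: supports M*N = 256*8
#' @export
multiplier_budget <- function(dsp_blocks, alm_multipliers) {
  if (dsp_blocks < 0 || alm_multipliers < 0) stop("resource counts must be >= 0")
  total <- 2 * dsp_blocks + alm_multipliers
  if (total < 1) stop("multiplier budget is zero; no datapath can be built")
  structure(list(dsp_blocks = dsp_blocks, alm_multipliers = alm_multipliers,
                 multipliers_total = total),
            class = "resource_budget")
}

#' Enumerate admissible (M, N) configurations
#'
#' All pairs with `M * N <= multipliers_total`, by default restricted to
#' powers of two (the sweep granularity hardware evaluations use); the
#' full integer grid is available behind the flag. Order is
#' deterministic: M ascending, then N ascending.
#'
#' @param budget A [multiplier_budget()].
#' @param powers_of_two If TRUE (default), restrict M and N to powers of 2.
#' @return Data frame with columns `M`, `N`.
#' @export
enumerate_configs <- function(budget, powers_of_two = TRUE) {
  stopifnot(inherits(budget, "resource_budget"))
  total <- budget$multipliers_total
  ms <- if (powers_of_two) 2^(0:floor(log2(total))) else seq_len(total)
  out <- do.call(rbind, lapply(ms, function(m) {
    ns <- if (powers_of_two) 2^(0:floor(log2(total / m))) else seq_len(total %/% m)
    data.frame(M = m, N = ns)
  }))
  out[order(out$M, out$N), , drop = FALSE]
}

#' Select the latency-optimal (M, N) under a multiplier budget
#'
#' Evaluates the closed-form total latency for every admissible
#' configuration and ranks them ascending. Ties resolve toward larger M
#' and then smaller N: in measured hardware, widening M is the cheaper
#' way to spend resources, so tied configurations fall toward that
#' corner.
#'
#' @param dims Model dimensions `c(input_size, layer_sizes...)`.
#' @param budget A [multiplier_budget()].
#' @param powers_of_two Restrict the sweep to powers of two (default TRUE).
#' @return Object of class `exploration_result`: `ranking` (data frame
#'   M, N, vcp, pcp, total, sorted by total then the tie-break), and
#'   `chosen` (the first row as a list).
#' @export
select_optimal <- function(dims, budget, powers_of_two = TRUE) {
  configs <- enumerate_configs(budget, powers_of_two)
  if (nrow(configs) == 0) stop("no admissible (M, N) configuration")
  reports <- lapply(seq_len(nrow(configs)), function(i) {
    a <- arch_config(configs$M[i], configs$N[i])
    r <- total_latency(dims, a)
    data.frame(M = configs$M[i], N = configs$N[i],
               vcp = r$vcp_total, pcp = r$pcp_total, total = r$total)
  })
  ranking <- do.call(rbind, reports)
  ranking <- ranking[order(ranking$total, -ranking$M, ranking$N), , drop = FALSE]
  rownames(ranking) <- NULL
  structure(list(ranking = ranking,
                 chosen = as.list(ranking[1, , drop = FALSE]),
                 dims = dims, budget = budget),
            class = "exploration_result")
}

#' @export
print.exploration_result <- function(x, ...) {
  cat(sprintf("exploration_result: %d configurations under %d multipliers\n",
              nrow(x$ranking), x$budget$multipliers_total))
  cat(sprintf("  chosen: M = %d, N = %d (total %d cycles, VCP %d, PCP %d)\n",
              x$chosen$M, x$chosen$N, x$chosen$total, x$chosen$vcp, x$chosen$pcp))
  print(utils::head(x$ranking, 10), row.names = FALSE)
  if (nrow(x$ranking) > 10) cat("  ...\n")
  invisible(x)
}
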