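#' Screening thresholds and conventions
#'
#' A single configuration object carries every tunable of the screen.
#'
#' * `alpha` — significance threshold for a down- or up-call (strict
#'   `p < alpha`). Default 0.05.
#' * `lfc_down` / `lfc_up` — log2 fold-change cutoffs for down-/up-calls
#'   (strict `log2fc < lfc_down`, `log2fc > lfc_up`). Defaults 0: any
#'   significant change of the right sign counts; no magnitude requirement.
#' * `hierarchy_threshold` — fraction of the reference checkpoint panel that
#'   a knockout must down-call (strictly more than) to classify as
#'   high-hierarchy. Default 0.20.
#' * `stringency_k`, `stringency_n` — the k-of-n rule of the final round: a
#'   candidate must be down-called under at least `k` of the `n`
#'   high-hierarchy knockout targets. Defaults 3 of 5.
#' * `percent_decimals` — decimals for display percentages (default 1);
#'   classification always uses unrounded fractions.
#' * `seed` — optional integer used by stochastic helpers.
#'
#' @param alpha,lfc_down,lfc_up,hierarchy_threshold,stringency_k,stringency_n,percent_decimals,seed
#'   See details above.
#' @return An object of class `screen_config`.
#' @examples
#' screen_config()
#' screen_config(alpha = 0.01, stringency_k = 4)
#' @export
screen_config <- function(alpha = 0.05, lfc_down = 0, lfc_up = 0,
                          hierarchy_threshold = 0.20,
                          stringency_k = 3L, stringency_n = 5L,
                          percent_decimals = 1L, seed = NULL) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop_ic("screen_config: alpha must be in (0, 1)")
  }
  if (!is.numeric(hierarchy_threshold) || hierarchy_threshold < 0 ||
      hierarchy_threshold >= 1) {
    stop_ic("screen_config: hierarchy_threshold must be in [0, 1)")
  }
  stringency_k <- as.integer(stringency_k)
  stringency_n <- as.integer(stringency_n)
  if (stringency_k < 1L || stringency_k > stringency_n) {
    stop_ic("screen_config: need 1 <= stringency_k <= stringency_n")
  }
  structure(
    list(alpha = alpha, lfc_down = lfc_down, lfc_up = lfc_up,
         hierarchy_threshold = hierarchy_threshold,
         stringency_k = stringency_k, stringency_n = stringency_n,
         percent_decimals = as.integer(percent_decimals), seed = seed),
    class = "screen_config"
  )
}

#' @export
print.screen_config <- function(x, ...) {
  cat("<screen_config>\n")
  cat(sprintf("  alpha                %.3g (strict p < alpha)\n", x$alpha))
  cat(sprintf("  lfc_down / lfc_up    %.3g / %.3g (strict)\n",
              x$lfc_down, x$lfc_up))
  cat(sprintf("  hierarchy_threshold  %.3g (strict >)\n",
              x$hierarchy_threshold))
  cat(sprintf("  stringency           >= %d of %d high-hierarchy targets\n",
              x$stringency_k, x$stringency_n))
  invisible(x)
}
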