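# Result containers for estimators. `mr_estimate` holds a scalar causal
# effect, `mr_mvestimate` one effect per exposure; both carry normal-theory
# CIs and p-values plus method metadata and instrument-strength diagnostics.

new_mr_estimate <- function(method, estimate, se, ci_level = 0.95,
                            p_value = NULL, ci = NULL, heterogeneity = NULL,
                            strength = NULL, options = list(), J = NA_integer_,
                            extra = list()) {
  ci <- ci %||% normal_ci(estimate, se, ci_level)
  p_value <- p_value %||% normal_p(estimate, se)
  structure(
    c(list(method = method, estimate = unname(estimate), se = unname(se),
           ci_lower = unname(ci[, "lower"]), ci_upper = unname(ci[, "upper"]),
           ci_level = ci_level, p_value = unname(p_value),
           heterogeneity = heterogeneity, strength = strength,
           options = options, J = J),
      extra),
    class = "mr_estimate")
}

new_mr_mvestimate <- function(method, exposures, estimate, se, ci_level = 0.95,
                              p_value = NULL, ci = NULL, heterogeneity = NULL,
                              strength = NULL, options = list(),
                              J = NA_integer_, extra = list()) {
  out <- new_mr_estimate(method, estimate, se, ci_level, p_value, ci,
                         heterogeneity, strength, options, J, extra)
  out$exposures <- exposures
  class(out) <- c("mr_mvestimate", "mr_estimate")
  out
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s (J = %d variants)\n", x$method, x$J))
  if (inherits(x, "mr_mvestimate")) {
    tab <- data.frame(
      Exposure = x$exposures,
      Estimate = sprintf("%.3f", x$estimate),
      `Std Error` = sprintf("%.3f", x$se),
      `95% CI` = sprintf("%.3f, %.3f", x$ci_lower, x$ci_upper),
      `p-value` = sprintf("%.3f", x$p_value),
      check.names = FALSE)
    if (!is.null(x$strength$conditional_f)) {
      tab$`Cond F-stat` <- sprintf("%.1f", x$strength$conditional_f)
    }
    print(tab, row.names = FALSE)
  } else {
    cat(sprintf("Estimate %.3f  Std Error %.3f  %g%% CI %.3f, %.3f  p-value %.3f\n",
                x$estimate, x$se, 100 * x$ci_level, x$ci_lower, x$ci_upper,
                x$p_value))
    if (!is.null(x$strength$f_stat)) {
      cat(sprintf("F statistic = %.1f\n", x$strength$f_stat))
    }
  }
  invisible(x)
}

#' Serialize an estimate (or other result) to JSON
#'
#' Produces stable key names so results can be consumed programmatically;
#' parsing and re-serializing the JSON is idempotent.
#'
#' @param x an `mr_estimate`, `mr_mvestimate`, `mr_prune`, or plain list.
#' @param pretty pretty-print the JSON (default TRUE).
#' @return a JSON string.
#' @export
mr_to_json <- function(x, pretty = TRUE) {
  strip <- function(l) {
    l <- unclass(l)
    if (!is.list(l)) return(l)
    l <- l[!vapply(l, is.null, TRUE)]
    lapply(l, strip)
  }
  jsonlite::toJSON(strip(x), auto_unbox = TRUE, digits = NA,
                   pretty = pretty, null = "null")
}
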