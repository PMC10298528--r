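#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an LFMM scan
#'
#' @param x An `lfmm_fit`.
#' @param ... Unused.
#' @return The per-(locus, variable) association tibble.
#' @method tidy lfmm_fit
#' @export
tidy.lfmm_fit <- function(x, ...) tibble::as_tibble(x$results)

#' One-row summary of an LFMM scan
#'
#' @param x An `lfmm_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `K`, `n`, `m`, `lambda_median`, `n_selected`.
#' @method glance lfmm_fit
#' @export
glance.lfmm_fit <- function(x, ...) {
  tibble::tibble(
    K = x$K, n = x$n, m = x$m,
    lambda_median = stats::median(x$lambda),
    n_selected = sum(x$results$selected, na.rm = TRUE)
  )
}

#' Tidy a kinship REML fit
#'
#' @param x An `emma_fit`.
#' @param ... Unused.
#' @return A tibble of variance components.
#' @method tidy emma_fit
#' @export
tidy.emma_fit <- function(x, ...) {
  tibble::tibble(
    term = c("sigma_g2", "sigma_e2", "delta"),
    estimate = c(x$sigma_g2, x$sigma_e2, x$delta)
  )
}

#' One-row summary of a kinship REML fit
#'
#' @param x An `emma_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `delta`, `heritability`, `reml_loglik`, `n`.
#' @method glance emma_fit
#' @export
glance.emma_fit <- function(x, ...) {
  tibble::tibble(
    delta = x$delta,
    heritability = 1 / (1 + x$delta),
    reml_loglik = as.numeric(x$reml_loglik),
    n = x$n
  )
}
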