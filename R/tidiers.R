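#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.varcomp_fit <- function(x, ...) {
  k <- length(x$sigma2) - 1L
  tibble::tibble(component = names(x$sigma2),
                 sigma2 = unname(x$sigma2),
                 se = unname(x$se),
                 h2 = c(unname(x$h2), NA_real_),
                 h2_se = c(unname(x$h2_se), NA_real_),
                 boundary = unname(x$boundary))
}

#' @export
glance.varcomp_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, n = x$n,
                 sigma2_p = x$sigma2_p,
                 h2_genetic = sum(x$h2),
                 converged = x$converged,
                 n_iter = max(x$trace$iter))
}

#' @export
tidy.fst_result <- function(x, ...) x$per_site

#' @export
glance.fst_result <- function(x, ...) {
  tibble::tibble(theta_overall = x$theta_overall,
                 n_sites = sum(!x$per_site$excluded),
                 n_excluded = sum(x$per_site$excluded))
}

#' @export
tidy.rda_result <- function(x, ...) x$partition

#' @export
glance.rda_result <- function(x, ...) {
  tibble::tibble(total_inertia = x$total_inertia,
                 full_proportion = x$partition$proportion[x$partition$model == "full"])
}

#' @export
tidy.ld_decay <- function(x, ...) x$bins

#' @export
glance.ld_decay <- function(x, ...) {
  tibble::tibble(rho = x$rho, extent_bp = x$extent_bp, n = x$n)
}
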