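#' Van Raden genomic relationship matrix
#'
#' `W = M - 2 p` column-centered dosages (missing values mean-imputed per
#' site, monomorphic sites dropped); `GRM = W W' / (2 sum p (1 - p))`.
#'
#' @param G a [geno_matrix()].
#' @param sites optional site subset (indices or logical) for regional /
#'   chromosome matrices.
#' @param tag construction tag stored on the matrix.
#' @return Symmetric samples-by-samples matrix with attributes `tag` and
#'   `n_sites`.
#' @export
van_raden_grm <- function(G, sites = NULL, tag = "G") {
  stopifnot(inherits(G, "geno_matrix"))
  M <- G$dosage
  if (!is.null(sites)) M <- M[, sites, drop = FALSE]
  if (anyNA(M)) {
    mu <- colMeans(M, na.rm = TRUE)
    na <- which(is.na(M), arr.ind = TRUE)
    M[na] <- mu[na[, 2]]
  }
  p <- colMeans(M) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) abort_input("no polymorphic sites for GRM construction")
  M <- M[, poly, drop = FALSE]; p <- p[poly]
  W <- sweep(M, 2, 2 * p)
  K <- tcrossprod(W) / (2 * sum(p * (1 - p)))
  dimnames(K) <- list(G$samples$sample_id, G$samples$sample_id)
  attr(K, "tag") <- tag
  attr(K, "n_sites") <- sum(poly)
  K
}

# REML log-likelihood pieces for V = sum_i s2_i K_i + s2_e I, X = intercept
reml_eval <- function(y, K_list, s2) {
  n <- length(y)
  V <- diag(s2[length(s2)], n)
  for (i in seq_along(K_list)) V <- V + s2[i] * K_list[[i]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  Vinv <- chol2inv(ch)
  X <- matrix(1, n, 1)
  VX <- Vinv %*% X
  XVX <- crossprod(X, VX)
  P <- Vinv - VX %*% solve(XVX, t(VX))
  Py <- drop(P %*% y)
  ll <- -0.5 * (2 * sum(log(diag(ch))) + log(XVX[1, 1]) + sum(y * Py))
  list(P = P, Py = Py, loglik = ll)
}

#' Multi-component AI-REML
#'
#' Restricted maximum likelihood for `y = 1 mu + sum_i u_i + e` with
#' `Var(u_i) = sigma2_i K_i`, via average-information updates with
#' expectation-maximization fallback (step halving when the update would
#' decrease the restricted likelihood; variances constrained nonnegative).
#' Standard errors come from the inverse average-information matrix.
#'
#' @param y phenotype vector.
#' @param K_list named list of kinship matrices aligned with `y`.
#' @param max_iter,tol iteration cap and log-likelihood convergence
#'   tolerance.
#' @param constrain keep variance estimates nonnegative (default). Set
#'   `FALSE` for unconstrained estimates, which keep sums of many components
#'   unbiased (noise cancels instead of rectifying at the zero boundary).
#' @param verbose print the iteration trace.
#' @return A `varcomp_fit`: estimates `sigma2` (components + residual),
#'   standard errors, `vcov`, heritability shares `h2`, log-likelihood,
#'   convergence flag and iteration trace.
#' @export
reml_ai <- function(y, K_list, max_iter = 100L, tol = 1e-8,
                    constrain = TRUE, verbose = FALSE) {
  n <- length(y)
  if (n < 10) abort_input("too few observations for REML")
  k <- length(K_list)
  if (is.null(names(K_list)) || any(!nzchar(names(K_list))))
    names(K_list) <- paste0("K", seq_len(k))
  for (K in K_list) if (!isTRUE(all.equal(dim(K), c(n, n))))
    abort_input("kinship dimensions must match y")
  vy <- stats::var(y)
  s2 <- rep(vy / (k + 1), k + 1)
  names(s2) <- c(names(K_list), "residual")
  ev <- reml_eval(y, K_list, s2)
  if (is.null(ev)) abort_data("initial variance matrix not positive definite")
  trace <- tibble::tibble(iter = 0L, loglik = ev$loglik)
  AI <- NULL
  floor_s2 <- vy * 1e-8
  for (it in seq_len(max_iter)) {
    KPy <- c(lapply(K_list, function(K) drop(K %*% ev$Py)), list(ev$Py))
    # score_i = -0.5 (tr(P K_i) - y'P K_i P y); tr via elementwise product
    trPK <- c(vapply(K_list, function(K) sum(ev$P * K), numeric(1)), sum(diag(ev$P)))
    PKPy <- lapply(KPy, function(v) drop(ev$P %*% v))
    yPKPy <- vapply(KPy, function(v) sum(v * ev$Py), numeric(1))  # y'P K_i P y
    score <- -0.5 * (trPK - yPKPy)
    AI <- matrix(0, k + 1, k + 1)
    for (i in seq_len(k + 1)) for (j in i:(k + 1)) {
      AI[i, j] <- AI[j, i] <- 0.5 * sum(KPy[[i]] * PKPy[[j]])
    }
    delta <- tryCatch(solve(AI + diag(1e-10 * mean(diag(AI)), k + 1), score),
                      error = function(e) score / (abs(diag(AI)) + 1e-10))
    clamp <- function(x) if (constrain) pmax(x, floor_s2) else x
    step <- 1
    repeat {
      s2_new <- clamp(s2 + step * delta)
      ev_new <- reml_eval(y, K_list, s2_new)
      if (!is.null(ev_new) && ev_new$loglik >= ev$loglik - 1e-10) break
      step <- step / 2
      if (step < 1e-4) {
        if (constrain) {   # EM-style multiplicative fallback (always uphill)
          s2_new <- pmax(s2 * sqrt(yPKPy / pmax(trPK, 1e-12)), floor_s2)
          ev_new <- reml_eval(y, K_list, s2_new)
        } else ev_new <- NULL
        if (is.null(ev_new)) { s2_new <- s2; ev_new <- ev }
        break
      }
    }
    conv <- abs(ev_new$loglik - ev$loglik) < tol && max(abs(s2_new - s2)) < 1e-8 * vy
    s2 <- s2_new; ev <- ev_new
    trace <- dplyr::bind_rows(trace, tibble::tibble(iter = it, loglik = ev$loglik))
    if (verbose) message(sprintf("iter %d  logLik %.6f", it, ev$loglik))
    if (conv) break
  }
  converged <- it < max_iter || conv
  Vcov <- tryCatch(solve(AI), error = function(e) matrix(NA_real_, k + 1, k + 1))
  se <- sqrt(pmax(diag(Vcov), 0))
  names(se) <- names(s2)
  s2p <- sum(s2)
  h2 <- s2[seq_len(k)] / s2p
  # delta-method SEs and covariance for h2_i = s2_i / sum(s2)
  Jc <- matrix(-s2[seq_len(k)] / s2p^2, k, k + 1)
  for (i in seq_len(k)) Jc[i, i] <- Jc[i, i] + 1 / s2p
  h2_vcov <- Jc %*% Vcov %*% t(Jc)
  h2_se <- sqrt(pmax(diag(h2_vcov), 0))
  structure(list(sigma2 = s2, se = se, vcov = Vcov, h2 = h2, h2_se = h2_se,
                 h2_vcov = h2_vcov, sigma2_p = s2p, loglik = ev$loglik,
                 converged = converged, n = n, trace = trace,
                 boundary = constrain & s2 <= floor_s2 * 1.0001),
            class = "varcomp_fit")
}

#' @export
print.varcomp_fit <- function(x, ...) {
  cat(sprintf("<varcomp_fit> %d components + residual, n = %d, logLik = %.3f%s\n",
              length(x$sigma2) - 1L, x$n, x$loglik,
              if (x$converged) "" else " (NOT converged)"))
  print(tibble::tibble(component = names(x$sigma2), sigma2 = unname(x$sigma2),
                       se = unname(x$se)))
  invisible(x)
}

#' Genome-wide plus regional heritability model
#'
#' Fits `y = 1 + u + v + e` with `Var(u) = G sigma2_u` (genome-wide kinship)
#' and `Var(v) = Q sigma2_v` (regional kinship), and reports
#' `h2_u = sigma2_u / sigma2_p`, `h2_v = sigma2_v / sigma2_p` and their sum.
#'
#' @param y phenotype vector.
#' @param G_kin genome-wide kinship matrix.
#' @param Q_kin regional kinship matrix.
#' @param ... passed to [reml_ai()].
#' @return A `varcomp_fit` with a `summary` tibble
#'   (`h2_u`, `h2_v`, `h2_total`, SEs).
#' @export
reml_gq <- function(y, G_kin, Q_kin, ...) {
  if (isTRUE(all.equal(G_kin, Q_kin)))
    warning("Q equals G: the two components are not identifiable")
  fit <- reml_ai(y, list(u = G_kin, v = Q_kin), ...)
  fit$summary <- tibble::tibble(
    h2_u = fit$h2[["u"]], h2_u_se = fit$h2_se[[1]],
    h2_v = fit$h2[["v"]], h2_v_se = fit$h2_se[[2]],
    h2_total = fit$h2[["u"]] + fit$h2[["v"]],
    h2_total_se = sqrt(sum(fit$h2_vcov)))
  fit
}

#' Chromosome-by-subgenome heritability partition
#'
#' Joint REML over one kinship per chromosome (the 18-matrix partition for a
#' 9-chromosome allotetraploid); subgenome heritabilities are the sums of the
#' per-chromosome shares, and shares-of-genetic divide by the total genetic
#' variance.
#'
#' @param y phenotype vector.
#' @param Q_list named list of chromosome kinship matrices.
#' @param subgenome_of named character vector mapping each `Q_list` name to
#'   its subgenome; defaults to the last character of the name.
#' @param min_sites matrices built from fewer sites are flagged.
#' @param constrain nonnegativity constraint on the per-chromosome
#'   variances. Off by default: with many small components, clipping at zero
#'   rectifies noise and biases every subgenome sum upward, whereas
#'   unconstrained estimates cancel in the sums.
#' @param ... passed to [reml_ai()].
#' @return A `varcomp_fit` with `partition` (per-chromosome tibble) and
#'   `subgenomes` (per-subgenome sums and shares of genetic variance).
#' @export
reml_partition <- function(y, Q_list, subgenome_of = NULL, min_sites = 10L,
                           constrain = FALSE, ...) {
  if (is.null(names(Q_list))) abort_input("Q_list must be named by chromosome")
  subgenome_of <- subgenome_of %||%
    stats::setNames(substr(names(Q_list), nchar(names(Q_list)), nchar(names(Q_list))),
                    names(Q_list))
  fit <- reml_ai(y, Q_list, constrain = constrain, ...)
  ns <- vapply(Q_list, function(K) attr(K, "n_sites") %||% NA_integer_, numeric(1))
  fit$partition <- tibble::tibble(
    component = names(Q_list),
    subgenome = unname(subgenome_of[names(Q_list)]),
    sigma2 = unname(fit$sigma2[seq_along(Q_list)]),
    h2 = unname(fit$h2), h2_se = unname(fit$h2_se),
    n_sites = unname(ns),
    low_sites = !is.na(ns) & ns < min_sites)
  genetic <- sum(fit$h2)
  fit$subgenomes <- fit$partition |>
    dplyr::group_by(.data$subgenome) |>
    dplyr::summarise(h2 = sum(.data$h2)) |>
    dplyr::mutate(share_of_genetic = .data$h2 / genetic)
  fit
}

#' Compare regional and genome-wide heritability
#'
#' Tabulates `h2_u`, `h2_v`, their ratio, and a two-sided Z test of the
#' difference using the delta-method covariance of the two shares.
#'
#' @param fit a `varcomp_fit` from [reml_gq()].
#' @return One-row tibble (`h2_u`, `h2_v`, SEs, `ratio_v_u`, `z`, `p_two_sided`).
#' @export
h2_summary <- function(fit) {
  stopifnot(inherits(fit, "varcomp_fit"))
  if (!fit$converged) warning("summarizing a non-converged fit")
  h2u <- fit$h2[[1]]; h2v <- fit$h2[[2]]
  se_d <- sqrt(fit$h2_vcov[1, 1] + fit$h2_vcov[2, 2] - 2 * fit$h2_vcov[1, 2])
  z <- if (se_d > 0) (h2v - h2u) / se_d else 0
  tibble::tibble(h2_u = h2u, h2_u_se = fit$h2_se[[1]],
                 h2_v = h2v, h2_v_se = fit$h2_se[[2]],
                 ratio_v_u = if (h2u > 0) h2v / h2u else Inf,
                 z = z, p_two_sided = 2 * stats::pnorm(-abs(z)))
}
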