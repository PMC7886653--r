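#' SNP post-filters
#'
#' Applies, in order, the depth-range, repeat-mask (with padding),
#' missingness and minor-allele-frequency rules; a site failing several rules
#' is reported under the first failing one.
#'
#' @param G a [geno_matrix()]; the depth rule needs a `depth` column in
#'   `G$sites` (skipped otherwise).
#' @param maf_min minor-allele frequency must be strictly greater.
#' @param missing_max maximum tolerated missing fraction (inclusive).
#' @param depth_range inclusive per-site mean depth bounds.
#' @param repeat_mask optional tibble of half-open masked intervals
#'   (`chrom`, `start`, `end`), same 0-based coordinates as `G`.
#' @param mask_pad bp of padding around masked intervals; a site strictly
#'   within `mask_pad` bp of an interval is removed.
#' @return Filtered `geno_matrix`; removal counts per rule in attribute
#'   `"filter_report"`.
#' @export
filter_snps <- function(G, maf_min = 0.005, missing_max = 0.20,
                        depth_range = c(8, 500), repeat_mask = NULL,
                        mask_pad = 25L) {
  stopifnot(inherits(G, "geno_matrix"))
  m <- ncol(G$dosage)
  fail <- rep(NA_character_, m)
  if (!is.null(col_or_null(G$sites, "depth"))) {
    bad <- G$sites$depth < depth_range[1] | G$sites$depth > depth_range[2]
    fail[is.na(fail) & bad] <- "depth"
  }
  if (!is.null(repeat_mask) && nrow(repeat_mask)) {
    near <- vapply(seq_len(m), function(j) {
      iv <- repeat_mask[repeat_mask$chrom == G$sites$chrom[j], ]
      nrow(iv) > 0 && any(G$sites$pos[j] >= iv$start - mask_pad &
                          G$sites$pos[j] <  iv$end + mask_pad)
    }, logical(1))
    fail[is.na(fail) & near] <- "mask"
  }
  miss <- colMeans(is.na(G$dosage))
  fail[is.na(fail) & miss > missing_max] <- "missing"
  f <- allele_freq(G)
  maf <- pmin(f, 1 - f)
  fail[is.na(fail) & !(maf > maf_min)] <- "maf"
  keep <- is.na(fail)
  report <- tibble::tibble(rule = c("depth", "mask", "missing", "maf"),
                           n_removed = vapply(c("depth", "mask", "missing", "maf"),
                                              function(r) sum(fail == r, na.rm = TRUE),
                                              integer(1), USE.NAMES = FALSE))
  out <- subset_geno(G, sites = keep)
  attr(out, "filter_report") <- report
  out
}

# per-site Weir & Cockerham (1984) variance components from per-population
# allele frequencies, het frequencies and sample sizes
wc_components <- function(n_i, p_i, h_i) {
  r <- length(n_i)
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  c_ <- hbar / 2
  c(a = a, b = b, c = c_)
}

#' Weir-Cockerham F_ST
#'
#' Per-site variance components `a` (among populations), `b` (among
#' individuals within populations) and `c` (within individuals) of the
#' Weir & Cockerham (1984) theta estimator, plus the multi-site
#' ratio-of-sums estimate `sum(a) / sum(a+b+c)`. Sites monomorphic across
#' all populations are excluded and flagged.
#'
#' @param G a [geno_matrix()].
#' @param pops population labels per sample (default `G$samples$pop`).
#' @return A `fst_result`: list with `per_site` tibble
#'   (`chrom`, `pos`, `a`, `b`, `c`, `theta`, `excluded`) and
#'   `theta_overall`.
#' @export
wc_fst <- function(G, pops = NULL) {
  stopifnot(inherits(G, "geno_matrix"))
  pops <- pops %||% col_or_null(G$samples, "pop")
  if (is.null(pops)) abort_input("population labels required")
  pops <- as.character(pops)
  if (dplyr::n_distinct(pops) < 2) abort_input("need >= 2 populations")
  D <- G$dosage
  m <- ncol(D)
  pl <- split(seq_len(nrow(D)), pops)
  r <- length(pl)
  # per-population, per-site counts (vectorized across sites)
  N <- P <- H <- matrix(0, r, m)
  for (k in seq_len(r)) {
    X <- D[pl[[k]], , drop = FALSE]
    N[k, ] <- colSums(!is.na(X))
    P[k, ] <- colMeans(X, na.rm = TRUE) / 2
    H[k, ] <- colMeans(X == 1, na.rm = TRUE)
  }
  nbar <- colMeans(N)
  nc <- (r * nbar - colSums(N^2) / (r * nbar)) / (r - 1)
  pbar <- colSums(N * P) / (r * nbar)
  s2 <- colSums(N * (P - rep(pbar, each = r))^2) / ((r - 1) * nbar)
  hbar <- colSums(N * H) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  c_ <- hbar / 2
  comp <- cbind(a = a, b = b, c = c_)
  excluded <- apply(N, 2, min) < 2 | pbar <= 0 | pbar >= 1 | !is.finite(a)
  comp[excluded, ] <- NA_real_
  per_site <- tibble::tibble(chrom = G$sites$chrom, pos = G$sites$pos,
                             a = unname(comp[, 1]), b = unname(comp[, 2]),
                             c = unname(comp[, 3]),
                             theta = unname(comp[, 1] / rowSums(comp)),
                             excluded = unname(excluded))
  ok <- !excluded
  structure(list(per_site = per_site,
                 theta_overall = sum(comp[ok, 1]) / sum(comp[ok, ]),
                 pops = sort(unique(pops))),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("<fst_result> overall theta = %.4f over %d sites (%d excluded)\n",
              x$theta_overall, sum(!x$per_site$excluded), sum(x$per_site$excluded)))
  invisible(x)
}

# dosage correlation between site columns, pairwise-complete
dosage_cor <- function(D) suppressWarnings(stats::cor(D, use = "pairwise.complete.obs"))

# greedy left-to-right LD prune: drop a site when |r| >= r_max with a kept
# site within both the SNP-count and bp windows (window closes at whichever
# bound is reached first). r is assessed within populations; max |r| governs.
ld_prune <- function(D, pos, pops, r_max, win_snps, win_bp) {
  m <- ncol(D)
  keep <- logical(m)
  kept_idx <- integer(0)
  pl <- split(seq_len(nrow(D)), pops)
  for (j in seq_len(m)) {
    cand <- kept_idx[pos[j] - pos[kept_idx] <= win_bp]
    if (length(cand) > win_snps) cand <- utils::tail(cand, win_snps)
    drop <- FALSE
    for (i in cand) {
      rs <- vapply(pl, function(ix)
        abs(suppressWarnings(stats::cor(D[ix, i], D[ix, j],
                                        use = "pairwise.complete.obs"))),
        numeric(1))
      rs <- rs[is.finite(rs)]
      if (length(rs) && max(rs) >= r_max) { drop <- TRUE; break }
    }
    if (!drop) { keep[j] <- TRUE; kept_idx <- c(kept_idx, j) }
  }
  keep
}

#' Select ancestry-informative markers
#'
#' Cascade: (1) site quality (MAF, missingness on the parental panel);
#' (2) at least one pairwise Weir-Cockerham F_ST above `fst_min`;
#' (3) two-stage within-population LD pruning, first `|r| < 0.9` in
#' 10-SNP/1-kb windows, then `|r| < 0.95` in 1,000-SNP/10-kb windows.
#'
#' @param G a [geno_matrix()] of designated parental (non-admixed) samples.
#' @param pops population labels (default `G$samples$pop`).
#' @param fst_min minimum pairwise F_ST.
#' @param maf_min,missing_max site quality thresholds for this cascade.
#' @param prune_stages list of stages, each `list(r_max=, win_snps=, win_bp=)`.
#' @return tibble of retained sites (`site`, `chrom`, `pos`, `max_pair_fst`);
#'   per-stage survivor counts in attribute `"stage_counts"`.
#' @export
select_aims <- function(G, pops = NULL, fst_min = 0.4, maf_min = 0.05,
                        missing_max = 0.05,
                        prune_stages = list(
                          list(r_max = 0.90, win_snps = 10L, win_bp = 1000L),
                          list(r_max = 0.95, win_snps = 1000L, win_bp = 10000L))) {
  stopifnot(inherits(G, "geno_matrix"))
  pops <- pops %||% col_or_null(G$samples, "pop")
  f <- allele_freq(G); maf <- pmin(f, 1 - f)
  miss <- colMeans(is.na(G$dosage))
  keep <- maf >= maf_min & miss <= missing_max
  counts <- c(quality = sum(keep))
  pop_lv <- sort(unique(pops))
  pairs <- utils::combn(pop_lv, 2, simplify = FALSE)
  max_fst <- rep(-Inf, ncol(G$dosage))
  for (pr in pairs) {
    sel <- pops %in% pr
    th <- wc_fst(subset_geno(G, samples = sel), pops[sel])$per_site$theta
    max_fst <- pmax(max_fst, th, na.rm = TRUE)
  }
  keep <- keep & max_fst > fst_min
  counts <- c(counts, fst = sum(keep))
  for (st in prune_stages) {
    idx <- which(keep)
    if (!length(idx)) break
    ok_chr <- unlist(lapply(split(idx, G$sites$chrom[idx]), function(ix) {
      ix[ld_prune(G$dosage[, ix, drop = FALSE], G$sites$pos[ix], pops,
                  st$r_max, st$win_snps, st$win_bp)]
    }), use.names = FALSE)
    keep <- seq_along(keep) %in% ok_chr
    counts <- c(counts, stage = sum(keep))
  }
  if (!any(keep)) warning("no site passed the AIM cascade")
  out <- tibble::tibble(site = which(keep),
                        chrom = G$sites$chrom[keep], pos = G$sites$pos[keep],
                        max_pair_fst = max_fst[keep])
  attr(out, "stage_counts") <- counts
  out
}

# Hill-Weir expected r^2 at recombination C = rho * d, sample size n
hill_weir_r2 <- function(d, rho, n) {
  C <- rho * d
  ((10 + C) / ((2 + C) * (11 + C))) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' Linkage-disequilibrium decay curve and extent
#'
#' Computes dosage-correlation r^2 for intra-chromosomal site pairs up to
#' `max_dist`, averages r^2 in distance bins, fits the Hill-Weir expected
#' decay by nonlinear least squares, and reports the decay extent: the
#' smallest distance at which the absolute slope of the fitted curve drops
#' below `slope_tol` times its initial value.
#'
#' @param G a [geno_matrix()].
#' @param max_dist maximum pair distance (bp).
#' @param bin bin width (bp, default 500).
#' @param max_pairs subsample cap on the number of pairs.
#' @param slope_tol stabilization tolerance (fraction of initial slope).
#' @param seed subsampling seed.
#' @return An `ld_decay` list: `bins` tibble (`dist`, `mean_r2`, `n_pairs`),
#'   `rho` (fitted), `extent_bp` (NA when the fit fails), `n` (samples).
#' @export
ld_decay <- function(G, max_dist = 2e6, bin = 500, max_pairs = 2e5,
                     slope_tol = 0.01, seed = 1L) {
  stopifnot(inherits(G, "geno_matrix"))
  set.seed(seed)
  pr <- list(); k <- 1L
  for (ch in unique(G$sites$chrom)) {
    ix <- which(G$sites$chrom == ch)
    if (length(ix) < 2) next
    cmb <- utils::combn(ix, 2)
    d <- G$sites$pos[cmb[2, ]] - G$sites$pos[cmb[1, ]]
    okp <- d > 0 & d <= max_dist
    pr[[k]] <- cbind(t(cmb[, okp, drop = FALSE]), d[okp]); k <- k + 1L
  }
  pr <- do.call(rbind, pr)
  if (is.null(pr) || !nrow(pr)) abort_data("no intra-chromosomal site pairs")
  if (nrow(pr) > max_pairs) pr <- pr[sample.int(nrow(pr), max_pairs), ]
  r2 <- vapply(seq_len(nrow(pr)), function(i)
    suppressWarnings(stats::cor(G$dosage[, pr[i, 1]], G$dosage[, pr[i, 2]],
                                use = "pairwise.complete.obs"))^2,
    numeric(1))
  bins <- tibble::tibble(dist = (floor((pr[, 3] - 1) / bin) + 0.5) * bin, r2 = r2) |>
    dplyr::filter(is.finite(.data$r2)) |>
    dplyr::group_by(.data$dist) |>
    dplyr::summarise(mean_r2 = mean(.data$r2), n_pairs = dplyr::n()) |>
    dplyr::arrange(.data$dist)
  n <- nrow(G$dosage)
  fit <- tryCatch(
    minpack.lm::nlsLM(mean_r2 ~ hill_weir_r2(dist, rho, n),
                      data = bins, start = list(rho = 1e-4),
                      lower = 1e-12, upper = 1,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  rho <- if (!is.null(fit)) stats::coef(fit)[["rho"]] else NA_real_
  extent <- NA_real_
  if (is.finite(rho)) {
    dd <- seq(bin / 2, max(bins$dist), by = bin / 2)
    slope <- abs(diff(hill_weir_r2(dd, rho, n)))
    hit <- which(slope < slope_tol * slope[1])
    extent <- if (length(hit)) dd[hit[1]] else NA_real_
  }
  structure(list(bins = bins, rho = rho, extent_bp = extent, n = n),
            class = "ld_decay")
}

#' DAPC-style classification
#'
#' PCA, retention of the top `n_pc` scores, k-means into `k` groups, then
#' linear discriminant axes on the groups. The first discriminant score is
#' what downstream introgression-phenotype summaries use.
#'
#' @param X numeric sample-by-feature table (data frame or matrix).
#' @param k number of groups.
#' @param n_pc principal components retained.
#' @param seed k-means seed.
#' @return list: `assignments` tibble (`sample`, `group`, `ld1` when k > 1),
#'   `pca` (prcomp), `lda` (MASS::lda fit or NULL).
#' @export
dapc_classify <- function(X, k = 3L, n_pc = 10L, seed = 1L) {
  X <- as.matrix(X)
  if (k > nrow(X)) abort_param("k exceeds the number of samples")
  if (nrow(X) <= n_pc) abort_param("need more samples than retained PCs")
  pca <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  n_pc <- min(n_pc, ncol(pca$x))
  S <- pca$x[, seq_len(n_pc), drop = FALSE]
  ids <- rownames(X) %||% paste0("S", seq_len(nrow(X)))
  if (k == 1L)
    return(list(assignments = tibble::tibble(sample = ids, group = 1L),
                pca = pca, lda = NULL))
  set.seed(seed)
  km <- stats::kmeans(S, centers = k, nstart = 25)
  ld <- MASS::lda(S, grouping = factor(km$cluster))
  scores <- stats::predict(ld, S)$x
  list(assignments = tibble::tibble(sample = ids, group = km$cluster,
                                    ld1 = scores[, 1]),
       pca = pca, lda = ld)
}

#' Eigenvector ancestry coefficients
#'
#' Leading eigenvectors of the centered kinship matrix are projected onto the
#' simplex spanned by population vertices (centroids of designated
#' non-admixed samples per population); barycentric coordinates are solved by
#' least squares, clipped to `[0, 1]` and renormalized to sum to one.
#'
#' @param G a [geno_matrix()].
#' @param n_axes eigenvectors used (default 2; needs `n_axes >= k - 1`).
#' @param ref_pops named list: population -> sample ids of non-admixed
#'   representatives. Defaults to grouping by `G$samples$pop`; without any
#'   labels, extreme points on the axes are used with a warning.
#' @return tibble `sample_id` plus one proportion column per population.
#' @export
ancestry_coefficients <- function(G, n_axes = 2L, ref_pops = NULL) {
  stopifnot(inherits(G, "geno_matrix"))
  if (nrow(G$dosage) < 3) abort_input("need >= 3 samples")
  K <- van_raden_grm(G)
  Kc <- sweep(sweep(K, 1, rowMeans(K)), 2, colMeans(K)) + mean(K)
  ev <- eigen(Kc, symmetric = TRUE)
  U <- ev$vectors[, seq_len(n_axes), drop = FALSE]
  ids <- G$samples$sample_id
  if (is.null(ref_pops)) {
    if (!is.null(col_or_null(G$samples, "pop")) && !all(is.na(G$samples$pop))) {
      ref_pops <- split(ids, G$samples$pop)
    } else {
      warning("no population vertices supplied; using extreme points per axis")
      ref_pops <- lapply(seq_len(n_axes + 1L), function(i) {
        if (i <= n_axes) ids[which.max(U[, i])] else ids[which.min(U[, 1])]
      })
      names(ref_pops) <- paste0("vertex", seq_along(ref_pops))
    }
  }
  V <- t(vapply(ref_pops, function(s)
    colMeans(U[match(s, ids), , drop = FALSE]), numeric(n_axes)))
  k <- nrow(V)
  # least-squares barycentric coordinates with the sum-to-one constraint
  A <- rbind(t(V), rep(1, k))
  props <- t(apply(U, 1, function(x) {
    w <- stats::lsfit(A, c(x, 1), intercept = FALSE)$coefficients
    w <- pmin(pmax(w, 0), 1)
    w / sum(w)
  }))
  colnames(props) <- names(ref_pops)
  dplyr::bind_cols(tibble::tibble(sample_id = ids), tibble::as_tibble(props))
}
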