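#' Collapse significant GWAS peaks into 20-kb regions
#'
#' Peaks with `log10_bf > bf_min` are assigned to the fixed tiling window
#' (anchored at 0) containing their position; one region is kept per window
#' per trait class, with the contributing subpopulations and peak counts
#' recorded.
#'
#' @param peaks tibble `chrom`, `pos`, `log10_bf` and optionally `class`
#'   (e.g. climate/fitness) and `subpop`.
#' @param bf_min significance threshold on the log10 Bayes factor (strict).
#' @param window tiling window size in bp (default 20,000).
#' @return A `region_set` tibble: `chrom`, `start`, `end`, `class`,
#'   `n_peaks`, `n_subpops`, `subpops`.
#' @export
collapse_regions <- function(peaks, bf_min = 2, window = 20000L) {
  peaks <- tibble::as_tibble(peaks)
  if (!"class" %in% names(peaks)) peaks$class <- "all"
  if (!"subpop" %in% names(peaks)) peaks$subpop <- "all"
  sig <- peaks[peaks$log10_bf > bf_min, ]
  out <- sig |>
    dplyr::mutate(start = (.data$pos %/% window) * window,
                  end = .data$start + window) |>
    dplyr::group_by(.data$chrom, .data$start, .data$end, .data$class) |>
    dplyr::summarise(n_peaks = dplyr::n(),
                     n_subpops = dplyr::n_distinct(.data$subpop),
                     subpops = paste(sort(unique(.data$subpop)), collapse = ","),
                     .groups = "drop") |>
    dplyr::arrange(.data$class, .data$chrom, .data$start)
  class(out) <- c("region_set", class(out))
  attr(out, "window") <- window
  out
}

#' Region bookkeeping report
#'
#' Counts regions per trait class and the regions polymorphic in more than
#' one subpopulation, with the percentage (one decimal).
#'
#' @param regions a [collapse_regions()] result.
#' @return tibble `class`, `n_regions`, `n_multi_subpop`, `percent_multi`.
#' @export
region_summary <- function(regions) {
  regions |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(n_regions = dplyr::n(),
                     n_multi_subpop = sum(.data$n_subpops > 1),
                     percent_multi = round(100 * .data$n_multi_subpop / .data$n_regions, 1))
}

#' Overlap enrichment between two region (or locus) sets
#'
#' Fisher's exact test on the 2x2 membership table over an explicit universe;
#' reports the conditional-MLE odds ratio (with the sample odds ratio
#' alongside) and the two-sided p-value.
#'
#' @param set_a,set_b character vectors of member ids (e.g. window keys).
#' @param universe_n size of the universe; must cover the union.
#' @return tibble `n_both`, `n_a_only`, `n_b_only`, `n_neither`,
#'   `odds_ratio`, `odds_ratio_sample`, `p`.
#' @export
overlap_enrichment <- function(set_a, set_b, universe_n) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  un <- length(union(set_a, set_b))
  if (universe_n < un) abort_input("universe smaller than the union of the sets")
  if (!length(set_a) || !length(set_b))
    return(tibble::tibble(n_both = 0L, n_a_only = length(set_a),
                          n_b_only = length(set_b),
                          n_neither = universe_n - un,
                          odds_ratio = NA_real_, odds_ratio_sample = NA_real_,
                          p = NA_real_))
  both <- length(intersect(set_a, set_b))
  a_only <- length(set_a) - both
  b_only <- length(set_b) - both
  neither <- universe_n - both - a_only - b_only
  tab <- matrix(c(both, a_only, b_only, neither), 2)
  ft <- stats::fisher.test(tab)
  or_sample <- if (a_only * b_only == 0) Inf else (both * neither) / (a_only * b_only)
  tibble::tibble(n_both = both, n_a_only = a_only, n_b_only = b_only,
                 n_neither = neither,
                 odds_ratio = unname(ft$estimate),
                 odds_ratio_sample = or_sample,
                 p = ft$p.value)
}

#' Cluster climate variables and pick representatives
#'
#' Partitioning-around-medoids on the correlation distance `1 - |r|` between
#' variables; within each cluster the representative is the variable most
#' correlated (absolute) with the cluster's first principal eigenvector.
#'
#' @param vars sample-by-variable numeric table (standardized internally).
#' @param k number of clusters (default 7).
#' @return list `clusters` (tibble `variable`, `cluster`, `representative`,
#'   `cor_with_pc1`) and `representatives` (character vector, one per
#'   cluster).
#' @export
cluster_climate <- function(vars, k = 7L) {
  X <- scale(as.matrix(vars))
  if (k > ncol(X)) abort_param("k exceeds the number of variables")
  R <- stats::cor(X, use = "pairwise.complete.obs")
  cl <- if (k == ncol(X)) {
    stats::setNames(seq_len(k), colnames(X))   # trivial partition
  } else {
    cluster::pam(stats::as.dist(1 - abs(R)), k = k, diss = TRUE)$clustering
  }
  rep_of <- character(k)
  corpc <- numeric(ncol(X)); names(corpc) <- colnames(X)
  for (g in seq_len(k)) {
    mem <- names(cl)[cl == g]
    if (length(mem) == 1L) { rep_of[g] <- mem; corpc[mem] <- 1; next }
    pc1 <- stats::prcomp(X[, mem], center = FALSE, scale. = FALSE)$x[, 1]
    cc <- abs(stats::cor(X[, mem], pc1))
    corpc[mem] <- cc
    rep_of[g] <- mem[which.max(cc)]
  }
  list(clusters = tibble::tibble(variable = names(cl), cluster = unname(cl),
                                 representative = names(cl) %in% rep_of,
                                 cor_with_pc1 = unname(corpc[names(cl)])),
       representatives = rep_of)
}

#' k-nearest-neighbour phenotype imputation
#'
#' A missing cell is replaced by the mean of that trait over the `k` nearest
#' samples (Euclidean distance on shared standardized traits, scaled by the
#' number of shared traits) among samples with the trait observed.
#'
#' @param pheno sample-by-trait numeric table (may contain NA).
#' @param k neighbours (default 5); fewer available donors are used with a
#'   warning.
#' @return Completed tibble of the same shape.
#' @export
knn_impute <- function(pheno, k = 5L) {
  X <- as.matrix(pheno)
  if (any(rowSums(!is.na(X)) == 0)) abort_input("each sample needs >= 1 observed trait")
  if (!anyNA(X)) return(tibble::as_tibble(pheno))
  Z <- scale(X)
  Z[!is.finite(Z)] <- 0        # constant traits carry no distance information
  Z[is.na(X)] <- NA            # but missing cells stay missing
  out <- X
  for (idx in which(is.na(X))) {
    i <- (idx - 1L) %% nrow(X) + 1L
    j <- (idx - 1L) %/% nrow(X) + 1L
    donors <- which(!is.na(X[, j]) & seq_len(nrow(X)) != i)
    dist_i <- vapply(donors, function(d) {
      shared <- which(!is.na(Z[i, ]) & !is.na(Z[d, ]))
      if (!length(shared)) return(Inf)
      sqrt(mean((Z[i, shared] - Z[d, shared])^2))
    }, numeric(1))
    donors <- donors[is.finite(dist_i)]
    dist_i <- dist_i[is.finite(dist_i)]
    if (length(donors) < k)
      warning(sprintf("trait %d observed in fewer than k donors; using all %d",
                      j, length(donors)))
    use <- donors[order(dist_i)][seq_len(min(k, length(donors)))]
    out[i, j] <- mean(X[use, j])
  }
  tibble::as_tibble(out)
}

#' Redundancy-analysis variance partitioning
#'
#' One full redundancy analysis of the introgression carrier matrix on
#' climate, geography and kinship predictors, plus three partial models with
#' each factor conditioned on the other two. Reports constrained inertia and
#' its proportion of total inertia per model, with permutation p-values.
#'
#' @param Y samples-by-loci carrier matrix (0/1).
#' @param climate,geography,kinship numeric predictor tables aligned with
#'   `Y` rows (standardized internally).
#' @param n_perm permutations for the significance tests (default 999).
#' @param seed permutation seed.
#' @return An `rda_result`: `partition` tibble (`model`, `inertia`,
#'   `proportion`, `p`), `total_inertia`, `loadings` (loci x retained axes of
#'   the full model), fitted vegan models in `models`.
#' @export
rda_partition <- function(Y, climate, geography, kinship, n_perm = 999, seed = 1L) {
  Y <- as.matrix(Y)
  std <- function(M) {
    M <- scale(as.matrix(M))
    M[, apply(M, 2, function(x) all(is.finite(x))), drop = FALSE]
  }
  preds <- list(climate = std(climate), geography = std(geography),
                kinship = std(kinship))
  ntot <- sum(vapply(preds, ncol, integer(1)))
  if (nrow(Y) <= ntot) abort_input("need more samples than predictors")
  all_X <- do.call(cbind, preds)
  set.seed(seed)
  full <- vegan::rda(Y ~ ., data = as.data.frame(all_X))
  models <- list(full = full)
  rows <- list(tibble::tibble(
    model = "full", inertia = full$CCA$tot.chi,
    proportion = full$CCA$tot.chi / full$tot.chi,
    p = vegan::anova.cca(full, permutations = n_perm)$`Pr(>F)`[1]))
  for (f in names(preds)) {
    cond <- do.call(cbind, preds[setdiff(names(preds), f)])
    mod <- vegan::rda(Y, preds[[f]], cond)
    models[[f]] <- mod
    rows[[f]] <- tibble::tibble(
      model = paste0(f, "_conditioned"), inertia = mod$CCA$tot.chi,
      proportion = mod$CCA$tot.chi / mod$tot.chi,
      p = vegan::anova.cca(mod, permutations = n_perm)$`Pr(>F)`[1])
  }
  loadings <- vegan::scores(full, display = "species",
                            choices = seq_len(min(3, full$CCA$rank)))
  structure(list(partition = dplyr::bind_rows(rows), total_inertia = full$tot.chi,
                 loadings = as.matrix(loadings), models = models),
            class = "rda_result")
}

#' @export
print.rda_result <- function(x, ...) {
  cat("<rda_result> total inertia", format(x$total_inertia, digits = 4), "\n")
  print(x$partition)
  invisible(x)
}

#' Loading outliers of an ordination
#'
#' Flags loci whose loading sits at least `sd_mult` standard deviations from
#' the mean on any retained axis, and reports the implied two-tailed normal
#' p-value `2 (1 - Phi(sd_mult))` rounded to three decimals.
#'
#' @param loadings loci-by-axes loading matrix (or an `rda_result`).
#' @param sd_mult outlier threshold in standard deviations (default 2.5).
#' @return list `outliers` (tibble `locus`, `axis`, `loading`, `z`),
#'   `implied_p`.
#' @export
rda_outliers <- function(loadings, sd_mult = 2.5) {
  if (inherits(loadings, "rda_result")) loadings <- loadings$loadings
  L <- as.matrix(loadings)
  if (nrow(L) < 10) warning("fewer than 10 loci: loading s.d. is unstable")
  ids <- rownames(L) %||% paste0("locus", seq_len(nrow(L)))
  hits <- purrr::map_dfr(seq_len(ncol(L)), function(a) {
    x <- L[, a]; s <- stats::sd(x)
    if (!is.finite(s) || s == 0) return(NULL)
    z <- (x - mean(x)) / s
    sel <- abs(z) >= sd_mult
    tibble::tibble(locus = ids[sel], axis = a, loading = x[sel], z = z[sel])
  })
  list(outliers = hits, implied_p = round(2 * (1 - stats::pnorm(sd_mult)), 3))
}

#' Joint climate-fitness outlier enrichment
#'
#' Fisher's exact test of overlap between climate-associated and
#' fitness-associated outlier locus sets over the tested universe.
#'
#' @param outliers_climate,outliers_fitness locus id vectors.
#' @param universe all tested locus ids (both sets must be subsets).
#' @return As [overlap_enrichment()], plus `n_overlap`.
#' @export
climate_fitness_joint <- function(outliers_climate, outliers_fitness, universe) {
  if (!all(outliers_climate %in% universe) || !all(outliers_fitness %in% universe))
    abort_input("outlier sets must be subsets of the universe")
  res <- overlap_enrichment(outliers_climate, outliers_fitness, length(universe))
  dplyr::mutate(res, n_overlap = .data$n_both, .before = 1)
}

#' Score and rank candidate genes
#'
#' Candidates are genes overlapping a supplied introgression interval or
#' whose midpoint falls within 10 kb of a peak (a 20-kb interval centered on
#' the peak). Each candidate gets the midpoint distance, the weighted SnpEff
#' score `20 high + 5 moderate + 1 low`, and any supplied presence-absence,
#' structural-variant and coexpression annotations; ranking is by score
#' (descending) then distance (ascending).
#'
#' @param genes tibble `gene_id`, `chrom`, `start`, `end`.
#' @param peaks optional tibble `chrom`, `pos` of GWAS peaks.
#' @param intervals optional tibble `chrom`, `start`, `end` of introgression
#'   intervals.
#' @param snpeff_counts optional tibble `gene_id`, `high`, `moderate`, `low`.
#' @param pav,sv,coexpr optional tibbles keyed by `gene_id` with columns
#'   `absence_fraction`, `sv_maf`, `module`.
#' @param flank half-width of the peak interval (default 10,000 bp).
#' @return Ranked tibble of candidates with `distance_bp`, `snpeff_score`
#'   and annotation columns.
#' @export
score_candidates <- function(genes, peaks = NULL, intervals = NULL,
                             snpeff_counts = NULL, pav = NULL, sv = NULL,
                             coexpr = NULL, flank = 10000L) {
  genes <- dplyr::mutate(tibble::as_tibble(genes),
                         mid = (.data$start + .data$end) / 2)
  cand <- NULL
  if (!is.null(peaks) && nrow(peaks)) {
    cand <- purrr::map_dfr(seq_len(nrow(peaks)), function(i) {
      g <- genes[genes$chrom == peaks$chrom[i] &
                   abs(genes$mid - peaks$pos[i]) <= flank, ]
      if (!nrow(g)) return(NULL)
      dplyr::mutate(g, anchor = sprintf("peak:%s:%d", peaks$chrom[i], peaks$pos[i]),
                    distance_bp = abs(.data$mid - peaks$pos[i]))
    })
  }
  if (!is.null(intervals) && nrow(intervals)) {
    cand2 <- purrr::map_dfr(seq_len(nrow(intervals)), function(i) {
      g <- genes[genes$chrom == intervals$chrom[i] &
                   genes$end > intervals$start[i] & genes$start < intervals$end[i], ]
      if (!nrow(g)) return(NULL)
      imid <- (intervals$start[i] + intervals$end[i]) / 2
      dplyr::mutate(g, anchor = sprintf("interval:%s:%d-%d", intervals$chrom[i],
                                        intervals$start[i], intervals$end[i]),
                    distance_bp = abs(.data$mid - imid))
    })
    cand <- dplyr::bind_rows(cand, cand2)
  }
  if (is.null(cand) || !nrow(cand))
    return(tibble::tibble(gene_id = character(), anchor = character(),
                          distance_bp = numeric(), snpeff_score = numeric()))
  if (!is.null(snpeff_counts)) {
    cand <- dplyr::left_join(cand, snpeff_counts, by = "gene_id") |>
      dplyr::mutate(snpeff_score = snpeff_score(.data$high, .data$moderate, .data$low))
  } else cand$snpeff_score <- 0
  for (ann in list(pav, sv, coexpr))
    if (!is.null(ann)) cand <- dplyr::left_join(cand, ann, by = "gene_id")
  cand |>
    dplyr::select(-"mid") |>
    dplyr::arrange(dplyr::desc(.data$snpeff_score), .data$distance_bp)
}

#' Weighted SnpEff impact score
#'
#' @param high,moderate,low per-gene counts of high/moderate/low-impact SNPs.
#' @return `20 high + 5 moderate + 1 low` (NA counts treated as 0).
#' @export
snpeff_score <- function(high, moderate, low) {
  z <- function(x) ifelse(is.na(x), 0, x)
  20 * z(high) + 5 * z(moderate) + 1 * z(low)
}
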