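test_that("peak collapse assigns fixed 20-kb windows and counts regions", {
  peaks <- tibble::tibble(chrom = "c1", pos = c(1000, 15000, 30000),
                          log10_bf = c(3, 3, 3))
  r <- collapse_regions(peaks)
  expect_equal(nrow(r), 2)                 # 1000 & 15000 share a window
  expect_true(all(r$start %% 20000 == 0))
  # sub-threshold peaks drop; threshold is strict
  r2 <- collapse_regions(dplyr::mutate(peaks, log10_bf = c(2, 3, 1.9)))
  expect_equal(nrow(r2), 1)
  # random peaks: region count equals the brute-force distinct-window tally
  set.seed(4)
  rp <- tibble::tibble(chrom = sample(c("c1", "c2"), 100, TRUE),
                       pos = sample.int(4e5, 100), log10_bf = runif(100, 0, 4))
  got <- collapse_regions(rp)
  brute <- length(unique(paste(rp$chrom, rp$pos %/% 20000)[rp$log10_bf > 2]))
  expect_equal(nrow(got), brute)
  # order invariance
  expect_equal(nrow(collapse_regions(rp[sample(100), ])), brute)
})

test_that("region bookkeeping reports the multi-subpopulation percentage", {
  peaks <- dplyr::bind_rows(
    tibble::tibble(chrom = "c1", pos = seq(0, by = 20000, length.out = 50) + 10,
                   log10_bf = 3, class = "climate", subpop = "gulf"),
    tibble::tibble(chrom = "c1", pos = seq(0, by = 20000, length.out = 5) + 15,
                   log10_bf = 3, class = "climate", subpop = "midwest"))
  rs <- region_summary(collapse_regions(peaks))
  expect_equal(rs$n_regions, 50)
  expect_equal(rs$n_multi_subpop, 5)
  expect_equal(rs$percent_multi, 10.0)
})

test_that("Fisher enrichment matches hypergeometric enumeration to 1e-10", {
  cases <- list(c(8, 2, 1, 9), c(5, 5, 5, 5), c(60, 40, 60, 840),
                c(3, 0, 0, 12), c(10, 30, 5, 155))
  for (cs in cases) {
    a <- cs[1]; b <- cs[2]; c_ <- cs[3]; d <- cs[4]
    setA <- paste0("w", seq_len(a + b))
    setB <- paste0("w", c(seq_len(a), a + b + seq_len(c_)))
    res <- overlap_enrichment(setA, setB, sum(cs))
    expect_equal(res$p, fisher_oracle_p(a, b, c_, d), tolerance = 1e-10)
  }
  # independence-like table: OR ~ 1, p = 1
  ind <- overlap_enrichment(paste0("w", 1:10),
                            paste0("w", c(1:5, 11:15)), 20)
  expect_equal(ind$p, 1, tolerance = 1e-12)
  expect_error(overlap_enrichment("a", "b", 1), class = "polyadapt_input_error")
})

test_that("joint climate-fitness outlier overlap delegates to the exact test", {
  universe <- paste0("L", 1:1000)
  A <- paste0("L", 1:100); B <- paste0("L", 41:160)
  res <- climate_fitness_joint(A, B, universe)
  expect_equal(res$n_overlap, 60)
  expect_equal(res$p, fisher_oracle_p(60, 40, 60, 840), tolerance = 1e-10)
  expect_gt(res$odds_ratio, 1)
  # identical nonempty proper subsets: sample OR unbounded
  same <- climate_fitness_joint(A, A, universe)
  expect_equal(same$odds_ratio_sample, Inf)
  expect_error(climate_fitness_joint(c(A, "Lx"), B, universe),
               class = "polyadapt_input_error")
})

test_that("climate PAM clustering recovers planted collinear blocks", {
  set.seed(6)
  base <- matrix(rnorm(60 * 3), 60)
  vars <- cbind(base[, c(1, 1, 1)] + rnorm(180, sd = 0.05),
                base[, c(2, 2)] + rnorm(120, sd = 0.05),
                base[, 3])
  colnames(vars) <- paste0("v", 1:6)
  res <- cluster_climate(vars, k = 3)
  cl <- res$clusters$cluster
  expect_equal(dplyr::n_distinct(cl[1:3]), 1)
  expect_equal(dplyr::n_distinct(cl[4:5]), 1)
  expect_equal(length(res$representatives), 3)
  # representative has the max |cor| with its cluster PC1 by construction
  by_cl <- split(res$clusters, res$clusters$cluster)
  for (g in by_cl)
    expect_equal(g$cor_with_pc1[g$representative], max(g$cor_with_pc1))
  # uncorrelated variables, k = n: every variable its own representative
  un <- matrix(rnorm(300), 50); colnames(un) <- paste0("u", 1:6)
  res7 <- cluster_climate(un, k = 6)
  expect_equal(sort(res7$representatives), paste0("u", 1:6))
  expect_error(cluster_climate(un, k = 10), class = "polyadapt_param_error")
})

test_that("kNN imputation is identity on complete data and beats column means", {
  ph <- tibble::tibble(a = rnorm(10), b = rnorm(10))
  expect_equal(knn_impute(ph), ph)
  # six identical samples: the imputed cell equals the common value
  same <- tibble::tibble(a = rep(1, 6), b = c(5, 5, 5, 5, 5, NA))
  expect_equal(knn_impute(same, k = 5)$b[6], 5)
  # MCAR masking: kNN RMSE below column-mean imputation RMSE
  set.seed(9)
  lat <- rnorm(80)
  X <- tibble::tibble(t1 = lat + rnorm(80, sd = 0.3),
                      t2 = -lat + rnorm(80, sd = 0.3),
                      t3 = lat + rnorm(80, sd = 0.3))
  mask <- matrix(runif(240) < 0.1, 80)
  mask[rowSums(mask) == 3, 1] <- FALSE
  Xm <- as.matrix(X); Xm[mask] <- NA
  imp <- as.matrix(knn_impute(tibble::as_tibble(Xm)))
  colm <- Xm
  for (j in 1:3) colm[is.na(colm[, j]), j] <- mean(colm[, j], na.rm = TRUE)
  rmse <- function(M) sqrt(mean((M[mask] - as.matrix(X)[mask])^2))
  expect_lt(rmse(imp), rmse(colm))
  expect_error(knn_impute(tibble::tibble(a = c(NA, 1), b = c(NA, 2))),
               class = "polyadapt_input_error")
})

test_that("RDA partitioning matches a direct projection oracle and isolates signal", {
  set.seed(11)
  n <- 40
  clim <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("c1", "c2")))
  geo <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("lat", "lon")))
  kin <- matrix(rnorm(n * 2), n, dimnames = list(NULL, c("k1", "k2")))
  Y <- scale(clim %*% matrix(c(1, -1, 0.5, 2), 2), scale = FALSE) # pure climate signal
  res <- rda_partition(Y, clim, geo, kin, n_perm = 99)
  part <- res$partition
  expect_true(all(part$proportion >= 0 & part$proportion <= 1))
  # conditioning on four noise covariates absorbs ~4/(n-1) of the pure
  # signal, so the climate-conditioned share sits just below 1
  expect_gt(part$proportion[part$model == "climate_conditioned"], 0.8)
  expect_lt(part$proportion[part$model == "geography_conditioned"], 0.1)
  # constrained inertia equals explicit projection + eigen decomposition
  Yc <- scale(Y, scale = FALSE)
  X <- scale(cbind(clim, geo, kin))
  H <- X %*% solve(crossprod(X), t(X))
  fitted <- H %*% Yc
  oracle_inertia <- sum(fitted^2) / (n - 1)
  expect_equal(part$inertia[part$model == "full"], oracle_inertia, tolerance = 1e-8)
  expect_equal(res$total_inertia, sum(Yc^2) / (n - 1), tolerance = 1e-8)
})

test_that("loading outliers use the 2.5-sd rule with its implied p", {
  out <- rda_outliers(matrix(rnorm(5000), ncol = 1), sd_mult = 2.5)
  expect_equal(out$implied_p, 0.012)
  frac <- nrow(out$outliers) / 5000
  expect_lt(abs(frac - 0.0124), 0.006)
  expect_equal(nrow(rda_outliers(matrix(1, 50, 1))$outliers), 0)
  expect_warning(rda_outliers(matrix(rnorm(5), ncol = 1)), "unstable")
})

test_that("candidate genes are scored by SnpEff weights and midpoint distance", {
  expect_equal(snpeff_score(2, 3, 4), 59)
  genes <- tibble::tibble(gene_id = c("g0", "g1", "g2"),
                          chrom = "c1",
                          start = c(49000, 55000, 62000),
                          end = c(51000, 57000, 64000))
  peaks <- tibble::tibble(chrom = "c1", pos = 50000)
  eff <- tibble::tibble(gene_id = c("g0", "g1", "g2"),
                        high = c(0, 2, 5), moderate = c(1, 0, 0), low = c(0, 1, 0))
  res <- score_candidates(genes, peaks = peaks, snpeff_counts = eff)
  # g2 midpoint 63000 is 13 kb away -> excluded; ranking by score then distance
  expect_setequal(res$gene_id, c("g0", "g1"))
  expect_equal(res$gene_id[1], "g1")
  expect_equal(res$distance_bp[res$gene_id == "g0"], 0)
  # a gene 10,001 bp from the peak midpoint is excluded
  far <- tibble::tibble(gene_id = "gx", chrom = "c1", start = 60000, end = 60002)
  expect_equal(nrow(score_candidates(far, peaks = peaks)), 0)
  near <- tibble::tibble(gene_id = "gy", chrom = "c1", start = 59998, end = 60000)
  expect_equal(nrow(score_candidates(near, peaks = peaks)), 1)
  # interval overlap route
  iv <- tibble::tibble(chrom = "c1", start = 61000, end = 70000)
  res2 <- score_candidates(genes, intervals = iv)
  expect_equal(res2$gene_id, "g2")
})
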