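make_filter_fixture <- function() {
  # 10 hand-set sites: 2 depth failures, 2 mask failures, 1 missing, 2 MAF
  dos <- matrix(1, nrow = 10, ncol = 10)
  dos[, 1] <- rep(0:1, 5)                    # fine
  dos[, 2] <- 1                              # depth fail (depth 4)
  dos[, 3] <- 1                              # depth fail (depth 600)
  dos[, 4] <- rep(0:1, 5)                    # mask fail
  dos[, 5] <- rep(0:1, 5)                    # mask fail (24 bp away)
  dos[1:3, 6] <- NA                          # 30% missing
  dos[, 7] <- c(1, rep(0, 9))                # MAF 0.05 retained
  dos[, 8] <- 0                              # monomorphic -> MAF fail
  dos[, 9] <- 2                              # monomorphic -> MAF fail
  dos[, 10] <- rep(c(0, 2), 5)               # fine
  sites <- tibble::tibble(chrom = "c1", pos = seq(0, 9000, by = 1000),
                          depth = c(60, 4, 600, 60, 60, 60, 60, 60, 60, 60))
  geno_matrix(dos, sites)
}

test_that("SNP filters apply rules in order and report first failures", {
  G <- make_filter_fixture()
  mask <- tibble::tibble(chrom = "c1", start = 3000, end = 3001)
  # site at 3000 inside; site at 4000 is 999 bp away -> outside 25 bp pad
  Gf <- filter_snps(G, repeat_mask = mask)
  rep_ <- attr(Gf, "filter_report")
  expect_equal(rep_$n_removed[rep_$rule == "depth"], 2L)
  expect_equal(rep_$n_removed[rep_$rule == "mask"], 1L)
  expect_equal(rep_$n_removed[rep_$rule == "missing"], 1L)
  expect_equal(rep_$n_removed[rep_$rule == "maf"], 2L)
  expect_equal(ncol(Gf$dosage), 10 - sum(rep_$n_removed))
  # strict MAF boundary
  G2 <- geno_matrix(cbind(c(1, rep(0, 99)), c(2, rep(0, 99))),
                    tibble::tibble(chrom = "c", pos = c(0, 10)))
  Gf2 <- filter_snps(G2, maf_min = 0.005)
  expect_equal(ncol(Gf2$dosage), 1L)        # MAF 0.005 removed, 0.01 kept
  # 25-bp padding boundary: site 24 bp before interval removed, 26 bp kept
  G3 <- geno_matrix(matrix(rep(0:1, 10), nrow = 10),
                    tibble::tibble(chrom = "c", pos = c(976, 1026)))
  Gf3 <- filter_snps(G3, repeat_mask = tibble::tibble(chrom = "c", start = 1000,
                                                      end = 1001))
  expect_equal(Gf3$sites$pos, 1026)
  # idempotence
  expect_equal(filter_snps(Gf, repeat_mask = mask)$sites, Gf$sites)
})

test_that("W&C84 theta equals the independent ANOVA-route oracle to 1e-6", {
  set.seed(42)
  for (t in 1:25) {
    r <- sample(2:4, 1)
    pops <- lapply(seq_len(r), function(k) sample(0:2, sample(4:20, 1), replace = TRUE))
    if (sum(unlist(pops)) %in% c(0, 2 * length(unlist(pops)))) next
    dos <- matrix(unlist(pops), ncol = 1)
    lab <- rep(paste0("p", seq_len(r)), vapply(pops, length, integer(1)))
    G <- geno_matrix(dos, tibble::tibble(chrom = "c", pos = 0),
                     tibble::tibble(sample_id = paste0("s", seq_along(lab)), pop = lab))
    got <- wc_fst(G)$per_site
    ora <- wc_oracle_site(pops)
    if (got$excluded[1]) next
    expect_equal(got$a[1], unname(ora["a"]), tolerance = 1e-6)
    expect_equal(got$theta[1], unname(ora["theta"]), tolerance = 1e-6)
  }
})

test_that("F_ST endpoints behave: fixed differences give 1, identity gives ~0", {
  G1 <- geno_matrix(matrix(c(rep(0, 20), rep(2, 20)), ncol = 1),
                    tibble::tibble(chrom = "c", pos = 0),
                    tibble::tibble(sample_id = paste0("s", 1:40),
                                   pop = rep(c("a", "b"), each = 20)))
  expect_equal(wc_fst(G1)$per_site$theta, 1)
  G0 <- make_panel(seed = 2, n_pops = 2, n_per = 80, n_sites = 300, fst = 1e-13)
  expect_lt(abs(wc_fst(G0)$theta_overall), 0.02)
  # ratio-of-sums, not mean of ratios
  f <- wc_fst(make_panel(seed = 4, n_per = 20, n_sites = 100))
  ok <- !f$per_site$excluded
  expect_equal(f$theta_overall,
               sum(f$per_site$a[ok]) / sum(f$per_site$a[ok] + f$per_site$b[ok] +
                                             f$per_site$c[ok]))
  # monomorphic site flagged
  Gm <- geno_matrix(matrix(0, 10, 1), tibble::tibble(chrom = "c", pos = 0),
                    tibble::tibble(sample_id = paste0("s", 1:10),
                                   pop = rep(c("a", "b"), 5)))
  expect_true(wc_fst(Gm)$per_site$excluded)
})

test_that("AIM cascade keeps differentiated sites and prunes correlated ones", {
  G <- make_panel(seed = 6, n_pops = 3, n_per = 40, n_sites = 300, fst = 0.27)
  aims <- select_aims(G, fst_min = 0.4)
  if (nrow(aims)) expect_true(all(aims$max_pair_fst > 0.4))
  # two perfectly correlated adjacent sites: exactly one survives stage 1
  base <- sample(0:2, 40, replace = TRUE)
  dos <- cbind(base, base)
  Gc <- geno_matrix(dos, tibble::tibble(chrom = "c", pos = c(0, 100)),
                    tibble::tibble(sample_id = paste0("s", 1:40),
                                   pop = rep(c("a", "b"), each = 20)))
  keep <- polyadapt:::ld_prune(Gc$dosage, Gc$sites$pos, Gc$samples$pop,
                               r_max = 0.9, win_snps = 10, win_bp = 1000)
  expect_equal(sum(keep), 1L)
  # uncorrelated sites survive pruning untouched
  set.seed(8)
  Du <- matrix(sample(0:2, 40 * 6, replace = TRUE), 40)
  keep_u <- polyadapt:::ld_prune(Du, seq(0, 500, by = 100), rep("a", 40),
                                 r_max = 0.9, win_snps = 10, win_bp = 1000)
  expect_true(all(keep_u))
  # sample-order invariance
  perm <- sample(nrow(G$dosage))
  a2 <- select_aims(subset_geno(G, samples = perm))
  expect_equal(aims$site, a2$site)
})

test_that("LD decay bins are order-invariant and detect independence", {
  G <- make_panel(seed = 3, n_pops = 1, n_per = 60, n_sites = 120)
  ld <- ld_decay(G, max_dist = 30000, bin = 500, seed = 2)
  expect_true(all(ld$bins$mean_r2 >= 0 & ld$bins$mean_r2 <= 1))
  # independent sites -> fitted curve flat at the sampling-noise floor:
  # mean r2 shows no distance trend
  ct <- suppressWarnings(cor.test(ld$bins$dist, ld$bins$mean_r2, method = "spearman"))
  expect_gt(ct$p.value, 0.001)
  # r2 of a site with itself is 1
  expect_equal(suppressWarnings(cor(G$dosage[, 1], G$dosage[, 1]))^2, 1)
})

test_that("DAPC recovers well-separated planted clusters", {
  set.seed(5)
  X <- rbind(matrix(rnorm(40 * 12), 40), matrix(rnorm(40 * 12, 10), 40),
             matrix(rnorm(40 * 12, -10), 40))
  truth <- rep(1:3, each = 40)
  res <- dapc_classify(X, k = 3, n_pc = 10, seed = 1)
  tab <- table(res$assignments$group, truth)
  expect_equal(sum(apply(tab, 2, max)), 120)   # perfect up to permutation
  expect_true("ld1" %in% names(res$assignments))
  res1 <- dapc_classify(X, k = 1)
  expect_true(all(res1$assignments$group == 1))
  expect_null(res1$lda)
  expect_identical(dapc_classify(X, seed = 9)$assignments,
                   dapc_classify(X, seed = 9)$assignments)
  expect_error(dapc_classify(X[1:5, ], k = 10), class = "polyadapt_param_error")
})

test_that("ancestry coefficients recover pure and F1 samples", {
  G <- make_panel(seed = 12, n_pops = 3, n_per = 30, n_sites = 800, fst = 0.3)
  pf <- attr(G, "pop_freqs")
  # append a synthetic F1 between pop1 and pop2
  set.seed(99)
  f1 <- t(vapply(1:6, function(i) rbinom(800, 1, pf[1, ]) + rbinom(800, 1, pf[2, ]),
                 numeric(800)))
  rownames(f1) <- paste0("F1_", 1:6)
  Gx <- geno_matrix(rbind(G$dosage, f1), G$sites,
                    dplyr::bind_rows(G$samples,
                                     tibble::tibble(sample_id = rownames(f1),
                                                    pop = NA)))
  ref <- split(G$samples$sample_id, G$samples$pop)
  ac <- ancestry_coefficients(Gx, n_axes = 2, ref_pops = ref)
  expect_equal(rowSums(as.matrix(ac[, -1])), rep(1, nrow(ac)), tolerance = 1e-9)
  # pure pop1 samples
  p1 <- ac[match(ref$pop1, ac$sample_id), ]
  expect_gt(mean(p1$pop1), 0.95)
  f1rows <- ac[grepl("^F1_", ac$sample_id), ]
  expect_lt(abs(mean(f1rows$pop1) - 0.5), 0.1)
  expect_lt(abs(mean(f1rows$pop2) - 0.5), 0.1)
  expect_lt(mean(f1rows$pop3), 0.1)
})
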