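# Independent oracles used across the suite.

# Weir & Cockerham (1984) theta via the ANOVA mean-squares route
# (allele-level sums of squares), algebraically distinct from the
# package's direct variance-component formulas.
wc_oracle_site <- function(pops_dosage) {
  n_i <- vapply(pops_dosage, length, numeric(1))
  p_i <- vapply(pops_dosage, function(x) mean(x) / 2, numeric(1))
  h_i <- vapply(pops_dosage, function(x) mean(x == 1), numeric(1))
  r <- length(n_i); N <- sum(n_i)
  nc <- (N - sum(n_i^2) / N) / (r - 1)
  pbar <- sum(n_i * p_i) / N
  MSP <- sum(2 * n_i * (p_i - pbar)^2) / (r - 1)
  MSI <- sum(2 * n_i * p_i * (1 - p_i) - n_i * h_i / 2) / (N - r)
  MSG <- sum(n_i * h_i) / (2 * N)
  a <- (MSP - MSI) / (2 * nc)
  b <- (MSI - MSG) / 2
  c <- MSG
  c(a = a, b = b, c = c, theta = a / (a + b + c))
}

# exact Fisher two-sided p by hypergeometric enumeration over all tables
# with the observed margins
fisher_oracle_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- vapply(lo:hi, function(x) stats::dhyper(x, m, n, k), numeric(1))
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force sliding-window canonical k-mer counter
brute_kmer_count <- function(seqs, k) {
  rc1 <- function(s) paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]),
                           collapse = "")
  all <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    out <- character(n - k + 1)
    for (i in seq_len(n - k + 1)) out[i] <- substr(s, i, i + k - 1)
    out <- out[!grepl("N", out, fixed = TRUE)]
    vapply(out, function(x) min(x, rc1(x)), "", USE.NAMES = FALSE)
  }))
  table(all)
}

# small structured panel shared by several tests
make_panel <- function(seed = 1, n_pops = 3, n_per = 30, n_sites = 400,
                       fst = 0.27, n_chroms = 1) {
  gen_structured_genotypes(sim_config(seed = seed, n_pops = n_pops,
                                      n_samples_per_pop = n_per,
                                      n_sites = n_sites, fst_target = fst,
                                      n_chroms = n_chroms))
}
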