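# Two-ancestry pulse-model HMM over diploidized dosages.
# Hidden state z = donor haplotype copies {0,1,2}; stationary prior
# Binomial(2, m); per-haplotype switch probability 1 - exp(-g d) toward the
# stationary mix; emissions are the convolution of z Bernoulli(f_donor) and
# (2-z) Bernoulli(f_recipient) draws, with allele-level error eps.

#' Ancestry HMM model
#'
#' @param f_donor,f_recipient per-site allele frequencies in the donor and
#'   recipient reference panels.
#' @param map_d genetic distances (Morgans) between consecutive sites
#'   (length = sites - 1); `Inf` breaks chromosomes.
#' @param g pulse age in generations (must not exceed `max_generations`).
#' @param m pulse proportion in (0, 1).
#' @param eps allele-level genotyping error in [0, 0.5).
#' @param ne effective population size (enters via the default
#'   `max_generations` bound only).
#' @param max_generations upper bound on `g`.
#' @return An `ancestry_model` list.
#' @export
ancestry_model <- function(f_donor, f_recipient, map_d, g, m,
                           eps = 0.001, ne = 1e5, max_generations = 1e4) {
  if (length(f_donor) != length(f_recipient))
    abort_input("frequency vectors differ in length")
  if (length(map_d) != length(f_donor) - 1L)
    abort_input("map_d must have length sites - 1")
  if (any(f_donor < 0 | f_donor > 1 | f_recipient < 0 | f_recipient > 1))
    abort_param("frequencies must lie in [0, 1]")
  check_fraction(m, "m")
  if (eps < 0 || eps >= 0.5) abort_param("eps must lie in [0, 0.5)")
  if (g <= 0 || g > max_generations)
    abort_param("g must lie in (0, max_generations]")
  if (any(map_d < 0)) abort_param("genetic distances must be >= 0")
  structure(list(f_donor = f_donor, f_recipient = f_recipient, map_d = map_d,
                 g = g, m = m, eps = eps, ne = ne,
                 max_generations = max_generations),
            class = "ancestry_model")
}

# P(dosage | z) matrix (sites x 3), allowing NA dosages (uninformative)
emission_probs <- function(dos, model) {
  eps <- model$eps
  fd <- model$f_donor * (1 - eps) + (1 - model$f_donor) * eps
  fr <- model$f_recipient * (1 - eps) + (1 - model$f_recipient) * eps
  m <- length(fd)
  E <- matrix(1, m, 3)
  obs <- !is.na(dos)
  d <- dos[obs]; pd <- fd[obs]; pr <- fr[obs]
  # z = 0: Binomial(2, fr); z = 2: Binomial(2, fd);
  # z = 1: convolution of Bernoulli(fd) and Bernoulli(fr)
  E[obs, 1] <- stats::dbinom(d, 2, pr)
  E[obs, 3] <- stats::dbinom(d, 2, pd)
  E[obs, 2] <- ifelse(d == 0, (1 - pd) * (1 - pr),
               ifelse(d == 2, pd * pr, pd * (1 - pr) + pr * (1 - pd)))
  E
}

# diploid 3x3 transition matrix at genetic distance d
trans_matrix <- function(d, g, m) {
  e <- exp(-g * d)
  a_dd <- e + (1 - e) * m       # donor hap stays donor
  a_rd <- (1 - e) * m           # recipient hap -> donor
  Tm <- matrix(0, 3, 3)
  for (z in 0:2) {
    # z donor haplotypes each -> donor w.p. a_dd; (2 - z) -> donor w.p. a_rd
    pz <- sapply(0:2, function(zp) {
      s <- 0
      for (kd in 0:min(z, zp)) {
        kr <- zp - kd
        if (kr > 2 - z) next
        s <- s + stats::dbinom(kd, z, a_dd) * stats::dbinom(kr, 2 - z, a_rd)
      }
      s
    })
    Tm[z + 1, ] <- pz
  }
  Tm
}

#' Posterior local-ancestry decoding for one sample
#'
#' Scaled forward-backward over the donor-copy-count chain.
#'
#' @param dosage per-site dosage vector (0/1/2, NA allowed).
#' @param model an [ancestry_model()].
#' @return tibble `site`, `p0`, `p1`, `p2`, `p_donor` (`P(z >= 1)`),
#'   `e_dosage` (posterior donor-copy expectation); total log-likelihood in
#'   attribute `"loglik"`.
#' @export
hmm_posteriors <- function(dosage, model) {
  m <- length(dosage)
  if (m == 0) abort_input("zero-length site list")
  E <- emission_probs(dosage, model)
  prior <- stats::dbinom(0:2, 2, model$m)
  Ts <- unique_trans(model)
  alpha <- matrix(0, m, 3); cscale <- numeric(m)
  a <- prior * E[1, ]
  cscale[1] <- sum(a); alpha[1, ] <- a / cscale[1]
  if (m > 1) for (t in 2:m) {
    a <- drop(alpha[t - 1, ] %*% Ts$Tm[[Ts$idx[t - 1]]]) * E[t, ]
    cscale[t] <- sum(a)
    if (!is.finite(cscale[t]) || cscale[t] <= 0)
      rlang::abort("non-finite likelihood in forward pass", class = "polyadapt_numeric_error")
    alpha[t, ] <- a / cscale[t]
  }
  beta <- matrix(0, m, 3); beta[m, ] <- 1
  if (m > 1) for (t in (m - 1):1) {
    b <- drop(Ts$Tm[[Ts$idx[t]]] %*% (E[t + 1, ] * beta[t + 1, ]))
    beta[t, ] <- b / cscale[t + 1]
  }
  post <- alpha * beta
  post <- post / rowSums(post)
  out <- tibble::tibble(site = seq_len(m), p0 = post[, 1], p1 = post[, 2],
                        p2 = post[, 3], p_donor = post[, 2] + post[, 3],
                        e_dosage = post[, 2] + 2 * post[, 3])
  attr(out, "loglik") <- sum(log(cscale))
  out
}

# precompute the distinct transition matrices (uniform maps have one)
unique_trans <- function(model) {
  d <- model$map_d
  ud <- unique(d)
  Tm <- lapply(ud, function(x) {
    if (!is.finite(x)) matrix(stats::dbinom(rep(0:2, each = 3), 2, model$m),
                              3, 3, byrow = FALSE)
    else trans_matrix(x, model$g, model$m)
  })
  list(Tm = Tm, idx = match(d, ud))
}

# cohort forward-backward, vectorized across samples: total log-likelihood
# and the cohort mean posterior donor fraction (for pulse-proportion updates)
cohort_fb <- function(D, model) {
  m <- ncol(D); n <- nrow(D)
  prior <- stats::dbinom(0:2, 2, model$m)
  Ts <- unique_trans(model)
  Es <- lapply(seq_len(n), function(i) emission_probs(D[i, ], model))
  Et_of <- function(t) t(vapply(Es, function(E) E[t, ], numeric(3)))
  alpha <- array(0, c(m, n, 3)); sc <- matrix(0, m, n)
  a <- matrix(prior, n, 3, byrow = TRUE) * Et_of(1)
  sc[1, ] <- rowSums(a); alpha[1, , ] <- a / sc[1, ]
  if (m > 1) for (t in 2:m) {
    a <- (alpha[t - 1, , ] %*% Ts$Tm[[Ts$idx[t - 1]]]) * Et_of(t)
    sc[t, ] <- rowSums(a)
    alpha[t, , ] <- a / sc[t, ]
  }
  beta <- matrix(1, n, 3)
  e_sum <- rowSums(alpha[m, , ] * beta * rep(c(0, 1, 2), each = n))
  if (m > 1) for (t in (m - 1):1) {
    beta <- ((Et_of(t + 1) * beta) %*% t(Ts$Tm[[Ts$idx[t]]])) / sc[t + 1, ]
    post <- alpha[t, , ] * beta
    post <- post / rowSums(post)
    e_sum <- e_sum + rowSums(post * rep(c(0, 1, 2), each = n))
  }
  list(loglik = sum(log(sc)), mean_donor = mean(e_sum / m) / 2)
}

# forward log-likelihood for a cohort (samples x sites dosage matrix)
cohort_loglik <- function(D, model) {
  m <- ncol(D); n <- nrow(D)
  prior <- stats::dbinom(0:2, 2, model$m)
  Ts <- unique_trans(model)
  Es <- lapply(seq_len(n), function(i) emission_probs(D[i, ], model))
  ll <- 0
  alpha <- matrix(prior, n, 3, byrow = TRUE)
  a0 <- alpha * t(vapply(Es, function(E) E[1, ], numeric(3)))
  sc <- rowSums(a0); ll <- ll + sum(log(sc)); alpha <- a0 / sc
  if (m > 1) for (t in 2:m) {
    Tm <- Ts$Tm[[Ts$idx[t - 1]]]
    Et <- t(vapply(Es, function(E) E[t, ], numeric(3)))
    a <- (alpha %*% Tm) * Et
    sc <- rowSums(a)
    ll <- ll + sum(log(sc))
    alpha <- a / sc
  }
  ll
}

#' Decode posterior ancestry into blocks
#'
#' Runs of sites with `P(z >= 1) >= threshold`, merged across gaps shorter
#' than `min_gap` sites, kept when at least `min_sites` long. Block
#' boundaries are placed midway between flanking sites (half-open bp
#' intervals).
#'
#' @param posteriors output of [hmm_posteriors()].
#' @param sites tibble `chrom`, `pos` aligned with the posteriors.
#' @param threshold posterior donor probability for a site to count.
#' @param min_sites minimum run length.
#' @param min_gap runs separated by fewer than this many low sites merge.
#' @param sample_id label stored with the blocks.
#' @return tibble `sample_id`, `chrom`, `start`, `end`, `n_sites`,
#'   `mean_dosage`, `label`.
#' @export
decode_blocks <- function(posteriors, sites, threshold = 0.8, min_sites = 5L,
                          min_gap = 2L, sample_id = "sample") {
  hot <- posteriors$p_donor >= threshold
  m <- length(hot)
  if (!any(hot))
    return(tibble::tibble(sample_id = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          n_sites = integer(), mean_dosage = numeric(),
                          label = character()))
  rl <- rle(hot)
  ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1L
  # merge hot runs across short cold gaps (same chromosome only)
  vals <- rl$values
  for (i in which(!vals)) {
    if (i > 1 && i < length(vals) && rl$lengths[i] < min_gap &&
        sites$chrom[starts[i]] == sites$chrom[ends[i]]) vals[i] <- TRUE
  }
  rl2 <- rle(rep(vals, rl$lengths))
  ends <- cumsum(rl2$lengths); starts <- ends - rl2$lengths + 1L
  keep <- rl2$values & rl2$lengths >= min_sites
  purrr::map_dfr(which(keep), function(i) {
    st <- starts[i]; en <- ends[i]
    left <- if (st > 1 && sites$chrom[st - 1] == sites$chrom[st])
      (sites$pos[st - 1] + sites$pos[st]) / 2 else sites$pos[st]
    right <- if (en < m && sites$chrom[en + 1] == sites$chrom[en])
      (sites$pos[en] + sites$pos[en + 1]) / 2 else sites$pos[en] + 1
    tibble::tibble(sample_id = sample_id, chrom = sites$chrom[st],
                   start = left, end = right, n_sites = en - st + 1L,
                   mean_dosage = mean(posteriors$e_dosage[st:en]),
                   label = "donor")
  })
}

#' Estimate the admixture pulse time by profile likelihood
#'
#' Grid search over the pulse age `g`; at each grid point the pulse
#' proportion is re-estimated as the cohort's expected posterior donor
#' fraction (one refinement pass), and the cohort forward log-likelihood is
#' profiled.
#'
#' @param G_cohort a [geno_matrix()] of admixed samples.
#' @param model an [ancestry_model()] template (frequencies, map, error).
#' @param g_grid candidate pulse ages (default log-spaced from 5 to the
#'   model's `max_generations` bound).
#' @return list `g_hat`, `m_hat`, `profile` (tibble `g`, `m`, `loglik`);
#'   `g_hat` is `NA` with a warning when the profile is flat.
#' @export
estimate_pulse <- function(G_cohort, model, g_grid = NULL) {
  stopifnot(inherits(G_cohort, "geno_matrix"), inherits(model, "ancestry_model"))
  g_grid <- g_grid %||% exp(seq(log(5), log(model$max_generations), length.out = 15))
  if (any(g_grid <= 0 | g_grid > model$max_generations))
    abort_param("g_grid must lie in (0, max_generations]")
  D <- G_cohort$dosage
  # m re-estimated at each grid point from the cohort's posterior donor
  # fraction (warm-started along the grid); likelihood profiled at that m
  m_cur <- model$m
  prof <- purrr::map_dfr(sort(g_grid), function(g) {
    mod <- model; mod$g <- g; mod$m <- m_cur
    fb <- cohort_fb(D, mod)
    m_cur <<- min(max(fb$mean_donor, 1e-4), 1 - 1e-4)
    mod$m <- m_cur
    tibble::tibble(g = g, m = m_cur, loglik = cohort_loglik(D, mod))
  })
  if (diff(range(prof$loglik)) < 1e-6) {
    warning("flat pulse-likelihood profile: no admixture signal")
    return(list(g_hat = NA_real_, m_hat = NA_real_, profile = prof))
  }
  best <- which.max(prof$loglik)
  list(g_hat = prof$g[best], m_hat = prof$m[best], profile = prof)
}

#' Bin ancestry blocks across samples into shared loci
#'
#' Single-linkage clustering of blocks with reciprocal overlap at least
#' `min_overlap`; clusters carried by at least `min_carriers` samples are
#' flagged high-frequency. Emits the sample-by-locus carrier matrix used by
#' the adaptation scan.
#'
#' @param blocks tibble of decoded blocks across samples
#'   (`sample_id`, `chrom`, `start`, `end`).
#' @param min_carriers carrier count for the high-frequency flag.
#' @param min_overlap reciprocal-overlap fraction linking two blocks.
#' @return list `loci` (tibble `locus`, `chrom`, `start`, `end`,
#'   `n_carriers`, `high_frequency`), `carriers` (0/1 matrix samples x loci),
#'   `blocks` (input plus `locus`).
#' @export
bin_blocks <- function(blocks, min_carriers = 10L, min_overlap = 0.5) {
  blocks <- tibble::as_tibble(blocks)
  if (nrow(blocks) == 0)
    return(list(loci = tibble::tibble(), carriers = matrix(0, 0, 0), blocks = blocks))
  n <- nrow(blocks)
  pairs <- NULL
  if (n > 1) {
    idx <- utils::combn(n, 2)
    ov <- apply(idx, 2, function(p) {
      i <- p[1]; j <- p[2]
      if (blocks$chrom[i] != blocks$chrom[j]) return(FALSE)
      o <- min(blocks$end[i], blocks$end[j]) - max(blocks$start[i], blocks$start[j])
      o > 0 &&
        o / (blocks$end[i] - blocks$start[i]) >= min_overlap &&
        o / (blocks$end[j] - blocks$start[j]) >= min_overlap
    })
    pairs <- idx[, ov, drop = FALSE]
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (!is.null(pairs) && ncol(pairs)) g <- igraph::add_edges(g, as.vector(pairs))
  blocks$locus <- igraph::components(g)$membership
  loci <- blocks |>
    dplyr::group_by(.data$locus) |>
    dplyr::summarise(chrom = .data$chrom[1],
                     start = min(.data$start), end = max(.data$end),
                     n_carriers = dplyr::n_distinct(.data$sample_id)) |>
    dplyr::mutate(high_frequency = .data$n_carriers >= min_carriers)
  samples <- sort(unique(blocks$sample_id))
  carriers <- matrix(0L, length(samples), nrow(loci),
                     dimnames = list(samples, paste0("locus", loci$locus)))
  for (i in seq_len(nrow(blocks)))
    carriers[blocks$sample_id[i], paste0("locus", blocks$locus[i])] <- 1L
  list(loci = loci, carriers = carriers, blocks = blocks)
}

#' Mean introgressed genome fraction
#'
#' @param blocks block tibble (`sample_id`, `start`, `end`).
#' @param genome_size genome length in bp.
#' @param sample_ids full cohort (samples without blocks count as zero).
#' @return Mean across samples of introgressed bp / `genome_size`.
#' @export
introgressed_fraction <- function(blocks, genome_size, sample_ids = NULL) {
  if (genome_size <= 0) abort_param("genome_size must be > 0")
  sample_ids <- sample_ids %||% unique(blocks$sample_id)
  if (!length(sample_ids)) return(0)
  bp <- vapply(sample_ids, function(s) {
    b <- blocks[blocks$sample_id == s, ]
    if (!nrow(b)) 0 else sum(b$end - b$start)
  }, numeric(1))
  mean(bp / genome_size)
}
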