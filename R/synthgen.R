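#' Simulation configuration
#'
#' Collects the knobs shared by the synthetic-data generators: panel layout,
#' differentiation target, admixture-pulse parameters, sequencing depth and
#' heritability targets.
#'
#' @param seed integer RNG seed; every generator is deterministic given it.
#' @param n_pops number of diverged subpopulations.
#' @param n_samples_per_pop samples per subpopulation.
#' @param n_sites number of biallelic sites.
#' @param fst_target differentiation level in (0,1); the Balding-Nichols
#'   `F` parameter, which the realized Weir-Cockerham FST tracks.
#' @param pulse_generations age of the admixture pulse, generations.
#' @param pulse_proportion admixed ancestry proportion in (0,1).
#' @param recomb_rate Morgans per site interval (uniform genetic map).
#' @param depth_mean mean sequencing depth (reads).
#' @param h2_u,h2_v genome-wide and regional heritability targets; must sum
#'   below 1.
#' @param ploidy 4 (tetraploid) or 8 (octoploid), for allele-balance draws.
#' @param n_chroms chromosomes to spread sites over; named `Chr01K`,
#'   `Chr01N`, ... with alternating subgenome labels.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_pops = 3L, n_samples_per_pop = 100L,
                       n_sites = 5000L, fst_target = 0.27,
                       pulse_generations = 100L, pulse_proportion = 0.05,
                       recomb_rate = 1e-3, depth_mean = 60,
                       h2_u = 0.2, h2_v = 0.5, ploidy = 4L, n_chroms = 1L) {
  check_fraction(fst_target, "fst_target")
  check_fraction(pulse_proportion, "pulse_proportion")
  check_count(n_pops, "n_pops"); check_count(n_sites, "n_sites")
  check_count(n_samples_per_pop, "n_samples_per_pop")
  check_count(n_chroms, "n_chroms")
  if (h2_u < 0 || h2_v < 0 || h2_u + h2_v >= 1)
    abort_param("h2_u + h2_v must be < 1, each >= 0")
  if (!ploidy %in% c(4L, 8L)) abort_param("ploidy must be 4 or 8")
  structure(list(seed = as.integer(seed), n_pops = as.integer(n_pops),
                 n_samples_per_pop = as.integer(n_samples_per_pop),
                 n_sites = as.integer(n_sites), fst_target = fst_target,
                 pulse_generations = pulse_generations,
                 pulse_proportion = pulse_proportion,
                 recomb_rate = recomb_rate, depth_mean = depth_mean,
                 h2_u = h2_u, h2_v = h2_v, ploidy = as.integer(ploidy),
                 n_chroms = as.integer(n_chroms)),
            class = "sim_config")
}

chrom_names <- function(n_chroms) {
  sprintf("Chr%02d%s", rep(seq_len(ceiling(n_chroms / 2)), each = 2)[seq_len(n_chroms)],
          rep(c("K", "N"), length.out = n_chroms))
}

#' Simulate a structured multi-population genotype panel
#'
#' Balding-Nichols model: an ancestral frequency `p ~ Uniform(0.05, 0.95)` is
#' drawn per site; each subpopulation's frequency is drawn from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` with `F = fst_target`, and diploidized
#' dosages are binomial with two draws. This directly parameterizes the
#' differentiation statistic the downstream stages estimate.
#'
#' @param cfg a [sim_config()].
#' @return A [geno_matrix()] with population labels `pop1..popK`; the per-site
#'   subpopulation frequencies are attached as attribute `"pop_freqs"`.
#' @export
gen_structured_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  m <- cfg$n_sites; r <- cfg$n_pops; n <- cfg$n_samples_per_pop
  Fst <- cfg$fst_target
  p <- stats::runif(m, 0.05, 0.95)
  # F -> 0 limit: subpop frequencies collapse to the ancestral frequency
  pk <- if (Fst < 1e-12) {
    matrix(rep(p, r), nrow = r, byrow = TRUE)
  } else {
    t(vapply(seq_len(r), function(k)
      stats::rbeta(m, p * (1 - Fst) / Fst, (1 - p) * (1 - Fst) / Fst),
      numeric(m)))
  }
  dosage <- do.call(rbind, lapply(seq_len(r), function(k)
    matrix(stats::rbinom(n * m, 2L, rep(pk[k, ], each = n)), nrow = n)))
  chroms <- chrom_names(cfg$n_chroms)
  chrom_of <- rep(chroms, length.out = 0) # placeholder
  per <- ceiling(m / cfg$n_chroms)
  chrom_of <- rep(chroms, each = per)[seq_len(m)]
  pos <- unlist(lapply(split(seq_len(m), chrom_of), function(ix) 200L * (seq_along(ix) - 1L)),
                use.names = FALSE)
  ord <- order(match(chrom_of, chroms))
  sites <- tibble::tibble(chrom = chrom_of[ord], pos = pos,
                          subgenome = substr(chrom_of[ord], 6L, 6L))
  samples <- tibble::tibble(
    sample_id = paste0("S", seq_len(r * n)),
    pop = rep(paste0("pop", seq_len(r)), each = n))
  G <- geno_matrix(dosage, sites, samples)
  attr(G, "pop_freqs") <- pk
  G
}

#' Simulate an admixed cohort with known donor tracts
#'
#' Per haplotype, ancestry follows a two-state Markov chain along the
#' chromosome: switch probability `1 - exp(-g d)` per interval of genetic
#' length `d`, with stationary donor probability `m` (the pulse proportion).
#' Donor-tract genetic lengths are therefore approximately exponential with
#' mean `1/(g (1-m))` Morgans. Alleles are drawn from the donor or recipient
#' per-site frequencies according to the latent state.
#'
#' @param donor,recipient [geno_matrix()] objects on identical site
#'   coordinates; their pooled allele frequencies parameterize the two
#'   ancestries.
#' @param cfg a [sim_config()]; uses `pulse_generations`, `pulse_proportion`,
#'   `recomb_rate`, `seed`.
#' @param n_samples cohort size (default `cfg$n_samples_per_pop`).
#' @return List with `geno` (a `geno_matrix`) and `blocks`, a tibble of truth
#'   donor tracts (`sample_id`, `haplotype`, `chrom`, `start`, `end`
#'   half-open bp, `start_site`, `end_site`, `morgans`).
#' @export
gen_admixed_cohort <- function(donor, recipient, cfg, n_samples = NULL) {
  stopifnot(inherits(donor, "geno_matrix"), inherits(recipient, "geno_matrix"))
  if (!identical(donor$sites[c("chrom", "pos")], recipient$sites[c("chrom", "pos")]))
    abort_input("donor and recipient must share site coordinates")
  set.seed(cfg$seed + 1L)
  n <- n_samples %||% cfg$n_samples_per_pop
  g <- cfg$pulse_generations; mix <- cfg$pulse_proportion
  fd <- allele_freq(donor); fr <- allele_freq(recipient)
  sites <- donor$sites
  m <- nrow(sites)
  d <- rep(cfg$recomb_rate, m - 1L)
  d[sites$chrom[-1L] != sites$chrom[-m]] <- Inf   # chromosome breaks
  q_switch <- 1 - exp(-g * d)
  blocks <- list(); bi <- 1L
  dosage <- matrix(0L, n, m)
  for (s in seq_len(n)) {
    hap_total <- integer(m)
    for (h in 1:2) {
      if (mix == 0) {
        state <- rep(0L, m)
      } else {
        state <- integer(m)
        state[1L] <- stats::rbinom(1L, 1L, mix)
        sw <- stats::runif(m - 1L) < q_switch
        dest <- stats::rbinom(m - 1L, 1L, mix)
        for (j in 2:m) state[j] <- if (sw[j - 1L]) dest[j - 1L] else state[j - 1L]
      }
      al <- stats::rbinom(m, 1L, ifelse(state == 1L, fd, fr))
      hap_total <- hap_total + al
      if (any(state == 1L)) {
        rl <- rle(state)
        ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1L
        keep <- rl$values == 1L
        if (any(keep)) {
          st <- starts[keep]; en <- ends[keep]
          blocks[[bi]] <- tibble::tibble(
            sample_id = paste0("A", s), haplotype = h,
            chrom = sites$chrom[st],
            start = sites$pos[st],
            end = sites$pos[en] + 1L,
            start_site = st, end_site = en,
            morgans = (en - st + 1L) * cfg$recomb_rate)
          bi <- bi + 1L
        }
      }
    }
    dosage[s, ] <- hap_total
  }
  blocks <- if (length(blocks)) dplyr::bind_rows(blocks) else
    tibble::tibble(sample_id = character(), haplotype = integer(),
                   chrom = character(), start = integer(), end = integer(),
                   start_site = integer(), end_site = integer(), morgans = numeric())
  geno <- geno_matrix(dosage, sites,
                      tibble::tibble(sample_id = paste0("A", seq_len(n)),
                                     pop = "admixed"))
  list(geno = geno, blocks = blocks)
}

#' Simulate per-site allele-balance read pairs
#'
#' Tetraploid heterozygous sites read at variant-allele frequency 0.5;
#' octoploid libraries are a mixture of 0.25-or-0.75 sites and 0.5 sites
#' (default weight 0.9 on the 0.25/0.75 class, chosen so the 0.48-0.52
#' band proportion of an octoploid library sits below the 0.035 decision
#' threshold at typical depth; the paper-scale weight is not stated and the
#' parameter is exposed). Total depth is Poisson.
#'
#' @param ploidy 4 or 8.
#' @param n_sites number of heterozygous biallelic sites.
#' @param depth_mean mean total depth (must be >= 8).
#' @param seed RNG seed.
#' @param octo_weight mixture weight on the 0.25/0.75 class for octoploids.
#' @return A `vaf_profile`: tibble with `ref_depth`, `alt_depth`, `vaf`.
#' @export
gen_allele_balance <- function(ploidy, n_sites, depth_mean, seed = 1L,
                               octo_weight = 0.9) {
  if (!ploidy %in% c(4, 8)) abort_param("ploidy must be 4 or 8")
  if (depth_mean < 8) abort_param("depth_mean must be >= 8")
  if (n_sites == 0)
    return(vaf_profile(tibble::tibble(ref_depth = integer(), alt_depth = integer())))
  set.seed(seed)
  depth <- stats::rpois(n_sites, depth_mean)
  vaf <- if (ploidy == 4) rep(0.5, n_sites) else {
    cls <- stats::runif(n_sites) < octo_weight
    ifelse(cls, ifelse(stats::runif(n_sites) < 0.5, 0.25, 0.75), 0.5)
  }
  alt <- stats::rbinom(n_sites, depth, vaf)
  vaf_profile(tibble::tibble(ref_depth = depth - alt, alt_depth = alt))
}

#' Simulate a phenotype with genome-wide and regional genetic components
#'
#' `y = u + v + e` with `u` drawn from the genome-wide van Raden kinship,
#' `v` from the kinship of the supplied regional site set, and independent
#' residuals; each component is rescaled so the realized variance fractions
#' equal the targets (phenotypic variance 1).
#'
#' @param G a [geno_matrix()].
#' @param regional_sites integer site indices defining the regional kinship.
#' @param h2_u,h2_v target heritability fractions, sum < 1.
#' @param seed RNG seed.
#' @return tibble `sample_id`, `y`; truth components in attribute `"truth"`.
#' @export
gen_phenotype <- function(G, regional_sites, h2_u, h2_v, seed = 1L) {
  if (h2_u + h2_v >= 1 || h2_u < 0 || h2_v < 0)
    abort_param("h2_u + h2_v must be < 1")
  if (h2_v > 0 && length(regional_sites) == 0)
    abort_param("regional_sites empty but h2_v > 0")
  set.seed(seed)
  n <- nrow(G$dosage)
  draw_scaled <- function(K, target) {
    if (target == 0) return(numeric(n))
    L <- chol(K + diag(1e-6, n))
    x <- drop(crossprod(L, stats::rnorm(n)))
    x <- x - mean(x)
    x * sqrt(target) / stats::sd(x)
  }
  u <- draw_scaled(van_raden_grm(G), h2_u)
  v <- if (h2_v > 0) draw_scaled(van_raden_grm(subset_geno(G, sites = regional_sites)), h2_v)
       else numeric(n)
  e <- stats::rnorm(n); e <- (e - mean(e)) * sqrt(1 - h2_u - h2_v) / stats::sd(e)
  out <- tibble::tibble(sample_id = G$samples$sample_id, y = u + v + e)
  attr(out, "truth") <- list(u = u, v = v, e = e, h2_u = h2_u, h2_v = h2_v)
  out
}

mutate_seq <- function(seq_chars, rate) {
  n <- length(seq_chars)
  hit <- stats::runif(n) < rate
  if (any(hit)) {
    alt <- c("A", "C", "G", "T")
    repl <- vapply(seq_chars[hit], function(b) sample(setdiff(alt, b), 1L), "")
    seq_chars[hit] <- repl
  }
  seq_chars
}

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

#' Simulate a toy genome with planted LTR families and duplicate haplotypes
#'
#' Builds two homologous chromosome sequences carrying family-specific LTR
#' insertions; families descend from two clade ancestors (one per homologue)
#' so that Jukes-Cantor distances split them into two clades. Also emits
#' near-identical duplicated-haplotype contig pairs for the 24-mer purge.
#'
#' @param n_families number of LTR families (>= 2; split across the clades).
#' @param seed RNG seed.
#' @param copies_per_family LTR copies planted per family.
#' @param ltr_len LTR element length (bp).
#' @param n_dup_pairs duplicated-haplotype contig pairs to plant.
#' @param within_rate,between_rate per-base mutation rates within a family
#'   and between clade ancestors.
#' @return list: `contigs` (tibble `contig_id`, `sequence`, `length`,
#'   `homologue_group`), `ltrs` (tibble `ltr_id`, `family`, `clade`,
#'   `homologue`, `sequence`), `dup_truth` (tibble of planted duplicate pairs),
#'   `family_truth` (tibble `family`, `clade`).
#' @export
gen_ltr_toy_genome <- function(n_families = 4L, seed = 1L,
                               copies_per_family = 6L, ltr_len = 300L,
                               n_dup_pairs = 2L,
                               within_rate = 0.01, between_rate = 0.25) {
  check_count(n_families, "n_families", min = 2L)
  set.seed(seed)
  clade_anc <- rand_seq(ltr_len)
  anc <- list(K = clade_anc,
              N = paste(mutate_seq(strsplit(clade_anc, "")[[1]], between_rate), collapse = ""))
  clade_of <- rep(c("K", "N"), length.out = n_families)
  fam_anc <- vapply(seq_len(n_families), function(f) {
    ch <- strsplit(anc[[clade_of[f]]], "")[[1]]
    paste(mutate_seq(ch, 0.08), collapse = "")   # family divergence within clade
  }, "")
  ltrs <- purrr::map_dfr(seq_len(n_families), function(f) {
    tibble::tibble(
      ltr_id = sprintf("fam%d_copy%d", f, seq_len(copies_per_family)),
      family = paste0("fam", f), clade = clade_of[f],
      homologue = clade_of[f],
      sequence = vapply(seq_len(copies_per_family), function(i)
        paste(mutate_seq(strsplit(fam_anc[f], "")[[1]], within_rate), collapse = ""), ""))
  })
  mk_chrom <- function(hom) {
    ins <- ltrs$sequence[ltrs$homologue == hom]
    spacers <- replicate(length(ins) + 1L, rand_seq(500L))
    paste(c(rbind(spacers[seq_along(ins)], ins), spacers[length(ins) + 1L]), collapse = "")
  }
  contigs <- tibble::tibble(
    contig_id = c("chrK", "chrN"),
    sequence = c(mk_chrom("K"), mk_chrom("N")),
    homologue_group = c("K", "N"))
  dup_truth <- NULL
  if (n_dup_pairs > 0) {
    dups <- purrr::map_dfr(seq_len(n_dup_pairs), function(i) {
      a <- rand_seq(1200L)
      b <- paste(mutate_seq(strsplit(a, "")[[1]], 0.005), collapse = "")
      tibble::tibble(contig_id = sprintf(c("dup%d_a", "dup%d_b"), i),
                     sequence = c(a, b), homologue_group = NA_character_,
                     pair = i)
    })
    dup_truth <- dups[c("contig_id", "pair")]
    contigs <- dplyr::bind_rows(contigs, dups[c("contig_id", "sequence", "homologue_group")])
  }
  contigs$length <- nchar(contigs$sequence)
  list(contigs = contigs[c("contig_id", "sequence", "length", "homologue_group")],
       ltrs = ltrs,
       dup_truth = dup_truth %||% tibble::tibble(contig_id = character(), pair = integer()),
       family_truth = tibble::tibble(family = paste0("fam", seq_len(n_families)),
                                     clade = clade_of))
}

#' Simulate a relative cross-coalescence rate series with a planted split
#'
#' Segments are ordered past to present. RCCR sits near 1 for segments older
#' than the split, declines sigmoidally across the split segment, and sits
#' near 0 after. Additive noise follows an AR(1) process across segments
#' (marginal standard deviation `noise_sd`): cross-coalescence estimates at
#' neighbouring time segments derive from shared data and are strongly
#' correlated, so independent per-segment noise would misrepresent the
#' error structure of this kind of series.
#'
#' @param split_generation generation of the population split.
#' @param n_segments number of time segments.
#' @param noise_sd marginal standard deviation of the additive AR(1) noise.
#' @param seed RNG seed.
#' @param max_generation oldest segment boundary (default 4x the split).
#' @param noise_rho AR(1) autocorrelation of the noise (default 0.85).
#' @return An `rccr_series` (see [rccr_series()]); planted split segment index
#'   in attribute `"truth_split"`.
#' @export
gen_rccr_series <- function(split_generation, n_segments = 30L, noise_sd = 0,
                            seed = 1L, max_generation = 4 * split_generation,
                            noise_rho = 0.85) {
  check_count(n_segments, "n_segments", min = 3L)
  if (split_generation <= 0 || split_generation >= max_generation)
    abort_param("split_generation must fall inside the segment range")
  set.seed(seed)
  # boundaries past -> present, log-spaced
  b <- exp(seq(log(max_generation), log(max_generation / 200), length.out = n_segments + 1L))
  mid <- sqrt(b[-1L] * b[-(n_segments + 1L)])
  width <- split_generation * 0.02
  clean <- 1 / (1 + exp(-(mid - split_generation) / width))
  noise <- numeric(n_segments)
  if (noise_sd > 0) {
    z <- stats::rnorm(n_segments)
    noise[1] <- z[1]
    for (t in 2:n_segments)
      noise[t] <- noise_rho * noise[t - 1] + sqrt(1 - noise_rho^2) * z[t]
    noise <- noise * noise_sd
  }
  rccr <- pmin(pmax(clean + noise, -0.2), 1.2)
  ser <- rccr_series(tibble::tibble(index = seq_len(n_segments) - 1L,
                                    left_time_boundary = b[-(n_segments + 1L)],
                                    right_time_boundary = b[-1L],
                                    rccr = rccr),
                     units = "generations", orientation = "past_to_present")
  # truth = first segment at which the noise-free series steps down
  attr(ser, "truth_split") <- which(-diff(clean) > 0.01)[1L] + 1L
  ser
}
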