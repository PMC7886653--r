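#' Variant-allele-frequency profile
#'
#' Per-site reference/alternate read depths at heterozygous biallelic SNPs of
#' one library. The VAF distribution separates tetraploid (single 0.5 band)
#' from octoploid (0.25/0.75 plus 0.5 bands) libraries.
#'
#' @param depths tibble/data frame with `ref_depth`, `alt_depth`.
#' @return A `vaf_profile` tibble with an added `vaf` column.
#' @export
vaf_profile <- function(depths) {
  depths <- tibble::as_tibble(depths)
  if (!all(c("ref_depth", "alt_depth") %in% names(depths)))
    abort_input("`depths` needs columns ref_depth, alt_depth")
  if (nrow(depths) && any(depths$ref_depth < 0 | depths$alt_depth < 0))
    abort_input("depths must be >= 0")
  tot <- depths$ref_depth + depths$alt_depth
  depths$vaf <- ifelse(tot > 0, depths$alt_depth / tot, NA_real_)
  class(depths) <- c("vaf_profile", class(depths))
  depths
}

usable_sites <- function(profile, min_depth) {
  tot <- profile$ref_depth + profile$alt_depth
  profile[tot >= min_depth & profile$ref_depth > 0 & profile$alt_depth > 0, ]
}

#' Proportion of VAF values in the diploid-like band
#'
#' Fraction of usable heterozygous sites (both alleles observed, depth at
#' least `min_depth`) whose VAF lies in `[lo, hi]`, both ends inclusive.
#'
#' @param profile a [vaf_profile()].
#' @param lo,hi band limits (defaults 0.48, 0.52).
#' @param min_depth minimum total depth for a site to count.
#' @param min_sites minimum usable sites; fewer raises an
#'   insufficient-data error.
#' @return Fraction in `[0, 1]`.
#' @export
vaf_band_proportion <- function(profile, lo = 0.48, hi = 0.52,
                                min_depth = 8L, min_sites = 500L) {
  use <- usable_sites(profile, min_depth)
  if (nrow(use) < min_sites)
    abort_data(sprintf("only %d usable sites (< %d): VAF band proportion unstable",
                       nrow(use), min_sites))
  mean(use$vaf >= lo & use$vaf <= hi)
}

#' Call ploidy from the VAF band proportion
#'
#' Octoploid if the proportion is below `threshold`, tetraploid if at or
#' above it.
#'
#' @param prop band proportion from [vaf_band_proportion()].
#' @param threshold decision threshold (default 0.035).
#' @return `"octoploid"` or `"tetraploid"` (vectorized).
#' @export
call_ploidy_vaf <- function(prop, threshold = 0.035) {
  if (any(prop < 0 | prop > 1)) abort_param("prop must lie in [0, 1]")
  ifelse(prop < threshold, "octoploid", "tetraploid")
}

#' Call ploidy from flow-cytometry fluorescence
#'
#' Bins: `[40000, 80000)` is 4x, `[80000, 100000)` is 6x,
#' `[100000, 140000]` is 8x; anything else is `"unknown"`. Touching
#' endpoints are resolved half-open (lower bin excludes its upper edge).
#'
#' @param fluorescence positive fluorescence readings.
#' @return Character vector in `{"4x","6x","8x","unknown"}`.
#' @export
call_ploidy_flow <- function(fluorescence) {
  if (any(!is.finite(fluorescence) | fluorescence <= 0))
    abort_param("fluorescence must be positive")
  dplyr::case_when(
    fluorescence >= 40000 & fluorescence < 80000 ~ "4x",
    fluorescence >= 80000 & fluorescence < 100000 ~ "6x",
    fluorescence >= 100000 & fluorescence <= 140000 ~ "8x",
    TRUE ~ "unknown")
}

norm_ploidy_label <- function(x) {
  dplyr::recode(x, "4x" = "tetraploid", "6x" = "hexaploid", "8x" = "octoploid")
}

#' Concordance between two ploidy call vectors
#'
#' Pairs with `"unknown"` (or `NA`) in either vector are excluded; flow-style
#' labels (`4x`/`6x`/`8x`) are harmonized with VAF-style labels before
#' comparison. Percent is rounded to one decimal.
#'
#' @param calls_a,calls_b equal-length call vectors.
#' @return tibble `n_match`, `n_total`, `percent`.
#' @export
ploidy_concordance <- function(calls_a, calls_b) {
  if (length(calls_a) != length(calls_b)) abort_input("call vectors differ in length")
  a <- norm_ploidy_label(calls_a); b <- norm_ploidy_label(calls_b)
  keep <- !is.na(a) & !is.na(b) & a != "unknown" & b != "unknown"
  n_total <- sum(keep)
  if (n_total == 0) abort_data("no comparable call pairs")
  n_match <- sum(a[keep] == b[keep])
  tibble::tibble(n_match = n_match, n_total = n_total,
                 percent = round(100 * n_match / n_total, 1))
}

# exact two-sided binomial p-value at p = 0.5 (sum of probabilities not
# exceeding that of the observed count)
binom_two_sided_half <- function(alt, depth) {
  probs <- stats::dbinom(0:depth, depth, 0.5)
  sum(probs[probs <= probs[alt + 1L] * (1 + 1e-7)])
}

#' Binomial genotype call from allele depths
#'
#' `no_call` when depth < 8; `hom_ref` when the alternate count is below 4;
#' otherwise a two-sided exact binomial test of the alternate count against
#' 0.5. Rejections on the high tail are `hom_alt`, on the low tail `no_call`
#' (hom-ref-leaning but failing the biallelic model), and non-rejections
#' `het`.
#'
#' @param ref,alt reference/alternate read counts (vectorized).
#' @param alpha test significance level.
#' @param min_depth,min_alt coverage and alternate-count floors.
#' @return Character vector in `{"hom_ref","het","hom_alt","no_call"}`.
#' @export
call_genotype_binomial <- function(ref, alt, alpha = 0.05,
                                   min_depth = 8L, min_alt = 4L) {
  depth <- ref + alt
  out <- character(length(depth))
  out[depth < min_depth] <- "no_call"
  idx <- which(depth >= min_depth)
  for (i in idx) {
    if (alt[i] < min_alt) { out[i] <- "hom_ref"; next }
    p <- binom_two_sided_half(alt[i], depth[i])
    out[i] <- if (p >= alpha) "het" else if (alt[i] > depth[i] / 2) "hom_alt" else "no_call"
  }
  out
}

#' End-to-end VAF ploidy call for one library
#'
#' @param profile a [vaf_profile()].
#' @param ... passed to [vaf_band_proportion()] / [call_ploidy_vaf()].
#' @inheritParams vaf_band_proportion
#' @inheritParams call_ploidy_vaf
#' @return tibble `n_usable`, `band_proportion`, `call`.
#' @export
call_ploidy_profile <- function(profile, lo = 0.48, hi = 0.52, threshold = 0.035,
                                min_depth = 8L, min_sites = 500L) {
  prop <- vaf_band_proportion(profile, lo, hi, min_depth, min_sites)
  tibble::tibble(n_usable = nrow(usable_sites(profile, min_depth)),
                 band_proportion = prop,
                 call = call_ploidy_vaf(prop, threshold))
}
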