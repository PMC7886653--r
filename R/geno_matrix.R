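#' Genotype dosage container
#'
#' Bundles a samples-by-sites dosage matrix (values 0/1/2, `NA` for missing)
#' with per-site metadata (chromosome, 0-based position, subgenome label,
#' optional mean depth) and per-sample metadata (id, optional population
#' label). All pipeline stages that consume genotypes take this object.
#'
#' @param dosage numeric matrix, samples x sites, entries in `{0,1,2,NA}`.
#' @param sites tibble with columns `chrom`, `pos` (0-based, strictly
#'   increasing within chromosome) and optionally `subgenome`
#'   (`"K"`/`"N"`/`"none"`) and `depth`.
#' @param samples tibble with column `sample_id` and optionally `pop`.
#' @return A `geno_matrix` object.
#' @export
geno_matrix <- function(dosage, sites, samples = NULL) {
  dosage <- as.matrix(dosage)
  if (!all(dosage %in% c(0, 1, 2) | is.na(dosage)))
    abort_input("dosage values must be 0, 1, 2 or NA")
  sites <- tibble::as_tibble(sites)
  if (!all(c("chrom", "pos") %in% names(sites)))
    abort_input("`sites` needs columns `chrom` and `pos`")
  if (nrow(sites) != ncol(dosage))
    abort_input("`sites` rows must match dosage columns")
  bad <- sites |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(ok = all(diff(.data$pos) > 0) || dplyr::n() == 1L) |>
    dplyr::pull(.data$ok)
  if (!all(bad)) abort_input("positions must be strictly increasing within chromosome")
  if (!"subgenome" %in% names(sites)) sites$subgenome <- "none"
  if (is.null(samples)) {
    samples <- tibble::tibble(sample_id = rownames(dosage) %||%
                                paste0("S", seq_len(nrow(dosage))))
  }
  samples <- tibble::as_tibble(samples)
  if (nrow(samples) != nrow(dosage))
    abort_input("`samples` rows must match dosage rows")
  rownames(dosage) <- samples$sample_id
  structure(list(dosage = dosage, sites = sites, samples = samples),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d samples x %d sites, %d chromosome(s)\n",
              nrow(x$dosage), ncol(x$dosage), dplyr::n_distinct(x$sites$chrom)))
  if (!is.null(col_or_null(x$samples, "pop")))
    cat("  populations:", paste(names(table(x$samples$pop)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by sites and/or samples
#'
#' @param G a [geno_matrix()].
#' @param sites integer or logical index over sites.
#' @param samples integer or logical index over samples.
#' @return A `geno_matrix`.
#' @export
subset_geno <- function(G, sites = NULL, samples = NULL) {
  stopifnot(inherits(G, "geno_matrix"))
  si <- sites %||% seq_len(ncol(G$dosage))
  sa <- samples %||% seq_len(nrow(G$dosage))
  geno_matrix(G$dosage[sa, si, drop = FALSE], G$sites[si, ], G$samples[sa, ])
}

#' Per-site allele frequencies (alt-allele, from dosages)
#'
#' @param G a [geno_matrix()].
#' @return Numeric vector, one frequency per site (missing dosages ignored).
#' @export
allele_freq <- function(G) {
  colMeans(G$dosage, na.rm = TRUE) / 2
}
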