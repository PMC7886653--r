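# Plain-text interchange: VCF (via vcfR), FASTA (via Biostrings), TSV/BED
# (via readr). The VCF and FASTA helpers require the corresponding Suggests
# package and error informatively without it.

need_pkg <- function(pkg) {
  if (!requireNamespace(pkg, quietly = TRUE))
    rlang::abort(sprintf("package '%s' is required for this reader/writer", pkg))
}

#' Read diploidized genotypes (GT, optionally AD) from a VCF
#'
#' @param path VCF file (plain or gzipped).
#' @return A [geno_matrix()]; per-site mean depth from AD when present.
#' @export
read_vcf_geno <- function(path) {
  need_pkg("vcfR")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_real_, ncol(gt), nrow(gt))
  clean <- gsub("\\|", "/", gt)
  dos <- t(matrix(dplyr::case_match(as.vector(clean),
                                    "0/0" ~ 0, "0/1" ~ 1, "1/0" ~ 1, "1/1" ~ 2,
                                    .default = NA),
                  nrow(gt), ncol(gt)))
  sites <- tibble::tibble(chrom = vcfR::getCHROM(v),
                          pos = vcfR::getPOS(v) - 1L)   # VCF is 1-based
  ad <- tryCatch(vcfR::extract.gt(v, element = "AD"), error = function(e) NULL)
  if (!is.null(ad) && !all(is.na(ad))) {
    dp <- matrix(vapply(strsplit(as.vector(ad), ","),
                        function(x) sum(suppressWarnings(as.numeric(x))), numeric(1)),
                 nrow(ad), ncol(ad))
    sites$depth <- rowMeans(dp, na.rm = TRUE)
  }
  geno_matrix(dos, sites, tibble::tibble(sample_id = colnames(gt)))
}

#' Write a genotype matrix as VCF with GT and AD fields
#'
#' AD values are synthesized from `depth_mean` reads split by the dosage
#' (used for interchange of simulated panels).
#'
#' @param G a [geno_matrix()].
#' @param path output path (`.vcf`).
#' @param depth_mean constant per-sample depth written into AD.
#' @return `path`, invisibly.
#' @export
write_vcf_geno <- function(G, path, depth_mean = 60L) {
  stopifnot(inherits(G, "geno_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
               paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                      paste(G$samples$sample_id, collapse = "\t"))), con)
  gt_str <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(G$dosage))) {
    dos <- G$dosage[, j]
    ad_alt <- round(depth_mean * dos / 2)
    fields <- ifelse(is.na(dos), "./.:.,.",
                     paste0(gt_str[dos + 1], ":", depth_mean - ad_alt, ",", ad_alt))
    writeLines(paste(c(G$sites$chrom[j], G$sites$pos[j] + 1L, ".", "A", "T",
                       ".", "PASS", ".", "GT:AD", fields), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read contigs from FASTA
#'
#' @param path FASTA file.
#' @return Contig tibble (`contig_id`, `sequence`, `length`).
#' @export
read_contigs_fasta <- function(path) {
  need_pkg("Biostrings")
  x <- Biostrings::readDNAStringSet(path)
  tibble::tibble(contig_id = names(x),
                 sequence = unname(toupper(as.character(x))),
                 length = Biostrings::width(x))
}

#' Write contigs to FASTA
#'
#' @param contigs contig tibble (`contig_id`, `sequence`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contigs_fasta <- function(contigs, path) {
  need_pkg("Biostrings")
  x <- Biostrings::DNAStringSet(contigs$sequence)
  names(x) <- contigs$contig_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write ancestry blocks as BED (sample id in the name field)
#'
#' @param blocks decoded block tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_blocks_bed <- function(blocks, path) {
  readr::write_tsv(dplyr::transmute(blocks, .data$chrom,
                                    start = as.integer(.data$start),
                                    end = as.integer(.data$end),
                                    name = .data$sample_id),
                   path, col_names = FALSE)
  invisible(path)
}
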