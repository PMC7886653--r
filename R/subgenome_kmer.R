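# K-mer based duplicate-haplotype purging and subgenome assignment.
# Sequences are handled as plain character vectors (uppercase ACGTN);
# k-mers are canonical (strand-collapsed).

revcomp <- function(x) {
  vapply(x, function(s)
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = ""),
    "", USE.NAMES = FALSE)
}

# all canonical k-mers of one sequence (k-mers containing N skipped)
seq_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character())
  starts <- seq_len(n - k + 1L)
  km <- substring(seq, starts, starts + k - 1L)
  km <- km[!grepl("N", km, fixed = TRUE)]
  if (!length(km)) return(km)
  rc <- revcomp(km)
  pmin(km, rc)
}

check_contigs <- function(contigs) {
  contigs <- tibble::as_tibble(contigs)
  if (nrow(contigs) == 0) abort_input("empty contig set")
  if (anyDuplicated(contigs$contig_id)) abort_input("contig ids must be unique")
  if (!"length" %in% names(contigs)) contigs$length <- nchar(contigs$sequence)
  if (any(contigs$length <= 0)) abort_input("contig lengths must be > 0")
  contigs
}

#' Bin contigs linked by shared exactly-twice k-mers
#'
#' Counts canonical k-mers across the whole contig set, keeps those occurring
#' exactly twice genome-wide, and links two contigs when they share at least
#' `min_shared` such k-mers. Connected components of that graph are the
#' duplicate-haplotype groups.
#'
#' @param contigs tibble with `contig_id`, `sequence` (uppercase ACGT, N
#'   allowed), optional `length`.
#' @param k k-mer size (default 24).
#' @param min_shared minimum exactly-twice k-mers shared to link two contigs.
#' @return tibble `contig_id`, `group` (NA for unlinked contigs), plus the
#'   pair table in attribute `"pairs"`.
#' @export
find_duplicate_kmers <- function(contigs, k = 24L, min_shared = 10L) {
  contigs <- check_contigs(contigs)
  if (k < 8) abort_param("k must be >= 8")
  km <- purrr::map(contigs$sequence, seq_kmers, k = k)
  tab <- tibble::tibble(
    kmer = unlist(km),
    contig = rep(contigs$contig_id, lengths(km)))
  counts <- dplyr::count(tab, .data$kmer, name = "total")
  twice <- counts$kmer[counts$total == 2L]
  tt <- tab[tab$kmer %in% twice, ]
  tt <- tt[order(tt$kmer), ]          # exactly two rows per kmer
  pairs <- if (nrow(tt) == 0) {
    tibble::tibble(a = character(), b = character(), n_shared = integer())
  } else {
    first <- seq.int(1L, nrow(tt) - 1L, by = 2L)
    tibble::tibble(a = pmin(tt$contig[first], tt$contig[first + 1L]),
                   b = pmax(tt$contig[first], tt$contig[first + 1L])) |>
      dplyr::filter(.data$a != .data$b) |>   # within-contig doubles link nothing
      dplyr::count(.data$a, .data$b, name = "n_shared") |>
      dplyr::filter(.data$n_shared >= min_shared)
  }
  group <- rep(NA_integer_, nrow(contigs))
  if (nrow(pairs)) {
    g <- igraph::graph_from_data_frame(pairs[c("a", "b")], directed = FALSE,
                                       vertices = contigs["contig_id"])
    comp <- igraph::components(g)
    linked <- comp$membership[comp$csize[comp$membership] >= 2L]
    group[match(names(linked), contigs$contig_id)] <-
      as.integer(factor(linked))
  }
  out <- tibble::tibble(contig_id = contigs$contig_id, group = group)
  attr(out, "pairs") <- pairs
  out
}

#' Purge redundant alternative haplotypes
#'
#' Within each duplicate group the longest contig is retained and the rest
#' removed. The accounting report conserves base pairs exactly:
#' `total = retained + removed`.
#'
#' @param contigs tibble as in [find_duplicate_kmers()].
#' @param groups output of [find_duplicate_kmers()].
#' @return list `retained`, `removed` (contig tibbles) and `accounting`
#'   (tibble `total_bp`, `removed_bp`, `retained_bp`).
#' @export
purge_haplotypes <- function(contigs, groups) {
  contigs <- check_contigs(contigs)
  contigs$group <- groups$group[match(contigs$contig_id, groups$contig_id)]
  drop <- contigs |>
    dplyr::filter(!is.na(.data$group)) |>
    dplyr::group_by(.data$group) |>
    dplyr::arrange(dplyr::desc(.data$length), .data$contig_id, .by_group = TRUE) |>
    dplyr::slice(-1L) |>
    dplyr::ungroup()
  removed <- contigs[contigs$contig_id %in% drop$contig_id, ]
  retained <- contigs[!contigs$contig_id %in% drop$contig_id, ]
  list(retained = retained[setdiff(names(retained), "group")],
       removed = removed[setdiff(names(removed), "group")],
       accounting = purge_accounting(sum(contigs$length), sum(removed$length)))
}

#' Purge accounting arithmetic
#'
#' @param total_bp total assembly size before purging.
#' @param removed_bp redundant sequence removed.
#' @return tibble `total_bp`, `removed_bp`, `retained_bp` with
#'   `retained_bp = total_bp - removed_bp` exactly.
#' @export
purge_accounting <- function(total_bp, removed_bp) {
  if (removed_bp > total_bp) abort_input("removed exceeds total")
  tibble::tibble(total_bp = total_bp, removed_bp = removed_bp,
                 retained_bp = total_bp - removed_bp)
}

count_kmers <- function(seqs, k) {
  km <- unlist(purrr::map(seqs, seq_kmers, k = k))
  if (!length(km)) return(integer())
  table(km)
}

#' Diagnostic k-mers distinguishing two homologue sequence sets
#'
#' A k-mer is diagnostic for a homologue when it occurs at most `max_self`
#' times in the other set and at least `min_other` times in that homologue.
#'
#' @param set_a,set_b character vectors of sequences (the two homologues).
#' @param k k-mer size (default 15).
#' @param max_self maximum hits tolerated in the opposite homologue.
#' @param min_other minimum hits required in the diagnosed homologue.
#' @return tibble `kmer`, `homologue` (`"A"`/`"B"`), `count_a`, `count_b`.
#' @export
diagnostic_kmers <- function(set_a, set_b, k = 15L, max_self = 1L, min_other = 100L) {
  if (!length(set_a) || !length(set_b)) abort_input("both homologue sets must be nonempty")
  ca <- count_kmers(set_a, k); cb <- count_kmers(set_b, k)
  all_k <- union(names(ca), names(cb))
  na <- as.integer(ca[all_k]); na[is.na(na)] <- 0L
  nb <- as.integer(cb[all_k]); nb[is.na(nb)] <- 0L
  diag_a <- na >= min_other & nb <= max_self
  diag_b <- nb >= min_other & na <= max_self
  tibble::tibble(kmer = all_k[diag_a | diag_b],
                 homologue = c("A", "B")[1L + diag_b[diag_a | diag_b]],
                 count_a = na[diag_a | diag_b],
                 count_b = nb[diag_a | diag_b])
}

#' Group LTR sequences sharing k-mers into superfamilies
#'
#' Connected components of the share-a-k-mer graph over the supplied
#' sequences.
#'
#' @param ltrs named character vector of LTR sequences.
#' @param k k-mer size (default 15).
#' @return tibble `ltr_id`, `superfamily`.
#' @export
cluster_superfamilies <- function(ltrs, k = 15L) {
  ids <- names(ltrs) %||% paste0("ltr", seq_along(ltrs))
  km <- purrr::map(ltrs, function(s) unique(seq_kmers(s, k)))
  tab <- tibble::tibble(kmer = unlist(km), id = rep(ids, lengths(km)))
  pairs <- tab |>
    dplyr::inner_join(tab, by = "kmer", relationship = "many-to-many") |>
    dplyr::filter(.data$id.x < .data$id.y) |>
    dplyr::distinct(.data$id.x, .data$id.y)
  g <- igraph::graph_from_data_frame(pairs, directed = FALSE, vertices = ids)
  comp <- igraph::components(g)
  tibble::tibble(ltr_id = ids,
                 superfamily = as.integer(comp$membership[ids]))
}

# fraction of the shorter sequence's k-mers contained in the longer one,
# plus an identity proxy from mismatches over a gap-free sliding comparison
pair_identity <- function(a, b, k = 11L) {
  ka <- unique(seq_kmers(a, k)); kb <- unique(seq_kmers(b, k))
  if (!length(ka) || !length(kb)) return(0)
  length(intersect(ka, kb)) / min(length(ka), length(kb))
}

#' Assign sequences within a superfamily to families
#'
#' Single-linkage clustering: two sequences join the same family when their
#' alignment-free similarity passes both the identity and the length-fraction
#' thresholds. Identity is measured as shared k-mer containment (robust proxy
#' for percent identity at these divergence levels); the length fraction
#' compares the shorter to the longer sequence.
#'
#' @param seqs named character vector (one superfamily's members).
#' @param min_identity similarity threshold (default 0.90 identity-equivalent;
#'   internally mapped to k-mer containment).
#' @param min_len_frac minimum shorter/longer length ratio.
#' @param k k-mer size for the containment statistic.
#' @return tibble `ltr_id`, `family`.
#' @export
assign_families <- function(seqs, min_identity = 0.90, min_len_frac = 0.90, k = 11L) {
  if (!length(seqs)) abort_input("empty superfamily")
  ids <- names(seqs) %||% paste0("ltr", seq_along(seqs))
  n <- length(seqs)
  # a k-mer survives point divergence (1 - identity) with prob identity^k;
  # containment threshold equivalent to the identity threshold:
  thr <- min_identity^k
  pairs <- NULL
  if (n > 1) {
    idx <- utils::combn(n, 2)
    keep <- apply(idx, 2, function(p) {
      la <- nchar(seqs[p[1]]); lb <- nchar(seqs[p[2]])
      if (min(la, lb) / max(la, lb) < min_len_frac) return(FALSE)
      pair_identity(seqs[p[1]], seqs[p[2]], k) >= thr
    })
    pairs <- t(idx[, keep, drop = FALSE])
  }
  g <- igraph::graph_from_edgelist(matrix(ids[pairs], ncol = 2), directed = FALSE)
  g <- igraph::add_vertices(g, length(setdiff(ids, igraph::V(g)$name)),
                            name = setdiff(ids, igraph::V(g)$name))
  comp <- igraph::components(g)
  tibble::tibble(ltr_id = ids, family = as.integer(comp$membership[ids]))
}

#' Jukes-Cantor distance
#'
#' `d = -(3/4) log(1 - 4 p / 3)` for mismatch proportion `p < 0.75`.
#'
#' @param p_mismatch observed proportion of mismatching sites.
#' @return Substitution distance (substitutions per site).
#' @export
jc_distance <- function(p_mismatch) {
  if (any(p_mismatch < 0 | p_mismatch >= 0.75))
    abort_param("p_mismatch must lie in [0, 0.75): Jukes-Cantor saturates at 0.75")
  -0.75 * log(1 - 4 * p_mismatch / 3)
}

#' Cluster LTR families into two subgenomes
#'
#' Average-linkage hierarchical clustering of the family distance matrix cut
#' at two clusters; chromosomes are labeled by the majority clade of their
#' families. Ties are flagged unassigned. Cluster labels are stable: the
#' cluster containing the alphabetically first family is `1`, or the caller
#' supplies `anchor` (a family known to sit in subgenome "K").
#'
#' @param family_distances symmetric distance matrix with family row/col names.
#' @param chrom_of_family named character vector: chromosome of each family.
#' @param anchor optional family name anchoring the "K" label.
#' @return list `families` (tibble `family`, `cluster`, `subgenome`) and
#'   `chromosomes` (tibble `chrom`, `subgenome`; ties -> `NA`).
#' @export
cluster_subgenomes <- function(family_distances, chrom_of_family, anchor = NULL) {
  d <- as.matrix(family_distances)
  if (nrow(d) < 2) abort_input("need >= 2 families to form two clusters")
  if (any(d < 0) || any(abs(d - t(d)) > 1e-12)) abort_input("distances must be symmetric, nonnegative")
  fams <- rownames(d) %||% paste0("fam", seq_len(nrow(d)))
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  cl <- stats::cutree(hc, k = 2)
  ref <- if (!is.null(anchor)) cl[[anchor]] else cl[[sort(fams)[1L]]]
  sub <- ifelse(cl == ref, "K", "N")
  families <- tibble::tibble(family = fams, cluster = unname(cl), subgenome = unname(sub))
  chroms <- tibble::tibble(family = fams, chrom = unname(chrom_of_family[fams]),
                           subgenome = unname(sub)) |>
    dplyr::count(.data$chrom, .data$subgenome) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(subgenome = {
      top <- .data$subgenome[.data$n == max(.data$n)]
      if (length(top) > 1L) NA_character_ else top
    })
  list(families = families, chromosomes = chroms)
}
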