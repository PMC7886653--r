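test_that("exactly-twice 24-mer binning groups duplicates and ignores repeats", {
  set.seed(1)
  base <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE), collapse = "")
  other <- paste(sample(c("A", "C", "G", "T"), 800, replace = TRUE), collapse = "")
  contigs <- tibble::tibble(contig_id = c("c1", "c2", "c3"),
                            sequence = c(base, base, other))
  grp <- find_duplicate_kmers(contigs)
  expect_equal(grp$group[1], grp$group[2])
  expect_true(is.na(grp$group[3]))
  # a k-mer occurring three times links nothing
  triple <- tibble::tibble(contig_id = c("t1", "t2", "t3"),
                           sequence = rep(base, 3))
  expect_true(all(is.na(find_duplicate_kmers(triple)$group)))
  expect_error(find_duplicate_kmers(tibble::tibble(contig_id = character(),
                                                   sequence = character())),
               class = "polyadapt_input_error")
})

test_that("planted duplicate haplotype pairs from the toy genome are grouped", {
  toy <- gen_ltr_toy_genome(4, seed = 5, n_dup_pairs = 3)
  grp <- find_duplicate_kmers(toy$contigs)
  for (pr in split(toy$dup_truth$contig_id, toy$dup_truth$pair)) {
    g <- grp$group[match(pr, grp$contig_id)]
    expect_false(any(is.na(g)))
    expect_equal(g[1], g[2])
  }
  # the two homologous chromosomes are not binned as duplicates
  expect_true(all(is.na(grp$group[match(c("chrK", "chrN"), grp$contig_id)])))
})

test_that("purge keeps the longest contig per group and conserves base pairs", {
  contigs <- tibble::tibble(
    contig_id = c("long", "short", "lone"),
    sequence = c(strrep("ACGT", 300), strrep("ACGT", 250), strrep("TTGCA", 100)))
  grp <- tibble::tibble(contig_id = contigs$contig_id, group = c(1L, 1L, NA))
  res <- purge_haplotypes(contigs, grp)
  expect_setequal(res$retained$contig_id, c("long", "lone"))
  expect_equal(res$removed$contig_id, "short")
  acc <- res$accounting
  expect_identical(acc$total_bp, acc$retained_bp + acc$removed_bp)
  # no groups -> nothing removed
  res0 <- purge_haplotypes(contigs, tibble::tibble(contig_id = contigs$contig_id,
                                                   group = NA_integer_))
  expect_equal(nrow(res0$removed), 0)
  expect_equal(res0$accounting$retained_bp, sum(nchar(contigs$sequence)))
})

test_that("diagnostic k-mers follow the max-self / min-other rule and match brute force", {
  set.seed(7)
  core <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = "")
  setA <- rep(core, 30)                       # every core 15-mer occurs 30x in A
  setB <- replicate(5, paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                             collapse = ""))
  dk <- diagnostic_kmers(setA, setB, min_other = 20)
  expect_true(all(dk$homologue == "A"))
  expect_gt(nrow(dk), 0)
  # threshold behaviour: 15x fails min_other = 20
  dk2 <- diagnostic_kmers(rep(core, 15), setB, min_other = 20)
  expect_equal(nrow(dk2), 0)
  # counts equal the brute-force sliding-window counter
  bf_a <- brute_kmer_count(setA, 15)
  expect_true(all(dk$count_a == as.integer(bf_a[dk$kmer])))
  expect_error(diagnostic_kmers(character(), setB), class = "polyadapt_input_error")
})

test_that("superfamily grouping is the transitive closure of k-mer sharing", {
  set.seed(3)
  a <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
  c_ <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
  b <- paste0(substr(a, 1, 40), substr(c_, 1, 40))   # shares k-mers with both
  lone <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = "")
  sf <- cluster_superfamilies(c(A = a, B = b, C = c_, D = lone))
  expect_equal(sf$superfamily[sf$ltr_id == "A"], sf$superfamily[sf$ltr_id == "B"])
  expect_equal(sf$superfamily[sf$ltr_id == "B"], sf$superfamily[sf$ltr_id == "C"])
  expect_false(sf$superfamily[sf$ltr_id == "D"] == sf$superfamily[sf$ltr_id == "A"])
})

test_that("family assignment separates planted divergence levels", {
  toy <- gen_ltr_toy_genome(4, seed = 13, copies_per_family = 5)
  k_ltrs <- toy$ltrs[toy$ltrs$clade == "K", ]
  fams <- assign_families(stats::setNames(k_ltrs$sequence, k_ltrs$ltr_id))
  # within-family copies (~1% divergence) cluster together; families
  # (~15% apart) stay separate
  tab <- table(k_ltrs$family, fams$family)
  expect_equal(max(table(fams$family[match(k_ltrs$ltr_id, fams$ltr_id)],
                         k_ltrs$family) > 0, na.rm = TRUE), 1)
  purity <- apply(tab, 1, function(r) max(r) / sum(r))
  expect_true(all(purity == 1))
  # identical sequences -> one family; a true partition covers all members
  same <- assign_families(c(x = k_ltrs$sequence[1], y = k_ltrs$sequence[1]))
  expect_equal(dplyr::n_distinct(same$family), 1)
  expect_setequal(fams$ltr_id, k_ltrs$ltr_id)
})

test_that("Jukes-Cantor distance matches its closed form and saturates", {
  expect_equal(jc_distance(0), 0)
  expect_equal(jc_distance(0.1), 0.1073256, tolerance = 1e-6)
  expect_error(jc_distance(0.75), class = "polyadapt_param_error")
  p <- seq(0, 0.7, by = 0.05)
  expect_true(all(diff(jc_distance(p)) > 0))
})

test_that("two planted clades are recovered and labeling is order-invariant", {
  toy <- gen_ltr_toy_genome(6, seed = 17, copies_per_family = 4)
  cons <- vapply(split(toy$ltrs$sequence, toy$ltrs$family), `[[`, "", 1)
  fams <- names(cons)
  pm <- function(a, b) mean(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  D <- outer(seq_along(cons), seq_along(cons),
             Vectorize(function(i, j) jc_distance(min(pm(cons[i], cons[j]), 0.74))))
  dimnames(D) <- list(fams, fams)
  chrom_of <- stats::setNames(ifelse(toy$family_truth$clade == "K", "chrK", "chrN"),
                              toy$family_truth$family)
  res <- cluster_subgenomes(D, chrom_of)
  truth <- stats::setNames(toy$family_truth$clade, toy$family_truth$family)
  got <- stats::setNames(res$families$subgenome, res$families$family)
  agree <- mean(got[names(truth)] == truth)
  expect_true(agree %in% c(0, 1))   # perfect up to label swap
  expect_equal(res$chromosomes$subgenome[res$chromosomes$chrom == "chrK"],
               got[names(truth)[truth == "K"]][[1]])
  # permuting input order leaves the partition unchanged
  perm <- sample(fams)
  res2 <- cluster_subgenomes(D[perm, perm], chrom_of)
  got2 <- stats::setNames(res2$families$subgenome, res2$families$family)
  expect_true(all(got2[fams] == got[fams]) || all(got2[fams] != got[fams]))
  expect_error(cluster_subgenomes(matrix(0, 1, 1), c(f = "c")),
               class = "polyadapt_input_error")
})
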