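make_call <- function(ids, labels, tissue = "t") {
  structure(list(tissue = tissue, sample_ids = ids,
                 label = setNames(factor(labels, c("negative", "positive")), ids),
                 k = 2L), class = "cimp_call")
}

test_that("hypergeometric tail matches brute-force pmf enumeration", {
  expect_equal(hypergeom_enrichment(0, 10, 6, 20), 1)      # whole support
  expect_equal(hypergeom_enrichment(5, 5, 5, 5), 1)        # forced outcome
  # exhaustive agreement with choose()-based enumeration for n_total <= 25
  for (n_total in c(8, 15, 25)) {
    for (n_pos in c(2, n_total %/% 2)) {
      for (n_mut in c(1, n_total %/% 3, n_total %/% 2)) {
        for (k in 0:min(n_pos, n_mut)) {
          expect_equal(hypergeom_enrichment(k, n_pos, n_mut, n_total),
                       brute_hyper_upper(k, n_pos, n_mut, n_total),
                       tolerance = 1e-12)
        }
      }
    }
  }
  expect_error(hypergeom_enrichment(7, 5, 6, 20), "margins")
  expect_error(hypergeom_enrichment(2, 25, 6, 20), "margins")
})

test_that("Benjamini-Hochberg agrees with the step-up definition", {
  expect_equal(benjamini_hochberg(rep(0.03, 5)), rep(0.03, 5))
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  set.seed(4)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    q <- benjamini_hochberg(p)
    expect_equal(q, brute_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p))
    # identical rejection sets at several alphas
    for (a in c(0.01, 0.05, 0.2))
      expect_identical(q <= a, brute_bh(p) <= a)
  }
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the genome-wide scan finds a planted association and respects the filter", {
  set.seed(8)
  n <- 300
  ids <- sprintf("S%03d", 1:n)
  labels <- rep(c("positive", "negative"), c(90, 210))
  call <- make_call(ids, labels)
  genes <- sprintf("G%03d", 1:120)
  mut <- matrix(rbinom(120 * n, 1, 0.05), 120, n, dimnames = list(genes, ids))
  # planted: odds ratio ~8 in CIMP-positive samples
  mut["G001", ] <- rbinom(n, 1, ifelse(labels == "positive", 0.30, 0.05))
  # a gene below the recurrence filter
  mut["G002", ] <- 0
  mut["G002", 1:2] <- 1
  res <- genomewide_mutation_scan(mut, call, min_mutated = 3)
  expect_identical(res$gene[1], "G001")
  expect_identical(res$direction[res$gene == "G001"], "positive")
  expect_false("G002" %in% res$gene)
  expect_true(all(res$q >= res$p))

  # gene order does not matter
  res2 <- genomewide_mutation_scan(mut[rev(genes), ], call, min_mutated = 3)
  expect_equal(res2[order(res2$gene), ], res[order(res$gene), ],
               ignore_attr = TRUE)

  none <- mut; none[] <- 0
  expect_warning(empty <- genomewide_mutation_scan(none, call), "nothing to test")
  expect_equal(nrow(empty), 0L)
})

test_that("burden comparison detects planted excess and survives degenerate ties", {
  set.seed(9)
  ids <- sprintf("S%03d", 1:200)
  labels <- rep(c("positive", "negative"), each = 100)
  call <- make_call(ids, labels)
  genes <- sprintf("G%03d", 1:60)
  counts <- ifelse(labels == "positive", 30, 10) / 60
  mut <- matrix(rbinom(60 * 200, 1, rep(counts, each = 60)), 60, 200,
                dimnames = list(genes, ids))
  res <- burden_comparison(mut, call)
  expect_lt(res$p_value, 1e-3)
  expect_gt(res$median_positive, res$median_negative)

  flat <- mut; flat[] <- 0; flat[1, ] <- 1  # every sample: exactly 1 mutation
  res_flat <- burden_comparison(flat, call)
  expect_equal(res_flat$p_value, 1)

  one_class <- make_call(ids, rep("negative", 200))
  expect_error(burden_comparison(mut, one_class), "both CIMP classes")
})

test_that("candidate gene table flags absent genes and localizes planted effects", {
  set.seed(10)
  mk_mut <- function(n, braf_rates) {
    ids <- sprintf("S%03d", 1:n)
    m <- matrix(rbinom(4 * n, 1, 0.03), 4, n,
                dimnames = list(c("IDH1", "BRAF", "KRAS", "TET2"), ids))
    m["BRAF", ] <- rbinom(n, 1, braf_rates)
    m
  }
  n <- 250
  labels <- rep(c("positive", "negative"), c(80, 170))
  muts <- list(colon = mk_mut(n, ifelse(labels == "positive", 0.4, 0.03)),
               lung = mk_mut(n, 0.05))
  calls <- list(colon = make_call(sprintf("S%03d", 1:n), labels, "colon"),
                lung = make_call(sprintf("S%03d", 1:n), labels, "lung"))
  tab <- candidate_gene_table(muts, calls)
  expect_false(tab$present[tab$gene == "IDH2" & tab$tissue == "colon"])
  expect_true(is.na(tab$p[tab$gene == "IDH2" & tab$tissue == "colon"]))
  expect_lt(tab$q[tab$gene == "BRAF" & tab$tissue == "colon"], 0.01)
  expect_gt(tab$q[tab$gene == "BRAF" & tab$tissue == "lung"], 0.1)
  # an unmutated gene cannot be enriched
  muts$colon["KRAS", ] <- 0
  tab2 <- candidate_gene_table(muts, calls)
  expect_equal(tab2$p[tab2$gene == "KRAS" & tab2$tissue == "colon"], 1)
})

test_that("MAF collapsing counts non-silent variants once per gene and sample", {
  maf <- data.frame(
    Hugo_Symbol = c("TP53", "TP53", "BRAF", "KRAS", "TP53"),
    Tumor_Sample_Barcode = c("s1", "s1", "s2", "s3", "s2"),
    Variant_Classification = c("Missense_Mutation", "Nonsense_Mutation",
                               "Missense_Mutation", "Silent", "Missense_Mutation"))
  m <- maf_to_matrix(maf, samples = c("s1", "s2", "s3"))
  expect_equal(m["TP53", ], c(s1 = 1L, s2 = 1L, s3 = 0L))
  expect_equal(m["BRAF", "s2"], 1L)
  expect_false("KRAS" %in% rownames(m))  # silent-only gene dropped
  expect_error(maf_to_matrix(data.frame(x = 1)), "missing column")
})
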