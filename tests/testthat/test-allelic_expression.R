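test_that("AE statistic matches its defining values and properties", {
  expect_equal(compute_ae(50, 50), 0)
  expect_equal(compute_ae(100, 0), 0.5)
  expect_equal(compute_ae(975, 25), 0.475)
  expect_error(compute_ae(0, 0), class = "xciae_validation_error")

  # symmetry, range, and 0.5 iff monoallelic, over random counts
  set.seed(42)
  a <- sample(0:500, 300, replace = TRUE)
  b <- sample(0:500, 300, replace = TRUE)
  keep <- a + b > 0
  a <- a[keep]; b <- b[keep]
  expect_equal(compute_ae(a, b), compute_ae(b, a))
  ae <- compute_ae(a, b)
  expect_true(all(ae >= 0 & ae <= 0.5))
  expect_equal(ae == 0.5, a == 0 | b == 0)
})

test_that("genotype filters apply per-mode depth and minor-fraction rules", {
  gts <- bind_rows(
    gt_row(position = 1L, refDepth = 25L, altDepth = 22L),
    gt_row(position = 2L, refDepth = 100L, altDepth = 5L),
    gt_row(position = 3L, refDepth = 10L, altDepth = 10L),
    gt_row(position = 4L, refDepth = 50L, altDepth = 50L, assay = "WGS"),
    gt_row(position = 5L, refDepth = 50L, altDepth = 50L, passed = FALSE)
  )
  screen <- apply_genotype_filters(gts, filter_policy("screen"))
  expect_setequal(screen$position, 1L)   # WES only; 2 fails both rules,
                                         # 3 fails depth, 5 failed VQSR
  detailed <- apply_genotype_filters(gts, filter_policy("detailed"))
  expect_setequal(detailed$position, c(1L, 3L, 4L))  # 10/10 boundary kept
})

test_that("filtering is monotone: loosening thresholds never drops a survivor", {
  set.seed(7)
  gts <- bind_rows(lapply(1:200, function(i) {
    gt_row(position = i, refDepth = rpois(1, 25), altDepth = rpois(1, 25))
  }))
  strict <- apply_genotype_filters(gts, filter_policy("screen"))
  loose <- apply_genotype_filters(
    gts, filter_policy("screen", min_genotype_depth_per_allele = 10L,
                       min_minor_fraction_genotype = 0.05))
  expect_true(all(strict$position %in% loose$position))

  recs <- bind_rows(lapply(1:200, function(i) {
    ac_row(position = i, refCount = rpois(1, 8), altCount = rpois(1, 8))
  }))
  strict <- apply_rna_filters(recs, filter_policy("screen"))
  loose <- apply_rna_filters(recs, filter_policy("detailed"))
  expect_true(all(strict$position %in% loose$position))
})

test_that("WES/WGS merge keeps the deeper record, ties to WGS", {
  recs <- bind_rows(
    ac_row(position = 1L, assay = "WES", refCount = 30L, altCount = 10L),
    ac_row(position = 1L, assay = "WGS", refCount = 70L, altCount = 20L),
    ac_row(position = 2L, assay = "WES", refCount = 9L, altCount = 9L),
    ac_row(position = 3L, assay = "WES", refCount = 25L, altCount = 25L),
    ac_row(position = 3L, assay = "WGS", refCount = 26L, altCount = 24L)
  )
  merged <- merge_assay_counts(recs)
  expect_equal(nrow(merged), 3L)
  expect_equal(merged$assay[merged$position == 1L], "WGS")  # 90 > 40
  expect_equal(merged$assay[merged$position == 2L], "WES")  # singleton
  expect_equal(merged$assay[merged$position == 3L], "WGS")  # 50/50 tie

  conflicting <- bind_rows(
    ac_row(position = 1L, assay = "WES", ref = "A", alt = "G"),
    ac_row(position = 1L, assay = "WGS", ref = "A", alt = "T")
  )
  expect_error(merge_assay_counts(conflicting), class = "xciae_data_error")
})

test_that("RNA depth thresholds are strict at their boundaries", {
  recs <- bind_rows(
    ac_row(position = 1L, refCount = 5L, altCount = 3L),   # 8 reads
    ac_row(position = 2L, refCount = 4L, altCount = 3L),   # 7 reads
    ac_row(position = 3L, refCount = 5L, altCount = 5L),   # 10 reads
    ac_row(position = 4L, refCount = 6L, altCount = 5L)    # 11 reads
  )
  expect_setequal(apply_rna_filters(recs, filter_policy("detailed"))$position,
                  c(1L, 3L, 4L))
  expect_setequal(apply_rna_filters(recs, filter_policy("screen"))$position,
                  4L)
})

test_that("one SNP per gene: screen by count, detailed by tissue coverage", {
  screen_recs <- bind_rows(
    ac_row(position = 1L, refCount = 80L, altCount = 40L),
    ac_row(position = 2L, refCount = 50L, altCount = 30L)
  ) %>% mutate(geneId = "G1")
  picked <- select_snp_per_gene(screen_recs, "screen")
  expect_equal(picked$position, 1L)

  # SNP 1 in 2 tissues, SNP 2 in 3 tissues -> SNP 2 despite lower counts
  det <- bind_rows(
    ac_row(position = 1L, tissue = "t1", refCount = 200L, altCount = 100L),
    ac_row(position = 1L, tissue = "t2", refCount = 200L, altCount = 100L),
    ac_row(position = 2L, tissue = "t1", refCount = 20L, altCount = 10L),
    ac_row(position = 2L, tissue = "t2", refCount = 20L, altCount = 10L),
    ac_row(position = 2L, tissue = "t3", refCount = 20L, altCount = 10L)
  ) %>% mutate(geneId = "G1")
  expect_setequal(select_snp_per_gene(det, "detailed")$position, 2L)

  # equal coverage -> higher summed count; equal again -> lower coordinate
  tie <- bind_rows(
    ac_row(position = 5L, tissue = "t1", refCount = 150L, altCount = 150L),
    ac_row(position = 9L, tissue = "t1", refCount = 100L, altCount = 100L)
  ) %>% mutate(geneId = "G1")
  expect_setequal(select_snp_per_gene(tie, "detailed")$position, 5L)
  tie$refCount <- 100L; tie$altCount <- 100L
  expect_setequal(select_snp_per_gene(tie, "detailed")$position, 5L)
})

test_that("Xi allele is the donor-wide minor allele, ties to alt", {
  recs <- bind_rows(
    ac_row(tissue = "t1", refCount = 90L, altCount = 10L),
    ac_row(tissue = "t2", refCount = 95L, altCount = 5L),
    ac_row(tissue = "t3", refCount = 88L, altCount = 12L)
  )
  expect_equal(assign_xi_allele(recs)$xiAllele, "alt")

  single <- ac_row(refCount = 2L, altCount = 30L)
  expect_equal(assign_xi_allele(single)$xiAllele, "ref")

  tied <- ac_row(refCount = 50L, altCount = 50L)
  expect_warning(xi <- assign_xi_allele(tied), "tie")
  expect_equal(xi$xiAllele, "alt")
})

test_that("sample exclusion honours the list and the low-median outlier rule", {
  genes <- tiny_panel()
  mk <- function(tissue, ae_vals) {
    bind_rows(lapply(seq_along(ae_vals), function(i) {
      tibble(donor = "D1", sample = paste0("D1.", tissue), tissue = tissue,
             geneId = c("G1", "G2")[1 + (i %% 2)],
             aeValue = ae_vals[i])
    }))
  }
  # per-tissue medians 0.49, 0.49, 0.48, 0.40; median of medians 0.485,
  # so the 0.40 tissue sits below 0.435 and is flagged
  ae <- bind_rows(mk("t1", c(0.49, 0.49)), mk("t2", c(0.49, 0.49)),
                  mk("t3", c(0.48, 0.48)), mk("t4", c(0.40, 0.40)))

  kept <- exclude_flagged_samples(ae, genes, outlier_rule = TRUE)
  expect_false("t4" %in% kept$tissue)
  expect_equal(attr(kept, "excluded")$reason, "low_median_outlier")

  kept <- exclude_flagged_samples(
    ae, genes, exclusions = tibble(donor = "D1", tissue = "t1"))
  expect_false("t1" %in% kept$tissue)
  expect_true("t4" %in% kept$tissue)   # outlier rule off by default

  kept <- exclude_flagged_samples(ae, genes)
  expect_setequal(unique(kept$tissue), c("t1", "t2", "t3", "t4"))
})

test_that("gene-level AE recovers the simulated minor fraction", {
  # one nmXCI donor, deep data: each gene's AE must sit within binomial
  # sampling error of |0.5 - f|, and xiFraction within error of true pi
  panel <- default_gene_panel(n_nonpar = 100, n_par = 4, seed = 13L)
  cfg <- sim_config(n_donors = 1, n_nmxci = 1, tissues_per_donor = 2,
                    genes = panel, het_prob = 1, snps_per_gene = 1,
                    rna_depth_mean = 1000, rna_depth_size = 100,
                    assays = c("WES", "WGS"),
                    seed_truth = 13L, seed_noise = 14L)
  s <- simulate_dataset(cfg)
  ae <- gene_tissue_ae(s$allele_counts, s$genotypes, s$genes,
                       filter_policy("detailed"))
  truth <- s$truth$gene_tissue %>%
    select(geneId, tissue, trueXi = xiFraction)
  j <- ae %>% inner_join(truth, by = c("geneId", "tissue"))
  expect_gt(nrow(j), 150)
  sigma <- sqrt(j$trueXi * (1 - j$trueXi) / j$usedDepth)
  within3 <- abs(j$xiFraction - j$trueXi) <= pmax(3 * sigma, 3 / j$usedDepth)
  expect_gt(mean(within3), 0.97)
  expect_equal(j$aeValue, abs(0.5 - (1 - j$xiFraction)))
})
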