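cons_row <- function(gene = "G1", status = "variable") {
  tibble(geneId = gene, consensusStatus = status, nDonors = 1L,
         nTissuesExpressed = NA_integer_, donorStatuses = status)
}

test_that("minimal detectable Xi fraction matches the binomial tail", {
  # depth 8: P(X >= 2 | 8, 0.025) ~ 0.0166 > 0.01, P(X >= 3) < 0.01
  expect_equal(min_detectable_xi_fraction(8), 3 / 8)
  expect_gt(brute_binom_tail(2, 8, 0.025), 0.01)
  expect_lt(brute_binom_tail(3, 8, 0.025), 0.01)
  # deep data detects small fractions
  f <- min_detectable_xi_fraction(10000)
  expect_lt(f, 0.03)
  expect_lt(brute_binom_tail(ceiling(f * 10000), 10000, 0.025), 0.01)
  # depth 1: even 1/1 reads are not significant at alpha = 0.01
  expect_gt(min_detectable_xi_fraction(1), 1)
})

test_that("over-estimation: deep significant calls at mono-allelic ratios revert", {
  # xiFraction 0.06 at depth 10,000 is astronomically significant yet the
  # allelic ratio 0.44 is mono-allelic by the 0.4 guideline
  expect_lt(brute_binom_tail(600, 10000, 0.025), 1e-50)
  calls <- bind_rows(lapply(1:5, function(i) {
    call_row(tissue = paste0("t", i), xiCount = 600L, usedDepth = 10000L,
             qValue = 1e-100)
  }))
  res <- curate_all(cons_row(status = "escape_across_tissues"), calls)
  expect_equal(res$audit$ruleApplied, "over_estimation")
  expect_equal(res$audit$curatedStatus, "inactive_across_tissues")

  # a genuinely biallelic significant gene is untouched
  calls_ok <- calls %>% mutate(xiCount = 3000L, xiFraction = 0.3,
                               aeValue = 0.2)
  res <- curate_all(cons_row(status = "escape_across_tissues"), calls_ok)
  expect_equal(res$audit$ruleApplied, "none")

  # no significant tissue -> nothing to over-estimate
  calls_ns <- calls %>% mutate(qValue = 0.5, escape = FALSE,
                               xiCount = 4L, usedDepth = 10L,
                               xiFraction = 0.4, aeValue = 0.1)
  res <- curate_all(cons_row(status = "inactive_across_tissues"), calls_ns)
  expect_equal(res$audit$ruleApplied, "none")
})

test_that("low read count: one underpowered tissue cannot break consistent escape", {
  # 9 significant tissues plus one at 2/12 reads (p > threshold)
  expect_gt(brute_binom_tail(2, 12, 0.025), 0.01)
  calls <- bind_rows(
    bind_rows(lapply(1:9, function(i) {
      call_row(tissue = paste0("t", i), xiCount = 30L, usedDepth = 100L,
               qValue = 1e-10)
    })),
    call_row(tissue = "t10", xiCount = 2L, usedDepth = 12L, qValue = 0.2)
  )
  res <- curate_all(cons_row(), calls)
  expect_equal(res$audit$ruleApplied, "low_read_count")
  expect_equal(res$audit$curatedStatus, "escape_across_tissues")

  # more than one non-significant tissue: the rule must not fire
  calls2 <- calls
  calls2$qValue[1:2] <- 0.5
  calls2$escape[1:2] <- FALSE
  res <- curate_all(cons_row(), calls2)
  expect_false(res$audit$ruleApplied == "low_read_count")

  # the non-significant tissue shows no Xi expression at all -> keep variable
  calls3 <- calls
  calls3[calls3$tissue == "t10", c("xiCount", "usedDepth")] <-
    list(1L, 100L)
  calls3$xiFraction[calls3$tissue == "t10"] <- 0.01
  res <- curate_all(cons_row(), calls3)
  expect_equal(res$audit$ruleApplied, "none")
})

test_that("low power: depths that cannot detect escape do not contradict it", {
  # tissue at depth 8 with 2/8 Xi reads: high fraction, undetectable escape
  calls <- bind_rows(
    call_row(tissue = "t1", xiCount = 30L, usedDepth = 100L,
             qValue = 1e-10),
    call_row(tissue = "t2", xiCount = 2L, usedDepth = 8L, qValue = 0.05),
    call_row(tissue = "t3", xiCount = 2L, usedDepth = 8L, qValue = 0.05)
  )
  res <- curate_all(cons_row(status = "inactive_across_tissues"), calls)
  expect_equal(res$audit$ruleApplied, "low_power")
  expect_equal(res$audit$curatedStatus, "escape_across_tissues")

  # all tissues deep and non-significant: genuinely inactive, no rescue
  deep_ns <- bind_rows(lapply(1:3, function(i) {
    call_row(tissue = paste0("t", i), xiCount = 10L, usedDepth = 1000L,
             qValue = 0.9)
  }))
  res <- curate_all(cons_row(status = "inactive_across_tissues"), deep_ns)
  expect_equal(res$audit$ruleApplied, "none")

  # a single underpowered tissue alone is flagged, never re-classified
  single <- call_row(tissue = "t1", xiCount = 2L, usedDepth = 8L,
                     qValue = 0.05)
  res <- curate_all(cons_row(status = "inactive_single_tissue"), single)
  expect_equal(res$audit$ruleApplied, "none")
  expect_equal(res$curated$curationFlags, "low_power_insufficient_evidence")
  expect_equal(res$curated$curatedStatus, "inactive_single_tissue")
})

test_that("rules apply in fixed order and PAR is never touched", {
  # deep significant mono-allelic calls would satisfy both over_estimation
  # and low_power preconditions; over_estimation must win
  calls <- bind_rows(
    call_row(tissue = "t1", xiCount = 600L, usedDepth = 10000L,
             qValue = 1e-100),
    call_row(tissue = "t2", xiCount = 1L, usedDepth = 12L, qValue = 0.3)
  )
  res <- curate_all(cons_row(status = "variable"), calls)
  expect_equal(res$audit$ruleApplied, "over_estimation")

  par_calls <- call_row(geneId = "PARG1", xiCount = 50L, usedDepth = 100L,
                        qValue = 1e-10)
  res <- curate_all(cons_row("PARG1", "PAR"), par_calls)
  expect_equal(res$audit$ruleApplied, "none")
  expect_equal(res$curated$curatedStatus, "PAR")
})

test_that("curation is idempotent and every change is audited", {
  calls <- bind_rows(
    bind_rows(lapply(1:9, function(i) {
      call_row(geneId = "Gvar", tissue = paste0("t", i), xiCount = 30L,
               usedDepth = 100L, qValue = 1e-10)
    })),
    call_row(geneId = "Gvar", tissue = "t10", xiCount = 4L,
             usedDepth = 12L, qValue = 0.2),
    bind_rows(lapply(1:5, function(i) {
      call_row(geneId = "Gover", tissue = paste0("t", i), xiCount = 600L,
               usedDepth = 10000L, qValue = 1e-100)
    })),
    call_row(geneId = "Gok", tissue = "t1", xiCount = 0L,
             usedDepth = 100L, qValue = 1)
  )
  cons <- bind_rows(cons_row("Gvar", "variable"),
                    cons_row("Gover", "escape_across_tissues"),
                    cons_row("Gok", "inactive_single_tissue"))
  first <- curate_all(cons, calls)
  changed <- first$audit %>% filter(originalStatus != curatedStatus)
  expect_setequal(changed$geneId, c("Gvar", "Gover"))
  expect_true(all(changed$ruleApplied != "none"))

  # feeding the curated statuses back through the rules changes nothing
  cons2 <- first$curated %>%
    mutate(consensusStatus = curatedStatus) %>%
    select(-curatedStatus, -curationFlags)
  second <- curate_all(cons2, calls)
  expect_equal(second$curated$curatedStatus, first$curated$curatedStatus)
  expect_true(all(second$audit$ruleApplied == "none"))
})

test_that("planted over-estimation genes are exactly the ones reverted", {
  # 5 deep inactive-leak genes at pi = 0.06 alongside true escape genes:
  # the binomial test calls them all escape; curation reverts only the
  # leak genes
  planted <- paste0("LEAK", 1:5)
  true_esc <- paste0("ESC", 1:5)
  calls <- bind_rows(
    bind_rows(lapply(planted, function(g) {
      bind_rows(lapply(1:4, function(i) {
        call_row(geneId = g, tissue = paste0("t", i),
                 xiCount = 600L, usedDepth = 10000L, qValue = 1e-100)
      }))
    })),
    bind_rows(lapply(true_esc, function(g) {
      bind_rows(lapply(1:4, function(i) {
        call_row(geneId = g, tissue = paste0("t", i),
                 xiCount = 2000L, usedDepth = 10000L, qValue = 1e-100)
      }))
    }))
  )
  cons <- bind_rows(lapply(c(planted, true_esc), function(g) {
    cons_row(g, "escape_across_tissues")
  }))
  res <- curate_all(cons, calls)
  reverted <- res$audit %>% filter(curatedStatus == "inactive_across_tissues")
  expect_setequal(reverted$geneId, planted)
  kept <- res$audit %>% filter(geneId %in% true_esc)
  expect_true(all(kept$ruleApplied == "none"))
})
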