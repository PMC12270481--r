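#' Screen one sample for non-mosaic X inactivation
#'
#' The screen statistic is the median AE over nonPAR X genes not
#' previously classified as variable. In a mosaic tissue the two cell
#' populations cancel and AE sits well below 0.5; in a completely skewed
#' (non-mosaic) donor every inactive gene is nearly monoallelic, pushing
#' the median above 0.475 — i.e. less than 2.5 percent of reads from the
#' inactive allele. The verdict is `nmXCI` iff the median is strictly
#' greater than the threshold. The standard error of the median is a
#' seeded nonparametric bootstrap over genes.
#'
#' @param ae Gene-tissue AE rows for a single sample.
#' @param genes Annotated gene panel with `parRegion` and `priorStatus`.
#' @param threshold Screen cutoff on the median nonPAR AE (default 0.475).
#' @param min_genes Minimum usable genes before a verdict is issued
#'   (default 10); below it the verdict is withheld (`NA`) with reason
#'   `"insufficient genes"` — a median over a handful of genes is too
#'   unstable to call a donor.
#' @param n_boot Bootstrap resamples for the SE of the median.
#' @param boot_seed Seed for the bootstrap.
#' @return One-row tibble: `donor`, `sample`, `tissue`, `nGenesUsed`,
#'   `medianNonParAE`, `standardError`, `verdict`, `reason`.
#' @export
screen_donor <- function(ae, genes, threshold = 0.475, min_genes = 10,
                         n_boot = 1000, boot_seed = 1L) {
  stopifnot(length(unique(ae$sample)) <= 1)
  used <- ae %>%
    left_join(genes %>% select("geneId", "parRegion", "priorStatus"),
              by = "geneId") %>%
    filter(.data$parRegion == "nonPAR",
           is.na(.data$priorStatus) | .data$priorStatus != "variable")

  n_used <- nrow(used)
  if (n_used == 0L) {
    return(tibble(donor = ae$donor[1] %||% NA_character_,
                  sample = ae$sample[1] %||% NA_character_,
                  tissue = ae$tissue[1] %||% NA_character_,
                  nGenesUsed = 0L, medianNonParAE = NA_real_,
                  standardError = NA_real_, verdict = NA_character_,
                  reason = "insufficient genes"))
  }

  med <- median(used$aeValue)
  se <- withr::with_seed(boot_seed, {
    boots <- vapply(seq_len(n_boot), function(i) {
      median(sample(used$aeValue, n_used, replace = TRUE))
    }, numeric(1))
    sd(boots)
  })

  if (n_used < min_genes) {
    verdict <- NA_character_
    reason <- "insufficient genes"
  } else {
    verdict <- if (med > threshold) "nmXCI" else "mosaic"
    reason <- NA_character_
  }
  tibble(
    donor = used$donor[1], sample = used$sample[1], tissue = used$tissue[1],
    nGenesUsed = n_used, medianNonParAE = med, standardError = se,
    verdict = verdict, reason = reason
  )
}

#' Screen a cohort of single-tissue samples
#'
#' Applies [screen_donor()] to every sample and returns the calls ranked
#' by median nonPAR AE, the layout of a cohort-wide skew screen.
#'
#' @inheritParams screen_donor
#' @param ae Gene-tissue AE tibble covering one designated sample per
#'   donor.
#' @return Tibble of per-sample calls sorted by `medianNonParAE`
#'   descending, with attribute `"n_nmxci"` (count of nmXCI verdicts).
#' @export
screen_cohort <- function(ae, genes, threshold = 0.475, min_genes = 10,
                          n_boot = 1000, boot_seed = 1L) {
  if (nrow(ae) == 0L) {
    out <- screen_donor(ae, genes)[0, ]
    attr(out, "n_nmxci") <- 0L
    return(out)
  }
  out <- ae %>%
    group_by(.data$donor, .data$sample) %>%
    dplyr::group_map(~ screen_donor(.x %>% mutate(donor = .y$donor,
                                                  sample = .y$sample),
                                    genes, threshold, min_genes,
                                    n_boot, boot_seed)) %>%
    bind_rows() %>%
    arrange(desc(.data$medianNonParAE))
  attr(out, "n_nmxci") <- sum(out$verdict == "nmXCI", na.rm = TRUE)
  out
}

#' Confirm a candidate nmXCI donor across all tissues
#'
#' Extends the screen statistic to every available tissue of one donor
#' (detailed-mode AE). The donor is confirmed non-mosaic iff every
#' retained tissue's median nonPAR AE exceeds the threshold, after
#' removing explicitly excluded samples.
#'
#' @inheritParams screen_donor
#' @param ae Detailed-mode AE rows for one donor, all tissues.
#' @param exclusions Optional `donor`/`tissue` exclusion tibble.
#' @return List with `calls` (per-tissue tibble) and `confirmed`
#'   (logical).
#' @export
confirm_multi_tissue <- function(ae, genes, threshold = 0.475,
                                 min_genes = 10, exclusions = NULL,
                                 n_boot = 1000, boot_seed = 1L) {
  stopifnot(length(unique(ae$donor)) <= 1)
  ae <- exclude_flagged_samples(ae, genes, exclusions)
  calls <- screen_cohort(ae, genes, threshold, min_genes, n_boot, boot_seed)
  confirmed <- nrow(calls) > 0L &&
    all(calls$medianNonParAE > threshold, na.rm = TRUE)
  list(calls = calls, confirmed = confirmed)
}
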