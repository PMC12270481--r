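#' Filter policy for allelic-expression analysis
#'
#' Two modes mirror the two stages of the analysis. The cohort `screen`
#' applies conservative filters to WES genotypes (both allele depths >= 20,
#' minor allele > 10 percent of the variant read count) and requires an RNA
#' read depth strictly greater than 10. The `detailed` per-donor analysis
#' relaxes the genotype depth to >= 10 per allele (applied to whichever
#' assay supplied the site) and the RNA depth to more than seven reads.
#' "RNA read depth" means `refCount + altCount`: the AE statistic uses only
#' the two alleles, and other-base reads are most often sequencing errors.
#'
#' @param mode `"screen"` or `"detailed"`.
#' @param min_genotype_depth_per_allele,min_minor_fraction_genotype,min_rna_depth
#'   Overrides for the mode defaults. RNA depth and minor-fraction
#'   comparisons are strict (`>`); genotype depth is inclusive (`>=`).
#' @return A `filter_policy` list.
#' @export
filter_policy <- function(mode = c("screen", "detailed"),
                          min_genotype_depth_per_allele = NULL,
                          min_minor_fraction_genotype = NULL,
                          min_rna_depth = NULL) {
  mode <- match.arg(mode)
  defaults <- if (mode == "screen") {
    list(depth = 20L, minor = 0.10, rna = 10L)
  } else {
    list(depth = 10L, minor = 0.10, rna = 7L)
  }
  pol <- list(
    mode = mode,
    min_genotype_depth_per_allele =
      min_genotype_depth_per_allele %||% defaults$depth,
    min_minor_fraction_genotype =
      min_minor_fraction_genotype %||% defaults$minor,
    min_rna_depth = min_rna_depth %||% defaults$rna
  )
  if (any(unlist(pol[-1]) < 0)) {
    abort("filter thresholds must be non-negative",
          class = "xciae_config_error")
  }
  class(pol) <- "filter_policy"
  pol
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Allelic expression statistic
#'
#' `abs(0.5 - refCount / (refCount + altCount))`: 0 is complete biallelic
#' expression, 0.5 complete monoallelic expression. Symmetric in ref/alt.
#'
#' @param refCount,altCount Non-negative integer read counts (vectorised).
#' @return Numeric vector of AE values in `[0, 0.5]`.
#' @export
compute_ae <- function(refCount, altCount) {
  total <- refCount + altCount
  if (any(total <= 0)) {
    abort("compute_ae undefined for refCount + altCount == 0",
          class = "xciae_validation_error")
  }
  abs(0.5 - refCount / total)
}

#' Filter heterozygous genotype calls
#'
#' Keeps sites where both allele depths reach the policy's per-allele depth
#' and the minor allele exceeds the minor-fraction threshold of the variant
#' read count; sites failing the upstream variant filter are dropped. In
#' screen mode only WES genotypes are considered (the screen ran off the
#' released WES call set); detailed mode filters each assay's calls on
#' their own depths.
#'
#' @param genotypes Het-SNP tibble ([read_het_snps()] layout).
#' @param policy A [filter_policy()].
#' @return The surviving genotype rows (donor x assay x site).
#' @export
apply_genotype_filters <- function(genotypes, policy) {
  g <- genotypes
  if (policy$mode == "screen") {
    g <- g %>% filter(.data$assay == "WES")
  }
  g %>%
    filter(
      .data$passedVariantFilter,
      .data$refDepth >= policy$min_genotype_depth_per_allele,
      .data$altDepth >= policy$min_genotype_depth_per_allele,
      pmin(.data$refDepth, .data$altDepth) /
        (.data$refDepth + .data$altDepth) >
        policy$min_minor_fraction_genotype
    )
}

#' Merge allele counts derived from WES and WGS site lists
#'
#' The two genotype pipelines count the same RNA reads, so a site present
#' in both produces two records per sample; the record from the assay with
#' the higher `totalCount` is kept, ties going to WGS (PCR-free, less
#' biased). Sites present once pass through. Records at identical
#' coordinates with conflicting ref/alt alleles are a data inconsistency.
#'
#' @param records Allele-count tibble with an `assay` column.
#' @return Merged records, one row per (donor, sample, site).
#' @export
merge_assay_counts <- function(records) {
  if (nrow(records) == 0L) return(records)
  conflict <- records %>%
    distinct(.data$donor, .data$sample, .data$contig, .data$position,
             .data$ref, .data$alt) %>%
    dplyr::count(.data$donor, .data$sample, .data$contig, .data$position) %>%
    filter(.data$n > 1)
  if (nrow(conflict) > 0L) {
    abort(paste0("conflicting ref/alt alleles at ", conflict$contig[1], ":",
                 conflict$position[1], " for donor ", conflict$donor[1]),
          class = "xciae_data_error")
  }
  records %>%
    mutate(.assay_pref = if_else(.data$assay == "WGS", 1L, 0L)) %>%
    group_by(.data$donor, .data$sample, .data$contig, .data$position) %>%
    arrange(desc(.data$totalCount), desc(.data$.assay_pref),
            .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    select(-".assay_pref")
}

#' Filter allele-count records on RNA read depth
#'
#' Keeps records whose two-allele read depth (`refCount + altCount`) is
#' strictly greater than the policy's RNA threshold.
#'
#' @param records Allele-count tibble.
#' @param policy A [filter_policy()].
#' @return Surviving records.
#' @export
apply_rna_filters <- function(records, policy) {
  records %>%
    filter(.data$refCount + .data$altCount > policy$min_rna_depth)
}

#' Select one hetSNP per gene
#'
#' A gene carrying several hetSNPs must be represented by a single site so
#' tissues and donors are comparable. In screen mode (one sample per
#' donor) the SNP with the highest RNA read count in that sample wins. In
#' detailed mode the SNP detected in the most tissues of the donor wins;
#' ties go to the higher summed RNA read count, remaining ties to the
#' lowest genomic coordinate (a deterministic final tie-break).
#'
#' @param records Gene-mapped allele-count tibble (with `geneId`).
#' @param mode `"screen"` or `"detailed"`.
#' @return `records` restricted to each gene's selected SNP. Genes with no
#'   surviving SNP are simply absent.
#' @export
select_snp_per_gene <- function(records, mode = c("screen", "detailed")) {
  mode <- match.arg(mode)
  if (nrow(records) == 0L) return(records)
  if (mode == "screen") {
    chosen <- records %>%
      mutate(.rna = .data$refCount + .data$altCount) %>%
      group_by(.data$donor, .data$sample, .data$geneId) %>%
      arrange(desc(.data$.rna), .data$position, .by_group = TRUE) %>%
      slice(1) %>%
      ungroup() %>%
      select("donor", "sample", "geneId", "contig", "position")
  } else {
    chosen <- records %>%
      group_by(.data$donor, .data$geneId, .data$contig, .data$position) %>%
      summarise(
        nTissues = dplyr::n_distinct(.data$tissue),
        sumCount = sum(.data$refCount + .data$altCount),
        .groups = "drop"
      ) %>%
      group_by(.data$donor, .data$geneId) %>%
      arrange(desc(.data$nTissues), desc(.data$sumCount), .data$position,
              .by_group = TRUE) %>%
      slice(1) %>%
      ungroup() %>%
      select("donor", "geneId", "contig", "position")
  }
  records %>% semi_join(chosen, by = names(chosen))
}

#' Assign the inactive-X allele per donor and SNP
#'
#' In a non-mosaic donor the inactive X contributes the minority of reads
#' at every informative site, so the Xi allele is taken as the allele with
#' the smaller read count summed over all the donor's tissues, fixed for
#' that donor across tissues. An exact all-tissue tie is uninformative;
#' the alt allele is chosen with a warning.
#'
#' @param records Allele-count tibble for donors that passed the nmXCI
#'   screen.
#' @return Tibble `donor`, `contig`, `position`, `xiAllele` (`"ref"` or
#'   `"alt"`).
#' @export
assign_xi_allele <- function(records) {
  sums <- records %>%
    group_by(.data$donor, .data$contig, .data$position) %>%
    summarise(refSum = sum(.data$refCount), altSum = sum(.data$altCount),
              .groups = "drop")
  ties <- sums$refSum == sums$altSum
  if (any(ties)) {
    warn(paste0(sum(ties), " donor-SNP(s) with an exact all-tissue allele ",
                "tie; Xi set to alt"))
  }
  sums %>%
    mutate(xiAllele = if_else(.data$refSum < .data$altSum, "ref", "alt")) %>%
    select("donor", "contig", "position", "xiAllele")
}

#' Per-gene, per-tissue allelic expression table
#'
#' Chains the module: genotype filtering, restriction of allele counts to
#' surviving het sites, WES/WGS merging, RNA-depth filtering, gene
#' mapping, one-SNP-per-gene selection, then the AE statistic and (in
#' detailed mode) donor-level Xi-allele assignment with Xi read fractions.
#'
#' @param allele_counts Allele-count tibble ([read_allele_counts()]
#'   layout, possibly several assays).
#' @param genotypes Het-SNP genotype tibble ([read_het_snps()] layout).
#' @param genes Annotated gene panel ([read_gene_annotation()]).
#' @param policy A [filter_policy()].
#' @return Tibble with one row per donor x tissue x gene: selected SNP,
#'   counts, `usedDepth`, `aeValue`, and in detailed mode `xiAllele`,
#'   `xiCount`, `xiFraction` (NA in screen mode, where no donor is yet
#'   known to be non-mosaic).
#' @export
gene_tissue_ae <- function(allele_counts, genotypes, genes, policy) {
  kept_sites <- apply_genotype_filters(genotypes, policy) %>%
    distinct(.data$donor, .data$assay, .data$contig, .data$position,
             .data$ref, .data$alt)

  recs <- allele_counts %>%
    semi_join(kept_sites,
              by = c("donor", "assay", "contig", "position", "ref", "alt")) %>%
    merge_assay_counts() %>%
    apply_rna_filters(policy) %>%
    map_snps_to_genes(genes) %>%
    select_snp_per_gene(mode = policy$mode)

  if (nrow(recs) == 0L) {
    return(empty_gene_tissue_ae())
  }

  recs <- recs %>%
    mutate(
      usedDepth = .data$refCount + .data$altCount,
      aeValue = compute_ae(.data$refCount, .data$altCount)
    )

  if (policy$mode == "detailed") {
    xi <- assign_xi_allele(recs)
    recs <- recs %>%
      left_join(xi, by = c("donor", "contig", "position")) %>%
      mutate(
        xiCount = if_else(.data$xiAllele == "ref",
                          .data$refCount, .data$altCount),
        xiFraction = .data$xiCount / .data$usedDepth
      )
  } else {
    recs <- recs %>%
      mutate(xiAllele = NA_character_, xiCount = NA_integer_,
             xiFraction = NA_real_)
  }

  recs %>%
    select("donor", "sample", "tissue", "geneId", "contig", "position",
           "ref", "alt", "refCount", "altCount", "usedDepth", "aeValue",
           "xiAllele", "xiCount", "xiFraction") %>%
    arrange(.data$donor, .data$tissue, .data$geneId)
}

empty_gene_tissue_ae <- function() {
  tibble(
    donor = character(), sample = character(), tissue = character(),
    geneId = character(), contig = character(), position = integer(),
    ref = character(), alt = character(), refCount = integer(),
    altCount = integer(), usedDepth = integer(), aeValue = numeric(),
    xiAllele = character(), xiCount = integer(), xiFraction = numeric()
  )
}

#' Exclude flagged samples
#'
#' Drops samples named on an explicit exclusion list (e.g. EBV-transformed
#' lymphoblast lines, whose X-chromosome state after transformation is
#' unclear) and, optionally, samples whose median nonPAR AE is a low
#' outlier against the donor's other tissues — more than 0.05 below the
#' donor's cross-tissue median of tissue medians. Every exclusion is
#' returned in an audit attribute with its reason.
#'
#' @param ae Gene-tissue AE tibble ([gene_tissue_ae()]).
#' @param genes Annotated gene panel (for `parRegion`).
#' @param exclusions Tibble with columns `donor`, `tissue` to drop, or
#'   `NULL`.
#' @param outlier_rule Apply the low-median outlier rule (default off).
#' @param outlier_margin Margin below the donor median-of-medians.
#' @return Filtered AE tibble; attribute `"excluded"` holds the audit
#'   table (`donor`, `tissue`, `reason`).
#' @export
exclude_flagged_samples <- function(ae, genes, exclusions = NULL,
                                    outlier_rule = FALSE,
                                    outlier_margin = 0.05) {
  audit <- tibble(donor = character(), tissue = character(),
                  reason = character())
  out <- ae
  if (!is.null(exclusions) && nrow(exclusions) > 0L) {
    audit <- bind_rows(audit,
                       exclusions %>% select("donor", "tissue") %>%
                         mutate(reason = "exclusion_list"))
    out <- out %>% anti_join(exclusions, by = c("donor", "tissue"))
  }
  if (outlier_rule && nrow(out) > 0L) {
    medians <- out %>%
      left_join(genes %>% select("geneId", "parRegion"), by = "geneId") %>%
      filter(.data$parRegion == "nonPAR") %>%
      group_by(.data$donor, .data$tissue) %>%
      summarise(med = median(.data$aeValue), .groups = "drop") %>%
      group_by(.data$donor) %>%
      mutate(donorMed = median(.data$med)) %>%
      ungroup()
    flagged <- medians %>%
      filter(.data$med < .data$donorMed - outlier_margin) %>%
      select("donor", "tissue")
    if (nrow(flagged) > 0L) {
      audit <- bind_rows(audit,
                         flagged %>% mutate(reason = "low_median_outlier"))
      out <- out %>% anti_join(flagged, by = c("donor", "tissue"))
    }
  }
  attr(out, "excluded") <- audit
  out
}
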