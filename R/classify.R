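#' One-sided binomial test of inactive-X expression
#'
#' Exact upper-tail probability `P(X >= xiCount)` for
#' `X ~ Binomial(usedDepth, nullP)`. The null is that at most 2.5 percent
#' of a gene's reads come from the inactive X — the residual expected from
#' leaky silencing and technical noise — so a small p-value is evidence of
#' escape from XCI.
#'
#' @param xiCount Reads assigned to the inactive-X allele (vectorised).
#' @param usedDepth Total informative reads (`refCount + altCount`).
#' @param nullP Null Xi read probability (default 0.025).
#' @return p-values in `[0, 1]`.
#' @export
binomial_escape_test <- function(xiCount, usedDepth, nullP = 0.025) {
  if (any(usedDepth < 1)) {
    abort("usedDepth must be >= 1", class = "xciae_validation_error")
  }
  if (any(xiCount < 0 | xiCount > usedDepth)) {
    abort("xiCount must lie in [0, usedDepth]",
          class = "xciae_validation_error")
  }
  pbinom(xiCount - 1, usedDepth, nullP, lower.tail = FALSE)
}

#' Benjamini-Hochberg correction within each tissue
#'
#' FDR correction is applied to the binomial p-values for each tissue
#' separately (and, since each donor's Xi allele and site list are their
#' own, within each donor): the adjustment universe is all tested hetSNPs
#' of one donor in one tissue.
#'
#' @param calls Tibble with `donor`, `tissue`, `pValue`.
#' @return `calls` with a `qValue` column.
#' @export
fdr_adjust_per_tissue <- function(calls) {
  if (any(calls$pValue < 0 | calls$pValue > 1)) {
    abort("p-values must lie in [0, 1]", class = "xciae_validation_error")
  }
  calls %>%
    group_by(.data$donor, .data$tissue) %>%
    mutate(qValue = p.adjust(.data$pValue, method = "BH")) %>%
    ungroup()
}

#' Per-gene, per-tissue escape calls
#'
#' Runs the binomial escape test on every gene x tissue row of a
#' detailed-mode AE table and FDR-corrects per donor and tissue. A gene
#' escapes in a tissue when `qValue < q_threshold` (default 0.01, strict).
#'
#' @param ae Detailed-mode [gene_tissue_ae()] table (needs `xiCount`).
#' @param nullP Binomial null probability.
#' @param q_threshold Significance cutoff on the q-value.
#' @return Tibble with `geneId`, `donor`, `tissue`, `xiCount`,
#'   `usedDepth`, `xiFraction`, `aeValue`, `pValue`, `qValue`, `escape`.
#' @export
escape_calls <- function(ae, nullP = 0.025, q_threshold = 0.01) {
  if (nrow(ae) == 0L) {
    return(tibble(geneId = character(), donor = character(),
                  tissue = character(), xiCount = integer(),
                  usedDepth = integer(), xiFraction = numeric(),
                  aeValue = numeric(), pValue = numeric(),
                  qValue = numeric(), escape = logical()))
  }
  stopifnot(!any(is.na(ae$xiCount)))
  ae %>%
    mutate(pValue = binomial_escape_test(.data$xiCount, .data$usedDepth,
                                         nullP)) %>%
    fdr_adjust_per_tissue() %>%
    mutate(escape = .data$qValue < q_threshold) %>%
    select("geneId", "donor", "tissue", "xiCount", "usedDepth",
           "xiFraction", "aeValue", "pValue", "qValue", "escape")
}

#' Classify a gene's XCI status within each donor
#'
#' Applies the across-tissue category rules per donor: PAR genes are
#' always `PAR`; a gene significant in every expressed tissue is
#' `escape_across_tissues`; significant in none, `inactive_across_tissues`;
#' significant in more than one but not all, `variable`; expressed in a
#' single tissue, `escape_single_tissue` or `inactive_single_tissue` by
#' its q-value. Significance in exactly one of several tissues does not
#' meet the wording for `variable`; such genes are classed
#' `inactive_across_tissues` and flagged `single_tissue_signal` for
#' curation review.
#'
#' @param calls [escape_calls()] tibble.
#' @param genes Annotated gene panel (for `parRegion`).
#' @return Tibble `geneId`, `donor`, `status`, `nTissues`, `nSignificant`,
#'   `flags`.
#' @export
classify_within_donor <- function(calls, genes) {
  calls %>%
    left_join(genes %>% select("geneId", "parRegion"), by = "geneId") %>%
    group_by(.data$geneId, .data$donor) %>%
    summarise(
      nTissues = dplyr::n(),
      nSignificant = sum(.data$escape),
      isPar = first(.data$parRegion) %in% c("PAR1", "PAR2"),
      .groups = "drop"
    ) %>%
    mutate(
      status = dplyr::case_when(
        .data$isPar ~ "PAR",
        .data$nTissues == 1 & .data$nSignificant == 1 ~
          "escape_single_tissue",
        .data$nTissues == 1 ~ "inactive_single_tissue",
        .data$nSignificant == .data$nTissues ~ "escape_across_tissues",
        .data$nSignificant == 0 ~ "inactive_across_tissues",
        .data$nSignificant > 1 ~ "variable",
        TRUE ~ "inactive_across_tissues"
      ),
      flags = if_else(!.data$isPar & .data$nTissues > 1 &
                        .data$nSignificant == 1,
                      "single_tissue_signal", "")
    ) %>%
    select("geneId", "donor", "status", "nTissues", "nSignificant", "flags")
}

#' Consensus XCI status across donors
#'
#' Aggregates per-donor statuses into one call per gene. PAR stays PAR.
#' Donors that all agree on escape-type (or all on inactive-type) yield an
#' escape (inactive) consensus, named `*_across_tissues` when at least one
#' donor contributed multi-tissue coverage and `*_single_tissue`
#' otherwise. Any donor-level `variable` call, or escape/inactive
#' disagreement between donors (interindividual variability), makes the
#' gene `variable`.
#'
#' @param donor_statuses [classify_within_donor()] tibble.
#' @param calls Optional [escape_calls()] tibble used to count the
#'   distinct tissues in which the gene was testable.
#' @return Tibble `geneId`, `consensusStatus`, `nDonors`,
#'   `nTissuesExpressed`, `donorStatuses` (collapsed string).
#' @export
consensus_across_donors <- function(donor_statuses, calls = NULL) {
  cons <- donor_statuses %>%
    group_by(.data$geneId) %>%
    summarise(
      nDonors = dplyr::n(),
      anyPar = any(.data$status == "PAR"),
      anyVar = any(.data$status == "variable"),
      anyEsc = any(is_escape_type(.data$status)),
      anyIna = any(is_inactive_type(.data$status)),
      multiTissue = any(.data$nTissues > 1),
      donorStatuses = paste(.data$status, collapse = ";"),
      .groups = "drop"
    ) %>%
    mutate(
      consensusStatus = dplyr::case_when(
        .data$anyPar ~ "PAR",
        .data$anyVar ~ "variable",
        .data$anyEsc & .data$anyIna ~ "variable",
        .data$anyEsc & .data$multiTissue ~ "escape_across_tissues",
        .data$anyEsc ~ "escape_single_tissue",
        .data$multiTissue ~ "inactive_across_tissues",
        TRUE ~ "inactive_single_tissue"
      )
    )
  if (!is.null(calls)) {
    tiss <- calls %>%
      group_by(.data$geneId) %>%
      summarise(nTissuesExpressed = dplyr::n_distinct(.data$tissue),
                .groups = "drop")
    cons <- cons %>% left_join(tiss, by = "geneId")
  } else {
    cons <- cons %>% mutate(nTissuesExpressed = NA_integer_)
  }
  cons %>%
    select("geneId", "consensusStatus", "nDonors", "nTissuesExpressed",
           "donorStatuses")
}

#' Compare two gene classification sets
#'
#' Cross-tabulates gene statuses between two classifications (e.g. this
#' pipeline versus a previously published set), reports genes unique to
#' either set, and the fraction of variable genes in each set as a
#' percentage to one decimal place.
#'
#' @param setA,setB Tibbles with `geneId` and a status column (`status` or
#'   `consensusStatus`).
#' @return List: `transitions` (tibble `statusA`, `statusB`, `n`),
#'   `unique_to_a`, `unique_to_b` (gene id vectors),
#'   `variable_fraction_a`, `variable_fraction_b` (percent, 1 d.p.).
#' @export
compare_classifications <- function(setA, setB) {
  std <- function(x) {
    col <- intersect(c("consensusStatus", "status"), names(x))[1]
    x %>% select("geneId", status = dplyr::all_of(col))
  }
  a <- std(setA)
  b <- std(setB)
  shared <- dplyr::inner_join(a, b, by = "geneId",
                              suffix = c("A", "B"))
  transitions <- shared %>%
    dplyr::count(.data$statusA, .data$statusB, name = "n") %>%
    arrange(desc(.data$n))
  var_frac <- function(x) {
    if (nrow(x) == 0L) return(NA_real_)
    round(100 * sum(grepl("variable", x$status)) / nrow(x), 1)
  }
  list(
    transitions = transitions,
    unique_to_a = setdiff(a$geneId, b$geneId),
    unique_to_b = setdiff(b$geneId, a$geneId),
    variable_fraction_a = var_frac(a),
    variable_fraction_b = var_frac(b)
  )
}
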