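#' Curation rule parameters
#'
#' The binomial test is sensitive to over-dispersion in read-count data:
#' very deep sites reach significance at Xi fractions that are biologically
#' mono-allelic, and shallow sites miss genuine escape. Three automated,
#' auditable rules re-examine the consensus calls: `over_estimation`
#' (significant calls whose allelic ratio everywhere exceeds the empirical
#' mono-allelic guideline of 0.4, i.e. Xi fraction below 0.1),
#' `low_read_count` (a consistent escape pattern broken by a single
#' non-significant tissue), and `low_power` (tissues too shallow to detect
#' a Xi fraction of `escape_consistency_xi` at all, but whose point
#' estimate is consistent with escape).
#'
#' @param monoallelic_ae_threshold AE above which expression is regarded
#'   as mono-allelic (default 0.4).
#' @param escape_consistency_xi Xi fraction tau above which a tissue's
#'   point estimate is treated as consistent with escape (default 0.05).
#' @param alpha Significance level used when computing the minimal
#'   detectable Xi fraction for the low-power rule (default 0.01, the
#'   q-value threshold).
#' @param nullP Binomial null probability (default 0.025).
#' @return A `curation_rules` list.
#' @export
curation_rules <- function(monoallelic_ae_threshold = 0.4,
                           escape_consistency_xi = 0.05,
                           alpha = 0.01, nullP = 0.025) {
  if (monoallelic_ae_threshold <= 0 || monoallelic_ae_threshold >= 0.5) {
    abort("monoallelic_ae_threshold must lie in (0, 0.5)",
          class = "xciae_config_error")
  }
  if (escape_consistency_xi <= nullP || escape_consistency_xi >= 0.5) {
    abort("escape_consistency_xi must lie in (nullP, 0.5)",
          class = "xciae_config_error")
  }
  structure(list(monoallelic_ae_threshold = monoallelic_ae_threshold,
                 escape_consistency_xi = escape_consistency_xi,
                 alpha = alpha, nullP = nullP),
            class = "curation_rules")
}

#' Minimal detectable Xi fraction at a given depth
#'
#' The smallest Xi read fraction `f` such that `ceiling(f * depth)` reads
#' would be significant under the one-sided binomial null at level
#' `alpha`. Depths where this exceeds the escape-consistency threshold are
#' underpowered: even true escape at that fraction cannot reach
#' significance.
#'
#' @param depth Read depth (vectorised).
#' @param alpha Significance level.
#' @param nullP Binomial null probability.
#' @return Minimal detectable fraction(s) in `(0, 1]` (`> 1` when no count
#'   up to `depth` is significant).
#' @export
min_detectable_xi_fraction <- function(depth, alpha = 0.01, nullP = 0.025) {
  vapply(depth, function(d) {
    # smallest count c with P(X >= c) < alpha
    c0 <- qbinom(1 - alpha, d, nullP) + 1
    while (c0 > 1 &&
           pbinom(c0 - 2, d, nullP, lower.tail = FALSE) < alpha) {
      c0 <- c0 - 1
    }
    if (pbinom(c0 - 1, d, nullP, lower.tail = FALSE) >= alpha) {
      return((d + 1) / d)  # unattainable at this depth
    }
    c0 / d
  }, numeric(1))
}

# Evaluate the three rules for one gene; calls = escape-call rows of that
# gene, status = current consensus status. Returns NULL or
# list(rule, status).
evaluate_curation_gene <- function(calls, status, rules) {
  n <- nrow(calls)
  sig <- calls$escape
  tau <- rules$escape_consistency_xi

  # over_estimation: deep sites drive significance although the allelic
  # ratio is mono-allelic everywhere
  if ((is_escape_type(status) || status == "variable") &&
      any(sig) &&
      all(calls$aeValue > rules$monoallelic_ae_threshold)) {
    new <- if (n > 1) "inactive_across_tissues" else "inactive_single_tissue"
    if (new != status) return(list(status = new, name = "over_estimation"))
  }

  # low_read_count: consistent escape with exactly one non-significant
  # tissue whose point estimate still supports escape
  if (status == "variable" && n > 1 && sum(!sig) == 1 &&
      all(calls$xiFraction >= tau)) {
    return(list(status = "escape_across_tissues", name = "low_read_count"))
  }

  # low_power: tissues too shallow to detect tau at all are not allowed to
  # contradict an otherwise consistent escape pattern. Requires something
  # to excuse (>= 1 non-significant tissue) and must not re-promote a
  # mono-allelic over-estimation pattern it would bounce against.
  if ((is_inactive_type(status) || status == "variable") && n > 1 &&
      any(sig) && any(!sig) &&
      !all(calls$aeValue > rules$monoallelic_ae_threshold)) {
    fmin <- min_detectable_xi_fraction(calls$usedDepth, rules$alpha,
                                       rules$nullP)
    supports <- sig | (fmin > tau & calls$xiFraction >= tau)
    if (all(supports)) {
      return(list(status = "escape_across_tissues", name = "low_power"))
    }
  }
  NULL
}

#' Curate consensus XCI calls
#'
#' Applies the curation rules in fixed order (`over_estimation`,
#' `low_read_count`, `low_power`); at most one rule changes a gene's
#' status, PAR labels are never touched, and every gene evaluated appears
#' in the audit table with the rule fired (or `"none"`) and its evidence.
#' Rules re-label genes between escape/inactive/variable only — they never
#' manufacture significance. Single-tissue genes with an underpowered but
#' escape-consistent point estimate are flagged
#' (`low_power_insufficient_evidence`) without a status change.
#'
#' @param consensus [consensus_across_donors()] tibble.
#' @param calls [escape_calls()] tibble (all donors).
#' @param rules A [curation_rules()] list.
#' @return List: `curated` (consensus tibble with `curatedStatus` and
#'   `curationFlags`), `audit` (tibble `geneId`, `originalStatus`,
#'   `curatedStatus`, `ruleApplied`, `evidence`).
#' @export
curate_all <- function(consensus, calls, rules = curation_rules()) {
  split_calls <- split(calls, calls$geneId)
  out <- purrr::map_dfr(seq_len(nrow(consensus)), function(i) {
    g <- consensus$geneId[i]
    status <- consensus$consensusStatus[i]
    gcalls <- split_calls[[g]]
    flag <- ""
    rule <- "none"
    new_status <- status

    if (status != "PAR" && !is.null(gcalls) && nrow(gcalls) > 0L) {
      res <- evaluate_curation_gene(gcalls, status, rules)
      if (!is.null(res)) {
        rule <- res$name
        new_status <- res$status
      } else if (nrow(gcalls) == 1L && !gcalls$escape[1]) {
        fmin <- min_detectable_xi_fraction(gcalls$usedDepth[1],
                                           rules$alpha, rules$nullP)
        if (fmin > rules$escape_consistency_xi &&
            gcalls$xiFraction[1] >= rules$escape_consistency_xi) {
          flag <- "low_power_insufficient_evidence"
        }
      }
    }

    evidence <- if (is.null(gcalls)) {
      "no escape calls"
    } else {
      paste0("xiFrac=",
             paste(sprintf("%.3f", gcalls$xiFraction), collapse = ","),
             ";q=", paste(signif(gcalls$qValue, 3), collapse = ","),
             ";depth=", paste(gcalls$usedDepth, collapse = ","))
    }
    tibble(geneId = g, originalStatus = status, curatedStatus = new_status,
           ruleApplied = rule, evidence = evidence, curationFlags = flag)
  })

  curated <- consensus %>%
    left_join(out %>% select("geneId", "curatedStatus", "curationFlags"),
              by = "geneId")
  list(curated = curated,
       audit = out %>% select("geneId", "originalStatus", "curatedStatus",
                              "ruleApplied", "evidence"))
}
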