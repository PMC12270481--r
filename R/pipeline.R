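#' Pipeline configuration
#'
#' Collects every threshold and path the pipeline uses into one
#' serialisable list: filter policies for both modes, the screen cutoff on
#' the median nonPAR AE, the binomial null, the q-value threshold,
#' curation parameters, PAR intervals, sample exclusions and seeds.
#' Defaults are the analysis defaults; overrides are merged shallowly.
#'
#' @param ... Named overrides of the defaults.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    screen_threshold = 0.475,
    min_genes = 10,
    null_p = 0.025,
    q_threshold = 0.01,
    n_boot = 1000,
    boot_seed = 1L,
    par_intervals = default_par_intervals(),
    screen_policy = filter_policy("screen"),
    detailed_policy = filter_policy("detailed"),
    curation = curation_rules(),
    exclusions = NULL,
    outlier_rule = FALSE,
    sim = sim_config()
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(cfg))
  if (length(bad) > 0L) {
    abort(paste0("unknown pipeline_config field(s): ",
                 paste(bad, collapse = ", ")),
          class = "xciae_config_error")
  }
  cfg[names(overrides)] <- overrides
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [pipeline_config()] fields; the nested
#' `sim`, `screen_policy`, `detailed_policy` and `curation` blocks are
#' passed to their respective constructors so every value is validated.
#'
#' @param path YAML file.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (f in c("screen_threshold", "min_genes", "null_p", "q_threshold",
              "n_boot", "boot_seed", "outlier_rule")) {
    if (!is.null(y[[f]])) args[[f]] <- y[[f]]
  }
  if (!is.null(y$sim)) args$sim <- do.call(sim_config, y$sim)
  if (!is.null(y$screen_policy)) {
    args$screen_policy <- do.call(filter_policy,
                                  c(list(mode = "screen"), y$screen_policy))
  }
  if (!is.null(y$detailed_policy)) {
    args$detailed_policy <- do.call(filter_policy,
                                    c(list(mode = "detailed"),
                                      y$detailed_policy))
  }
  if (!is.null(y$curation)) args$curation <- do.call(curation_rules, y$curation)
  if (!is.null(y$par_intervals)) {
    pi <- y$par_intervals
    args$par_intervals <- list(contig = pi$contig %||% "chrX",
                               PAR1 = as.integer(pi$PAR1),
                               PAR2 = as.integer(pi$PAR2))
  }
  if (!is.null(y$exclusions)) {
    args$exclusions <- dplyr::bind_rows(lapply(y$exclusions, as_tibble))
  }
  do.call(pipeline_config, args)
}

#' Run the full pipeline on a simulated cohort
#'
#' Chains simulate -> allelic expression -> nmXCI screen -> multi-tissue
#' detailed AE on the screen hits -> binomial escape classification ->
#' consensus -> curation, writing every stage table as TSV to `out_dir`
#' (when given) plus a config echo and a run summary. Stage boundaries log
#' record counts so filter attrition is auditable.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param detailed_tissues Number of tissues simulated for the detailed
#'   stage of screen-positive donors (default 10).
#' @param quiet Suppress stage logging.
#' @return List: `screen` (cohort calls), `ae_detailed`, `escape_calls`,
#'   `donor_statuses`, `consensus`, `curated`, `audit`, `summary`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         detailed_tissues = 10, quiet = FALSE) {
  say <- function(...) if (!quiet) inform(paste0("[xciae] ", ...))

  # stage 1: simulate the screening cohort
  sim <- simulate_screen_cohort(config$sim)
  say("simulate: ", nrow(sim$allele_counts), " allele-count rows, ",
      nrow(sim$genotypes), " genotype rows, ",
      nrow(sim$truth$donors), " donors")

  # stage 2: screen-mode AE + cohort screen
  ae_screen <- gene_tissue_ae(sim$allele_counts, sim$genotypes, sim$genes,
                              config$screen_policy)
  say("ae (screen): ", nrow(ae_screen), " gene-tissue rows")
  screen <- screen_cohort(ae_screen, sim$genes,
                          threshold = config$screen_threshold,
                          min_genes = config$min_genes,
                          n_boot = config$n_boot,
                          boot_seed = config$boot_seed)
  hits <- screen %>% filter(.data$verdict == "nmXCI") %>% pull("donor")
  say("screen: ", length(hits), " nmXCI candidate(s) of ",
      nrow(screen), " donors")

  # stage 3: detailed multi-tissue data for the screen hits
  det_cfg <- config$sim
  det_cfg$tissues_per_donor <- detailed_tissues
  det_cfg$assays <- c("WES", "WGS")
  det <- simulate_dataset(det_cfg)
  keep <- function(x) x %>% filter(.data$donor %in% hits)
  ae_det <- gene_tissue_ae(keep(det$allele_counts), keep(det$genotypes),
                           det$genes, config$detailed_policy)
  ae_det <- exclude_flagged_samples(ae_det, det$genes,
                                    exclusions = config$exclusions,
                                    outlier_rule = config$outlier_rule)
  say("ae (detailed): ", nrow(ae_det), " gene-tissue rows across ",
      length(unique(ae_det$tissue)), " tissues")

  # stage 4: escape classification
  calls <- escape_calls(ae_det, nullP = config$null_p,
                        q_threshold = config$q_threshold)
  donor_statuses <- classify_within_donor(calls, det$genes)
  consensus <- consensus_across_donors(donor_statuses, calls)
  say("classify: ", nrow(consensus), " genes classified")

  # stage 5: curation
  cur <- curate_all(consensus, calls, config$curation)
  n_changed <- sum(cur$audit$ruleApplied != "none")
  say("curate: ", n_changed, " gene(s) re-classified")

  tally <- table(cur$curated$curatedStatus)
  n_var <- sum(grepl("variable", cur$curated$curatedStatus))
  n_tot <- nrow(cur$curated)
  summary <- list(
    n_donors = nrow(screen),
    n_nmxci = length(hits),
    nmxci_donors = hits,
    status_tally = as.list(tally),
    n_genes = n_tot,
    variable_fraction_pct = if (n_tot > 0) round(100 * n_var / n_tot, 1)
                            else NA_real_,
    n_curated = n_changed
  )

  result <- list(screen = screen, ae_detailed = ae_det,
                 escape_calls = calls, donor_statuses = donor_statuses,
                 consensus = consensus, curated = cur$curated,
                 audit = cur$audit, truth = sim$truth, summary = summary)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(screen, file.path(out_dir, "screen_cohort.tsv"),
                     progress = FALSE)
    readr::write_tsv(ae_det, file.path(out_dir, "ae_detailed.tsv"),
                     progress = FALSE)
    readr::write_tsv(calls, file.path(out_dir, "escape_calls.tsv"),
                     progress = FALSE)
    readr::write_tsv(cur$curated, file.path(out_dir, "consensus_curated.tsv"),
                     progress = FALSE)
    readr::write_tsv(cur$audit, file.path(out_dir, "curation_audit.tsv"),
                     progress = FALSE)
    readr::write_tsv(render_matrix(cur$curated, calls),
                     file.path(out_dir, "gene_tissue_matrix.tsv"),
                     progress = FALSE)
    yaml::write_yaml(config_echo(config), file.path(out_dir, "config.yaml"))
    yaml::write_yaml(summary, file.path(out_dir, "summary.yaml"))
  }
  result
}

config_echo <- function(config) {
  ce <- unclass(config)
  ce$screen_policy <- unclass(ce$screen_policy)
  ce$detailed_policy <- unclass(ce$detailed_policy)
  ce$curation <- unclass(ce$curation)
  ce$sim <- lapply(unclass(ce$sim), function(x) {
    if (is.data.frame(x)) "<gene panel>" else x
  })
  ce
}

#' Gene-by-tissue AE matrix with significance markers
#'
#' Wide table mirroring an escape heatmap: one row per gene, one column
#' per tissue holding the AE value formatted to three decimals with an
#' asterisk when Xi expression is significant in that tissue (any donor),
#' `NA` for missing data (gene not testable in the tissue), plus the
#' consensus-call column.
#'
#' @param consensus Curated consensus tibble (needs `geneId` and
#'   `curatedStatus` or `consensusStatus`).
#' @param calls [escape_calls()] tibble.
#' @return Wide tibble, genes x (status + tissues).
#' @export
render_matrix <- function(consensus, calls) {
  status_col <- intersect(c("curatedStatus", "consensusStatus"),
                          names(consensus))[1]
  base <- consensus %>%
    select("geneId", consensusCall = dplyr::all_of(status_col))
  if (nrow(calls) == 0L) {
    return(base)
  }
  cells <- calls %>%
    group_by(.data$geneId, .data$tissue) %>%
    summarise(
      cell = paste0(sprintf("%.3f", mean(.data$aeValue)),
                    if_else(any(.data$escape), "*", "")),
      .groups = "drop"
    ) %>%
    tidyr::pivot_wider(names_from = "tissue", values_from = "cell")
  base %>% left_join(cells, by = "geneId")
}
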