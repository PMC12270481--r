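#' Default X-linked gene panel for simulation
#'
#' Lays out a panel of genes along an X-like contig: a few PAR genes
#' (always biallelic, Xi fraction 0.5), constitutive escape genes
#' (Xi fraction drawn uniformly from `escape_pi_range`), variable-escape
#' genes, and inactive genes expressing the Xi allele only at a small leak
#' rate. Coordinates place PAR genes inside the configured PAR intervals
#' and all other genes between them.
#'
#' @param n_nonpar Number of nonPAR genes.
#' @param n_par Number of PAR genes (split PAR1/PAR2).
#' @param escape_frac,variable_frac Fractions of nonPAR genes that escape
#'   constitutively / variably; the remainder is inactive.
#' @param escape_pi_range Range of Xi expression fraction for escape genes.
#' @param inactive_leak Xi leak fraction of inactive genes (kept below the
#'   2.5 percent binomial null so the test's null is realistic).
#' @param par_intervals PAR definition, see [default_par_intervals()].
#' @param seed Integer seed for the panel's random draws.
#' @return Tibble with `geneId`, `geneName`, `contig`, `start`, `end`,
#'   `class`, `xiFraction`, `priorStatus` (truth class, usable as a prior
#'   classification table), plus `parRegion`.
#' @export
default_gene_panel <- function(n_nonpar = 56, n_par = 4,
                               escape_frac = 0.15, variable_frac = 0.10,
                               escape_pi_range = c(0.15, 0.4),
                               inactive_leak = 0.005,
                               par_intervals = default_par_intervals(),
                               seed = 1L) {
  stopifnot(n_nonpar >= 1, n_par >= 0, escape_frac + variable_frac <= 1)
  withr::with_seed(seed, {
    n_esc <- round(n_nonpar * escape_frac)
    n_var <- round(n_nonpar * variable_frac)
    n_ina <- n_nonpar - n_esc - n_var
    classes <- sample(c(rep("escape", n_esc), rep("variable", n_var),
                        rep("inactive", n_ina)))

    gene_len <- 20000L
    # nonPAR gene starts spread between PAR1 and PAR2
    np_start <- as.integer(seq(par_intervals$PAR1[2] + 500000,
                               par_intervals$PAR2[1] - 500000 - gene_len,
                               length.out = n_nonpar))
    nonpar <- tibble(
      geneId = sprintf("GENE%03d", seq_len(n_nonpar)),
      contig = par_intervals$contig,
      start = np_start,
      end = np_start + gene_len,
      class = classes,
      xiFraction = dplyr::case_when(
        classes == "escape" ~ runif(n_nonpar, escape_pi_range[1],
                                    escape_pi_range[2]),
        classes == "variable" ~ NA_real_,  # tissue-resolved at sim time
        TRUE ~ inactive_leak
      )
    )

    par <- tibble()
    if (n_par > 0) {
      n_p1 <- ceiling(n_par / 2)
      p_start <- c(
        seq(par_intervals$PAR1[1] + 40000L, by = 300000L, length.out = n_p1),
        seq(par_intervals$PAR2[1] + 40000L, by = 80000L,
            length.out = n_par - n_p1)
      )
      par <- tibble(
        geneId = sprintf("PARG%02d", seq_len(n_par)),
        contig = par_intervals$contig,
        start = as.integer(p_start),
        end = as.integer(p_start) + gene_len,
        class = "PAR",
        xiFraction = 0.5
      )
    }

    panel <- bind_rows(par, nonpar) %>%
      arrange(.data$start) %>%
      mutate(
        geneName = .data$geneId,
        priorStatus = dplyr::recode(.data$class, PAR = "escape",
                                    escape = "escape", inactive = "inactive",
                                    variable = "variable")
      )
    annotate_par(panel, par_intervals)
  })
}

#' Simulation configuration
#'
#' Bundles the generative model for a cohort of female donors: per-donor
#' XCI skew (the fraction delta of cells inactivating the same parental X;
#' 0.5 is balanced mosaicism, 1.0 is complete non-mosaic XCI), a gene panel
#' with per-gene Xi expression fractions pi, heterozygosity, sequencing
#' depth models, optional reference-mapping bias and beta-binomial
#' over-dispersion. For an expressed hetSNP the expected fraction of RNA
#' reads from the haplotype that is on the inactive X in the majority cell
#' lineage is `f = delta * pi + (1 - delta) * (1 - pi)`; counts are drawn
#' (beta-)binomially at the sampled depth and pushed through the bias.
#'
#' @param n_donors Cohort size.
#' @param n_nmxci Number of donors with non-mosaic XCI.
#' @param nmxci_skew Skew delta assigned to nmXCI donors (default 1.0).
#' @param mosaic_skew_range Uniform range of delta for mosaic donors.
#' @param tissues_per_donor Number of tissues sampled per donor (all donors
#'   share the same tissue set, drawn from a fixed pool of tissue codes).
#' @param genes Gene panel tibble ([default_gene_panel()]); `NULL` builds
#'   the default panel under `seed_truth`.
#' @param snps_per_gene Candidate hetSNP positions per gene.
#' @param het_prob Probability a donor is heterozygous at a site.
#' @param rna_depth_mean,rna_depth_size Negative-binomial RNA depth per
#'   SNP x tissue (mean is scaled by a per-tissue lognormal factor with
#'   sdlog `tissue_depth_sdlog`).
#' @param wes_depth_mean,wes_depth_size,wgs_depth_mean,wgs_depth_size
#'   Negative-binomial genotype depth models per assay.
#' @param reference_bias Probability that a read from a site with balanced
#'   true allelic expression is counted as reference (0.5 = unbiased);
#'   applied as an odds tilt on the per-SNP reference probability.
#' @param overdispersion Beta-binomial concentration; `Inf` gives a pure
#'   binomial.
#' @param variable_escape_prob Per-tissue Bernoulli probability that a
#'   variable gene escapes in that tissue.
#' @param variable_pi_range Xi fraction range for a variable gene in the
#'   tissues where it escapes.
#' @param inactive_leak Xi fraction of variable genes in non-escaping
#'   tissues (and default leak of inactive panel genes).
#' @param other_base_rate Poisson rate (per read) of non-ref/alt bases, so
#'   `totalCount` can exceed `refCount + altCount` as in real tables.
#' @param assays Genotype assays to emit (`"WES"`, `"WGS"` or both).
#' @param seed_truth,seed_noise Separate seeds for truth structure (who is
#'   nmXCI, gene classes, haplotype phase) and count noise, so noise can be
#'   re-drawn over fixed truth.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_donors = 285, n_nmxci = 3, nmxci_skew = 1.0,
                       mosaic_skew_range = c(0.5, 0.9),
                       tissues_per_donor = 1, genes = NULL,
                       snps_per_gene = 2, het_prob = 0.5,
                       rna_depth_mean = 50, rna_depth_size = 5,
                       tissue_depth_sdlog = 0.3,
                       wes_depth_mean = 80, wes_depth_size = 10,
                       wgs_depth_mean = 40, wgs_depth_size = 10,
                       reference_bias = 0.5, overdispersion = Inf,
                       variable_escape_prob = 0.5,
                       variable_pi_range = c(0.1, 0.3),
                       inactive_leak = 0.005, other_base_rate = 0.005,
                       assays = "WES",
                       seed_truth = 1L, seed_noise = 2L) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_donors < 0 || cfg$n_nmxci > cfg$n_donors) {
    abort("n_donors must be >= 0 and >= n_nmxci", class = "xciae_config_error")
  }
  skews <- c(cfg$nmxci_skew, cfg$mosaic_skew_range)
  if (any(skews < 0.5 | skews > 1)) {
    abort("XCI skew delta must lie in [0.5, 1]", class = "xciae_config_error")
  }
  pis <- c(cfg$variable_pi_range, cfg$inactive_leak)
  if (!is.null(cfg$genes)) pis <- c(pis, cfg$genes$xiFraction)
  pis <- pis[!is.na(pis)]
  if (any(pis < 0 | pis > 0.5)) {
    abort("Xi fraction pi must lie in [0, 0.5]", class = "xciae_config_error")
  }
  if (cfg$reference_bias <= 0 || cfg$reference_bias >= 1) {
    abort("reference_bias must lie in (0, 1)", class = "xciae_config_error")
  }
  if (!all(cfg$assays %in% c("WES", "WGS"))) {
    abort("assays must be a subset of WES, WGS", class = "xciae_config_error")
  }
  invisible(cfg)
}

sim_tissue_pool <- function() {
  c("muscle", "skin_leg", "thyroid", "adipose_subc", "artery_tibi",
    "esophagus_muco", "nerve", "adipose_visc", "ovary", "uterus",
    "lung", "heart", "spleen", "pancreas", "pituitary", "liver",
    "stomach", "colon", "breast", "brain_cortex")
}

# Odds tilt: a site with balanced true expression yields reference
# fraction b; b = 0.5 leaves p untouched.
apply_reference_bias <- function(p, b) {
  p * b / (p * b + (1 - p) * (1 - b))
}

#' Simulate a cohort of donors, genotypes and allele-count tables
#'
#' Generates the full synthetic input set for the pipeline: per-donor
#' heterozygous genotypes with per-assay depths, per donor x tissue
#' allele-count tables in ASEReadCounter layout, and a truth record that is
#' emitted alongside the data but never consumed by the pipeline.
#'
#' @param config A [sim_config()].
#' @return List with elements `genotypes` (het-SNP tibble, layout of
#'   [read_het_snps()]), `allele_counts` (layout of
#'   [read_allele_counts()]), `genes` (the annotated panel) and `truth`
#'   (list of `donors`, `genes`, `gene_tissue` tibbles).
#' @export
simulate_dataset <- function(config) {
  validate_sim_config(config)
  truth <- withr::with_seed(config$seed_truth, sim_truth(config))
  data <- withr::with_seed(config$seed_noise, sim_counts(config, truth))
  list(
    genotypes = data$genotypes,
    allele_counts = data$allele_counts,
    genes = truth$panel,
    truth = list(
      donors = truth$donors,
      genes = truth$panel %>% select("geneId", "class", "xiFraction"),
      gene_tissue = truth$gene_tissue
    )
  )
}

sim_truth <- function(config) {
  panel <- config$genes
  if (is.null(panel)) {
    panel <- default_gene_panel(inactive_leak = config$inactive_leak,
                                seed = config$seed_truth)
  }

  n <- config$n_donors
  donors <- tibble(
    donor = sprintf("D%04d", seq_len(n)),
    delta = if (n > 0) runif(n, config$mosaic_skew_range[1],
                             config$mosaic_skew_range[2]) else numeric()
  )
  if (n > 0 && config$n_nmxci > 0) {
    idx <- sample(n, config$n_nmxci)
    donors$delta[idx] <- config$nmxci_skew
  }
  donors$is_nmxci <- donors$delta >= 0.995

  tissues <- sim_tissue_pool()[seq_len(config$tissues_per_donor)]

  # tissue-level escape indicators and pi for variable genes; constant pi
  # for all other classes
  gene_tissue <- tidyr::crossing(
    panel %>% select("geneId", "class", "xiFraction"),
    tissue = tissues
  ) %>%
    mutate(
      escaping = dplyr::case_when(
        .data$class %in% c("PAR", "escape") ~ TRUE,
        .data$class == "variable" ~
          runif(dplyr::n()) < config$variable_escape_prob,
        TRUE ~ FALSE
      ),
      xiFraction = dplyr::case_when(
        .data$class == "variable" & .data$escaping ~
          runif(dplyr::n(), config$variable_pi_range[1],
                config$variable_pi_range[2]),
        .data$class == "variable" ~ config$inactive_leak,
        TRUE ~ .data$xiFraction
      )
    ) %>%
    select("geneId", "tissue", "class", "escaping", "xiFraction")

  # candidate SNP positions per gene, spread across the gene body
  snps <- panel %>%
    select("geneId", "contig", "start", "end") %>%
    tidyr::crossing(snpIdx = seq_len(config$snps_per_gene)) %>%
    mutate(
      position = as.integer(.data$start +
        .data$snpIdx * (.data$end - .data$start) /
          (config$snps_per_gene + 1)),
      ref = sample(c("A", "C", "G", "T"), dplyr::n(), replace = TRUE)
    ) %>%
    mutate(alt = vapply(.data$ref, function(r) {
      sample(setdiff(c("A", "C", "G", "T"), r), 1)
    }, character(1))) %>%
    select("geneId", "contig", "position", "ref", "alt")

  # heterozygosity and haplotype phase per donor x SNP
  donor_snps <- tidyr::crossing(donors %>% select("donor"), snps) %>%
    mutate(
      het = runif(dplyr::n()) < config$het_prob,
      xiHapIsRef = runif(dplyr::n()) < 0.5
    ) %>%
    filter(.data$het) %>%
    select(-"het")

  list(panel = panel, donors = donors, gene_tissue = gene_tissue,
       tissues = tissues, donor_snps = donor_snps)
}

sim_counts <- function(config, truth) {
  ds <- truth$donor_snps
  genotypes <- purrr::map_dfr(config$assays, function(as_) {
    mean_d <- if (as_ == "WES") config$wes_depth_mean else config$wgs_depth_mean
    size_d <- if (as_ == "WES") config$wes_depth_size else config$wgs_depth_size
    depth <- rnbinom(nrow(ds), mu = mean_d, size = size_d)
    refd <- rbinom(nrow(ds), depth, 0.5)
    tibble(
      contig = ds$contig, position = ds$position, ref = ds$ref,
      alt = ds$alt, donor = ds$donor, assay = as_,
      refDepth = as.integer(refd), altDepth = as.integer(depth - refd),
      passedVariantFilter = depth > 0
    )
  })

  obs <- ds %>%
    left_join(truth$donors %>% select("donor", "delta"), by = "donor") %>%
    tidyr::crossing(tissue = truth$tissues) %>%
    left_join(truth$gene_tissue %>% select("geneId", "tissue", "xiFraction"),
              by = c("geneId", "tissue"))

  if (nrow(obs) == 0L) {
    counts <- empty_allele_counts()
  } else {
    tissue_factor <- stats::setNames(
      rlnorm(length(truth$tissues), 0, config$tissue_depth_sdlog),
      truth$tissues
    )
    depth <- rnbinom(nrow(obs),
                     mu = config$rna_depth_mean * tissue_factor[obs$tissue],
                     size = config$rna_depth_size)

    f <- obs$delta * obs$xiFraction + (1 - obs$delta) * (1 - obs$xiFraction)
    p_ref <- ifelse(obs$xiHapIsRef, f, 1 - f)
    p_ref <- apply_reference_bias(p_ref, config$reference_bias)
    if (is.finite(config$overdispersion)) {
      k <- config$overdispersion
      p_ref <- rbeta(nrow(obs), p_ref * k, (1 - p_ref) * k)
    }
    refc <- rbinom(nrow(obs), depth, p_ref)
    other <- rpois(nrow(obs), config$other_base_rate * depth)

    counts <- obs %>%
      mutate(
        sample = paste0(.data$donor, ".", .data$tissue),
        refCount = as.integer(refc),
        altCount = as.integer(depth - refc),
        totalCount = as.integer(depth + other)
      ) %>%
      filter(.data$refCount + .data$altCount > 0) %>%
      select("contig", "position", "ref", "alt", "donor", "sample",
             "tissue", "refCount", "altCount", "totalCount")
  }

  # counts are emitted once per genotype assay that called the site: both
  # pipelines count the same RNA reads, so shared sites carry equal counts
  # and the downstream merge dedups them
  counts <- purrr::map_dfr(config$assays, function(as_) {
    counts %>% mutate(assay = as_)
  })

  list(genotypes = genotypes, allele_counts = counts)
}

empty_allele_counts <- function() {
  tibble(
    contig = character(), position = integer(), ref = character(),
    alt = character(), donor = character(), sample = character(),
    tissue = character(), refCount = integer(), altCount = integer(),
    totalCount = integer()
  )
}

#' Simulate a single-tissue screening cohort
#'
#' [simulate_dataset()] restricted to one tissue per donor and WES-derived
#' site lists: the design of the cohort-wide skew screen. Donors with
#' delta >= 0.995 carry the true nmXCI label.
#'
#' @param config A [sim_config()]; `tissues_per_donor` and `assays` are
#'   overridden to the screen design.
#' @return As [simulate_dataset()].
#' @export
simulate_screen_cohort <- function(config = sim_config()) {
  config$tissues_per_donor <- 1
  config$assays <- "WES"
  simulate_dataset(config)
}

#' Write a simulated dataset to disk in pipeline input formats
#'
#' Emits one VCF per assay, one ASEReadCounter-layout TSV per
#' donor x tissue, a gene annotation TSV, and the truth tables under a
#' `truth/` subdirectory (file-level separation from pipeline inputs).
#'
#' @param sim Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(file.path(dir, "counts"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)

  for (as_ in unique(sim$genotypes$assay)) {
    write_genotype_vcf(sim$genotypes %>% filter(.data$assay == as_),
                       file.path(dir, paste0("genotypes_", as_, ".vcf")))
  }
  by_sample <- sim$allele_counts %>%
    distinct(.data$donor, .data$sample, .data$tissue, .data$assay)
  for (i in seq_len(nrow(by_sample))) {
    s <- by_sample[i, ]
    recs <- sim$allele_counts %>%
      semi_join(s, by = c("donor", "sample", "tissue", "assay"))
    write_allele_counts(
      recs, file.path(dir, "counts",
                      paste0(s$sample, ".", s$assay, ".tsv")))
  }
  readr::write_tsv(
    sim$genes %>% select("geneId", "geneName", "contig", "start", "end",
                         "priorStatus"),
    file.path(dir, "genes.tsv"), progress = FALSE)
  readr::write_tsv(sim$truth$donors, file.path(dir, "truth", "donors.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$truth$gene_tissue,
                   file.path(dir, "truth", "gene_tissue.tsv"),
                   progress = FALSE)
  invisible(dir)
}
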