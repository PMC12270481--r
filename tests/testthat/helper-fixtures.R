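suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

# Independent brute-force upper-tail binomial oracle (log-space summation;
# deliberately not pbinom, which the implementation uses).
brute_binom_tail <- function(x, n, p) {
  if (x <= 0) return(1)
  ks <- x:n
  sum(exp(lchoose(n, ks) + ks * log(p) + (n - ks) * log1p(-p)))
}

# Hand Benjamini-Hochberg: p * m / rank with cumulative minimum taken from
# the largest rank downwards, capped at 1.
hand_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

# Minimal genotype row builder
gt_row <- function(donor = "D1", position = 1000L, ref = "A", alt = "G",
                   refDepth = 25L, altDepth = 25L, assay = "WES",
                   contig = "chrX", passed = TRUE) {
  tibble(contig = contig, position = as.integer(position), ref = ref,
         alt = alt, donor = donor, assay = assay,
         refDepth = as.integer(refDepth), altDepth = as.integer(altDepth),
         passedVariantFilter = passed)
}

# Minimal allele-count row builder
ac_row <- function(donor = "D1", tissue = "muscle", position = 1000L,
                   refCount = 50L, altCount = 50L, ref = "A", alt = "G",
                   assay = "WES", contig = "chrX",
                   totalCount = refCount + altCount,
                   sample = paste0(donor, ".", tissue)) {
  tibble(contig = contig, position = as.integer(position), ref = ref,
         alt = alt, donor = donor, sample = sample, tissue = tissue,
         assay = assay, refCount = as.integer(refCount),
         altCount = as.integer(altCount),
         totalCount = as.integer(totalCount))
}

# Tiny annotated gene panel: two nonPAR genes, one PAR1 gene, one
# previously-variable nonPAR gene
tiny_panel <- function() {
  annotate_par(tibble(
    geneId = c("PARG1", "G1", "G2", "GVAR"),
    geneName = c("PARG1", "G1", "G2", "GVAR"),
    contig = "chrX",
    start = c(200000L, 4000000L, 8000000L, 12000000L),
    end = c(210000L, 4020000L, 8020000L, 12020000L),
    priorStatus = c("escape", "inactive", "escape", "variable")
  ))
}

# Escape-call row builder for classify/curate tests
call_row <- function(geneId = "G1", donor = "D1", tissue = "t1",
                     xiCount = 0L, usedDepth = 100L,
                     qValue = 1, escape = qValue < 0.01,
                     xiFraction = xiCount / usedDepth,
                     aeValue = abs(0.5 - (1 - xiFraction)),
                     pValue = qValue) {
  tibble(geneId = geneId, donor = donor, tissue = tissue,
         xiCount = as.integer(xiCount), usedDepth = as.integer(usedDepth),
         xiFraction = xiFraction, aeValue = aeValue, pValue = pValue,
         qValue = qValue, escape = escape)
}

# Small fast simulation config for structural tests
small_sim <- function(...) {
  args <- list(n_donors = 6, n_nmxci = 1,
               genes = default_gene_panel(n_nonpar = 12, n_par = 2,
                                          seed = 3L),
               snps_per_gene = 2, seed_truth = 3L, seed_noise = 4L)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}
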