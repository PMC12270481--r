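#' Default pseudoautosomal region intervals (GRCh38)
#'
#' PAR coordinates are an assembly property, not a result; the defaults are
#' the GRCh38 definitions and can be overridden wherever a `par_intervals`
#' argument is accepted (coordinates are 1-based inclusive).
#'
#' @param contig X-chromosome contig name the intervals refer to.
#' @return A list with elements `contig`, `PAR1` and `PAR2`, each region a
#'   length-2 integer vector `c(start, end)`.
#' @export
default_par_intervals <- function(contig = "chrX") {
  list(
    contig = contig,
    PAR1 = c(10001L, 2781479L),
    PAR2 = c(155701383L, 156030895L)
  )
}

#' Read heterozygous X-linked SNP genotypes from a VCF
#'
#' Extracts biallelic heterozygous genotypes for one donor (one VCF sample
#' column) on the X contig, with per-allele depths taken from the `AD`
#' FORMAT field. Multi-allelic records are skipped with a warning; the
#' downstream allele-count model is strictly biallelic.
#'
#' @param path Path to a VCF (v4.x) file with GT and AD per sample.
#' @param donor Sample name in the VCF to extract.
#' @param assay `"WES"` or `"WGS"`; recorded on every returned row.
#' @param contig X contig name to retain (default `"chrX"`).
#' @return A tibble with columns `contig`, `position`, `ref`, `alt`,
#'   `donor`, `assay`, `refDepth`, `altDepth`, `passedVariantFilter`.
#' @export
read_het_snps <- function(path, donor, assay = c("WES", "WGS"),
                          contig = "chrX") {
  assay <- match.arg(assay)
  if (!file.exists(path)) {
    abort(paste0("VCF not found: ", path), class = "xciae_format_error")
  }
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) {
      abort(paste0("malformed VCF '", path, "': ", conditionMessage(e)),
            class = "xciae_format_error")
    }
  )
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(empty_het_snps())
  }
  samples <- colnames(vcf@gt)[-1]
  if (!donor %in% samples) {
    abort(paste0("donor '", donor, "' absent from VCF samples (",
                 paste(samples, collapse = ", "), ")"),
          class = "xciae_lookup_error")
  }

  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    warn(paste0(sum(multi), " multi-allelic site(s) skipped in ", path))
  }

  gt <- vcfR::extract.gt(vcf, element = "GT")[, donor]
  ad <- vcfR::extract.gt(vcf, element = "AD")[, donor]
  het <- gt %in% c("0/1", "1/0", "0|1", "1|0")
  keep <- !multi & het & fix$CHROM == contig & !is.na(ad)
  if (!any(keep)) {
    return(empty_het_snps())
  }

  ad_split <- strsplit(unname(ad[keep]), ",", fixed = TRUE)
  ref_d <- vapply(ad_split, function(x) as.integer(x[1]), integer(1))
  alt_d <- vapply(ad_split, function(x) as.integer(x[2]), integer(1))

  tibble(
    contig = fix$CHROM[keep],
    position = as.integer(fix$POS[keep]),
    ref = fix$REF[keep],
    alt = fix$ALT[keep],
    donor = donor,
    assay = assay,
    refDepth = ref_d,
    altDepth = alt_d,
    passedVariantFilter = fix$FILTER[keep] %in% c("PASS", ".")
  )
}

empty_het_snps <- function() {
  tibble(
    contig = character(), position = integer(), ref = character(),
    alt = character(), donor = character(), assay = character(),
    refDepth = integer(), altDepth = integer(),
    passedVariantFilter = logical()
  )
}

#' Write per-donor genotypes to a multi-sample VCF
#'
#' Emits the minimal VCF dialect that [read_het_snps()] consumes (GT:AD per
#' sample). Sites a donor is homozygous for are written as `0/0` so the file
#' also exercises the reader's het-only contract.
#'
#' @param genotypes Tibble in the layout returned by [read_het_snps()], one
#'   row per donor x site; absent donor/site pairs are written as `0/0` with
#'   zero depth.
#' @param path Output path (plain text `.vcf`).
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(genotypes, path) {
  donors <- sort(unique(genotypes$donor))
  sites <- genotypes %>%
    distinct(.data$contig, .data$position, .data$ref, .data$alt) %>%
    arrange(.data$contig, .data$position)

  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", unique(sites$contig), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", donors), collapse = "\t")
  )

  key <- function(d) paste(d$contig, d$position, d$ref, d$alt, sep = ":")
  gt_lookup <- split(genotypes, genotypes$donor)
  site_keys <- key(sites)
  site_filter <- genotypes %>%
    group_by(.data$contig, .data$position, .data$ref, .data$alt) %>%
    summarise(pass = all(.data$passedVariantFilter), .groups = "drop")
  filt <- if_else(site_filter$pass[match(site_keys, key(site_filter))],
                  "PASS", "FAIL")
  body <- vapply(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    cells <- vapply(donors, function(dn) {
      g <- gt_lookup[[dn]]
      hit <- g[key(g) == site_keys[i], ]
      if (nrow(hit) == 1L) {
        paste0("0/1:", hit$refDepth, ",", hit$altDepth)
      } else {
        "0/0:0,0"
      }
    }, character(1))
    paste(c(s$contig, s$position, ".", s$ref, s$alt, ".", filt[i], ".",
            "GT:AD", cells), collapse = "\t")
  }, character(1))

  writeLines(c(header, body), path)
  invisible(path)
}

ase_required_cols <- c("contig", "position", "refAllele", "altAllele",
                       "refCount", "altCount", "totalCount")

#' Read an allele-count table (ASEReadCounter layout)
#'
#' Reads a tab-separated allele-count table with the de facto ASEReadCounter
#' header. Positions are kept 1-based as in the file. Sample provenance
#' (donor, sample, tissue, genotype assay) is supplied by the caller because
#' the format itself carries none.
#'
#' @param path Path to the TSV.
#' @param donor,sample,tissue Identifiers recorded on every row.
#' @param assay Which genotype pipeline produced the site list (`"WES"` or
#'   `"WGS"`).
#' @return A tibble with columns `contig`, `position`, `ref`, `alt`,
#'   `donor`, `sample`, `tissue`, `assay`, `refCount`, `altCount`,
#'   `totalCount`.
#' @export
read_allele_counts <- function(path, donor, sample, tissue,
                               assay = c("WES", "WGS")) {
  assay <- match.arg(assay)
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(ase_required_cols, names(tab))
  if (length(missing) > 0L) {
    abort(paste0("allele-count table '", path, "' lacks required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "xciae_format_error")
  }
  validate_allele_counts(tab, path)
  tibble(
    contig = as.character(tab$contig),
    position = as.integer(tab$position),
    ref = as.character(tab$refAllele),
    alt = as.character(tab$altAllele),
    donor = donor, sample = sample, tissue = tissue, assay = assay,
    refCount = as.integer(tab$refCount),
    altCount = as.integer(tab$altCount),
    totalCount = as.integer(tab$totalCount)
  )
}

validate_allele_counts <- function(tab, path) {
  if (nrow(tab) == 0L) return(invisible(TRUE))
  neg <- tab$refCount < 0 | tab$altCount < 0 | tab$totalCount < 0
  if (any(neg)) {
    abort(paste0("negative count in '", path, "' at row ",
                 which(neg)[1]),
          class = "xciae_validation_error")
  }
  bad_total <- tab$totalCount < tab$refCount + tab$altCount
  if (any(bad_total)) {
    abort(paste0("totalCount < refCount + altCount in '", path,
                 "' at row ", which(bad_total)[1]),
          class = "xciae_validation_error")
  }
  invisible(TRUE)
}

#' Write an allele-count table in ASEReadCounter layout
#'
#' Inverse of [read_allele_counts()]: integer counts round-trip exactly.
#'
#' @param records Allele-count tibble for one donor/sample (layout of
#'   [read_allele_counts()] output).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_allele_counts <- function(records, path) {
  out <- tibble(
    contig = records$contig,
    position = records$position,
    variantID = ".",
    refAllele = records$ref,
    altAllele = records$alt,
    refCount = records$refCount,
    altCount = records$altCount,
    totalCount = records$totalCount,
    otherBases = records$totalCount - records$refCount - records$altCount
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Minimal six-column TSV (`geneId`, `geneName`, `contig`, `start`, `end`,
#' `priorStatus`) with 1-based inclusive coordinates. `priorStatus` carries
#' an earlier XCI classification (`escape`, `inactive`, `variable`,
#' `unknown`); genes previously called variable are excluded from the
#' nmXCI screen statistic.
#'
#' @param path Path to the TSV.
#' @param par_intervals PAR definition, see [default_par_intervals()].
#' @return Annotation tibble with a `parRegion` column added.
#' @export
read_gene_annotation <- function(path, par_intervals = default_par_intervals()) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("geneId", "geneName", "contig", "start", "end", "priorStatus")
  missing <- setdiff(needed, names(tab))
  if (length(missing) > 0L) {
    abort(paste0("gene annotation '", path, "' lacks column(s): ",
                 paste(missing, collapse = ", ")),
          class = "xciae_format_error")
  }
  if (any(tab$start > tab$end)) {
    abort("gene annotation has start > end", class = "xciae_validation_error")
  }
  annotate_par(as_tibble(tab), par_intervals)
}

#' Assign pseudoautosomal-region membership to genes
#'
#' Labels each gene `PAR1`, `PAR2` or `nonPAR` by the position of its
#' gene-body midpoint relative to the configured PAR intervals. The midpoint
#' rule gives every gene exactly one label, which the classification tables
#' require, including the rare gene straddling a PAR boundary. Genes not on
#' the configured X contig get `nonPAR` with a warning.
#'
#' @param genes Tibble with `geneId`, `contig`, `start`, `end` (1-based
#'   inclusive).
#' @param par_intervals See [default_par_intervals()].
#' @return `genes` with a `parRegion` column (`"PAR1"`, `"PAR2"`,
#'   `"nonPAR"`).
#' @export
annotate_par <- function(genes, par_intervals = default_par_intervals()) {
  off_x <- genes$contig != par_intervals$contig
  if (any(off_x)) {
    warn(paste0(sum(off_x), " gene(s) not on ", par_intervals$contig,
                "; assigned nonPAR"))
  }
  mid <- (as.numeric(genes$start) + as.numeric(genes$end)) / 2
  in_iv <- function(x, iv) x >= iv[1] & x <= iv[2]
  genes$parRegion <- dplyr::case_when(
    off_x ~ "nonPAR",
    in_iv(mid, par_intervals$PAR1) ~ "PAR1",
    in_iv(mid, par_intervals$PAR2) ~ "PAR2",
    TRUE ~ "nonPAR"
  )
  genes
}

#' Map SNP records to genes by position
#'
#' Joins allele-count (or genotype) records to every gene whose interval
#' contains the SNP position on the same contig. A SNP inside two
#' overlapping genes contributes to both, mirroring per-gene read counting.
#'
#' @param records Tibble with `contig` and `position` columns.
#' @param genes Gene annotation tibble ([read_gene_annotation()]).
#' @return `records` with `geneId` (rows outside every gene are dropped).
#' @export
map_snps_to_genes <- function(records, genes) {
  hits <- dplyr::inner_join(
    records,
    genes %>% select("geneId", "contig", "start", "end"),
    by = "contig", relationship = "many-to-many"
  ) %>%
    filter(.data$position >= .data$start, .data$position <= .data$end) %>%
    select(-"start", -"end")
  hits
}
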