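# Readers and writers for the package's plain-text interchange formats:
# genotype matrices (TSV or VCF), covariate/trait tables, FAM-style sibship
# maps, truth records, and the pipeline's result tables.

#' Read a genotype matrix
#'
#' TSV format: one row per individual, first column `individual_id`,
#' remaining columns minor-allele counts 0/1/2 (NA allowed). VCF: biallelic
#' sites with a GT field; unphased or phased separators are accepted and
#' multi-allelic sites are skipped with a warning (requires the vcfR
#' package). In both formats minor-allele orientation is enforced: columns
#' whose counted-allele frequency exceeds 0.5 are recoded as `2 - g`, with
#' recode events recorded in the attached `recoded` attribute.
#'
#' @param path input file.
#' @param format "auto" (by extension), "tsv" or "vcf".
#' @return individuals x SNPs integer matrix with attribute `recoded`
#'   (character vector of recoded SNP ids).
#' @export
read_genotypes <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (names(tab)[1] != "individual_id")
      stop("genotype TSV must have 'individual_id' as its first column")
    g <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(g) <- "integer"
    rownames(g) <- tab$individual_id
  } else {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("reading VCF requires the vcfR package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    alt <- vcfR::getALT(v)
    multi <- grepl(",", alt)
    if (any(multi)) {
      warning(sum(multi), " multi-allelic site(s) skipped")
      v <- v[!multi, ]
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    code <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
    g <- matrix(code[gsub("\\|", "/", gt)], nrow = nrow(gt),
                dimnames = list(vcfR::getID(v), colnames(gt)))
    g <- t(g)
  }
  bad <- !is.na(g) & !(g %in% 0:2)
  if (any(bad)) stop("malformed genotype entries (not 0/1/2/NA) at ",
                     sum(bad), " cell(s)")
  recoded <- character(0)
  for (j in seq_len(ncol(g))) {
    fr <- mean(g[, j], na.rm = TRUE) / 2
    if (is.finite(fr) && fr > 0.5) {
      g[, j] <- 2L - g[, j]
      recoded <- c(recoded, colnames(g)[j])
    }
  }
  attr(g, "recoded") <- recoded
  g
}

#' Write a genotype matrix to TSV
#' @param g individuals x SNPs matrix (rownames = individual ids).
#' @param path output file.
#' @export
write_genotypes_tsv <- function(g, path) {
  tab <- data.frame(individual_id = rownames(g), g, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genotype matrix to VCF (unphased GT)
#'
#' Minimal VCF 4.2 writer: one biallelic site per SNP with REF/ALT
#' placeholder alleles and an unphased GT field; missing genotypes become
#' `./.`. Site coordinates come from `snp_meta` when supplied.
#'
#' @param g individuals x SNPs matrix of minor-allele counts.
#' @param path output file.
#' @param snp_meta optional data.frame with `snp_id`, `chrom`, `pos`.
#' @export
write_genotypes_vcf <- function(g, path, snp_meta = NULL) {
  ids <- colnames(g)
  if (is.null(snp_meta)) {
    chrom <- rep("1", ncol(g)); pos <- seq_len(ncol(g)) * 1000L
  } else {
    m <- snp_meta[match(ids, snp_meta$snp_id), ]
    chrom <- as.character(m$chrom); pos <- m$pos
  }
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(g)), collapse = "\t")), con)
  for (j in seq_len(ncol(g))) {
    calls <- ifelse(is.na(g[, j]), "./.", gt_code[as.character(g[, j])])
    writeLines(paste(c(chrom[j], pos[j], ids[j], "A", "G", ".", "PASS", ".",
                       "GT", calls), collapse = "\t"), con)
  }
  invisible(path)
}

#' Write the covariate + trait table to TSV
#' @param covariates data.frame including `individual_id`.
#' @param path output file.
#' @export
write_covariates_tsv <- function(covariates, path) {
  utils::write.table(covariates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the sibship map to a FAM-style TSV
#' @param pedigree data.frame with `individual_id`, `sibship_id`.
#' @param path output file.
#' @export
write_pedigree_fam <- function(pedigree, path) {
  utils::write.table(pedigree[, c("sibship_id", "individual_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = c("family_id", "individual_id"))
  invisible(path)
}

#' Read a FAM-style sibship map
#' @param path TSV with columns `family_id`, `individual_id`.
#' @return data.frame with `individual_id`, `sibship_id`.
#' @export
read_pedigree_fam <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  data.frame(individual_id = tab$individual_id, sibship_id = tab$family_id,
             stringsAsFactors = FALSE)
}

#' Write the pipeline result tables
#'
#' Writes `scan_results.tsv`, `screened_results.tsv` (sorted by overall pass
#' then interaction p-value), `criteria_summary.tsv` (one row per criterion,
#' one column per test family), `model_steps.tsv` and `manifest.json`
#' (configuration, seeds, package version, skip log).
#'
#' @param out_dir output directory (created if needed).
#' @param scan_results data.frame from [run_scan()].
#' @param screened data.frame from [apply_criteria()] (optional).
#' @param model_steps data.frame from [model_summary()] (optional).
#' @param config the [criteria_config()] used (optional).
#' @param extra named list merged into the manifest.
#' @return invisible vector of written paths.
#' @export
write_results <- function(out_dir, scan_results, screened = NULL,
                          model_steps = NULL, config = NULL, extra = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wt <- function(tab, name) {
    p <- file.path(out_dir, name)
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wt(scan_results, "scan_results.tsv")
  if (!is.null(screened)) {
    ord <- order(-as.integer(isTRUE_vec(screened$pass_all)), screened$p_value)
    wt(screened[ord, , drop = FALSE], "screened_results.tsv")
    wt(criteria_summary(screened), "criteria_summary.tsv")
  }
  if (!is.null(model_steps)) wt(model_steps, "model_steps.tsv")
  skips <- attr(scan_results, "skips")
  manifest <- c(list(
    package_version = as.character(utils::packageVersion("episcreen")),
    n_tests = nrow(scan_results),
    config = if (is.null(config)) NULL else unclass(config),
    skips = if (is.null(skips)) list() else skips
  ), extra)
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, null = "null",
                       digits = NA)
  paths <- c(paths, mp)
  invisible(paths)
}

#' Assemble a cohort from its component tables
#'
#' @param genotypes individuals x SNPs matrix of minor-allele counts.
#' @param covariates data.frame with `individual_id`, `sibship_id`, the
#'   trait column and covariates.
#' @param pedigree data.frame with `individual_id`, `sibship_id`; defaults
#'   to the covariate table's columns.
#' @param trait_name trait column name (default "lvm").
#' @param snp_meta optional per-SNP metadata.
#' @return object of class `cohort`.
#' @export
as_cohort <- function(genotypes, covariates, pedigree = NULL,
                      trait_name = "lvm", snp_meta = NULL) {
  if (is.null(pedigree))
    pedigree <- covariates[, c("individual_id", "sibship_id")]
  if (!all(covariates$individual_id %in% rownames(genotypes)))
    stop("individual ids in covariates and genotypes do not match")
  genotypes <- genotypes[covariates$individual_id, , drop = FALSE]
  structure(list(genotypes = genotypes, covariates = covariates,
                 pedigree = pedigree, snp_meta = snp_meta,
                 trait_name = trait_name, truth = NULL),
            class = "cohort")
}

#' Write all cohort tables to a directory
#'
#' Genotypes to TSV and VCF, covariates + trait to TSV, pedigree to
#' FAM-style TSV, and (for simulated cohorts) the truth record to TSV.
#'
#' @param cohort a `cohort` object.
#' @param out_dir output directory.
#' @return invisible vector of written paths.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- c(
    write_genotypes_tsv(cohort$genotypes, file.path(out_dir, "genotypes.tsv")),
    write_genotypes_vcf(cohort$genotypes, file.path(out_dir, "genotypes.vcf"),
                        cohort$snp_meta),
    write_covariates_tsv(cohort$covariates, file.path(out_dir, "covariates.tsv")),
    write_pedigree_fam(cohort$pedigree, file.path(out_dir, "pedigree.fam"))
  )
  if (!is.null(cohort$truth)) {
    tp <- file.path(out_dir, "truth.tsv")
    utils::write.table(cohort$truth$individuals, tp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p <- c(p, tp)
  }
  invisible(p)
}
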