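#' Read a fully phased VCF into a haplotype panel
#'
#' Ingests biallelic SNP records with phased genotypes (`|` separator).
#' Every sample contributes two haplotype rows. Missing genotypes,
#' unphased calls, multiallelic sites and non-SNP alleles are hard errors:
#' the scan's contract is complete phased input (phasing happens upstream),
#' so nothing is imputed or silently dropped.
#'
#' @param path path to a VCF (optionally bgzipped).
#' @param line_label population tag stored on the panel.
#' @return A [haplotype_panel()] with `H = 2 * n_samples` rows; alleles
#'   coded 0 = REF, 1 = ALT; markers sorted by (chrom, pos).
#' @export
read_phased_vcf <- function(path, line_label = "panel") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("no variant records in ", path)
  multi <- grepl(",", fix$ALT) | is.na(fix$ALT) | fix$ALT == "."
  if (any(multi)) {
    stop("multiallelic or ALT-less record at ", fix$CHROM[which(multi)[1]],
         ":", fix$POS[which(multi)[1]], "; only biallelic SNPs are supported")
  }
  notsnp <- nchar(fix$REF) != 1L | nchar(fix$ALT) != 1L
  if (any(notsnp)) {
    stop("non-SNP alleles at ", fix$CHROM[which(notsnp)[1]], ":",
         fix$POS[which(notsnp)[1]])
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || ncol(gt) == 0) stop("VCF has no sample genotype columns")
  # %in% and grepl drop matrix dimensions; restore them so arr.ind works
  as_gt_matrix <- function(x) matrix(x, nrow = nrow(gt), ncol = ncol(gt))
  bad <- which(as_gt_matrix(is.na(gt) | gt %in% c(".", ".|.", "./.")),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("missing genotype at ", fix$CHROM[bad[1, 1]], ":", fix$POS[bad[1, 1]],
         " (sample ", colnames(gt)[bad[1, 2]], "); this tool does not impute")
  }
  unph <- which(as_gt_matrix(grepl("/", gt, fixed = TRUE)), arr.ind = TRUE)
  if (nrow(unph) > 0) {
    stop("unphased genotype at ", fix$CHROM[unph[1, 1]], ":",
         fix$POS[unph[1, 1]], " (sample ", colnames(gt)[unph[1, 2]],
         "); all genotypes must use the '|' separator")
  }
  okform <- as_gt_matrix(grepl("^[01]\\|[01]$", gt))
  if (!all(okform)) {
    bad <- which(!okform, arr.ind = TRUE)
    stop("unparseable genotype '", gt[bad[1, 1], bad[1, 2]], "' at ",
         fix$CHROM[bad[1, 1]], ":", fix$POS[bad[1, 1]])
  }
  a1 <- substr(gt, 1L, 1L) == "1"
  a2 <- substr(gt, 3L, 3L) == "1"
  M <- nrow(gt); S <- ncol(gt)
  X <- matrix(0L, nrow = 2L * S, ncol = M)
  X[seq(1L, 2L * S, by = 2L), ] <- t(a1) + 0L
  X[seq(2L, 2L * S, by = 2L), ] <- t(a2) + 0L
  sample_ids <- as.vector(rbind(paste0(colnames(gt), "_1"),
                                paste0(colnames(gt), "_2")))
  markers <- data.frame(
    chrom = fix$CHROM, pos = as.numeric(fix$POS),
    id = ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0(fix$CHROM, "_", fix$POS), fix$ID),
    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE
  )
  haplotype_panel(X, markers, sample_ids, line_label)
}

#' Read an IMPUTE-style .hap/.legend pair
#'
#' The `.hap` file holds one whitespace-separated row of 0/1 alleles per
#' marker (columns are haplotypes); the legend holds one header line and
#' columns `id pos a0 a1 [chrom]`, one body row per marker. When the legend
#' lacks a `chrom` column every marker is placed on chromosome `"1"`.
#'
#' @param hap_path path to the .hap allele table.
#' @param legend_path path to the legend.
#' @param samples_path optional path to a file of haplotype labels, one per
#'   line (as written by [write_panel()]); labels are synthesised if absent.
#' @param line_label population tag.
#' @return A [haplotype_panel()] in H x M orientation.
#' @export
read_hap_legend <- function(hap_path, legend_path, samples_path = NULL,
                            line_label = "panel") {
  leg <- utils::read.table(legend_path, header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("id", "pos", "a0", "a1") %in% names(leg))) {
    stop("legend must have header columns: id pos a0 a1 [chrom]")
  }
  hap <- utils::read.table(hap_path, header = FALSE,
                           colClasses = "integer")
  if (nrow(hap) != nrow(leg)) {
    stop("row-count mismatch: .hap has ", nrow(hap), " rows, legend has ",
         nrow(leg))
  }
  hap <- as.matrix(hap)
  if (!all(hap %in% c(0L, 1L))) stop(".hap contains tokens other than 0/1")
  sample_ids <- NULL
  if (!is.null(samples_path) && file.exists(samples_path)) {
    sample_ids <- readLines(samples_path)
  }
  markers <- data.frame(
    chrom = if ("chrom" %in% names(leg)) as.character(leg$chrom) else "1",
    pos = leg$pos, id = leg$id, ref = leg$a0, alt = leg$a1,
    stringsAsFactors = FALSE
  )
  haplotype_panel(t(hap), markers, sample_ids, line_label)
}

#' Write a panel as a .hap/.legend/.samples triple
#'
#' Emits `<prefix>.hap` (marker-major 0/1 table), `<prefix>.legend`
#' (`id pos a0 a1 chrom`, with header) and `<prefix>.samples` (one
#' haplotype label per line). [read_hap_legend()] on the written files
#' reproduces the panel exactly.
#'
#' @param panel a [haplotype_panel()].
#' @param prefix output path prefix.
#' @return Invisibly, the three file paths written.
#' @export
write_panel <- function(panel, prefix) {
  validate_panel(panel)
  if (ncol(panel$haplotypes) == 0) stop("panel has no markers to write")
  paths <- paste0(prefix, c(".hap", ".legend", ".samples"))
  leg <- data.frame(id = panel$markers$id, pos = panel$markers$pos,
                    a0 = panel$markers$ref, a1 = panel$markers$alt,
                    chrom = panel$markers$chrom)
  utils::write.table(leg, paths[2], quote = FALSE, row.names = FALSE,
                     sep = " ")
  utils::write.table(t(panel$haplotypes), paths[1], quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = " ")
  writeLines(panel$sample_ids, paths[3])
  invisible(paths)
}

#' Write a marker-filter report as TSV
#'
#' @param report the `report` element of [filter_markers()].
#' @param path output TSV path.
#' @return Invisibly, `path`.
#' @export
write_filter_report <- function(report, path) {
  utils::write.table(report, path, quote = FALSE, row.names = FALSE,
                     sep = "\t")
  invisible(path)
}
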