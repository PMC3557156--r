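# End-to-end pipeline stages: run_scan, run_annotate, run_contrast.
# Each stage writes deterministic TSVs plus a single manifest.json per
# output directory recording the resolved configuration, input digests and
# per-stage record counts (timestamps are the only non-reproducible field).

read_panel_auto <- function(input, legend = NULL, samples = NULL,
                            line_label = "panel") {
  if (grepl("\\.vcf(\\.gz)?$", input)) {
    return(read_phased_vcf(input, line_label = line_label))
  }
  if (grepl("\\.hap$", input)) {
    if (is.null(legend)) {
      legend <- sub("\\.hap$", ".legend", input)
    }
    return(read_hap_legend(input, legend, samples_path = samples,
                           line_label = line_label))
  }
  # bare prefix of a .hap/.legend(/.samples) triple
  hap <- paste0(input, ".hap")
  if (file.exists(hap)) {
    smp <- paste0(input, ".samples")
    return(read_hap_legend(hap, paste0(input, ".legend"),
                           samples_path = if (file.exists(smp)) smp,
                           line_label = line_label))
  }
  stop("cannot determine input format for ", input,
       ": expected .vcf/.vcf.gz, .hap, or a .hap/.legend prefix")
}

manifest_path <- function(dir) file.path(dir, "manifest.json")

read_manifest <- function(dir) {
  path <- manifest_path(dir)
  if (!file.exists(path)) {
    return(list(tool = "sweepscan",
                version = as.character(utils::packageVersion("sweepscan")),
                stages = list()))
  }
  jsonlite::read_json(path)
}

write_manifest <- function(dir, manifest) {
  jsonlite::write_json(manifest, manifest_path(dir), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(manifest_path(dir))
}

add_stage <- function(manifest, name, inputs, config, counts, outputs) {
  digests <- as.list(tools::md5sum(unlist(inputs)))
  manifest$stages[[name]] <- list(
    inputs = digests, config = config, counts = counts,
    outputs = lapply(outputs, basename),
    completed_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  manifest
}

#' Run the full selection scan pipeline on a haplotype panel file
#'
#' Reads a phased panel (VCF or IMPUTE-style hap/legend), applies the MAF /
#' placement filter, detects core regions, runs the EHH/REHH scan, and
#' writes the four report TSVs plus `filter_report.tsv` and a
#' `manifest.json` into `out_dir`. Rerunning with identical inputs and
#' configuration reproduces byte-identical TSVs.
#'
#' @param input path to a `.vcf`/`.vcf.gz`, a `.hap` file, or the bare
#'   prefix of a `.hap`/`.legend` pair.
#' @param out_dir output directory (created if needed).
#' @param config a [scan_config()].
#' @param legend,samples optional explicit paths for hap/legend input.
#' @return Invisibly, the `sweep_scan` object.
#' @export
run_scan <- function(input, out_dir, config = scan_config(), legend = NULL,
                     samples = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  panel <- read_panel_auto(input, legend = legend, samples = samples)
  filtered <- filter_markers(panel, min_maf = config$min_maf)
  write_filter_report(filtered$report,
                      file.path(out_dir, "filter_report.tsv"))
  scan <- genome_scan(filtered$panel, config, filter = FALSE)
  paths <- scan_report(scan, out_dir)
  manifest <- read_manifest(out_dir)
  manifest <- add_stage(
    manifest, "scan",
    inputs = c(input, legend, samples),
    config = unclass(config),
    counts = list(markers_in = nrow(panel$markers),
                  markers_used = nrow(filtered$panel$markers),
                  core_regions = nrow(scan$regions),
                  tests = nrow(scan$records),
                  significant = nrow(scan$significant)),
    outputs = c(paths, file.path(out_dir, "filter_report.tsv"))
  )
  write_manifest(out_dir, manifest)
  invisible(scan)
}

#' Annotate a completed scan's significant regions with interval features
#'
#' Reads `significant_regions.tsv` from a scan output directory, overlaps
#' the distinct regions with one or more BED files, and writes
#' `annotated_regions.tsv` (one row per region x overlapping feature;
#' regions without features carry `"/"`). If no region chromosome appears
#' in a BED file, a warning lists the per-chromosome zero-overlap counts.
#'
#' @param scan_dir a directory produced by [run_scan()].
#' @param bed_paths character vector of BED file paths.
#' @return Invisibly, the annotation data.frame.
#' @export
run_annotate <- function(scan_dir, bed_paths) {
  sig_path <- file.path(scan_dir, "significant_regions.tsv")
  if (!file.exists(sig_path)) {
    stop("no significant_regions.tsv in ", scan_dir,
         "; run_scan must complete first")
  }
  sig <- utils::read.table(sig_path, header = TRUE, sep = "\t",
                           colClasses = c(chrom = "character"))
  regions <- unique(sig[, c("chrom", "core_start", "core_end"), drop = FALSE])
  names(regions) <- c("chrom", "start_pos", "end_pos")
  features <- do.call(rbind, lapply(bed_paths, read_intervals))
  if (is.null(features)) {
    features <- data.frame(chrom = character(), start = numeric(),
                           end = numeric(), name = character(),
                           source = character())
  }
  if (nrow(regions) > 0 && nrow(features) > 0 &&
      !any(regions$chrom %in% features$chrom)) {
    tally <- paste0(unique(regions$chrom), ": 0", collapse = ", ")
    warning("no BED feature shares a chromosome with the scan regions (",
            tally, "); check chromosome naming")
  }
  ann <- overlap_regions(regions, features)
  out_path <- file.path(scan_dir, "annotated_regions.tsv")
  utils::write.table(ann, out_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- read_manifest(scan_dir)
  manifest <- add_stage(
    manifest, "annotate", inputs = bed_paths,
    config = list(bed_files = basename(bed_paths)),
    counts = list(regions = nrow(regions), features = nrow(features),
                  rows = nrow(ann)),
    outputs = out_path
  )
  write_manifest(scan_dir, manifest)
  invisible(ann)
}

#' Between-line haplotype contrast over a region list
#'
#' Runs [haplotype_contrast()] for each region on two panels and writes a
#' TSV with one row per haplotype class per region (per-line counts and
#' frequencies) plus the region's chi-square statistic and p-value.
#' Regions whose markers are missing from either panel are skipped with a
#' warning.
#'
#' @param panel_a,panel_b `haplotype_panel` objects (or file paths readable
#'   by the same rules as [run_scan()]'s `input`).
#' @param regions a `core_regions` data.frame, or the path of a scan output
#'   directory whose `significant_regions.tsv` supplies the regions.
#' @param out_dir output directory for `contrast.tsv` and the manifest.
#' @param min_expected pooling threshold passed to [haplotype_contrast()].
#' @return Invisibly, the contrast data.frame.
#' @export
run_contrast <- function(panel_a, panel_b, regions, out_dir,
                         min_expected = 1) {
  input_paths <- character()
  if (is.character(panel_a)) {
    input_paths <- c(input_paths, panel_a)
    panel_a <- read_panel_auto(panel_a, line_label = "line_a")
  }
  if (is.character(panel_b)) {
    input_paths <- c(input_paths, panel_b)
    panel_b <- read_panel_auto(panel_b, line_label = "line_b")
  }
  if (is.character(regions)) {
    sig_path <- file.path(regions, "significant_regions.tsv")
    input_paths <- c(input_paths, sig_path)
    sig <- utils::read.table(sig_path, header = TRUE, sep = "\t",
                             colClasses = c(chrom = "character"))
    regions <- unique(sig[, c("chrom", "core_start", "core_end"),
                          drop = FALSE])
    names(regions) <- c("chrom", "start_pos", "end_pos")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  skipped <- 0L
  for (k in seq_len(nrow(regions))) {
    region <- regions[k, ]
    ct <- tryCatch(
      haplotype_contrast(panel_a, panel_b, region,
                         min_expected = min_expected),
      error = function(e) NULL
    )
    if (is.null(ct)) {
      warning("region ", region$chrom, ":", region$start_pos, "-",
              region$end_pos, " skipped: markers absent from a panel")
      skipped <- skipped + 1L
      next
    }
    tab <- ct$table
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = region$chrom, start_pos = region$start_pos,
      end_pos = region$end_pos, haplotype = rownames(tab),
      count_a = tab[, 1], freq_a = ct$frequencies[, 1],
      count_b = tab[, 2], freq_b = ct$frequencies[, 2],
      chi2 = ct$chi2, df = ct$df,
      p_value = ct$p_value, status = ct$status,
      row.names = NULL
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    chrom = character(), start_pos = numeric(), end_pos = numeric(),
    haplotype = character(), count_a = integer(), freq_a = numeric(),
    count_b = integer(), freq_b = numeric(), chi2 = numeric(),
    df = integer(), p_value = numeric(), status = character()
  )
  out_path <- file.path(out_dir, "contrast.tsv")
  # round for the file only; the returned object keeps full precision so
  # frequencies still sum exactly to one within each region and line
  disk <- out
  for (col in c("freq_a", "freq_b", "chi2")) disk[[col]] <- round(disk[[col]], 4)
  disk$p_value <- signif(disk$p_value, 4)
  utils::write.table(disk, out_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- read_manifest(out_dir)
  manifest <- add_stage(
    manifest, "contrast", inputs = input_paths,
    config = list(min_expected = min_expected,
                  line_a = panel_a$line_label, line_b = panel_b$line_label),
    counts = list(regions = nrow(regions), skipped = skipped,
                  rows = nrow(out)),
    outputs = out_path
  )
  write_manifest(out_dir, manifest)
  invisible(out)
}
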