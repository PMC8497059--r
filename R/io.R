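# Shared readers and writers. All tabular formats are plain TSV; variant
# panels are read from multi-sample VCF 4.2 (GT fields) with strain
# metadata as TSV; masks follow the BED convention (0-based half-open).

#' Load a pooled-amplicon pileup TSV
#'
#' Expected columns: `pos, ref, depth, A, C, G, T, ins, del` (1-based
#' amplicon positions, per-event insertion/deletion counts).
#'
#' @param path Path to the TSV file.
#' @return Validated, position-sorted pileup data frame.
#' @export
load_pileup <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("pos", "ref", "depth", "A", "C", "G", "T", "ins", "del")
  if (!all(required %in% names(df))) {
    stop("pileup must have columns: ", paste(required, collapse = ", "))
  }
  if (nrow(df) == 0) stop("empty pileup file: ", path)
  over <- which(df$A + df$C + df$G + df$T > df$depth |
                  df$ins > df$depth | df$del > df$depth)
  if (length(over)) {
    stop("allele counts exceed depth at row(s): ",
         paste(head(over, 5), collapse = ", "))
  }
  if (is.unsorted(df$pos)) {
    warning("pileup not sorted by position; sorting")
    df <- df[order(df$pos), , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' @rdname load_pileup
#' @param pileup Pileup data frame to write.
#' @export
write_pileup <- function(pileup, path) {
  write.table(pileup, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load / write a read-pair co-occurrence TSV
#'
#' Columns: `pos_i, alt_i, pos_j, alt_j, reads_both, reads_any`.
#'
#' @param path Path to the TSV file.
#' @return Validated co-occurrence data frame.
#' @export
load_cooccurrence <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(alt_i = "character", alt_j = "character"))
  required <- c("pos_i", "alt_i", "pos_j", "alt_j", "reads_both", "reads_any")
  if (!all(required %in% names(df))) {
    stop("co-occurrence table must have columns: ",
         paste(required, collapse = ", "))
  }
  if (any(df$reads_both > df$reads_any)) {
    stop("reads_both exceeds reads_any at row(s): ",
         paste(head(which(df$reads_both > df$reads_any), 5), collapse = ", "))
  }
  df
}

#' @rdname load_cooccurrence
#' @param cooc Co-occurrence data frame to write.
#' @export
write_cooccurrence <- function(cooc, path) {
  write.table(cooc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a variant panel from VCF and strain metadata
#'
#' Reads a multi-sample VCF 4.2 (GT fields), drops multiallelic records
#' (logged), resolves genotypes to 0/1/2/NA and attaches strain metadata.
#'
#' @param vcf_path Path to a VCF (optionally bgzipped).
#' @param meta Strain metadata data frame or path to a TSV with columns
#'   `name, clade, ploidy, zygosity, include`.
#' @return A [variant_panel()].
#' @export
load_variants <- function(vcf_path, meta) {
  if (is.character(meta)) meta <- read.delim(meta, stringsAsFactors = FALSE)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    message(sprintf("load_variants: dropped %d multiallelic record(s)", sum(multi)))
  }
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt_raw)
  missing_meta <- setdiff(samples, meta$name)
  missing_vcf <- setdiff(meta$name, samples)
  if (length(missing_meta) || length(missing_vcf)) {
    stop("sample-name mismatch between VCF and metadata; offenders: ",
         paste(c(missing_meta, missing_vcf), collapse = ", "))
  }
  keep <- !multi
  fix <- fix[keep, , drop = FALSE]
  gt_raw <- gt_raw[keep, , drop = FALSE]
  code_gt <- function(x) {
    x <- gsub("|", "/", x, fixed = TRUE)
    out <- rep(NA_integer_, length(x))
    out[x %in% c("0/0", "0")] <- 0L
    out[x %in% c("0/1", "1/0")] <- 1L
    out[x %in% c("1/1", "1")] <- 2L
    out
  }
  gt <- apply(gt_raw, 2, code_gt)
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))
  gt <- gt[, meta$name, drop = FALSE]
  variants <- data.frame(chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         ref = fix[, "REF"], alt = fix[, "ALT"],
                         stringsAsFactors = FALSE)
  variant_panel(variants, gt, meta)
}

#' Write a variant panel as VCF 4.2
#'
#' @param panel A [variant_panel()].
#' @param path Output path (plain text).
#' @export
write_panel_vcf <- function(panel, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel$strains$name), collapse = "\t")),
             con)
  gt_str <- matrix("./.", nrow(panel$gt), ncol(panel$gt))
  gt_str[panel$gt == 0L] <- "0/0"
  gt_str[panel$gt == 1L] <- "0/1"
  gt_str[panel$gt == 2L] <- "1/1"
  v <- panel$variants
  body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", ".", "GT",
                apply(gt_str, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Read / write a mutation-spectrum TSV (`class`, `count` columns)
#'
#' @param path Path to the TSV file.
#' @return A [spectrum_counts()] object.
#' @export
load_spectrum <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("class", "count") %in% names(df))) {
    stop("spectrum TSV must have columns 'class' and 'count'")
  }
  spectrum_counts(setNames(df$count, df$class),
                  include_indels = any(df$class %in% INDEL_CLASSES))
}

#' @rdname load_spectrum
#' @param spectrum A [spectrum_counts()] object.
#' @export
write_spectrum <- function(spectrum, path) {
  write.table(data.frame(class = names(spectrum),
                         count = as.numeric(spectrum)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load / write an amplicon map YAML
#'
#' Keys: `chrom, genome_start, orf_strand, cds_start, cds_end,
#' amplicon_length`.
#'
#' @param path Path to the YAML file.
#' @return An [amplicon_map()].
#' @export
load_amplicon_map <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(amplicon_map, y[c("chrom", "genome_start", "orf_strand",
                            "cds_start", "cds_end", "amplicon_length")])
}

#' @rdname load_amplicon_map
#' @param amap An [amplicon_map()] to write.
#' @export
write_amplicon_map <- function(amap, path) {
  yaml::write_yaml(unclass(amap), path)
  invisible(path)
}

#' Write a JSON analysis report
#'
#' Embeds a schema version, the seed and the full resolved configuration so
#' that any report can be reproduced from its own metadata.
#'
#' @param results Named list of results (must be serializable).
#' @param path Output JSON path.
#' @param seed Seed used for the run.
#' @param config Optional named list of configuration values.
#' @export
write_report <- function(results, path, seed = NULL, config = list()) {
  payload <- list(schema_version = "1.0",
                  seed = seed,
                  config = lapply(config, function(x)
                    if (is.object(x)) unclass(x) else x),
                  results = results)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
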