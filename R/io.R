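# Plain-text interchange: clinical/coverage/counts TSVs, BED intervals and
# a minimal VCF 4.2 writer/reader for variant tables.

#' Path to a packaged example data file
#'
#' @param file File name under `inst/extdata`; lists the directory when
#'   missing.
#' @return Absolute path.
#' @export
oltseq_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "oltseq")))
  }
  system.file("extdata", file, package = "oltseq", mustWork = TRUE)
}

#' Read a clinical table
#'
#' Expects one row per patient with at least `patient`, `time` (months) and
#' `event` (0/1); covariate columns are carried through. The packaged
#' `clinical_21.tsv` encodes the 21-patient transplant cohort this package
#' emulates (9 recurrence events within 24 months; non-recurrent patients
#' censored at 24 months).
#'
#' @param path TSV file path.
#' @return Tibble, validated.
#' @export
#' @examples
#' cl <- read_clinical_table(oltseq_example("clinical_21.tsv"))
#' sum(cl$event)
read_clinical_table <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("patient", "time", "event") %in% names(d)),
            all(d$time >= 0), all(d$event %in% 0:1))
  d
}

#' Write genomic regions as BED
#'
#' 0-based half-open intervals; an optional `category` (or `gene`) column
#' becomes the BED name field.
#'
#' @param regions Tibble with `chrom`, `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  name <- regions[["category"]] %||% regions[["gene"]] %||% "."
  readr::write_tsv(
    tibble::tibble(chrom = regions$chrom,
                   start = as.integer(regions$start),
                   end = as.integer(regions$end),
                   name = name),
    path, col_names = FALSE)
  invisible(path)
}

#' Read a BED file into a region tibble
#'
#' @param path BED path (0-based half-open).
#' @return Tibble: `chrom`, `start`, `end` and `name` when present.
#' @export
read_bed <- function(path) {
  d <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE)
  names(d)[1:3] <- c("chrom", "start", "end")
  if (ncol(d) >= 4) names(d)[4] <- "name"
  d
}

#' Write a variant table as minimal VCF 4.2
#'
#' One sample column carrying `AD` (ref,alt depths) and `DP`; annotation
#' (gene, effect) goes to INFO.
#'
#' @param variants Variant tibble (`chrom`, `pos`, `ref`, `alt`,
#'   `ref_reads`, `alt_reads`, optional `gene`, `effect`).
#' @param path Output path.
#' @param sample Sample column name.
#' @return `path`, invisibly.
#' @export
write_vcf_minimal <- function(variants, path, sample = "SAMPLE") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=EFF,Number=1,Type=String,Description=\"Effect class\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"))
  info <- paste0(
    "GENE=", dplyr::coalesce(variants[["gene"]], "."),
    ";EFF=", dplyr::coalesce(variants[["effect"]], "."))
  body <- paste(variants$chrom, variants$pos, ".", variants$ref,
                variants$alt, ".", "PASS", info, "AD:DP",
                paste0(variants$ref_reads, ",", variants$alt_reads, ":",
                       variants$ref_reads + variants$alt_reads),
                sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a minimal VCF 4.2 into a variant table
#'
#' Parses the single-sample `AD`/`DP` layout written by
#' [write_vcf_minimal()] (multiallelic records must be pre-split).
#'
#' @param path VCF path.
#' @return Variant tibble: `chrom`, `pos`, `ref`, `alt`, `ref_reads`,
#'   `alt_reads`, `gene`, `effect`.
#' @export
read_vcf_minimal <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0) stop("no records in VCF", call. = FALSE)
  f <- strsplit(body, "\t", fixed = TRUE)
  get <- function(i) vapply(f, `[[`, character(1), i)
  info <- get(8)
  grab <- function(tag) {
    v <- sub(paste0(".*", tag, "=([^;]*).*"), "\\1", info)
    ifelse(v == "." | v == info, NA_character_, v)
  }
  ad <- sub(":.*", "", get(10))
  adm <- do.call(rbind, lapply(strsplit(ad, ","), as.integer))
  tibble::tibble(chrom = get(1), pos = as.integer(get(2)),
                 ref = get(4), alt = get(5),
                 ref_reads = adm[, 1], alt_reads = adm[, 2],
                 gene = grab("GENE"), effect = grab("EFF"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
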