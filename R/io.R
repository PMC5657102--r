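#' Write and read genotype TSV files
#'
#' The genotype table is tab-separated with `#`-prefixed header comments
#' (recording the seed when known), a `sample` column, a `label` column
#' (`case`/`control`) and one column per site. Values are small non-negative
#' integers (0 reference, 1/2 carrier allele counts). The reader validates
#' shape, labels, uniqueness of sample ids and the genotype alphabet, and
#' round-trips with the writer.
#'
#' @param ds A `rare_dataset`.
#' @param path Output file.
#' @param seed Optional seed recorded in the header comment.
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(ds, path, seed = NULL) {
  stopifnot(inherits(ds, "rare_dataset"))
  header <- c("# rareburden genotype table",
              if (!is.null(seed)) paste0("# seed=", seed))
  writeLines(header, path)
  readr::write_tsv(as_tibble(ds), path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_genotype_tsv
#' @return For the reader: a `rare_dataset` (without MAF annotations).
#' @export
read_genotype_tsv <- function(path) {
  tb <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  if (!all(c("sample", "label") %in% names(tb)[1:2]))
    abort("Genotype TSV must start with `sample` and `label` columns.")
  if (anyDuplicated(tb$sample)) abort("Duplicate sample ids.")
  if (!all(tb$label %in% c("case", "control")))
    abort("Labels must be `case` or `control`.")
  geno <- as.matrix(tb[, -(1:2)])
  if (any(is.na(geno)) || !all(geno %in% 0:2))
    abort("Genotype cells must be 0, 1 or 2.")
  storage.mode(geno) <- "integer"
  rownames(geno) <- tb$sample
  m <- ncol(geno)
  new_rare_dataset(geno, tb$label, integer(m), rep(NA_real_, m),
                   rep(NA_real_, m),
                   coding = if (max(geno) > 1) "diploid" else "carrier")
}

#' Write and read the causal-truth table
#'
#' @param ds A `rare_dataset` (writer) or file path (reader).
#' @param path Output file.
#' @return The path (writer) or a tibble `site`, `causal` (reader).
#' @export
write_causal_tsv <- function(ds, path) {
  readr::write_tsv(tibble(site = colnames(ds$genotypes),
                          causal = ds$causal_truth), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_causal_tsv
#' @export
read_causal_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write and read read-count tables (long format)
#'
#' Long tab-separated format with one row per sample/site:
#' `sample`, `site`, `c_plus`, `d_plus`, `c_minus`, `d_minus`
#' (tumour support/depth, normal support/depth).
#'
#' @param ds A `rare_dataset` with read counts.
#' @param path File path.
#' @return The path (writer); a read-count matrix list (reader).
#' @export
write_read_counts_tsv <- function(ds, path) {
  rc <- ds$read_counts
  if (is.null(rc)) abort("Dataset has no read counts.")
  long <- tibble(
    sample = rep(rownames(rc$tumor_support), times = ncol(rc$tumor_support)),
    site = rep(colnames(rc$tumor_support), each = nrow(rc$tumor_support)),
    c_plus = as.vector(rc$tumor_support), d_plus = as.vector(rc$tumor_depth),
    c_minus = as.vector(rc$normal_support),
    d_minus = as.vector(rc$normal_depth))
  readr::write_tsv(long, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_read_counts_tsv
#' @export
read_read_counts_tsv <- function(path) {
  long <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  samples <- unique(long$sample); sites <- unique(long$site)
  shape <- function(col) {
    mat <- matrix(long[[col]], nrow = length(samples),
                  dimnames = list(samples, sites))
    mat
  }
  list(tumor_support = shape("c_plus"), tumor_depth = shape("d_plus"),
       normal_support = shape("c_minus"), normal_depth = shape("d_minus"))
}

#' Write intervals as BED
#'
#' 0-based half-open intervals on a synthetic chromosome.
#'
#' @param intervals Interval tibble.
#' @param path File path.
#' @param chrom Chromosome name used in the BED records.
#' @return The path, invisibly.
#' @export
write_intervals_bed <- function(intervals, path, chrom = "sim1") {
  readr::write_tsv(tibble(chrom = chrom, start = intervals$start,
                          end = intervals$end,
                          name = intervals$provenance),
                   path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname write_intervals_bed
#' @export
read_intervals_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name"),
                         show_col_types = FALSE, progress = FALSE)
  new_interval_set(bed$start, bed$end, bed$name)
}

#' Minimal VCF export and import
#'
#' The writer emits a GT-only VCF (1-based positions on a synthetic
#' chromosome, one ALT per site); the reader extracts carrier status from the
#' GT field of any VCF (any non-reference allele makes a carrier; missing
#' genotypes are `NA`). Import requires the `vcfR` package.
#'
#' @param ds A `rare_dataset`.
#' @param path File path.
#' @param chrom Chromosome name.
#' @return The path (writer); a list with a carrier matrix (samples x sites,
#'   `NA` for missing) and positions (reader).
#' @export
write_vcf_minimal <- function(ds, path, chrom = "sim1") {
  stopifnot(inherits(ds, "rare_dataset"))
  geno <- ds$genotypes
  gt <- matrix("0/0", nrow(geno), ncol(geno))
  gt[geno == 1L] <- "0/1"
  gt[geno >= 2L] <- "1/1"
  lines <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", chrom, ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(geno)), collapse = "\t"))
  body <- vapply(seq_len(ncol(geno)), function(s) {
    paste(c(chrom, s, colnames(geno)[s], "A", "T", ".", "PASS", ".", "GT",
            gt[, s]), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' @rdname write_vcf_minimal
#' @export
read_vcf_minimal <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    abort("Reading VCF requires the `vcfR` package.")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  carrier <- apply(gt, c(1, 2), function(g) {
    if (is.na(g) || g %in% c("./.", ".|.", ".")) return(NA_integer_)
    alleles <- strsplit(g, "[/|]")[[1]]
    as.integer(any(alleles != "0" & alleles != "."))
  })
  list(genotypes = t(carrier),
       positions = as.integer(vcfR::getPOS(v)) - 1L,
       site_ids = rownames(gt))
}

# On-disk artifacts for a pipeline result: genotype TSV, intervals BED,
# fitted-model JSON and the test row, each stamped with seed and config hash.
write_result_artifacts <- function(res, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- res$config
  cfg$output_dir <- NULL  # the hash must identify the analysis, not the path
  cfg_hash <- substr(rlang::hash(cfg), 1, 12)
  write_genotype_tsv(res$dataset, file.path(dir, "genotypes.tsv"),
                     seed = res$seed)
  write_causal_tsv(res$dataset, file.path(dir, "causal_truth.tsv"))
  write_intervals_bed(res$intervals, file.path(dir, "intervals.bed"))
  fit <- res$fit
  jsonlite::write_json(
    list(seed = res$seed, config_hash = cfg_hash,
         params = fit$params, gate = fit$gate, gate_pass = fit$gate_pass,
         selected_sites = fit$selected_sites, X = fit$X,
         region_posterior = fit$r),
    file.path(dir, "fit.json"), auto_unbox = TRUE, digits = NA)
  readr::write_tsv(dplyr::select(res$test, -"selected"),
                   file.path(dir, "test.tsv"), progress = FALSE)
  invisible(dir)
}
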