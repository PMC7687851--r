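#' Read and write genotype matrices as TSV
#'
#' The TSV dialect is a plain table with one row per individual, one column
#' per variant, values in {0, 1, 2} (minor-allele counts) and a header row of
#' variant IDs.
#'
#' @param genotypes matrix of minor-allele counts in {0, 1, 2}.
#' @param path file path.
#' @param variant_ids column names to write; defaults to existing column
#'   names or `V1..Vk`.
#' @return `write_genotypes_tsv()` returns `path` invisibly;
#'   `read_genotypes_tsv()` returns an integer matrix with variant IDs as
#'   column names.
#' @export
write_genotypes_tsv <- function(genotypes, path, variant_ids = NULL) {
  genotypes <- as.matrix(genotypes)
  if (!all(genotypes %in% 0:2)) {
    stop("invalid genotype: entries must be 0, 1 or 2", call. = FALSE)
  }
  if (is.null(variant_ids)) {
    variant_ids <- colnames(genotypes)
    if (is.null(variant_ids)) variant_ids <- paste0("V", seq_len(ncol(genotypes)))
  }
  colnames(genotypes) <- variant_ids
  utils::write.table(genotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  if (!all(m %in% 0:2)) {
    stop("invalid genotype: entries must be 0, 1 or 2", call. = FALSE)
  }
  m
}

#' Read and write phenotypes as two-column TSV
#'
#' Columns: `sample_id` and `value`.
#'
#' @param sample_id character or integer identifiers.
#' @param value numeric trait values, same length as `sample_id`.
#' @param path file path.
#' @return `write_phenotypes_tsv()` returns `path` invisibly;
#'   `read_phenotypes_tsv()` returns a data frame with columns `sample_id`
#'   and `value`.
#' @export
write_phenotypes_tsv <- function(sample_id, value, path) {
  stopifnot(length(sample_id) == length(value))
  utils::write.table(data.frame(sample_id = sample_id, value = value),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes_tsv
#' @export
read_phenotypes_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  if (!all(c("sample_id", "value") %in% names(df))) {
    stop("phenotype TSV must have columns sample_id and value", call. = FALSE)
  }
  df[, c("sample_id", "value")]
}

#' Serialize a variant panel as TSV
#'
#' Columns: `variant_id`, `maf`, `is_causal`, `beta`.
#'
#' @param panel a [variant_panel()].
#' @param path file path.
#' @return `write_panel_tsv()` returns `path` invisibly; `read_panel_tsv()`
#'   returns a validated [variant_panel()] (with `latent_rho` taken from the
#'   argument, as the TSV stores per-variant fields only).
#' @export
write_panel_tsv <- function(panel, path) {
  utils::write.table(
    data.frame(variant_id = paste0("V", seq_len(panel$k)), maf = panel$maf,
               is_causal = panel$is_causal, beta = panel$beta),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel_tsv
#' @param latent_rho AR base to attach on read (default 0.4).
#' @export
read_panel_tsv <- function(path, latent_rho = 0.4) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  variant_panel(maf = df$maf, is_causal = df$is_causal, beta = df$beta,
                latent_rho = latent_rho)
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits a plain-text VCF 4.2 with one biallelic site per variant (REF `A`,
#' ALT `C`, the ALT allele being the minor allele) and a GT-only FORMAT
#' column per individual; minor-allele counts 0/1/2 become `0/0`, `0/1`,
#' `1/1` (or phased `0|0` style with `phased = TRUE`).
#'
#' @param genotypes matrix (individuals x variants) of counts in {0, 1, 2}.
#' @param path file path.
#' @param chrom chromosome label (default `"1"`).
#' @param positions integer positions, default `1:k` scaled by 1000.
#' @param variant_ids,sample_ids identifiers; sensible defaults generated.
#' @param phased write phased separators.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, path, chrom = "1",
                                positions = NULL, variant_ids = NULL,
                                sample_ids = NULL, phased = FALSE) {
  genotypes <- as.matrix(genotypes)
  if (!all(genotypes %in% 0:2)) {
    stop("invalid genotype: entries must be 0, 1 or 2", call. = FALSE)
  }
  k <- ncol(genotypes)
  n <- nrow(genotypes)
  if (is.null(positions)) positions <- seq_len(k) * 1000L
  if (is.null(variant_ids)) variant_ids <- paste0("V", seq_len(k))
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  sep <- if (phased) "|" else "/"
  gt_codes <- c(paste0("0", sep, "0"), paste0("0", sep, "1"),
                paste0("1", sep, "1"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##contig=<ID=", chrom, ">"),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", sample_ids), collapse = "\t")), con)
  gt <- matrix(gt_codes[genotypes + 1L], n, k)
  lines <- vapply(seq_len(k), function(i) {
    paste(c(chrom, positions[i], variant_ids[i], "A", "C", ".", "PASS", ".",
            "GT", gt[, i]), collapse = "\t")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Read a biallelic VCF into a genotype matrix
#'
#' Parses the GT field of a biallelic VCF (via the vcfR package) and counts
#' ALT alleles, returning an individuals x variants matrix of minor-allele
#' counts 0/1/2. Phased and unphased separators are both accepted.
#'
#' @param path VCF file path.
#' @return Integer matrix with variant IDs as column names and sample IDs as
#'   row names.
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  counts <- vapply(seq_len(ncol(gt)), function(j) {
    vapply(strsplit(gt[, j], "[/|]"), function(al) {
      sum(al == "1")
    }, integer(1))
  }, integer(nrow(gt)))
  if (nrow(gt) == 1L) counts <- matrix(counts, nrow = 1L)
  m <- t(counts)  # individuals x variants
  dimnames(m) <- list(colnames(gt), rownames(gt))
  m
}

#' Write a population snapshot as a phased VCF
#'
#' Haplotypes are paired into diploid individuals (rows 2j-1, 2j) and written
#' with phased GT fields; the QTL column is written like any other locus with
#' ID `"QTL"`.
#'
#' @param pop a [haplotype_population][init_population()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_population_vcf <- function(pop, path) {
  n_loci <- ncol(pop$haplotypes)
  ids <- character(n_loci)
  ids[pop$qtl_index] <- "QTL"
  ids[pop$marker_cols] <- paste0("M", seq_along(pop$marker_cols))
  odd <- seq.int(1L, 2L * pop$pop_size, by = 2L)
  h1 <- pop$haplotypes[odd, , drop = FALSE]
  h2 <- pop$haplotypes[odd + 1L, , drop = FALSE]
  n <- pop$pop_size
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2", "##contig=<ID=1>",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", paste0("S", seq_len(n))),
                     collapse = "\t")), con)
  lines <- vapply(seq_len(n_loci), function(i) {
    paste(c("1", i * 1000L, ids[i], "A", "C", ".", "PASS", ".", "GT",
            paste0(h1[, i], "|", h2[, i])), collapse = "\t")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Write and read an experiment report as TSV
#'
#' The cells table round-trips exactly; the design metadata is serialized as
#' JSON in a `#design` comment line on the first row.
#'
#' @param report an `"experiment_report"` (see [run_table1()]).
#' @param path file path.
#' @return `write_report_tsv()` returns `path` invisibly;
#'   `read_report_tsv()` returns the reconstructed report.
#' @export
write_report_tsv <- function(report, path) {
  stopifnot(inherits(report, "experiment_report"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#design\t", jsonlite::toJSON(report$design,
                                                  auto_unbox = TRUE,
                                                  digits = NA,
                                                  null = "null")), con)
  utils::write.table(report$cells, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_report_tsv
#' @export
read_report_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#design\t")) {
    stop("not an experiment-report TSV (missing #design header)",
         call. = FALSE)
  }
  design <- jsonlite::fromJSON(sub("^#design\t", "", first),
                               simplifyVector = TRUE)
  cells <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L)
  experiment_report(design = design, cells = cells)
}
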