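#' Write genotypes to a minimal GT-only VCF
#'
#' @param geno a [genotype_matrix].
#' @param path output file (plain text, uncompressed).
#' @export
write_genotypes_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(geno$values)), collapse = "\t")
  ), con)
  gt_code <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(geno$values))) {
    g <- geno$values[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    writeLines(paste(c(geno$map$chr[j], geno$map$pos[j], geno$map$snp_id[j],
                       "A", "G", ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a GT-only VCF into a genotype matrix
#'
#' Plain-text parser for minimal biallelic GT-only VCFs (the format
#' [write_genotypes_vcf()] emits).
#'
#' @param path VCF file.
#' @return a [genotype_matrix].
#' @export
read_genotypes_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  hdr <- strsplit(body[1], "\t")[[1]]
  samples <- hdr[-(1:9)]
  rows <- strsplit(body[-1], "\t")
  map <- data.frame(
    snp_id = vapply(rows, `[`, "", 3),
    chr = vapply(rows, `[`, "", 1),
    pos = as.integer(vapply(rows, `[`, "", 2)),
    stringsAsFactors = FALSE
  )
  code <- function(gt) {
    gt <- sub(":.*", "", gt)
    a <- substr(gt, 1, 1)
    b <- substr(gt, 3, 3)
    ifelse(a == "." | b == ".", NA_integer_,
           as.integer(a != "0") + as.integer(b != "0"))
  }
  values <- vapply(rows, function(r) code(r[-(1:9)]),
                   integer(length(samples)))
  values <- matrix(values, nrow = length(samples),
                   dimnames = list(samples, NULL))
  suppressWarnings(chr_num <- as.numeric(map$chr))
  map$chr <- ifelse(is.na(chr_num), map$chr, chr_num)
  genotype_matrix(values, map)
}

#' Write genotypes as a coded 0/1/2 TSV
#'
#' @param geno a [genotype_matrix].
#' @param path output file.
#' @export
write_genotypes_tsv <- function(geno, path) {
  df <- data.frame(sample_id = rownames(geno$values),
                   geno$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an abundance table with a taxonomy header row
#'
#' Row 1: taxon ids; row 2: `phylum|genus` labels; then one row per
#' sample.
#'
#' @param table an [abundance_table].
#' @param path output file.
#' @export
write_abundance_tsv <- function(table, path) {
  stopifnot(inherits(table, "abundance_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("sample_id", table$taxonomy$taxon_id), collapse = "\t"), con)
  writeLines(paste(c("#taxonomy",
                     paste(table$taxonomy$phylum, table$taxonomy$genus,
                           sep = "|")), collapse = "\t"), con)
  utils::write.table(
    data.frame(sample_id = rownames(table$values), table$values,
               check.names = FALSE),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read an abundance table written by [write_abundance_tsv()]
#'
#' @param path input file.
#' @param kind `"counts"` or `"relative"`.
#' @return an [abundance_table].
#' @export
read_abundance_tsv <- function(path, kind = "relative") {
  lines <- readLines(path, n = 2)
  ids <- strsplit(lines[1], "\t")[[1]][-1]
  has_tax <- startsWith(lines[2], "#taxonomy")
  taxonomy <- if (has_tax) {
    lab <- strsplit(lines[2], "\t")[[1]][-1]
    parts <- strsplit(lab, "|", fixed = TRUE)
    data.frame(
      taxon_id = ids,
      phylum = vapply(parts, `[`, "", 1),
      genus = vapply(parts, `[`, "", 2),
      is_classified = !grepl("unclassified", lab, ignore.case = TRUE),
      stringsAsFactors = FALSE
    )
  } else NULL
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = if (has_tax) 0 else 0,
                          comment.char = "#", check.names = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df[[1]]
  abundance_table(v, taxonomy, kind = kind)
}

#' Write a relationship matrix in GCTA text format
#'
#' Produces `<prefix>.grm.id` (family/within-family id) and
#' `<prefix>.grm` (lower-triangle triplets: i, j, n_markers, value).
#'
#' @param rel a [relationship_matrix].
#' @param prefix output path prefix.
#' @export
write_grm_gcta <- function(rel, prefix) {
  stopifnot(inherits(rel, "relationship_matrix"))
  ids <- rownames(rel$values)
  utils::write.table(data.frame(ids, ids), paste0(prefix, ".grm.id"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  n <- nrow(rel$values)
  idx <- which(lower.tri(rel$values, diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  utils::write.table(
    data.frame(idx[, 1], idx[, 2], rel$n_markers,
               rel$values[idx]),
    paste0(prefix, ".grm"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(prefix)
}

#' Read a GCTA text-format relationship matrix
#'
#' @param prefix path prefix (expects `<prefix>.grm` and
#'   `<prefix>.grm.id`).
#' @param source `"GRM"` or `"MRM"`.
#' @return a [relationship_matrix].
#' @export
read_grm_gcta <- function(prefix, source = "GRM") {
  ids <- utils::read.table(paste0(prefix, ".grm.id"), sep = "\t",
                           stringsAsFactors = FALSE)[[1]]
  tri <- utils::read.table(paste0(prefix, ".grm"), sep = "\t")
  n <- length(ids)
  V <- matrix(0, n, n, dimnames = list(ids, ids))
  V[cbind(tri[[1]], tri[[2]])] <- tri[[4]]
  V[cbind(tri[[2]], tri[[1]])] <- tri[[4]]
  relationship_matrix(V, source, n_markers = tri[[3]][1])
}

#' Write a relationship matrix as a square TSV
#'
#' @param rel a [relationship_matrix].
#' @param path output file.
#' @export
write_relmatrix_tsv <- function(rel, path) {
  utils::write.table(
    data.frame(sample_id = rownames(rel$values), rel$values,
               check.names = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Write a cohort's phenotype/covariate table and truth set
#'
#' @param phenotype phenotype data.frame from [simulate_phenotype()].
#' @param path output TSV.
#' @export
write_phenotype_tsv <- function(phenotype, path) {
  utils::write.table(phenotype, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @param truth truth list from [simulate_cohort()].
#' @param path output JSON.
#' @rdname write_phenotype_tsv
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
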