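#' Genotype matrix container
#'
#' Individuals x SNPs matrix coded 0/1/2 (copies of the alternative
#' allele), `NA` for missing, with a marker map (chromosome, position).
#'
#' @param values integer matrix, rows = individuals, cols = SNPs.
#' @param map data.frame with columns `snp_id`, `chr`, `pos`.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(values, map) {
  stopifnot(is.matrix(values), ncol(values) == nrow(map))
  ok <- values %in% c(0L, 1L, 2L) | is.na(values)
  if (!all(ok)) stop("genotype values must be 0/1/2 or NA", call. = FALSE)
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("ind%04d", seq_len(nrow(values)))
  }
  colnames(values) <- map$snp_id
  structure(
    list(values = values, map = map),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$values), "individuals x",
      ncol(x$values), "SNPs,",
      sum(is.na(x$values)), "missing calls\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

#' Per-SNP alternative-allele frequency
#'
#' @param geno a [genotype_matrix].
#' @return numeric vector of allele frequencies (missing calls excluded).
#' @export
allele_freq <- function(geno) {
  colMeans(geno$values, na.rm = TRUE) / 2
}

#' Sample x taxon abundance table
#'
#' @param values non-negative matrix, rows = samples, cols = taxa.
#' @param taxonomy data.frame with columns `taxon_id`, `phylum`, `genus`,
#'   `is_classified`.
#' @param kind `"counts"` or `"relative"`.
#' @return an object of class `abundance_table`.
#' @export
abundance_table <- function(values, taxonomy = NULL, kind = c("counts", "relative")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values))
  if (any(values < 0)) stop("abundances must be non-negative", call. = FALSE)
  if (is.null(taxonomy)) {
    taxonomy <- data.frame(
      taxon_id = colnames(values) %||% sprintf("taxon%03d", seq_len(ncol(values))),
      phylum = NA_character_, genus = NA_character_, is_classified = TRUE,
      stringsAsFactors = FALSE
    )
  }
  stopifnot(nrow(taxonomy) == ncol(values))
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("ind%04d", seq_len(nrow(values)))
  }
  colnames(values) <- taxonomy$taxon_id
  if (kind == "relative" && nrow(values) > 0 && ncol(values) > 0) {
    rs <- rowSums(values)
    if (any(abs(rs - 1) > 1e-9)) {
      stop("relative-abundance rows must sum to 1", call. = FALSE)
    }
  }
  structure(list(values = values, taxonomy = taxonomy, kind = kind),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("abundance_table (", x$kind, "): ", nrow(x$values), " samples x ",
      ncol(x$values), " taxa\n", sep = "")
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$values)

#' Convert a count table to relative abundances (total-sum scaling)
#'
#' @param table an [abundance_table] of counts.
#' @return an [abundance_table] with `kind = "relative"`.
#' @export
relative_abundance <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$kind == "relative") return(table)
  rs <- rowSums(table$values)
  if (any(rs == 0)) stop("cannot normalise samples with zero total count", call. = FALSE)
  abundance_table(table$values / rs, table$taxonomy, kind = "relative")
}

#' Subset the taxa of an abundance table
#'
#' @param table an [abundance_table].
#' @param keep logical or integer index over taxa.
#' @param renormalise re-scale rows of a relative table to sum to 1 over the
#'   retained taxa (the container invariant); `FALSE` keeps raw proportions
#'   in a plain matrix.
#' @return an [abundance_table] (or, with `renormalise = FALSE` on a relative
#'   table, a plain matrix of the retained proportions).
#' @export
subset_taxa <- function(table, keep, renormalise = TRUE) {
  stopifnot(inherits(table, "abundance_table"))
  v <- table$values[, keep, drop = FALSE]
  tx <- table$taxonomy[keep, , drop = FALSE]
  if (table$kind == "relative") {
    if (!renormalise) return(v)
    rs <- rowSums(v)
    rs[rs == 0] <- 1
    v <- v / rs
  }
  abundance_table(v, tx, kind = table$kind)
}

#' Relationship matrix container (GRM or MRM)
#'
#' @param values symmetric n x n numeric matrix with sample ids as dimnames.
#' @param source `"GRM"` or `"MRM"`.
#' @param n_markers number of SNPs or taxa the matrix was built from.
#' @return an object of class `relationship_matrix`.
#' @export
relationship_matrix <- function(values, source = c("GRM", "MRM"), n_markers) {
  source <- match.arg(source)
  stopifnot(is.matrix(values), nrow(values) == ncol(values))
  if (max(abs(values - t(values))) > 1e-10) {
    stop("relationship matrix must be symmetric", call. = FALSE)
  }
  structure(list(values = values, source = source, n_markers = n_markers),
            class = "relationship_matrix")
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(x$source, "relationship matrix: ", nrow(x$values), "x", nrow(x$values),
      "from", x$n_markers, "markers\n")
  invisible(x)
}

#' @export
dim.relationship_matrix <- function(x) dim(x$values)
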