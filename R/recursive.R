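#' Indirect scenario: SNPs acting on phenotype-associated marker genera
#'
#' Marker genera are the Bonferroni-significant taxa of the MWAS; the
#' indirect SNP set of each marker genus is its mbGWAS hits at the chosen
#' significance tier.
#'
#' @param mwas an `mwas_result` table ([mwas_two_part()]).
#' @param mbgwas named list of `gwas_result` tables (one per genus,
#'   [mbgwas_scan()]).
#' @param tier `"suggestive"`, `"genome_wide"` or `"study_wide"` — the
#'   minimum tier a hit must reach.
#' @return named list of SNP-id vectors, one per marker genus (possibly
#'   empty when no genus is significant).
#' @export
indirect_scenario <- function(mwas, mbgwas,
                              tier = c("suggestive", "genome_wide", "study_wide")) {
  tier <- match.arg(tier)
  rank <- c(none = 0, suggestive = 1, genome_wide = 2, study_wide = 3)
  need <- rank[tier]
  markers <- mwas$taxon[mwas$significant]
  out <- list()
  for (g in markers) {
    tab <- mbgwas[[g]]
    if (is.null(tab)) next
    out[[g]] <- tab$snp_id[!is.na(tab$p_value) & rank[tab$tier] >= need]
  }
  out
}

#' Overlap of indirect SNPs with phenotype-GWAS hits
#'
#' Exact SNP-identity intersection (optionally a +/- `window` bp
#' positional match) between the union of per-genus indirect SNP sets
#' and the phenotype GWAS hits at the given tier.
#'
#' @param indirect_snps list from [indirect_scenario()] (or a character
#'   vector of SNP ids).
#' @param gwas a `gwas_result` table for the phenotype.
#' @param tier minimum GWAS tier for a phenotype hit.
#' @param window positional window in bp (0 = exact id match).
#' @return character vector of overlapping SNP ids.
#' @export
overlap_loci <- function(indirect_snps, gwas,
                         tier = c("suggestive", "genome_wide", "study_wide"),
                         window = 0L) {
  tier <- match.arg(tier)
  rank <- c(none = 0, suggestive = 1, genome_wide = 2, study_wide = 3)
  ind <- unique(unlist(indirect_snps, use.names = FALSE))
  hits <- gwas[!is.na(gwas$p_value) & rank[gwas$tier] >= rank[tier], , drop = FALSE]
  if (window <= 0) return(intersect(ind, hits$snp_id))
  ind_rows <- gwas[gwas$snp_id %in% ind, , drop = FALSE]
  keep <- vapply(seq_len(nrow(ind_rows)), function(i) {
    any(hits$chr == ind_rows$chr[i] & abs(hits$pos - ind_rows$pos[i]) <= window)
  }, logical(1))
  ind_rows$snp_id[keep]
}

#' Kruskal-Wallis test of a phenotype across SNP genotype groups
#'
#' Rank-based H statistic with tie correction, chi-square reference with
#' `groups - 1` df (via [stats::kruskal.test()]).
#'
#' @param y phenotype vector.
#' @param genotype 0/1/2 genotype vector for one SNP.
#' @return list with `H` and `p`.
#' @export
kruskal_wallis <- function(y, genotype) {
  g <- factor(genotype)
  tab <- table(g)
  if (length(tab) < 2 || sum(tab >= 2) < 2) {
    stop("need at least 2 genotype groups with at least 2 observations",
         call. = FALSE)
  }
  if (length(unique(y)) == 1L) return(list(H = 0, p = 1))  # full tie
  kt <- stats::kruskal.test(y, g)
  list(H = unname(kt$statistic), p = unname(kt$p.value))
}

#' Scenario report: indirect vs recursive SNPs
#'
#' Every indirect SNP (mbGWAS hit of an MWAS marker genus) is tested for
#' a direct phenotype-genotype difference: membership in the phenotype
#' GWAS hit set ("recursive (overlap)") and a Kruskal-Wallis test of the
#' phenotype across its genotype groups ("recursive (KW)" when
#' `p < kw_alpha`). SNPs with neither label are "indirect only". Labels
#' are not exclusive.
#'
#' @param mwas `mwas_result` table.
#' @param mbgwas named list of per-genus `gwas_result` tables.
#' @param gwas phenotype `gwas_result` table.
#' @param y phenotype vector (unadjusted or adjusted; used for the KW
#'   test).
#' @param geno the [genotype_matrix] (for genotype groups).
#' @param tier mbGWAS tier defining the indirect sets.
#' @param gwas_tier phenotype-GWAS tier for the overlap.
#' @param kw_alpha Kruskal-Wallis significance threshold.
#' @return list of class `scenario_report`: `marker_genera`,
#'   `indirect_snps` (per genus), `overlap_snps`, `kw_recursive_snps`,
#'   `table` (snp, genus, mbgwas_p, gwas_p, kw_p, labels), `summary`.
#' @export
recursive_report <- function(mwas, mbgwas, gwas, y, geno,
                             tier = "suggestive", gwas_tier = "suggestive",
                             kw_alpha = 0.01) {
  ind <- indirect_scenario(mwas, mbgwas, tier = tier)
  overlap <- overlap_loci(ind, gwas, tier = gwas_tier)
  rows <- list()
  kw_cache <- list()
  for (g in names(ind)) {
    for (s in ind[[g]]) {
      if (is.null(kw_cache[[s]])) {
        gvec <- geno$values[, s]
        kw_cache[[s]] <- tryCatch(kruskal_wallis(y, gvec),
                                  error = function(e) list(H = NA_real_, p = NA_real_))
      }
      kw <- kw_cache[[s]]
      labels <- character(0)
      if (s %in% overlap) labels <- c(labels, "recursive (overlap)")
      if (!is.na(kw$p) && kw$p < kw_alpha) labels <- c(labels, "recursive (KW)")
      if (!length(labels)) labels <- "indirect only"
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = s, genus = g,
        mbgwas_p = mbgwas[[g]]$p_value[match(s, mbgwas[[g]]$snp_id)],
        gwas_p = gwas$p_value[match(s, gwas$snp_id)],
        kw_p = kw$p,
        labels = paste(labels, collapse = "; "),
        stringsAsFactors = FALSE
      )
    }
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(snp_id = character(0), genus = character(0),
               mbgwas_p = numeric(0), gwas_p = numeric(0),
               kw_p = numeric(0), labels = character(0))
  kw_rec <- unique(tab$snp_id[grepl("recursive \\(KW\\)", tab$labels)])
  structure(list(
    marker_genera = names(ind),
    indirect_snps = ind,
    overlap_snps = overlap,
    kw_recursive_snps = kw_rec,
    table = tab,
    summary = c(
      n_marker_genera = length(ind),
      n_indirect = length(unique(unlist(ind, use.names = FALSE))),
      n_overlap = length(overlap),
      n_kw_recursive = length(kw_rec)
    )
  ), class = "scenario_report")
}

#' @export
print.scenario_report <- function(x, ...) {
  cat("scenario_report:", x$summary["n_marker_genera"], "marker genera,",
      x$summary["n_indirect"], "indirect SNPs,",
      x$summary["n_overlap"], "overlap and",
      x$summary["n_kw_recursive"], "KW recursive SNPs\n")
  invisible(x)
}
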