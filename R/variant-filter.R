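#' Causal-variant exclusion filter
#'
#' Among candidate variants in a mapped interval, the causal mutation of a
#' fully penetrant recessive trait must satisfy three clauses:
#' (a) all affected (case) individuals share one homozygous genotype;
#' (b) no control is homozygous for that same genotype;
#' (c) every obligate heterozygote is heterozygous.
#' A variant is retained iff all three hold; otherwise the first violated
#' clause and a witness individual are recorded.  Missing calls are
#' compatible with every clause (they are evidence of nothing); a variant
#' with no case data at all is excluded with reason `no_data`.
#'
#' @param variants A [genotype_matrix()] whose columns are biallelic
#'   variants and whose individuals carry `case`/`control`/`obligate_het`
#'   phenotype labels, or a plain 0/1/2/`NA` matrix.
#' @param phenotypes Phenotype labels per individual (defaults to the labels
#'   carried by `variants`).
#' @return A `data.frame` with one row per variant: `variant`, `pos` (when a
#'   map is available), `retained`, `reason`
#'   (`case_not_homozygous` / `control_matches_case_homozygote` /
#'   `obligate_het_not_heterozygous` / `no_data`), `witness`.
#' @export
variant_exclusion_filter <- function(variants, phenotypes = NULL) {
  if (inherits(variants, "genotype_matrix")) {
    geno <- variants$geno
    if (is.null(phenotypes)) phenotypes <- variants$individuals$phenotype
    ids <- variants$individuals$id
    map <- variants$map
  } else {
    geno <- as.matrix(variants)
    ids <- rownames(geno)
    map <- NULL
  }
  if (is.null(phenotypes)) stop("phenotype labels are required")
  if (is.null(ids)) ids <- sprintf("ind_%d", seq_len(nrow(geno)))
  bad <- setdiff(unique(phenotypes), .pheno_levels)
  if (length(bad)) stop("unknown phenotype label(s): ",
                        paste(bad, collapse = ", "))

  is_case <- phenotypes == "case"
  is_ctrl <- phenotypes == "control"
  is_het <- phenotypes == "obligate_het"

  one <- function(j) {
    v <- geno[, j]
    cs <- v[is_case]
    if (all(is.na(cs)))
      return(c("FALSE", "no_data", NA_character_))
    obs <- cs[!is.na(cs)]
    off <- which(!is.na(cs) & (cs == 1L | cs != obs[1]))
    if (any(obs == 1L) || length(unique(obs)) > 1)
      return(c("FALSE", "case_not_homozygous", ids[is_case][off[1]]))
    shared <- obs[1]
    hit <- which(!is.na(v) & is_ctrl & v == shared)
    if (length(hit))
      return(c("FALSE", "control_matches_case_homozygote", ids[hit[1]]))
    hit <- which(!is.na(v) & is_het & v != 1L)
    if (length(hit))
      return(c("FALSE", "obligate_het_not_heterozygous", ids[hit[1]]))
    c("TRUE", NA_character_, NA_character_)
  }
  res <- t(vapply(seq_len(ncol(geno)), one, character(3)))
  out <- data.frame(
    variant = colnames(geno) %||% sprintf("V%d", seq_len(ncol(geno))),
    retained = res[, 1] == "TRUE",
    reason = res[, 2],
    witness = res[, 3],
    stringsAsFactors = FALSE)
  if (!is.null(map)) out <- cbind(out[1], pos = map$pos, out[-1])
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Tabulate genotype counts at one variant by population and phenotype
#'
#' Counts the three genotype classes (plus missing) per population within
#' each phenotype class, with subtotals and a grand total, and evaluates the
#' complete-association predicate: every case homozygous alternate, every
#' control homozygous reference, every obligate heterozygote heterozygous
#' (individuals with a missing call sit in the `missing` column and are
#' excluded from the predicate).
#'
#' @param geno Genotype codes 0/1/2/`NA` at the variant, one per individual.
#' @param phenotype `case`/`control`/`obligate_het`/`unknown` labels.
#' @param population Population (breed) labels; optional.
#' @return A list of class `association_table`: `counts` (per population),
#'   `class_totals` (per phenotype class), `grand_total`,
#'   `complete_association`.
#' @export
association_table <- function(geno, phenotype, population = NULL) {
  if (length(geno) == 0) stop("no individuals")
  if (length(phenotype) != length(geno))
    stop("phenotype labels do not match genotypes")
  if (is.null(population)) population <- rep("all", length(geno))
  gclass <- factor(ifelse(is.na(geno), "missing",
                          c("hom_ref", "het", "hom_alt")[geno + 1L]),
                   levels = c("hom_alt", "het", "hom_ref", "missing"))
  pclass <- factor(phenotype, levels = .pheno_levels)

  tab <- as.data.frame.matrix(table(
    paste(pclass, population, sep = "\r"), gclass))
  key <- do.call(rbind, strsplit(rownames(tab), "\r", fixed = TRUE))
  counts <- data.frame(phenotype = key[, 1], population = key[, 2],
                       tab, row.names = NULL, stringsAsFactors = FALSE)
  counts <- counts[order(match(counts$phenotype, .pheno_levels),
                         counts$population), ]
  rownames(counts) <- NULL

  class_totals <- as.data.frame.matrix(table(pclass, gclass))
  class_totals <- data.frame(phenotype = rownames(class_totals), class_totals,
                             row.names = NULL, stringsAsFactors = FALSE)

  ok <- !is.na(geno)
  complete <- all(geno[ok & phenotype == "case"] == 2L) &&
    all(geno[ok & phenotype == "control"] == 0L) &&
    all(geno[ok & phenotype == "obligate_het"] == 1L)

  structure(list(counts = counts, class_totals = class_totals,
                 grand_total = length(geno),
                 complete_association = complete),
            class = "association_table")
}

#' @export
print.association_table <- function(x, ...) {
  print(x$class_totals)
  cat(sprintf("grand total %d; complete association: %s\n",
              x$grand_total, x$complete_association))
  invisible(x)
}
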