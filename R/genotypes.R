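#' Genotype codes
#'
#' Genotypes are stored unphased as integer codes: 0 = homozygous reference,
#' 1 = heterozygous, 2 = homozygous alternate, `NA` = missing.  Phenotype
#' labels come from the closed set `case` (recessive homozygote, h/h),
#' `control` (wild-type, H/H), `obligate_het` (known carrier, H/h) and
#' `unknown`.
#'
#' @name geno-codes
NULL

.pheno_levels <- c("case", "control", "obligate_het", "unknown")

#' Construct a genotype matrix
#'
#' @param geno Integer matrix, individuals x markers, values 0/1/2/`NA`
#'   (see [geno-codes]).  Row names are individual ids, column names marker
#'   ids.
#' @param individuals `data.frame` with columns `id`, `phenotype`,
#'   `population`; one row per row of `geno`, in the same order.
#' @param map Optional [marker_map()] whose markers match the columns of
#'   `geno`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `geno`, `individuals`, `map`.
#' @export
genotype_matrix <- function(geno, individuals, map = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (any(!geno %in% c(0L, 1L, 2L, NA)))
    stop("genotype codes must be 0, 1, 2 or NA")
  if (nrow(geno) != nrow(individuals))
    stop("individuals table does not match genotype rows")
  individuals$id <- as.character(individuals$id)
  if (is.null(individuals$phenotype)) individuals$phenotype <- "unknown"
  if (is.null(individuals$population)) individuals$population <- "unknown"
  bad <- setdiff(unique(individuals$phenotype), .pheno_levels)
  if (length(bad)) stop("unknown phenotype label(s): ",
                        paste(bad, collapse = ", "))
  if (!is.null(map)) {
    if (ncol(geno) != nrow(map))
      stop("marker map does not match genotype columns")
    colnames(geno) <- map$marker
  }
  rownames(geno) <- individuals$id
  structure(list(geno = geno, individuals = individuals, map = map),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  tab <- table(factor(x$individuals$phenotype, levels = .pheno_levels))
  cat(sprintf("genotype_matrix: %d individuals x %d markers (%s)\n",
              nrow(x$geno), ncol(x$geno),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Subset a genotype matrix by phenotype
#' @param gm A [genotype_matrix()].
#' @param phenotype Labels to keep.
#' @return A `genotype_matrix` restricted to those individuals.
#' @export
subset_phenotype <- function(gm, phenotype) {
  keep <- gm$individuals$phenotype %in% phenotype
  genotype_matrix(gm$geno[keep, , drop = FALSE],
                  gm$individuals[keep, , drop = FALSE], gm$map)
}

#' Read a phenotype file
#'
#' Tab-separated with a header; columns `id`, `phenotype` and optionally
#' `population`.  Labels must come from the closed set in [geno-codes].
#'
#' @param path File path.
#' @return `data.frame` with columns `id`, `phenotype`, `population`.
#' @export
read_phenotypes <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  if (!all(c("id", "phenotype") %in% names(df)))
    stop("phenotype file needs columns id, phenotype")
  bad <- setdiff(unique(df$phenotype), .pheno_levels)
  if (length(bad)) stop("unknown phenotype label(s): ",
                        paste(bad, collapse = ", "))
  if (is.null(df$population)) df$population <- "unknown"
  df[c("id", "phenotype", "population")]
}

.attach_phenotypes <- function(ids, phenotypes) {
  out <- data.frame(id = as.character(ids),
                    phenotype = "unknown",
                    population = "unknown",
                    stringsAsFactors = FALSE)
  if (!is.null(phenotypes)) {
    ph <- if (is.character(phenotypes) && length(phenotypes) == 1L)
      read_phenotypes(phenotypes) else phenotypes
    m <- match(out$id, ph$id)
    hit <- !is.na(m)
    out$phenotype[hit] <- ph$phenotype[m[hit]]
    out$population[hit] <- ph$population[m[hit]]
  }
  out
}

#' Read genotypes from disk
#'
#' Supported formats:
#' \describe{
#'   \item{`tsv_matrix`}{Header `id`, `phenotype`, `population`, then one
#'     column per marker holding codes 0/1/2 with `-` (or `NA`) for missing —
#'     the format written by [write_genotypes()].}
#'   \item{`vcf`}{A VCF v4.x file; only the GT field is consumed.
#'     Multi-allelic records are rejected.  Calls `0/0`, `0/1`, `1/1`, `./.`
#'     map to codes 0, 1, 2, `NA` (phase separators `|` accepted).}
#'   \item{`plink_ped`}{A PLINK `.ped` file; `map` must be the matching
#'     `.map` path or a [marker_map()].  Per marker, the alphabetically first
#'     allele observed is taken as the reference label.}
#' }
#'
#' Individuals absent from the phenotype file are labelled `unknown`.
#'
#' @param path Genotype file path.
#' @param format One of `"tsv_matrix"`, `"vcf"`, `"plink_ped"`.
#' @param phenotypes Optional phenotype file path or `data.frame`
#'   (see [read_phenotypes()]).
#' @param map For `plink_ped`, the `.map` path or a [marker_map()]; ignored
#'   for `vcf` (map comes from the records) and `tsv_matrix` (optional).
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("tsv_matrix", "vcf", "plink_ped"),
                           phenotypes = NULL, map = NULL) {
  format <- match.arg(format)
  switch(format,
         tsv_matrix = .read_geno_tsv(path, phenotypes, map),
         vcf = .read_geno_vcf(path, phenotypes),
         plink_ped = .read_geno_ped(path, phenotypes, map))
}

.read_geno_tsv <- function(path, phenotypes, map) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   na.strings = c("NA", "-"), check.names = FALSE)
  meta_cols <- intersect(c("id", "phenotype", "population"), names(df))
  marker_cols <- setdiff(names(df), meta_cols)
  geno <- as.matrix(df[marker_cols])
  if (any(!geno %in% c(0, 1, 2, NA)))
    stop("genotype symbol outside the alphabet {0,1,2,-,NA}")
  ind <- .attach_phenotypes(df$id, phenotypes)
  if ("phenotype" %in% names(df) && is.null(phenotypes)) {
    ind$phenotype <- df$phenotype
    if ("population" %in% names(df)) ind$population <- df$population
  }
  gm <- genotype_matrix(geno, ind, map)
  if (is.null(map)) colnames(gm$geno) <- marker_cols
  gm
}

.read_geno_vcf <- function(path, phenotypes) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))   # single-record VCF
  if (any(grepl(",", fix[, "ALT"], fixed = TRUE)))
    stop("multi-allelic variant records are not supported")
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep(NA_integer_, length(g))
    out[g %in% "0/0"] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g %in% "1/1"] <- 2L
    bad <- !is.na(g) & !g %in% c("0/0", "0/1", "1/0", "1/1", "./.", ".")
    if (any(bad)) stop("genotype symbol outside the alphabet: ", g[bad][1])
    out
  }
  geno <- vapply(seq_len(ncol(gt)), function(j) code(gt[, j]),
                 integer(nrow(gt)))
  geno <- t(matrix(geno, nrow = nrow(gt)))   # samples x sites
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[
    is.na(ids) | ids == "."]
  mm <- marker_map(ids, fix[, "CHROM"], as.numeric(fix[, "POS"]))
  ord <- match(mm$marker, ids)
  geno <- geno[, ord, drop = FALSE]
  ind <- .attach_phenotypes(colnames(gt), phenotypes)
  gm <- genotype_matrix(geno, ind, mm)
  attr(gm, "alleles") <- data.frame(marker = mm$marker,
                                    ref = fix[ord, "REF"],
                                    alt = fix[ord, "ALT"])
  gm
}

.read_geno_ped <- function(path, phenotypes, map) {
  if (is.null(map)) stop("plink_ped format needs the matching .map")
  mm <- if (inherits(map, "marker_map")) map
        else read_marker_map(map, format = "plink_map")
  ped <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  n_mark <- (ncol(ped) - 6L) / 2L
  if (n_mark != nrow(mm))
    stop("individual/marker mismatch: .ped has ", n_mark,
         " markers, .map has ", nrow(mm))
  a1 <- as.matrix(ped[, 6L + 2L * seq_len(n_mark) - 1L])
  a2 <- as.matrix(ped[, 6L + 2L * seq_len(n_mark)])
  geno <- matrix(NA_integer_, nrow(ped), n_mark)
  for (j in seq_len(n_mark)) {
    obs <- c(a1[, j], a2[, j])
    alleles <- sort(setdiff(unique(obs), "0"))
    if (length(alleles) > 2) stop("marker ", mm$marker[j], " is multi-allelic")
    ref <- alleles[1]
    ok <- a1[, j] != "0" & a2[, j] != "0"
    geno[ok, j] <- (a1[ok, j] != ref) + (a2[ok, j] != ref)
  }
  ind <- .attach_phenotypes(ped[[2]], phenotypes)
  genotype_matrix(geno, ind, mm)
}

#' Write a genotype matrix as a TSV table
#'
#' One row per individual: `id`, `phenotype`, `population`, then marker
#' columns with codes 0/1/2 and `-` for missing.  [read_genotypes()] with
#' `format = "tsv_matrix"` restores every call, including missing cells.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path) {
  geno <- gm$geno
  out <- cbind(gm$individuals[c("id", "phenotype", "population")],
               as.data.frame(geno))
  out[is.na(out)] <- "-"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
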