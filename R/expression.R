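# Downstream quantitative comparisons: relative expression by the Livak
# 2^-ddCt estimator, allelic expression imbalance from pyrosequencing
# allele-quantification ratios, and dual-luciferase reporter normalization.
# "t-test" defaults to Welch (unequal variances); var_equal = TRUE gives the
# classical pooled Student test.

# t-test wrapper; degenerate (zero-variance) data resolve to p = 1 when the
# means agree and p = 0 when they differ, rather than erroring.
.safe_t <- function(x, y, paired = FALSE, var_equal = FALSE) {
  if (length(x) < 2 || length(y) < 2) return(NA_real_)
  if (paired && length(x) != length(y)) return(NA_real_)
  p <- tryCatch(t.test(x, y, paired = paired, var.equal = var_equal)$p.value,
                error = function(e) NaN)
  if (is.nan(p)) {
    if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0
  } else p
}

#' Relative expression by the 2^-ddCt method
#'
#' Per individual, technical replicates are averaged per gene and
#' `dCt = Ct_target - Ct_reference`.  Per group,
#' `ddCt = mean(dCt) - mean(dCt of the reference group)` and the fold change
#' is `2^-ddCt`, so the reference group's fold is 1 by construction.  Groups
#' are compared to the reference group by a t-test on the dCt values.
#'
#' @param ct `data.frame` with columns `id`, `group`, `gene`
#'   (`target`/`reference`), `ct` and optionally `replicate`
#'   (see [simulate_ct_table()]).
#' @param reference_group Group label the fold changes are relative to.
#' @param var_equal `FALSE` for Welch (default), `TRUE` for pooled Student.
#' @return A list: `groups` (data.frame with `group`, `n`, `mean_dct`,
#'   `sd_dct`, `ddct`, `fold`, `p_value`; `p_value` is `NA` for the
#'   reference group and for groups with n < 2) and `dct` (per-individual
#'   dCt values).
#' @export
ddct_fold_change <- function(ct, reference_group, var_equal = FALSE) {
  stopifnot(all(c("id", "group", "gene", "ct") %in% names(ct)),
            all(ct$gene %in% c("target", "reference")), all(ct$ct > 0))
  if (!reference_group %in% ct$group)
    stop("reference group not present: ", reference_group)

  per_ind <- function(d) {
    tg <- mean(d$ct[d$gene == "target"])
    rf <- mean(d$ct[d$gene == "reference"])
    if (is.nan(tg) || is.nan(rf))
      stop("individual ", d$id[1], " lacks a target or reference Ct")
    data.frame(id = d$id[1], group = d$group[1], dct = tg - rf,
               stringsAsFactors = FALSE)
  }
  dct <- do.call(rbind, lapply(split(ct, ct$id), per_ind))
  rownames(dct) <- NULL

  ref_dct <- dct$dct[dct$group == reference_group]
  groups <- lapply(split(dct, dct$group), function(d) {
    ddct <- mean(d$dct) - mean(ref_dct)
    data.frame(group = d$group[1], n = nrow(d),
               mean_dct = mean(d$dct), sd_dct = sd(d$dct),
               ddct = ddct, fold = 2^(-ddct),
               p_value = if (d$group[1] == reference_group) NA_real_
                         else .safe_t(d$dct, ref_dct, var_equal = var_equal),
               stringsAsFactors = FALSE)
  })
  groups <- do.call(rbind, groups)
  rownames(groups) <- NULL
  list(groups = groups, dct = dct)
}

#' Allelic expression imbalance test
#'
#' Within each genotype, the cDNA major-allele fraction is compared to the
#' gDNA fraction of the same individuals by a paired t-test (individuals
#' lacking either template are dropped with a warning).  cDNA fractions are
#' additionally compared between genotypes (unpaired).  A cDNA fraction
#' exceeding the ~0.5 gDNA fraction in heterozygotes is evidence of
#' cis-regulatory imbalance.
#'
#' @param ratios `data.frame` with columns `id`, `genotype`, `template`
#'   (`gDNA`/`cDNA`), `major_fraction` (see [simulate_aei_table()]).
#' @param var_equal Passed to the unpaired between-genotype tests.
#' @return A list: `summary` (mean/sd/n per genotype x template),
#'   `within` (paired cDNA-vs-gDNA test per genotype), `between`
#'   (pairwise cDNA tests across genotypes; empty with one genotype).
#' @export
aei_test <- function(ratios, var_equal = FALSE) {
  stopifnot(all(c("id", "genotype", "template", "major_fraction") %in%
                  names(ratios)),
            all(ratios$template %in% c("gDNA", "cDNA")),
            all(ratios$major_fraction >= 0 & ratios$major_fraction <= 1))

  summ <- aggregate(major_fraction ~ genotype + template, ratios,
                    function(x) c(n = length(x), mean = mean(x), sd = sd(x)))
  summ <- cbind(summ[1:2], as.data.frame(summ$major_fraction))

  within <- lapply(split(ratios, ratios$genotype), function(d) {
    g <- d[d$template == "gDNA", ]
    c <- d[d$template == "cDNA", ]
    paired_ids <- intersect(g$id, c$id)
    dropped <- setdiff(union(g$id, c$id), paired_ids)
    if (length(dropped))
      warning("dropping unpaired individual(s): ",
              paste(dropped, collapse = ", "))
    gv <- g$major_fraction[match(paired_ids, g$id)]
    cv <- c$major_fraction[match(paired_ids, c$id)]
    data.frame(genotype = d$genotype[1], n_pairs = length(paired_ids),
               mean_gdna = mean(gv), mean_cdna = mean(cv),
               p_value = .safe_t(cv, gv, paired = TRUE),
               stringsAsFactors = FALSE)
  })
  within <- do.call(rbind, within)
  rownames(within) <- NULL

  geno <- unique(ratios$genotype)
  between <- NULL
  if (length(geno) > 1) {
    pairs <- utils::combn(geno, 2)
    between <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
      a <- ratios$major_fraction[ratios$genotype == pairs[1, k] &
                                   ratios$template == "cDNA"]
      b <- ratios$major_fraction[ratios$genotype == pairs[2, k] &
                                   ratios$template == "cDNA"]
      data.frame(genotype_a = pairs[1, k], genotype_b = pairs[2, k],
                 p_value = .safe_t(a, b, var_equal = var_equal),
                 stringsAsFactors = FALSE)
    }))
  }
  list(summary = summ, within = within, between = between)
}

#' Normalized luciferase reporter activity
#'
#' Per well, `ratio = firefly / renilla`.  Per construct per biological
#' repeat, activity is the mean of its technical-replicate ratios divided by
#' that repeat's reference-construct mean, so the reference construct has
#' activity 1 in every repeat.  Constructs are summarised as mean and SD
#' over biological repeats and compared pairwise by t-tests on the
#' per-repeat activities.
#'
#' @param lum `data.frame` with columns `construct`, `firefly`, `renilla`,
#'   `tech_rep`, `bio_rep` (see [simulate_luciferase_table()]).
#' @param reference_construct The promoterless reference vector label.
#' @param comparisons List of length-2 character vectors naming construct
#'   pairs to test; `NULL` tests all pairs of non-reference constructs.
#' @param var_equal `FALSE` for Welch (default), `TRUE` for pooled Student.
#' @return A list: `activity` (per construct: `n_repeats`, `mean`, `sd`),
#'   `per_repeat` (construct x biological repeat activities), `tests`.
#' @export
luciferase_fold <- function(lum, reference_construct = "pGL3-Basic",
                            comparisons = NULL, var_equal = FALSE) {
  stopifnot(all(c("construct", "firefly", "renilla", "bio_rep") %in%
                  names(lum)),
            all(lum$renilla > 0))
  if (!reference_construct %in% lum$construct)
    stop("reference construct not present: ", reference_construct)
  lum$ratio <- lum$firefly / lum$renilla

  per_rep <- aggregate(ratio ~ construct + bio_rep, lum, mean)
  keep_reps <- per_rep$bio_rep[per_rep$construct == reference_construct]
  lost <- setdiff(unique(per_rep$bio_rep), keep_reps)
  if (length(lost))
    warning("biological repeat(s) without the reference construct excluded: ",
            paste(lost, collapse = ", "))
  per_rep <- per_rep[per_rep$bio_rep %in% keep_reps, ]
  ref <- per_rep[per_rep$construct == reference_construct, ]
  per_rep$activity <- per_rep$ratio /
    ref$ratio[match(per_rep$bio_rep, ref$bio_rep)]

  activity <- aggregate(activity ~ construct, per_rep, function(x)
    c(n_repeats = length(x), mean = mean(x), sd = sd(x)))
  activity <- cbind(activity[1], as.data.frame(activity$activity))

  if (is.null(comparisons)) {
    others <- setdiff(unique(per_rep$construct), reference_construct)
    comparisons <- if (length(others) > 1)
      apply(utils::combn(others, 2), 2, identity, simplify = FALSE)
    else list()
  }
  tests <- do.call(rbind, lapply(comparisons, function(p) {
    a <- per_rep$activity[per_rep$construct == p[1]]
    b <- per_rep$activity[per_rep$construct == p[2]]
    data.frame(construct_a = p[1], construct_b = p[2],
               fold_a_over_b = mean(a) / mean(b),
               p_value = .safe_t(a, b, var_equal = var_equal),
               stringsAsFactors = FALSE)
  }))
  list(activity = activity, per_repeat = per_rep, tests = tests)
}
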