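# Generators for the three downstream expression assays: qPCR Ct tables,
# pyrosequencing allele-ratio tables, and dual-luciferase luminescence
# tables.  Replicate noise is Gaussian with user-stated SDs.

#' Simulate a qPCR Ct table
#'
#' Gaussian Ct draws per replicate for a target and a reference gene, per
#' group.  Group means are stated as Ct cycles; a group whose target sits one
#' cycle higher at equal reference expression has half the relative
#' expression.
#'
#' @param groups `data.frame` with columns `group`, `target_mean`,
#'   `target_sd`, `ref_mean`, `ref_sd`, `n` (individuals per group).
#' @param n_replicates Technical replicates per individual per gene.
#' @param seed Integer seed.
#' @return A `data.frame` with columns `id`, `group`, `gene`
#'   (`target`/`reference`), `ct`, `replicate` — the input of
#'   [ddct_fold_change()].
#' @export
simulate_ct_table <- function(groups, n_replicates = 3, seed = NULL)
  with_seed(seed, {
  stopifnot(all(c("group", "target_mean", "target_sd", "ref_mean", "ref_sd",
                  "n") %in% names(groups)),
            all(groups$target_sd >= 0), all(groups$ref_sd >= 0))
  rows <- lapply(seq_len(nrow(groups)), function(g) {
    gr <- groups[g, ]
    do.call(rbind, lapply(seq_len(gr$n), function(i) {
      id <- sprintf("%s_%02d", gr$group, i)
      data.frame(
        id = id, group = gr$group,
        gene = rep(c("target", "reference"), each = n_replicates),
        ct = c(rnorm(n_replicates, gr$target_mean, gr$target_sd),
               rnorm(n_replicates, gr$ref_mean, gr$ref_sd)),
        replicate = rep(seq_len(n_replicates), 2),
        stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
})

#' Simulate a pyrosequencing allele-ratio table
#'
#' Paired gDNA and cDNA major-allele fractions per heterozygous individual.
#' A genomic DNA fraction of 0.5 with a cDNA fraction above it is the
#' signature of allelic expression imbalance.
#'
#' @param n Individuals.
#' @param gdna_mean,gdna_sd Mean and SD of the gDNA major-allele fraction.
#' @param cdna_mean,cdna_sd Mean and SD of the cDNA major-allele fraction.
#' @param genotype Genotype label for the rows.
#' @param seed Integer seed.
#' @return A `data.frame` with columns `id`, `genotype`, `template`
#'   (`gDNA`/`cDNA`), `major_fraction` — the input of [aei_test()].
#' @export
simulate_aei_table <- function(n = 11, gdna_mean = 0.5, gdna_sd = 0.02,
                               cdna_mean = 0.65, cdna_sd = 0.03,
                               genotype = "H/h", seed = NULL)
  with_seed(seed, {
  stopifnot(gdna_sd >= 0, cdna_sd >= 0)
  clip <- function(x) pmin(pmax(x, 0), 1)
  ids <- sprintf("het_%02d", seq_len(n))
  data.frame(
    id = rep(ids, 2),
    genotype = genotype,
    template = rep(c("gDNA", "cDNA"), each = n),
    major_fraction = clip(c(rnorm(n, gdna_mean, gdna_sd),
                            rnorm(n, cdna_mean, cdna_sd))),
    stringsAsFactors = FALSE)
})

#' Simulate a dual-luciferase luminescence table
#'
#' Firefly/Renilla luminescence per well for several promoter constructs.
#' `activities` states each construct's true activity relative to the
#' reference (empty) vector; per-well multiplicative noise has coefficient of
#' variation `cv`.
#'
#' @param activities Named numeric vector of true relative activities; must
#'   include the reference construct (activity 1).
#' @param cv Per-well coefficient of variation of the firefly/Renilla ratio.
#' @param n_tech Technical replicates per construct per biological repeat.
#' @param n_bio Biological repeats.
#' @param renilla_mean Mean Renilla luminescence per well.
#' @param seed Integer seed.
#' @return A `data.frame` with columns `construct`, `firefly`, `renilla`,
#'   `tech_rep`, `bio_rep` — the input of [luciferase_fold()].
#' @export
simulate_luciferase_table <- function(activities = c("pGL3-Basic" = 1,
                                                     "H" = 46, "h" = 8),
                                      cv = 0.1, n_tech = 3, n_bio = 3,
                                      renilla_mean = 1000, seed = NULL)
  with_seed(seed, {
  stopifnot(cv >= 0, !is.null(names(activities)))
  rows <- expand.grid(construct = names(activities),
                      tech_rep = seq_len(n_tech),
                      bio_rep = seq_len(n_bio),
                      stringsAsFactors = FALSE)
  n <- nrow(rows)
  renilla <- rnorm(n, renilla_mean, 0.05 * renilla_mean)
  act <- activities[rows$construct]
  ratio <- act * pmax(1 + rnorm(n, 0, cv), 0.01)
  data.frame(construct = rows$construct,
             firefly = ratio * renilla,
             renilla = renilla,
             tech_rep = rows$tech_rep,
             bio_rep = rows$bio_rep,
             stringsAsFactors = FALSE)
})

#' Simulate expression-assay input tables
#'
#' Umbrella over the three assay generators; dispatches on `kind`.
#'
#' @param kind `"qpcr"`, `"aei"` or `"luciferase"`.
#' @param ... Passed to [simulate_ct_table()], [simulate_aei_table()] or
#'   [simulate_luciferase_table()].
#' @return The corresponding assay table.
#' @export
simulate_expression <- function(kind = c("qpcr", "aei", "luciferase"), ...) {
  switch(match.arg(kind),
         qpcr = simulate_ct_table(...),
         aei = simulate_aei_table(...),
         luciferase = simulate_luciferase_table(...))
}
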