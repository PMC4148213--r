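# Shared fixture builders (all generated in code; the two extdata TSVs are
# transcriptions of published tables).

table1_map <- function() {
  read_marker_map(system.file("extdata", "markers_chr3.tsv",
                              package = "silkymap"))
}

# Expand the per-breed association counts into one genotype call per bird.
association_individuals <- function() {
  tab <- read.table(system.file("extdata", "association_counts.tsv",
                                package = "silkymap"),
                    sep = "\t", header = TRUE, check.names = FALSE)
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    geno <- rep(c(2L, 1L, 0L),
                c(tab$hom_alt[i], tab$het[i], tab$hom_ref[i]))
    if (length(geno) == 0) return(NULL)
    data.frame(population = tab$population[i], phenotype = tab$phenotype[i],
               geno = geno, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Random case genotype matrices for the block-finder oracle comparison.
random_case_matrix <- function(max_ind = 10, max_mark = 20,
                               missing_rate = 0.15) {
  n <- sample(max_ind, 1)
  m <- sample(max_mark, 1)
  g <- matrix(sample(c(0L, 1L, 2L), n * m, replace = TRUE,
                     prob = c(0.35, 0.3, 0.35)), n, m)
  g[matrix(runif(n * m) < missing_rate, n, m)] <- NA_integer_
  g
}

# Simulated candidate-variant panel: cases carry two copies of one ancestral
# haplotype (which alone bears the causal allele), controls carry random
# background haplotypes, obligate hets one of each.  Variants are in LD with
# the causal site through the shared ancestral haplotype.
simulate_variant_panel <- function(n_variants = 85, n_cases = 8,
                                   n_controls = 9, n_hets = 3,
                                   n_bg_haps = 20) {
  causal <- sample(n_variants, 1)
  anc <- rbinom(n_variants, 1, 0.5)
  anc[causal] <- 1L
  freq <- runif(n_variants, 0.1, 0.9)
  bg <- matrix(rbinom(n_bg_haps * n_variants, 1, rep(freq, each = n_bg_haps)),
               n_bg_haps, n_variants)
  bg[, causal] <- 0L
  draw_bg <- function() bg[sample(n_bg_haps, 1), ]
  geno <- rbind(
    t(replicate(n_cases, 2L * anc)),
    t(replicate(n_controls, draw_bg() + draw_bg())),
    t(replicate(n_hets, anc + draw_bg())))
  storage.mode(geno) <- "integer"
  colnames(geno) <- sprintf("V%02d", seq_len(n_variants))
  rownames(geno) <- c(sprintf("case_%d", seq_len(n_cases)),
                      sprintf("ctrl_%d", seq_len(n_controls)),
                      sprintf("het_%d", seq_len(n_hets)))
  list(geno = geno,
       phenotype = rep(c("case", "control", "obligate_het"),
                       c(n_cases, n_controls, n_hets)),
       causal = causal)
}

# Toy fine-mapping panel encoding the printed boundary facts: cases share a
# homozygous block; in the extended panel two birds are heterozygous and one
# is homozygous for the other allele at the boundary marker (70,460,738 bp),
# and no bird is discordant further in.
boundary_toy <- function() {
  pos <- c(70447648, 70460738, 70461033, 70466750, 70481788, 70504365)
  map <- marker_map(sprintf("T%d", seq_along(pos)), "3", pos)
  cases <- matrix(2L, nrow = 8, ncol = 6)
  panel <- matrix(2L, nrow = 3, ncol = 6)
  panel[1:2, 2] <- 1L   # two heterozygous birds at the boundary marker
  panel[3, 2] <- 0L     # one bird homozygous for the non-shared allele
  list(map = map, cases = cases, panel = panel)
}
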