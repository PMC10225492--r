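#!/usr/bin/env Rscript
# Stage 1: generate the synthetic six-species study set with known ground
# truth. Genic sizes are held near-constant across species while genome
# sizes vary three-fold, so intergenic size carries the genome-size
# variation; the smallest genome (sp01) is the focal species. All inputs
# for the later stages are written under results/simdata/ in their
# standard formats (GFF3, seqlen TSV, RepeatMasker .out, ortholog TSV,
# domain TSV, expression TSV, GMT).

library(minigenomics)

seed <- 1  # every generator gets its own derived seed: two generators
           # run on one literal seed share sample() draws and correlate
out <- "results/simdata"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## Six genomes, 6.2-18 Mb (a 1:100 scale model of scallop-sized genomes),
## each with ~3.66 Mb of genic sequence.
genome_sizes <- seq(6.2e6, 18e6, length.out = 6)
genic_target <- 3.66e6
gs <- gen_genome_set(6, genome_sizes, genic_target / genome_sizes,
                     n_genes = 400, seed = seed, dir = out)
cat("wrote annotations for", length(gs$annotations), "species\n")

## TE copies per species: the focal species carries only ancient insertions
## (no recent burst); the others keep recent activity. One .out per species.
species <- vapply(gs$annotations, `[[`, "", "species")
rates <- data.frame(species = species, rate_r = 0.002)
write.table(rates, file.path(out, "rates.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
for (i in seq_along(species)) {
  ages <- if (i == 1) c(100, 150) else c(10, 50, 100, 150)
  copies <- if (i == 1) 150 else 300
  tc <- gen_te_copies(ages, copies_per_age = copies, copy_length = 1500,
                      rate_r = 0.002, seed = seed + i)
  write_repeatmasker_out(tc$records,
                         file.path(out, paste0(species[i], ".out")))
}
cat("wrote TE copy tables (focal species sp01 lacks insertions < 100 MY)\n")

## Single-copy orthologs: 2000 groups, 300 with a 30% focal length
## reduction, 10% relative length noise.
ot <- gen_ortholog_table(2000, species, "sp01", n_reduced = 300,
                         effect = 0.3, noise_sd = 0.1, seed = seed + 10,
                         dir = out)
writeLines(ot$truth$planted_reduced_groups,
           file.path(out, "truth_reduced_groups.txt"))

## Pfam domain counts: 200 null families plus 5 planted 5-fold
## contractions in the focal species.
dc <- gen_domain_counts(205, species, "sp01",
                        planted = setNames(rep(0.2, 5),
                                           sprintf("dom%03d", 201:205)),
                        baseline_mean = 100, seed = seed + 11, dir = out)
writeLines(names(dc$truth$planted_shifted_domains),
           file.path(out, "truth_contracted_domains.txt"))

## Expression: 1500 genes, 4 tissues x 3 replicates, three co-expression
## modules (100/80/60 genes, within-correlation 0.7, 10 hubs each) and 50
## mantle-specific genes.
ge <- gen_expression(1500,
                     c(mantle = 3, striated_muscle = 3, gill = 3,
                       kidney = 3),
                     modules = data.frame(size = c(100, 80, 60), cor = 0.7),
                     hub_per_module = 10, specific = c(mantle = 50),
                     seed = seed + 12, dir = out)
truth <- ge$truth
write.table(data.frame(gene = names(truth$module_assignment),
                       module = truth$module_assignment),
            file.path(out, "truth_modules.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(truth$hub_genes, file.path(out, "truth_hubs.txt"))
writeLines(truth$tissue_specific_genes$mantle,
           file.path(out, "truth_mantle_specific.txt"))

## Pathways: 21 gene sets over the ortholog groups, one planted to overlap
## the 300 length-reduced groups at 50%.
pw <- gen_pathways(21, sprintf("og%05d", 1:2000),
                   enriched_pathway_overlap = 0.5,
                   target_set = ot$truth$planted_reduced_groups,
                   seed = seed + 13, dir = out)
writeLines(pw$truth$enriched_pathway,
           file.path(out, "truth_enriched_pathway.txt"))

cat("simulation complete; inputs and truths under", out, "\n")
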