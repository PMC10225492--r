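#!/usr/bin/env Rscript
# Stage 5: size-reducing genes and pathway enrichment. Single-copy
# ortholog lengths are standardized by each species' genic size
# (lambda = length / genic size); focal-species genes with lambda below
# the five-species comparator mean are size-reducing. The size-reducing
# set is then tested for pathway over-representation against the planted
# GMT annotation.

library(minigenomics)

simdir <- "results/simdata"
out <- "results"
focal <- "sp01"

orths <- read_ortholog_table(file.path(simdir, "orthologs.tsv"))
ptab <- read.delim(file.path(out, "partition_table.tsv"))
genic <- setNames(ptab$genic_size, ptab$species)

rel <- relative_lengths(orths, genic)
cls <- classify_size_shift(rel, focal)
write.table(cls, file.path(out, "size_shift_calls.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

reducing <- cls$group_id[cls$call == "size-reducing"]
increasing <- cls$group_id[cls$call == "size-increasing"]
cat(length(reducing), "size-reducing and", length(increasing),
    "size-increasing ortholog groups in", focal, "\n")
truth <- readLines(file.path(simdir, "truth_reduced_groups.txt"))
cat(sprintf("planted length reductions recalled: %d/%d (%.1f%%)\n",
            length(intersect(reducing, truth)), length(truth),
            100 * length(intersect(reducing, truth)) / length(truth)))

pathways <- read_gmt(file.path(simdir, "pathways.gmt"))
universe <- unique(orths$group_id)
enr <- hypergeom_enrich(reducing, pathways, universe, alpha = 0.05)
write.table(enr, file.path(out, "enrichment.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\ntop enriched pathways for the size-reducing set:\n")
print(head(enr[, c("pathway", "k", "K_path", "p_value", "q_value")], 5),
      row.names = FALSE)
planted_pw <- readLines(file.path(simdir, "truth_enriched_pathway.txt"))
cat("planted pathway", planted_pw, "ranked",
    match(planted_pw, enr$pathway), "of", nrow(enr), "\n")
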