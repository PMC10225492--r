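#!/usr/bin/env Rscript
# Stage 4: gene-family expansion/contraction screen. Each Pfam domain
# family's focal-species gene count is tested against the rounded mean of
# the five comparator species with a two-sided Fisher exact test; families
# at raw p < 0.05 are called contracted or expanded.

library(minigenomics)

simdir <- "results/simdata"
out <- "results"
focal <- "sp01"

mat <- read_domain_counts(file.path(simdir, "domain_counts.tsv"))
res <- family_shift_test(mat, focal, alpha = 0.05)
write.table(res, file.path(out, "family_shift.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

called <- res[res$direction != "none", ]
cat(nrow(called), "of", nrow(res), "domain families shifted at p < 0.05:\n")
print(called[, c("domain_id", "focal_count", "comparator_mean",
                 "direction", "p_value")], row.names = FALSE)

truth <- readLines(file.path(simdir, "truth_contracted_domains.txt"))
hit <- truth %in% called$domain_id[called$direction == "contracted"]
cat(sprintf("planted contractions recovered: %d/%d\n", sum(hit),
            length(truth)))
nulls <- setdiff(res$domain_id, truth)
fp <- mean(res$direction[match(nulls, res$domain_id)] != "none")
cat(sprintf("null families flagged: %.1f%% (alpha = 5%%)\n", 100 * fp))

# copy numbers per 1000 annotated genes, e.g. for plotting family panels
norm <- normalized_copy_number(mat, setNames(rep(20000, nrow(mat$counts)),
                                             rownames(mat$counts)))
write.table(data.frame(species = rownames(norm), norm, check.names = FALSE),
            file.path(out, "normalized_copy_number.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
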