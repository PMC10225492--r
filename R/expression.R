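# Expression summaries: TPM, cross-species ratios, cumulative family
# expression, tissue specificity, and a miniature weighted co-expression
# network with module detection, intramodular connectivity and hub ranking.

#' Construct an expression matrix container
#'
#' @param counts Gene x sample matrix of non-negative integer read counts
#'   with gene ids as rownames and sample ids as colnames.
#' @param gene_lengths Named vector of gene lengths in bp (> 0) covering
#'   every gene in `counts`.
#' @param samples data.frame with columns `sample_id`, `tissue`, `replicate`;
#'   one row per column of `counts`.
#' @return Object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(counts, gene_lengths, samples) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  if (any(counts < 0)) stop("counts must be non-negative")
  gene_lengths <- gene_lengths[rownames(counts)]
  if (anyNA(gene_lengths)) stop("gene_lengths must cover every gene")
  if (any(gene_lengths <= 0)) stop("gene lengths must be positive")
  need <- c("sample_id", "tissue", "replicate")
  stopifnot(all(need %in% names(samples)),
            identical(as.character(samples$sample_id), colnames(counts)))
  structure(list(counts = counts, gene_lengths = gene_lengths,
                 samples = as.data.frame(samples)),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("ExpressionMatrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples (", length(unique(x$samples$tissue)), "tissues )\n")
  invisible(x)
}

#' Transcripts per million
#'
#' Per sample, counts are divided by gene length (reads per base), and the
#' rates rescaled to sum to 1e6, so every non-degenerate column sums to one
#' million. All-zero samples yield all-zero columns and are flagged in the
#' `"zero_samples"` attribute (with a warning).
#'
#' @param expr An [expression_matrix()].
#' @return Object of class `TPMMatrix`: list with `values` (gene x sample
#'   TPM matrix) and `samples` (the sample sheet).
#' @export
tpm <- function(expr) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  rate <- expr$counts / expr$gene_lengths
  denom <- colSums(rate)
  zero <- denom == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero sample(s): ",
            paste(colnames(expr$counts)[zero], collapse = ", "))
    denom[zero] <- 1
  }
  values <- sweep(rate, 2, denom, "/") * 1e6
  structure(list(values = values, samples = expr$samples,
                 zero_samples = colnames(expr$counts)[zero]),
            class = "TPMMatrix")
}

#' @export
print.TPMMatrix <- function(x, ...) {
  cat("TPMMatrix:", nrow(x$values), "genes x", ncol(x$values), "samples\n")
  invisible(x)
}

# Mean TPM per gene across the replicates of one tissue.
tissue_mean_tpm <- function(tpm_obj, tissue) {
  stopifnot(inherits(tpm_obj, "TPMMatrix"))
  sel <- tpm_obj$samples$tissue == tissue
  if (!any(sel)) stop("tissue '", tissue, "' not present")
  rowMeans(tpm_obj$values[, sel, drop = FALSE])
}

#' Cross-species expression ratio in one tissue
#'
#' Per ortholog group: focal species' mean TPM (replicates averaged) divided
#' by the mean of the comparator species' mean TPMs. Groups whose comparator
#' mean is zero get `ratio = NA` (flagged, excluded from summaries).
#'
#' @param tpm_by_species Named list of `TPMMatrix`, one per species.
#' @param gene_map data.frame with columns `group_id`, `species`, `gene_id`
#'   mapping orthologs across species.
#' @param focal Focal species id.
#' @param comparators Comparator species ids.
#' @param tissue Tissue label present in every species.
#' @return data.frame with `group_id`, `focal_tpm`, `comparator_mean`,
#'   `ratio`.
#' @export
expression_ratio <- function(tpm_by_species, gene_map, focal, comparators,
                             tissue) {
  for (sp in c(focal, comparators)) {
    if (!sp %in% names(tpm_by_species)) stop("no TPM matrix for ", sp)
    if (!tissue %in% tpm_by_species[[sp]]$samples$tissue) {
      stop("tissue '", tissue, "' missing in species '", sp, "'")
    }
  }
  means <- lapply(tpm_by_species[c(focal, comparators)],
                  tissue_mean_tpm, tissue = tissue)
  groups <- unique(gene_map$group_id)
  rows <- lapply(groups, function(g) {
    gm <- gene_map[gene_map$group_id == g, , drop = FALSE]
    fg <- gm$gene_id[gm$species == focal]
    if (length(fg) != 1 || !fg %in% names(means[[focal]])) return(NULL)
    cv <- vapply(comparators, function(sp) {
      cg <- gm$gene_id[gm$species == sp]
      if (length(cg) == 1 && cg %in% names(means[[sp]]))
        means[[sp]][[cg]] else NA_real_
    }, numeric(1))
    cv <- cv[!is.na(cv)]
    if (length(cv) == 0) return(NULL)
    cm <- mean(cv)
    data.frame(group_id = g, focal_tpm = means[[focal]][[fg]],
               comparator_mean = cm,
               ratio = if (cm > 0) means[[focal]][[fg]] / cm else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cumulative family expression in one tissue
#'
#' Per gene family: the sum over member genes of their mean TPM across the
#' tissue's replicates (e.g. total mantle expression of a biomineralization
#' gene family). Families with no member present score 0 with a warning.
#'
#' @param tpm_obj A `TPMMatrix`.
#' @param families Named list of character vectors of gene ids.
#' @param tissue Tissue label.
#' @return Named numeric vector of per-family summed mean TPM.
#' @export
cumulative_family_tpm <- function(tpm_obj, families, tissue) {
  stopifnot(length(families) > 0)
  m <- tissue_mean_tpm(tpm_obj, tissue)
  vapply(names(families), function(fam) {
    members <- intersect(families[[fam]], names(m))
    if (length(members) == 0) {
      warning("family '", fam, "' has no gene present; cumulative TPM = 0")
      return(0)
    }
    sum(m[members])
  }, numeric(1))
}

#' Call tissue-specific genes
#'
#' A gene is specific to the target tissue when its mean TPM there is at
#' least `fold` times the largest mean TPM over every other tissue, and at
#' least `min_tpm`.
#'
#' @param tpm_obj A `TPMMatrix` with >= 2 tissues.
#' @param target_tissue Tissue label.
#' @param fold Fold-change threshold over the best other tissue (default 2).
#' @param min_tpm Minimum mean TPM in the target tissue (default 1).
#' @return Character vector of gene ids.
#' @export
tissue_specific_genes <- function(tpm_obj, target_tissue, fold = 2,
                                  min_tpm = 1) {
  stopifnot(inherits(tpm_obj, "TPMMatrix"))
  tissues <- unique(tpm_obj$samples$tissue)
  if (!target_tissue %in% tissues) {
    stop("unknown tissue '", target_tissue, "'")
  }
  if (length(tissues) < 2) stop("need at least 2 tissues")
  target <- tissue_mean_tpm(tpm_obj, target_tissue)
  other_max <- do.call(pmax, lapply(setdiff(tissues, target_tissue),
                                    tissue_mean_tpm, tpm_obj = tpm_obj))
  names(target)[target >= fold * other_max & target >= min_tpm]
}

#' Weighted co-expression adjacency
#'
#' Unsigned network on log2(TPM + 1): a_ij = |Pearson(g_i, g_j)|^beta with a
#' zero diagonal. Genes with zero variance across samples are removed (their
#' count is messaged).
#'
#' @param tpm_obj A `TPMMatrix` with >= 4 samples.
#' @param beta Soft-threshold power (default 6).
#' @return Gene x gene adjacency matrix in `[0, 1]`.
#' @export
coexpression_network <- function(tpm_obj, beta = 6) {
  stopifnot(inherits(tpm_obj, "TPMMatrix"), beta > 0)
  x <- log2(tpm_obj$values + 1)
  if (ncol(x) < 4) stop("need at least 4 samples to build a network")
  v <- apply(x, 1, stats::var)
  if (any(v == 0)) {
    message(sum(v == 0), " zero-variance gene(s) removed from the network")
    x <- x[v > 0, , drop = FALSE]
  }
  a <- abs(stats::cor(t(x)))^beta
  diag(a) <- 0
  a
}

#' Detect co-expression modules by static tree cut
#'
#' Average-linkage hierarchical clustering on the dissimilarity 1 - a;
#' the tree is cut at `cut_height` and clusters smaller than `min_size` are
#' pooled into an unassigned module (`module_id = "module_0"`).
#'
#' @param adjacency Symmetric gene x gene adjacency matrix.
#' @param cut_height Dissimilarity threshold for the static cut
#'   (default 0.99; with an unsigned power-6 adjacency, uncorrelated gene
#'   pairs sit near dissimilarity 1 and genuinely co-expressed pairs well
#'   below it, so the useful cut lies close to 1).
#' @param min_size Minimum module size (default 30).
#' @return List of `CoexpressionModule` objects (lists with `module_id` and
#'   `genes`), largest module first, the unassigned pool last (if any).
#' @export
detect_modules <- function(adjacency, cut_height = 0.99, min_size = 30) {
  stopifnot(is.matrix(adjacency), nrow(adjacency) == ncol(adjacency))
  if (max(abs(adjacency - t(adjacency))) > 1e-12) {
    stop("adjacency must be symmetric")
  }
  ord <- order(rownames(adjacency))  # gene-order invariance
  a <- adjacency[ord, ord, drop = FALSE]
  hc <- stats::hclust(stats::as.dist(1 - a), method = "average")
  cl <- stats::cutree(hc, h = cut_height)
  sizes <- table(cl)
  big <- names(sizes)[sizes >= min_size]
  big <- big[order(-sizes[big])]
  modules <- lapply(seq_along(big), function(i) {
    structure(list(module_id = paste0("module_", i),
                   genes = sort(names(cl)[cl == big[i]])),
              class = "CoexpressionModule")
  })
  small <- names(cl)[!cl %in% big]
  if (length(small) > 0) {
    modules[[length(modules) + 1L]] <-
      structure(list(module_id = "module_0", genes = sort(small)),
                class = "CoexpressionModule")
  }
  modules
}

#' @export
print.CoexpressionModule <- function(x, ...) {
  cat("CoexpressionModule", x$module_id, "-", length(x$genes), "genes\n")
  invisible(x)
}

#' Intramodular connectivity
#'
#' For each gene of a module, k_within is the sum of its adjacency weights to
#' the other module members.
#'
#' @param adjacency Gene x gene adjacency matrix.
#' @param module A `CoexpressionModule` whose genes are all in `adjacency`.
#' @return Named numeric vector of k_within values.
#' @export
intramodular_connectivity <- function(adjacency, module) {
  genes <- module$genes
  if (!all(genes %in% rownames(adjacency))) {
    stop("module contains genes absent from the adjacency matrix")
  }
  sub <- adjacency[genes, genes, drop = FALSE]
  diag(sub) <- 0
  rowSums(sub)
}

#' Top hub genes by intramodular connectivity
#'
#' Returns the `min(n_hubs, length(k_within) - 1)` genes with the largest
#' k_within; ties are broken by gene id ascending, so the ranking is
#' deterministic.
#'
#' @param k_within Named vector from [intramodular_connectivity()].
#' @param n_hubs Number of hubs to report (default 40).
#' @return Character vector of hub gene ids, highest connectivity first.
#' @export
top_hubs <- function(k_within, n_hubs = 40) {
  n <- min(n_hubs, length(k_within) - 1L)
  if (n <= 0) return(character())
  ord <- order(-k_within, names(k_within))
  names(k_within)[ord][seq_len(n)]
}

#' Enrichment of a gene set within a co-expression module
#'
#' Tests whether `gene_set` is over-represented among the module's genes by
#' delegating to [hypergeom_enrich()] with the module as query and the set
#' as a single pathway.
#'
#' @param module A `CoexpressionModule` with genes in `background`.
#' @param gene_set Character vector of genes (intersected with background).
#' @param background Character vector: the gene universe.
#' @return One-row `EnrichmentResult` data.frame.
#' @export
module_gene_set_enrichment <- function(module, gene_set, background) {
  if (!all(module$genes %in% background)) {
    stop("module genes must be a subset of the background")
  }
  hypergeom_enrich(module$genes,
                   stats::setNames(list(as.character(gene_set)),
                                   module$module_id),
                   background)
}
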