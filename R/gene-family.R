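# Gene-family (Pfam domain) counting and focal-vs-comparator
# expansion/contraction testing.

#' Build a domain-count matrix from gene-to-domain assignments
#'
#' Counts, per species and Pfam domain, the number of genes whose domain set
#' contains that domain. A gene carrying multiple copies of the same domain
#' contributes once (set semantics). Per-species totals are the number of
#' distinct domain-bearing genes.
#'
#' @param assignments data.frame with columns `gene_id`, `species`,
#'   `domain_id`; one row per (gene, domain) occurrence, duplicates allowed.
#' @return Object of class `DomainCountMatrix`: list with `counts`
#'   (species x domain integer matrix) and `totals` (named vector of
#'   domain-bearing gene counts per species).
#' @export
count_domains <- function(assignments) {
  need <- c("gene_id", "species", "domain_id")
  if (!all(need %in% names(assignments))) {
    stop("assignments must have columns: ", paste(need, collapse = ", "))
  }
  a <- unique(assignments[need])
  species <- sort(unique(a$species))
  domains <- sort(unique(a$domain_id))
  counts <- table(factor(a$species, levels = species),
                  factor(a$domain_id, levels = domains))
  counts <- matrix(as.integer(counts), nrow = length(species),
                   dimnames = list(species, domains))
  totals <- vapply(species, function(s) {
    length(unique(a$gene_id[a$species == s]))
  }, integer(1))
  domain_count_matrix(counts, totals)
}

#' Construct a DomainCountMatrix from a counts matrix and totals
#'
#' @param counts Species x domain matrix of non-negative integer gene counts.
#' @param totals Named vector of per-species total domain-bearing gene counts;
#'   every count must be <= its species total.
#' @return Object of class `DomainCountMatrix`.
#' @export
domain_count_matrix <- function(counts, totals) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  totals <- totals[rownames(counts)]
  if (anyNA(totals)) stop("totals must be named for every species in counts")
  if (any(counts < 0)) stop("domain counts must be non-negative")
  if (any(counts > totals[rep(seq_len(nrow(counts)), ncol(counts))])) {
    stop("a domain count exceeds its species' total gene count")
  }
  structure(list(counts = counts, totals = totals),
            class = "DomainCountMatrix")
}

#' @export
print.DomainCountMatrix <- function(x, ...) {
  cat("DomainCountMatrix:", nrow(x$counts), "species x",
      ncol(x$counts), "domains\n")
  invisible(x)
}

#' Test per-family expansion/contraction of a focal species
#'
#' For each domain family, the focal species' (count, total - count) is
#' compared against the comparator species' average count and total, rounded
#' to the nearest integer, in a 2x2 two-sided Fisher exact test. Families with
#' p below `alpha` are called expanded or contracted according to whether the
#' focal species is over- or under-represented; otherwise the direction is
#' `"none"`.
#'
#' @param matrix A `DomainCountMatrix`.
#' @param focal Focal species id (must be a row of the matrix).
#' @param alpha Significance level for calling a direction (default 0.05, raw
#'   p-values; see `adjust`).
#' @param comparator `"mean"` (default; arithmetic mean of comparator counts
#'   and totals, rounded) or `"pooled"` (summed comparator counts and totals).
#' @param adjust `"none"` (default) or `"BH"`; with `"BH"` the direction call
#'   uses Benjamini-Hochberg q-values instead of raw p.
#' @return data.frame sorted by p-value with columns `domain_id`,
#'   `focal_count`, `comparator_mean`, `direction`, `p_value` (and `q_value`).
#' @export
family_shift_test <- function(matrix, focal, alpha = 0.05,
                              comparator = c("mean", "pooled"),
                              adjust = c("none", "BH")) {
  stopifnot(inherits(matrix, "DomainCountMatrix"))
  comparator <- match.arg(comparator)
  adjust <- match.arg(adjust)
  counts <- matrix$counts
  if (!focal %in% rownames(counts)) {
    stop("focal species '", focal, "' not present in the count matrix")
  }
  others <- setdiff(rownames(counts), focal)
  if (length(others) < 2) stop("need at least 2 comparator species")
  t_f <- matrix$totals[[focal]]
  if (comparator == "mean") {
    c_cmp <- round(colMeans(counts[others, , drop = FALSE]))
    t_cmp <- round(mean(matrix$totals[others]))
  } else {
    c_cmp <- colSums(counts[others, , drop = FALSE])
    t_cmp <- sum(matrix$totals[others])
  }
  doms <- colnames(counts)
  p <- numeric(length(doms))
  for (j in seq_along(doms)) {
    tab <- matrix(c(counts[focal, j], t_f - counts[focal, j],
                    c_cmp[j], t_cmp - c_cmp[j]),
                  nrow = 2, byrow = TRUE)
    p[j] <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  }
  q <- stats::p.adjust(p, method = "BH")
  crit <- if (adjust == "BH") q else p
  rate_f <- counts[focal, ] / t_f
  rate_c <- c_cmp / t_cmp
  direction <- ifelse(crit >= alpha, "none",
                      ifelse(rate_f < rate_c, "contracted", "expanded"))
  res <- data.frame(domain_id = doms,
                    focal_count = counts[focal, ],
                    comparator_mean = colMeans(counts[others, , drop = FALSE]),
                    direction = direction,
                    p_value = p,
                    q_value = q,
                    stringsAsFactors = FALSE)
  res <- res[order(res$p_value, res$domain_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Normalized domain copy numbers per 1000 annotated genes
#'
#' @param matrix A `DomainCountMatrix`.
#' @param per Named vector of per-species total annotated gene counts (> 0);
#'   the normalization denominator (usually all annotated genes, not just
#'   domain-bearing ones).
#' @return Species x domain matrix of counts per 1000 annotated genes.
#' @export
normalized_copy_number <- function(matrix, per) {
  stopifnot(inherits(matrix, "DomainCountMatrix"))
  per <- per[rownames(matrix$counts)]
  if (anyNA(per)) stop("per must name every species in the matrix")
  if (any(per <= 0)) stop("annotated gene totals must be positive")
  1000 * matrix$counts / as.numeric(per)
}
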