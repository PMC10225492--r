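# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: per-base boolean marking instead of interval
# algebra, and log-factorial enumeration over the full hypergeometric
# support instead of stats::fisher.test / stats::phyper.

# Genic size by marking every genic base of every sequence.
oracle_genic_size <- function(ann) {
  total <- 0L
  for (sid in names(ann$seq_lengths)) {
    mask <- logical(ann$seq_lengths[[sid]])
    g <- ann$genes[ann$genes$seq_id == sid, , drop = FALSE]
    for (i in seq_len(nrow(g))) mask[g$start[i]:g$end[i]] <- TRUE
    total <- total + sum(mask)
  }
  total
}

# Two-sided Fisher exact p by enumerating every table with the observed
# margins and summing the probabilities not exceeding the observed one
# (with the classical 1 + 1e-7 relative guard against floating-point ties).
oracle_fisher_two_sided <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  row1 <- a + b; row2 <- c + d; col1 <- a + c; N <- row1 + row2
  xs <- max(0, col1 - row2):min(col1, row1)
  logp <- lchoose(row1, xs) + lchoose(row2, col1 - xs) - lchoose(N, col1)
  ps <- exp(logp)
  p_obs <- exp(lchoose(row1, a) + lchoose(row2, c) - lchoose(N, col1))
  sum(ps[ps <= p_obs * (1 + 1e-7)])
}

# Upper-tail hypergeometric P(X >= k) by term-by-term enumeration.
oracle_hypergeom_upper <- function(k, K, N, n) {
  xs <- k:min(K, n)
  if (length(xs) == 0 || k > min(K, n)) return(0)
  sum(exp(lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)))
}

# A random annotation allowing overlapping genes (the package generator
# plants non-overlapping genes, so oracle checks build their own).
random_overlapping_annotation <- function(genome_size, n_genes,
                                          max_gene_len = 5000) {
  starts <- sample.int(genome_size, n_genes, replace = TRUE)
  lens <- sample.int(max_gene_len, n_genes, replace = TRUE)
  ends <- pmin(starts + lens - 1L, genome_size)
  genome_annotation(
    "rand",
    c(chr1 = genome_size),
    data.frame(gene_id = sprintf("g%04d", seq_len(n_genes)),
               seq_id = "chr1", start = starts, end = ends,
               strand = sample(c("+", "-"), n_genes, replace = TRUE),
               stringsAsFactors = FALSE))
}

md5 <- function(path) unname(tools::md5sum(path))
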