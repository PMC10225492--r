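# Relative-gene-length statistic over single-copy ortholog tables,
# size-reducing/size-increasing gene calls, gene-length ratios, and
# hypergeometric gene-set over-representation.

#' Construct a single-copy ortholog table
#'
#' @param df data.frame with columns `group_id`, `species`, `gene_id`,
#'   `length` (gene length in bp, > 0); at most one gene per species per
#'   group.
#' @return Object of class `OrthologTable` (the validated data.frame with a
#'   `complete` flag column: TRUE when the group has a gene in every species).
#' @export
ortholog_table <- function(df) {
  need <- c("group_id", "species", "gene_id", "length")
  if (!all(need %in% names(df))) {
    stop("ortholog table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(df$length <= 0)) stop("gene lengths must be positive")
  if (anyDuplicated(df[c("group_id", "species")])) {
    stop("more than one gene per species per group: not single-copy")
  }
  species <- unique(df$species)
  n_per <- table(df$group_id)
  df$complete <- as.vector(n_per[df$group_id]) == length(species)
  structure(as.data.frame(df), class = c("OrthologTable", "data.frame"))
}

#' Relative gene lengths (lambda)
#'
#' Standardizes gene lengths for cross-species comparison as
#' lambda = gene length / genic-region size of the species, making species
#' with different genome compaction comparable. Groups missing a species are
#' flagged incomplete and excluded from downstream classification.
#'
#' @param orths An [ortholog_table()].
#' @param partitions Named list of `PartitionSummary` objects (or a named
#'   numeric vector of genic sizes), one per species in the table.
#' @return Object of class `RelativeLengthTable`: the ortholog table with a
#'   `lambda` column.
#' @export
relative_lengths <- function(orths, partitions) {
  stopifnot(inherits(orths, "OrthologTable"))
  genic <- if (is.numeric(partitions)) partitions else
    vapply(partitions, function(p) p$genic_size, numeric(1))
  missing_sp <- setdiff(unique(orths$species), names(genic))
  if (length(missing_sp) > 0) {
    stop("no genic size for species: ", paste(missing_sp, collapse = ", "))
  }
  if (any(genic[unique(orths$species)] <= 0)) {
    stop("genic sizes must be positive")
  }
  orths$lambda <- orths$length / as.numeric(genic[orths$species])
  structure(as.data.frame(orths),
            class = c("RelativeLengthTable", "OrthologTable", "data.frame"))
}

#' Classify size-reducing and size-increasing genes
#'
#' A complete single-copy group is size-reducing when the focal species'
#' relative length (lambda) is strictly below the mean lambda of the
#' comparator species, size-increasing when strictly above, and neutral on
#' ties. Incomplete groups are not classified.
#'
#' @param rel A [relative_lengths()] table.
#' @param focal Focal species id.
#' @param comparators Character vector of comparator species (>= 1).
#' @return data.frame with one row per complete group: `group_id`,
#'   `gene_id` (focal), `lambda_focal`, `comparator_mean`, `call` in
#'   {"size-reducing", "size-increasing", "neutral"}.
#' @export
classify_size_shift <- function(rel, focal,
                                comparators = setdiff(unique(rel$species),
                                                      focal)) {
  stopifnot(inherits(rel, "RelativeLengthTable"), length(comparators) >= 1)
  d <- rel[rel$complete, , drop = FALSE]
  foc <- d[d$species == focal, , drop = FALSE]
  cmp <- d[d$species %in% comparators, , drop = FALSE]
  cmp_mean <- tapply(cmp$lambda, cmp$group_id, mean)
  m <- cmp_mean[foc$group_id]
  call <- ifelse(foc$lambda < m, "size-reducing",
                 ifelse(foc$lambda > m, "size-increasing", "neutral"))
  out <- data.frame(group_id = foc$group_id,
                    gene_id = foc$gene_id,
                    lambda_focal = foc$lambda,
                    comparator_mean = as.numeric(m),
                    call = call,
                    stringsAsFactors = FALSE)
  out[order(out$group_id), , drop = FALSE]
}

#' Per-gene length ratio of a focal species to the comparator mean
#'
#' For a named gene set (e.g. bone-marker or biomineralization genes), the
#' ratio of the focal species' gene length to the mean length across
#' comparator species; ratios above 1 mark a relative length increase.
#' Genes missing in the focal species are skipped with a warning; missing
#' comparator entries are dropped from the mean and counted in a message.
#'
#' @param gene_map data.frame with columns `gene` (set member name),
#'   `species`, `length`.
#' @param focal Focal species id.
#' @param comparators Comparator species ids.
#' @return data.frame with `gene`, `focal_length`, `comparator_mean`, `ratio`.
#' @export
length_ratio <- function(gene_map, focal, comparators) {
  need <- c("gene", "species", "length")
  stopifnot(all(need %in% names(gene_map)), length(comparators) >= 1)
  genes <- unique(gene_map$gene)
  foc <- gene_map[gene_map$species == focal, , drop = FALSE]
  absent <- setdiff(genes, foc$gene)
  if (length(absent) > 0) {
    warning(length(absent), " gene(s) absent in focal species skipped: ",
            paste(utils::head(absent, 5), collapse = ", "))
    genes <- setdiff(genes, absent)
  }
  n_dropped <- 0L
  rows <- lapply(genes, function(g) {
    cl <- gene_map$length[gene_map$gene == g &
                            gene_map$species %in% comparators]
    n_dropped <<- n_dropped + (length(comparators) - length(cl))
    if (length(cl) == 0) return(NULL)
    fl <- foc$length[foc$gene == g][1]
    data.frame(gene = g, focal_length = fl, comparator_mean = mean(cl),
               ratio = fl / mean(cl), stringsAsFactors = FALSE)
  })
  if (n_dropped > 0) {
    message(n_dropped, " missing comparator entr",
            if (n_dropped == 1) "y" else "ies", " dropped from means")
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(gene = character(),
                                      focal_length = numeric(),
                                      comparator_mean = numeric(),
                                      ratio = numeric())
  rownames(out) <- NULL
  out
}

#' Hypergeometric over-representation of pathways in a query gene set
#'
#' One-sided enrichment: for each pathway, p = P(X >= k) where X is
#' hypergeometric with the pathway (intersected with the background) as
#' successes and the query as the draw. Benjamini-Hochberg q-values are
#' reported over all tested pathways.
#'
#' @param query Character vector of query genes; must be a subset of
#'   `background`.
#' @param pathways Named list of character vectors (e.g. from [read_gmt()]).
#' @param background Character vector: the gene universe.
#' @param alpha Significance level recorded alongside results (default 0.05).
#' @return data.frame of class `EnrichmentResult`, sorted by p-value, with
#'   columns `pathway`, `k` (overlap), `n` (query size), `K_path`
#'   (pathway size in background), `N` (background size), `p_value`,
#'   `q_value`, `significant` (p < alpha).
#' @export
hypergeom_enrich <- function(query, pathways, background, alpha = 0.05) {
  if (length(background) == 0) stop("empty background")
  background <- unique(background)
  query <- unique(query)
  if (!all(query %in% background)) {
    stop("query genes must be a subset of the background")
  }
  n <- length(query)
  N <- length(background)
  rows <- lapply(names(pathways), function(pw) {
    members <- intersect(unique(pathways[[pw]]), background)
    K <- length(members)
    k <- length(intersect(query, members))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = pw, k = k, n = n, K_path = K, N = N,
               p_value = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res$significant <- res$p_value < alpha
  res <- res[order(res$p_value, res$pathway), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("EnrichmentResult", "data.frame")
  res
}

#' Read gene sets from a GMT file
#'
#' @param path Path to a GMT file (one set per line: id, description,
#'   member genes, tab-separated).
#' @return Named list of character vectors; the description is kept in the
#'   `"description"` attribute of each element.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("GMT line with fewer than 3 fields: ", f[1])
    genes <- f[-(1:2)]
    attr(genes, "description") <- f[2]
    out[[f[1]]] <- genes
  }
  out
}

#' Write gene sets to a GMT file
#'
#' @param pathways Named list of character vectors.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(names(pathways), function(pw) {
    desc <- attr(pathways[[pw]], "description") %||% "na"
    paste(c(pw, desc, as.character(pathways[[pw]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
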