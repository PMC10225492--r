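# Synthetic-data generators. Every pipeline input (GFF3 annotations,
# RepeatMasker .out tables, ortholog tables, domain counts, expression
# counts, GMT pathways) can be generated with planted ground truth, so each
# downstream stage is testable at desk scale with known answers.

#' Generate a set of annotated genomes with controlled genic fractions
#'
#' Each species gets one chromosome of the requested size carrying `n_genes`
#' non-overlapping genes whose total span equals `round(genic_fraction *
#' genome_size)` exactly: gene lengths are a uniform random composition of
#' the genic target, and the intergenic remainder is randomly split into the
#' gaps, so the realised genic fraction matches the request to within
#' rounding.
#'
#' @param n_species Number of species.
#' @param genome_sizes Genome size(s) in bp (recycled across species).
#' @param genic_fraction Target genic fraction(s) in (0, 1) (recycled).
#' @param n_genes Genes per species.
#' @param seed Integer seed; the same seed reproduces the set exactly.
#' @param dir Optional directory: when given, per-species GFF3 and
#'   sequence-length TSV files are written there.
#' @return List with `annotations` (list of [genome_annotation()]) and
#'   `files` (data.frame of written paths, or NULL).
#' @export
gen_genome_set <- function(n_species, genome_sizes, genic_fraction, n_genes,
                           seed, dir = NULL) {
  stopifnot(n_species >= 1, n_genes >= 1,
            all(genic_fraction > 0), all(genic_fraction < 1))
  genome_sizes <- rep_len(genome_sizes, n_species)
  genic_fraction <- rep_len(genic_fraction, n_species)
  with_seed(seed, {
    anns <- vector("list", n_species)
    files <- list()
    for (i in seq_len(n_species)) {
      sp <- sprintf("sp%02d", i)
      G <- genome_sizes[i]
      target <- round(genic_fraction[i] * G)
      if (target < n_genes || target > G) {
        stop("infeasible packing for ", sp, ": cannot fit ", n_genes,
             " non-overlapping genes totalling ", target, " bp in ", G, " bp")
      }
      # random composition of `target` into n_genes parts >= 1
      lens <- if (n_genes == 1) target else
        diff(c(0, sort(sample.int(target - 1L, n_genes - 1L)), target))
      # random composition of the intergenic remainder into n_genes + 1 gaps >= 0
      inter <- G - target
      gaps <- if (inter == 0) rep(0, n_genes + 1L) else
        diff(c(0, sort(sample.int(inter + n_genes, n_genes)),
               inter + n_genes + 1L)) - 1L
      starts <- cumsum(gaps[seq_len(n_genes)]) +
        cumsum(c(0, lens[-n_genes])) + 1
      genes <- data.frame(
        gene_id = sprintf("%s_g%05d", sp, seq_len(n_genes)),
        seq_id = "chr1",
        start = starts,
        end = starts + lens - 1,
        strand = sample(c("+", "-"), n_genes, replace = TRUE),
        stringsAsFactors = FALSE)
      anns[[i]] <- genome_annotation(sp, c(chr1 = G), genes)
      if (!is.null(dir)) {
        gff <- file.path(dir, paste0(sp, ".gff3"))
        lenf <- file.path(dir, paste0(sp, ".seqlen.tsv"))
        write_annotation(anns[[i]], gff, lenf)
        files[[sp]] <- data.frame(species = sp, gff3 = gff, seqlen = lenf,
                                  stringsAsFactors = FALSE)
      }
    }
    list(annotations = anns,
         files = if (length(files) > 0) do.call(rbind, files) else NULL)
  })
}

#' Write a genome annotation as GFF3 plus a sequence-length TSV
#'
#' @param ann A [genome_annotation()].
#' @param gff3_path Output GFF3 path (1-based inclusive coordinates).
#' @param seqlen_path Output two-column `<seq_id>\t<length>` TSV path.
#' @return `gff3_path`, invisibly.
#' @export
write_annotation <- function(ann, gff3_path, seqlen_path) {
  stopifnot(inherits(ann, "GenomeAnnotation"))
  lines <- "##gff-version 3"
  if (nrow(ann$genes) > 0) {
    g <- ann$genes
    lines <- c(lines, sprintf("%s\tminigenomics\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                              g$seq_id, as.integer(g$start),
                              as.integer(g$end), g$strand, g$gene_id))
  }
  writeLines(lines, gff3_path)
  writeLines(sprintf("%s\t%d", names(ann$seq_lengths),
                     as.integer(ann$seq_lengths)), seqlen_path)
  invisible(gff3_path)
}

#' Generate TE copies diverged under Jukes-Cantor at known ages
#'
#' For each age T, copies diverge from their family consensus by the total
#' distance K = 2 r T (both lineages' substitutions collapsed onto the copy,
#' matching how copies are compared against a consensus). Each site
#' mismatches independently with the exact Jukes-Cantor probability
#' p = 0.75 (1 - exp(-4K/3)), and the observed divergence d is the realised
#' mismatch proportion.
#'
#' @param ages_my Vector of true insertion ages in million years (>= 0).
#' @param copies_per_age Copies to generate per age.
#' @param copy_length Copy length in bp.
#' @param rate_r Substitution rate, substitutions/site/MY (> 0).
#' @param seed Integer seed.
#' @param dir Optional directory; when given, a RepeatMasker-style `.out`
#'   file is written there.
#' @return List with `records` (TE copy data.frame), `truth`
#'   (`te_true_ages`: named vector copy id -> age), and `out_path`.
#' @export
gen_te_copies <- function(ages_my, copies_per_age, copy_length, rate_r,
                          seed, dir = NULL) {
  stopifnot(all(ages_my >= 0), rate_r > 0, copies_per_age >= 1,
            copy_length >= 1)
  p_exp <- 0.75 * (1 - exp(-8 * rate_r * ages_my / 3))
  if (any(!is.finite(p_exp)) || any(p_exp >= 0.75 - 1e-9)) {
    stop("parameters imply divergence saturation (expected d >= 0.75); ",
         "insertion times would be unidentifiable")
  }
  with_seed(seed, {
    rows <- list()
    for (j in seq_along(ages_my)) {
      mism <- stats::rbinom(copies_per_age, copy_length, p_exp[j])
      cls <- rep_len(te_classes, copies_per_age)
      rows[[j]] <- data.frame(
        age = ages_my[j],
        te_class = cls,
        family = sprintf("%s-age%g", cls, ages_my[j]),
        divergence_d = mism / copy_length,
        stringsAsFactors = FALSE)
    }
    rec <- do.call(rbind, rows)
    n <- nrow(rec)
    starts <- (seq_len(n) - 1L) * (copy_length + 100L) + 1L
    records <- data.frame(
      copy_id = sprintf("te_%06d", seq_len(n)),
      te_class = rec$te_class,
      family = rec$family,
      seq_id = "chr1",
      start = starts,
      end = starts + copy_length - 1L,
      divergence_d = rec$divergence_d,
      compartment = "unassigned",
      stringsAsFactors = FALSE)
    truth <- list(te_true_ages = stats::setNames(rec$age, records$copy_id))
    out_path <- NULL
    if (!is.null(dir)) {
      out_path <- file.path(dir, "te_copies.out")
      write_repeatmasker_out(records, out_path)
    }
    list(records = records, truth = truth, out_path = out_path)
  })
}

#' Write TE copy records as a RepeatMasker-style .out file
#'
#' Classic 15-column whitespace-aligned layout with the standard two header
#' lines plus a blank line; the divergence column is written as a percentage
#' with 4 decimals.
#'
#' @param records TE copy data.frame (see [gen_te_copies()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repeatmasker_out <- function(records, path) {
  header <- c(
    "   SW   perc perc perc  query     position in query              matching       repeat          position in repeat",
    "score   div. del. ins.  sequence  begin  end          (left)    repeat         class/family   begin  end  (left)     ID",
    "")
  class_family <- ifelse(records$te_class == "other", "Unknown",
                         paste0(records$te_class, "/", records$family))
  body <- sprintf(
    "%5d %8.4f %4.1f %4.1f  %-10s %8d %8d (%d) + %-14s %-14s %5d %5d (%d) %s",
    1000L, records$divergence_d * 100, 0, 0, records$seq_id,
    as.integer(records$start), as.integer(records$end), 0L,
    records$family, class_family,
    1L, as.integer(records$end - records$start + 1), 0L, records$copy_id)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Generate a single-copy ortholog table with planted length reductions
#'
#' Every group shares a lognormal baseline gene length across species;
#' per-(group, species) lengths get multiplicative lognormal noise with mean
#' 1 and relative SD `noise_sd`, and the planted groups' focal-species
#' lengths are additionally scaled by `(1 - effect)`. Lengths are rounded to
#' whole bp.
#'
#' @param n_groups Number of ortholog groups.
#' @param species Character vector of species ids.
#' @param focal Focal species id (member of `species`).
#' @param n_reduced Number of groups with a planted focal-length reduction.
#' @param effect Proportional reduction in (0, 1).
#' @param noise_sd Relative SD of the multiplicative length noise (0 = none).
#' @param seed Integer seed.
#' @param dir Optional directory; writes `orthologs.tsv` (long format).
#' @return List with `table` (an [ortholog_table()]), `truth`
#'   (`planted_reduced_groups`: character vector), and `path`.
#' @export
gen_ortholog_table <- function(n_groups, species, focal, n_reduced,
                               effect, noise_sd, seed, dir = NULL) {
  stopifnot(n_reduced <= n_groups, effect > 0, effect < 1,
            focal %in% species, noise_sd >= 0)
  with_seed(seed, {
    groups <- sprintf("og%05d", seq_len(n_groups))
    baseline <- pmax(200, round(stats::rlnorm(n_groups, meanlog = 8,
                                              sdlog = 0.6)))
    planted <- sort(sample(groups, n_reduced))
    sdlog <- sqrt(log(1 + noise_sd^2))
    df <- do.call(rbind, lapply(species, function(sp) {
      noise <- if (noise_sd == 0) rep(1, n_groups) else
        stats::rlnorm(n_groups, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      len <- baseline * noise
      if (sp == focal) len[groups %in% planted] <-
          len[groups %in% planted] * (1 - effect)
      data.frame(group_id = groups, species = sp,
                 gene_id = sprintf("%s_%s", sp, groups),
                 length = as.integer(pmax(1, round(len))),
                 stringsAsFactors = FALSE)
    }))
    tab <- ortholog_table(df)
    path <- NULL
    if (!is.null(dir)) {
      path <- file.path(dir, "orthologs.tsv")
      write_tsv_plain(tab[c("group_id", "species", "gene_id", "length")],
                      path)
    }
    list(table = tab, truth = list(planted_reduced_groups = planted),
         path = path)
  })
}

#' Read a long-format ortholog TSV
#'
#' @param path TSV with columns `group_id`, `species`, `gene_id`, `length`.
#' @return An [ortholog_table()].
#' @export
read_ortholog_table <- function(path) {
  ortholog_table(read_tsv_plain(path))
}

#' Generate a domain-count matrix with planted contractions/expansions
#'
#' Each domain gets a gamma-distributed mean shared by all species (so null
#' domains follow one common count distribution), and per-species counts are
#' Poisson draws around it; planted domains have the focal species' mean
#' multiplied by the stated fold change.
#'
#' @param n_domains Number of domain families.
#' @param species Character vector of species ids.
#' @param focal Focal species id.
#' @param planted Named numeric vector, domain index name -> fold change
#'   (> 0; < 1 plants a contraction, > 1 an expansion). Names must be among
#'   the generated domain ids `dom001`, `dom002`, ... or it may be given as
#'   an unnamed vector of folds applied to the first domains.
#' @param baseline_mean Mean per-domain gene count (default 100).
#' @param total_genes Per-species total domain-bearing gene count
#'   (default 20000).
#' @param seed Integer seed.
#' @param dir Optional directory; writes `domain_counts.tsv`.
#' @return List with `matrix` (a `DomainCountMatrix`), `truth`
#'   (`planted_shifted_domains`: named character vector domain ->
#'   "contracted"/"expanded"), and `path`.
#' @export
gen_domain_counts <- function(n_domains, species, focal, planted = numeric(),
                              baseline_mean = 100, total_genes = 20000,
                              seed = 1, dir = NULL) {
  stopifnot(all(planted > 0), baseline_mean >= 1, focal %in% species)
  domains <- sprintf("dom%03d", seq_len(n_domains))
  if (length(planted) > 0 && is.null(names(planted))) {
    names(planted) <- domains[seq_along(planted)]
  }
  stopifnot(all(names(planted) %in% domains))
  with_seed(seed, {
    mu <- stats::rgamma(n_domains, shape = 10, rate = 10 / baseline_mean)
    names(mu) <- domains
    counts <- matrix(0L, nrow = length(species), ncol = n_domains,
                     dimnames = list(species, domains))
    for (sp in species) {
      m <- mu
      if (sp == focal) m[names(planted)] <- m[names(planted)] * planted
      counts[sp, ] <- stats::rpois(n_domains, m)
    }
    totals <- stats::setNames(rep(as.integer(total_genes), length(species)),
                              species)
    mat <- domain_count_matrix(counts, totals)
    truth <- list(planted_shifted_domains =
                    if (length(planted) > 0)
                      stats::setNames(ifelse(planted < 1, "contracted",
                                             "expanded"), names(planted))
                    else stats::setNames(character(), character()))
    path <- NULL
    if (!is.null(dir)) {
      path <- file.path(dir, "domain_counts.tsv")
      write_domain_counts(mat, path)
    }
    list(matrix = mat, truth = truth, path = path)
  })
}

#' Write / read a DomainCountMatrix TSV
#'
#' Wide layout: a `#totals` comment line carrying the per-species
#' domain-bearing gene totals, then one row per domain with one column per
#' species.
#'
#' @param matrix A `DomainCountMatrix`.
#' @param path File path.
#' @return `path` invisibly (writer); a `DomainCountMatrix` (reader).
#' @export
write_domain_counts <- function(matrix, path) {
  stopifnot(inherits(matrix, "DomainCountMatrix"))
  sp <- rownames(matrix$counts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#totals\t",
                    paste(sprintf("%s=%d", sp, as.integer(matrix$totals)),
                          collapse = "\t")), con)
  df <- data.frame(domain_id = colnames(matrix$counts),
                   t(matrix$counts), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n")
  invisible(path)
}

#' @rdname write_domain_counts
#' @export
read_domain_counts <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#totals\t")) {
    stop("missing #totals header line in ", basename(path))
  }
  kv <- strsplit(sub("^#totals\t", "", first), "\t")[[1]]
  totals <- stats::setNames(as.integer(sub(".*=", "", kv)),
                            sub("=.*", "", kv))
  df <- utils::read.delim(path, skip = 1, check.names = FALSE,
                          stringsAsFactors = FALSE)
  counts <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(counts) <- df$domain_id
  storage.mode(counts) <- "integer"
  domain_count_matrix(counts, totals)
}

#' Generate an expression count matrix with planted modules, hubs and
#' tissue-specific genes
#'
#' Gene expression is built on a log2 scale: module genes load on a shared
#' per-module latent factor (loading `sqrt(cor)` for ordinary members, so
#' ordinary pairs have the stated expected correlation; loading 1 for hubs,
#' which therefore track the module program exactly and correlate more
#' strongly with every member), background genes are independent noise, and
#' tissue-specific genes get a +5 log2 boost in their tissue over a low
#' baseline. Module factors are drawn mutually orthogonal across samples so
#' the planted programs are distinct by construction. Counts are Poisson
#' draws around `2^z`, or `round(2^z)` when `poisson = FALSE`.
#'
#' @param n_genes Total genes (>= sum of module sizes + specific genes).
#' @param samples Named integer vector, tissue -> number of replicates.
#' @param modules data.frame with columns `size` and `cor` (expected
#'   within-module correlation in (0, 1)), one row per planted module.
#' @param hub_per_module Number of designated hub genes per module.
#' @param specific Named integer vector, tissue -> number of planted
#'   tissue-specific genes (drawn from background genes).
#' @param seed Integer seed.
#' @param poisson Draw Poisson counts (default TRUE); FALSE gives
#'   deterministic rounded means, useful for limit checks.
#' @param dir Optional directory; writes `expression_counts.tsv` with
#'   `tissue:replicate` sample headers.
#' @return List with `expr` (an [expression_matrix()]), `truth`
#'   (`module_assignment` named vector, `hub_genes`, `tissue_specific_genes`
#'   named list), and `path`.
#' @export
gen_expression <- function(n_genes, samples, modules, hub_per_module = 0,
                           specific = integer(), seed = 1, poisson = TRUE,
                           dir = NULL) {
  modules <- as.data.frame(modules)
  stopifnot(all(c("size", "cor") %in% names(modules)),
            all(modules$cor > 0), all(modules$cor < 1),
            sum(modules$size) + sum(specific) <= n_genes,
            all(hub_per_module <= modules$size))
  tissues <- names(samples)
  stopifnot(!is.null(tissues), all(samples >= 1))
  with_seed(seed, {
    sample_df <- do.call(rbind, lapply(tissues, function(t) {
      data.frame(sample_id = sprintf("%s:%d", t, seq_len(samples[[t]])),
                 tissue = t, replicate = seq_len(samples[[t]]),
                 stringsAsFactors = FALSE)
    }))
    n_samp <- nrow(sample_df)
    n_mod <- nrow(modules)
    if (n_mod > n_samp) stop("cannot plant more modules than samples")
    genes <- sprintf("g%05d", seq_len(n_genes))
    baseline <- stats::runif(n_genes, 6, 9)
    amp <- 2.5
    z <- matrix(baseline, n_genes, n_samp)
    # orthonormal module programs, rescaled to unit sample SD; drawn in the
    # orthogonal complement of the tissue-indicator subspace so planted
    # modules stay distinct from each other and from tissue effects
    factors <- if (n_mod > 0) {
      tis_ind <- stats::model.matrix(~ 0 + factor(sample_df$tissue))
      proj <- diag(n_samp) -
        tis_ind %*% solve(crossprod(tis_ind)) %*% t(tis_ind)
      if (n_mod > n_samp - ncol(tis_ind)) {
        stop("cannot plant more modules than residual degrees of freedom ",
             "(samples minus tissues)")
      }
      raw <- proj %*% matrix(stats::rnorm(n_samp * n_mod), n_samp, n_mod)
      qr.Q(qr(raw)) * sqrt(n_samp - 1)
    } else NULL
    module_assignment <- stats::setNames(character(), character())
    hub_genes <- character()
    idx <- 1L
    for (m in seq_len(n_mod)) {
      size <- modules$size[m]
      a <- rep(sqrt(modules$cor[m]), size)
      if (hub_per_module > 0) a[seq_len(hub_per_module)] <- 1
      rows <- idx:(idx + size - 1L)
      eps <- matrix(stats::rnorm(size * n_samp), size, n_samp)
      z[rows, ] <- z[rows, ] +
        amp * (a %o% factors[, m] + sqrt(1 - a^2) * eps)
      mid <- paste0("module_", m)
      module_assignment <- c(module_assignment,
                             stats::setNames(rep(mid, size), genes[rows]))
      if (hub_per_module > 0) {
        hub_genes <- c(hub_genes, genes[rows[seq_len(hub_per_module)]])
      }
      idx <- idx + size
    }
    tissue_specific <- stats::setNames(vector("list", length(specific)),
                                       names(specific))
    for (t in names(specific)) {
      rows <- idx:(idx + specific[[t]] - 1L)
      z[rows, ] <- 2 +
        matrix(stats::rnorm(length(rows) * n_samp, sd = 0.5),
               length(rows), n_samp)
      z[rows, sample_df$tissue == t] <- z[rows, sample_df$tissue == t] + 5
      tissue_specific[[t]] <- genes[rows]
      idx <- idx + specific[[t]]
    }
    if (idx <= n_genes) {
      rows <- idx:n_genes
      z[rows, ] <- z[rows, ] +
        amp * matrix(stats::rnorm(length(rows) * n_samp),
                     length(rows), n_samp)
    }
    mu <- 2^z
    counts <- if (poisson) {
      matrix(stats::rpois(length(mu), mu), n_genes, n_samp)
    } else {
      round(mu)
    }
    dimnames(counts) <- list(genes, sample_df$sample_id)
    lengths <- stats::setNames(
      pmax(200, round(stats::rlnorm(n_genes, log(1500), 0.4))), genes)
    expr <- expression_matrix(counts, lengths, sample_df)
    path <- NULL
    if (!is.null(dir)) {
      path <- file.path(dir, "expression_counts.tsv")
      write_expression(expr, path)
    }
    list(expr = expr,
         truth = list(module_assignment = module_assignment,
                      hub_genes = hub_genes,
                      tissue_specific_genes = tissue_specific),
         path = path)
  })
}

#' Write / read an expression count TSV
#'
#' Layout: columns `gene`, `length`, then one column per sample with
#' `tissue:replicate` headers.
#'
#' @param expr An [expression_matrix()].
#' @param path File path.
#' @return `path` invisibly (writer); an `ExpressionMatrix` (reader).
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  df <- data.frame(gene = rownames(expr$counts),
                   length = as.integer(expr$gene_lengths),
                   expr$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_plain(df, path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  df <- read_tsv_plain(path)
  counts <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(counts) <- df$gene
  storage.mode(counts) <- "integer"
  sample_ids <- colnames(counts)
  parts <- strsplit(sample_ids, ":", fixed = TRUE)
  samples <- data.frame(sample_id = sample_ids,
                        tissue = vapply(parts, `[`, "", 1),
                        replicate = as.integer(vapply(parts, `[`, "", 2)),
                        stringsAsFactors = FALSE)
  expression_matrix(counts, stats::setNames(df$length, df$gene), samples)
}

#' Generate pathway annotations with one planted enriched pathway
#'
#' One pathway (recorded in the truth) is built to overlap `target_set` at
#' the stated proportion of its size (the remainder drawn from the rest of
#' the universe); the other pathways sample the universe uniformly.
#'
#' @param n_pathways Total number of pathways, including the planted one.
#' @param genes Character vector: the gene universe.
#' @param enriched_pathway_overlap Proportion in `[0, 1]` of the planted
#'   pathway drawn from `target_set`.
#' @param target_set Character vector of target genes (subset of `genes`).
#' @param null_size_range Size range for null pathways (default scaled to
#'   the target set: 50%-150% of its size).
#' @param seed Integer seed.
#' @param dir Optional directory; writes `pathways.gmt`.
#' @return List with `pathways` (named list), `truth`
#'   (`enriched_pathway`: pathway id), and `path`.
#' @export
gen_pathways <- function(n_pathways, genes, enriched_pathway_overlap,
                         target_set, null_size_range = NULL, seed = 1,
                         dir = NULL) {
  stopifnot(n_pathways >= 1, enriched_pathway_overlap >= 0,
            enriched_pathway_overlap <= 1, all(target_set %in% genes))
  size <- length(target_set)
  null_size_range <- null_size_range %||%
    c(max(5, round(0.5 * size)), round(1.5 * size))
  with_seed(seed, {
    ids <- sprintf("pw%03d", seq_len(n_pathways))
    planted_id <- ids[1]
    n_in <- round(enriched_pathway_overlap * size)
    complement <- setdiff(genes, target_set)
    planted <- c(sample(target_set, n_in),
                 sample(complement, size - n_in))
    pathways <- stats::setNames(vector("list", n_pathways), ids)
    pathways[[planted_id]] <- sort(planted)
    for (i in seq_len(n_pathways)[-1]) {
      sz <- sample(seq(null_size_range[1], null_size_range[2]), 1)
      pathways[[ids[i]]] <- sort(sample(genes, sz))
    }
    path <- NULL
    if (!is.null(dir)) {
      path <- file.path(dir, "pathways.gmt")
      write_gmt(pathways, path)
    }
    list(pathways = pathways,
         truth = list(enriched_pathway = planted_id),
         path = path)
  })
}
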