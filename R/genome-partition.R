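#' Genome annotation container
#'
#' Bundles a species label, per-sequence lengths and gene intervals
#' (1-based, inclusive, GFF3 convention). This is the unit the
#' genic/intergenic partition operates on.
#'
#' @param species Species identifier.
#' @param seq_lengths Named numeric vector, sequence id -> length in bp.
#' @param genes data.frame with columns `gene_id`, `seq_id`, `start`, `end`,
#'   `strand`. May have zero rows.
#' @return An object of class `GenomeAnnotation`.
#' @export
genome_annotation <- function(species, seq_lengths, genes) {
  stopifnot(is.character(species), length(species) == 1L)
  if (is.null(names(seq_lengths)) || anyNA(names(seq_lengths))) {
    stop("seq_lengths must be a named vector of sequence lengths")
  }
  if (nrow(genes) > 0) {
    need <- c("gene_id", "seq_id", "start", "end", "strand")
    if (!all(need %in% names(genes))) {
      stop("genes must have columns: ", paste(need, collapse = ", "))
    }
    bad_seq <- setdiff(genes$seq_id, names(seq_lengths))
    if (length(bad_seq) > 0) {
      off <- genes$gene_id[match(bad_seq[1], genes$seq_id)]
      stop("gene '", off, "' lies on unknown sequence '", bad_seq[1], "'")
    }
    if (any(genes$end < genes$start)) {
      off <- genes$gene_id[which(genes$end < genes$start)[1]]
      stop("gene '", off, "' has end < start")
    }
    if (any(genes$start < 1) ||
        any(genes$end > seq_lengths[genes$seq_id])) {
      off <- genes$gene_id[which(genes$start < 1 |
                                   genes$end > seq_lengths[genes$seq_id])[1]]
      stop("gene '", off, "' extends beyond its sequence bounds")
    }
    if (anyDuplicated(genes$gene_id)) {
      stop("duplicate gene ids in annotation for species '", species, "'")
    }
  }
  structure(list(species = species,
                 seq_lengths = seq_lengths,
                 genes = as.data.frame(genes)),
            class = "GenomeAnnotation")
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  cat("GenomeAnnotation:", x$species, "-",
      length(x$seq_lengths), "sequence(s),",
      format(sum(x$seq_lengths), big.mark = ","), "bp,",
      nrow(x$genes), "gene(s)\n")
  invisible(x)
}

#' Read a genome annotation from GFF3 plus sequence lengths
#'
#' Loads records of type `gene` from a GFF3 file (coordinates kept 1-based,
#' inclusive) together with per-sequence lengths from either a FASTA file or
#' a two-column `<seq_id>\t<length>` TSV.
#'
#' @param gff3_path Path to a GFF3 file.
#' @param seqlen_source Path to a FASTA file (`.fa`, `.fasta`, `.fna`) or a
#'   two-column TSV of sequence lengths.
#' @param species Species label; defaults to the GFF3 file name sans extension.
#' @return A [genome_annotation()] object.
#' @export
read_annotation <- function(gff3_path, seqlen_source, species = NULL) {
  species <- species %||% sub("\\.gff3?$", "", basename(gff3_path))
  seq_lengths <- read_seq_lengths(seqlen_source)
  lines <- readLines(gff3_path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  genes <- list()
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 9L) {
      stop("malformed GFF3 line ", i, " in ", basename(gff3_path),
           ": expected 9 tab-separated fields, got ", length(f))
    }
    if (f[3] != "gene") next
    start <- suppressWarnings(as.integer(f[4]))
    end <- suppressWarnings(as.integer(f[5]))
    if (is.na(start) || is.na(end)) {
      stop("malformed GFF3 line ", i, ": non-integer coordinates")
    }
    id <- sub(".*ID=([^;]+).*", "\\1", f[9])
    if (identical(id, f[9])) id <- paste0("gene_", length(genes) + 1L)
    genes[[length(genes) + 1L]] <-
      data.frame(gene_id = id, seq_id = f[1], start = start, end = end,
                 strand = f[7], stringsAsFactors = FALSE)
  }
  genes <- if (length(genes) > 0) do.call(rbind, genes) else
    data.frame(gene_id = character(), seq_id = character(),
               start = integer(), end = integer(), strand = character())
  genome_annotation(species, seq_lengths, genes)
}

read_seq_lengths <- function(seqlen_source) {
  if (grepl("\\.(fa|fasta|fna)$", seqlen_source, ignore.case = TRUE)) {
    lens <- Biostrings::fasta.seqlengths(seqlen_source)
    names(lens) <- sub("\\s.*", "", names(lens))
    return(lens)
  }
  df <- utils::read.delim(seqlen_source, header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("sequence-length TSV must have two columns")
  stats::setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}

#' Partition a genome into genic and intergenic regions
#'
#' The genic region is the strand-agnostic union of annotated gene spans
#' (overlapping and bookended intervals merged); the intergenic region is the
#' remainder of the assembly, so `genic_size + intergenic_size` equals the
#' genome size exactly.
#'
#' @param ann A [genome_annotation()] object.
#' @return An object of class `PartitionSummary`: a list with `species`,
#'   `genome_size`, `genic_size`, `intergenic_size` and
#'   `intergenic_genic_ratio` (NA when genic_size is 0).
#' @export
partition <- function(ann) {
  stopifnot(inherits(ann, "GenomeAnnotation"))
  genome_size <- as.numeric(sum(ann$seq_lengths))
  genic <- 0
  if (nrow(ann$genes) > 0) {
    for (sid in unique(ann$genes$seq_id)) {
      g <- ann$genes[ann$genes$seq_id == sid, , drop = FALSE]
      ir <- IRanges::reduce(IRanges::IRanges(start = g$start, end = g$end))
      genic <- genic + sum(IRanges::width(ir))
    }
  }
  structure(list(species = ann$species,
                 genome_size = genome_size,
                 genic_size = genic,
                 intergenic_size = genome_size - genic,
                 intergenic_genic_ratio =
                   if (genic > 0) (genome_size - genic) / genic else NA_real_),
            class = "PartitionSummary")
}

#' @export
print.PartitionSummary <- function(x, ...) {
  cat(sprintf("PartitionSummary [%s]: genome %s bp, genic %s bp, intergenic %s bp (ratio %.3f)\n",
              x$species, format(x$genome_size, big.mark = ","),
              format(x$genic_size, big.mark = ","),
              format(x$intergenic_size, big.mark = ","),
              x$intergenic_genic_ratio))
  invisible(x)
}

#' @export
as.data.frame.PartitionSummary <- function(x, ...) {
  data.frame(species = x$species, genome_size = x$genome_size,
             genic_size = x$genic_size, intergenic_size = x$intergenic_size,
             ratio = x$intergenic_genic_ratio, stringsAsFactors = FALSE)
}

#' Write a cross-species partition table as TSV
#'
#' Fixed column order: species, genome_size, genic_size, intergenic_size,
#' ratio.
#'
#' @param summaries List of `PartitionSummary` objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_partition_table <- function(summaries, path) {
  tab <- do.call(rbind, lapply(summaries, as.data.frame))
  write_tsv_plain(tab, path)
}

#' Genome size from k-mer statistics
#'
#' Estimates genome size as total k-mer count divided by k-mer depth
#' (sequencing coverage at the k-mer level).
#'
#' @param kmer_count Total number of k-mers observed.
#' @param kmer_depth Modal k-mer coverage; must be positive.
#' @return Estimated genome size in bp.
#' @export
kmer_genome_size <- function(kmer_count, kmer_depth) {
  if (any(kmer_depth <= 0)) stop("kmer_depth must be positive")
  kmer_count / kmer_depth
}

#' Pearson correlation with explicit degenerate-input errors
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Pearson product-moment correlation coefficient.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  stats::cor(x, y, method = "pearson")
}

#' Cross-species partition comparison
#'
#' Tabulates per-species genome/genic/intergenic sizes (sorted by genome size,
#' largest first), reports the mean and sample SD (n-1 denominator) of genic
#' and intergenic sizes, and the Pearson correlation of genome size with
#' intergenic size.
#'
#' @param summaries List of `PartitionSummary` objects (>= 2 species).
#' @return A list with `table` (data.frame), `genic_mean`, `genic_sd`,
#'   `intergenic_mean`, `intergenic_sd`, and `cor_genome_intergenic`.
#' @export
compare_partitions <- function(summaries) {
  stopifnot(length(summaries) >= 2,
            all(vapply(summaries, inherits, logical(1), "PartitionSummary")))
  tab <- do.call(rbind, lapply(summaries, as.data.frame))
  tab <- tab[order(-tab$genome_size), , drop = FALSE]
  rownames(tab) <- NULL
  r <- if (stats::sd(tab$genome_size) > 0 && stats::sd(tab$intergenic_size) > 0)
    correlate(tab$genome_size, tab$intergenic_size) else NA_real_
  list(table = tab,
       genic_mean = mean(tab$genic_size),
       genic_sd = stats::sd(tab$genic_size),
       intergenic_mean = mean(tab$intergenic_size),
       intergenic_sd = stats::sd(tab$intergenic_size),
       cor_genome_intergenic = r)
}
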