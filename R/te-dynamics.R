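# Transposable-element dynamics: RepeatMasker .out parsing, divergence
# landscapes, Jukes-Cantor correction and insertion-time dating, and
# per-compartment TE content summaries.

te_classes <- c("DNA", "LINE", "LTR", "SINE")
non_te_prefixes <- c("Simple_repeat", "Low_complexity", "Satellite", "Tandem")

map_te_class <- function(class_family) {
  top <- sub("/.*", "", class_family)
  out <- rep("other", length(top))
  for (cl in te_classes) out[startsWith(top, cl)] <- cl
  out
}

#' Read TE copies from a RepeatMasker .out file
#'
#' Parses the classic 15-column layout (3 header lines). The `% div` column
#' becomes `divergence_d` (a proportion), the class/family column is mapped by
#' prefix to one of DNA/LINE/LTR/SINE/other, and tandem, simple and
#' low-complexity records are dropped.
#'
#' @param path Path to a RepeatMasker `.out` file.
#' @return data.frame of TE copy records with columns `copy_id`, `te_class`,
#'   `family`, `seq_id`, `start`, `end`, `divergence_d`, `compartment`
#'   (initialised to `"unassigned"`).
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  if (length(lines) > 3) lines <- lines[-(1:3)] else lines <- character()
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(empty_te_records())
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 15L) {
      stop("unparseable RepeatMasker row at line ", i + 3L,
           ": expected >= 15 whitespace-separated fields, got ", length(f))
    }
    d <- suppressWarnings(as.numeric(f[2])) / 100
    start <- suppressWarnings(as.integer(f[6]))
    end <- suppressWarnings(as.integer(f[7]))
    if (is.na(d) || is.na(start) || is.na(end)) {
      stop("unparseable RepeatMasker row at line ", i + 3L)
    }
    rows[[i]] <- data.frame(copy_id = f[15], family = f[10],
                            class_family = f[11], seq_id = f[5],
                            start = start, end = end, divergence_d = d,
                            stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, rows)
  top <- sub("/.*", "", rec$class_family)
  keep <- !top %in% non_te_prefixes
  rec <- rec[keep, , drop = FALSE]
  if (nrow(rec) == 0) return(empty_te_records())
  data.frame(copy_id = rec$copy_id,
             te_class = map_te_class(rec$class_family),
             family = rec$family,
             seq_id = rec$seq_id,
             start = rec$start,
             end = rec$end,
             divergence_d = rec$divergence_d,
             compartment = "unassigned",
             stringsAsFactors = FALSE)
}

empty_te_records <- function() {
  data.frame(copy_id = character(), te_class = character(),
             family = character(), seq_id = character(),
             start = integer(), end = integer(),
             divergence_d = numeric(), compartment = character(),
             stringsAsFactors = FALSE)
}

#' Assign TE copies to the genic or intergenic compartment
#'
#' A copy is genic when its midpoint falls inside the genic union of its
#' sequence, intergenic otherwise. Copies on sequences absent from the
#' annotation stay `"unassigned"` and a warning reports their count.
#'
#' @param records TE copy records (see [read_repeatmasker_out()]).
#' @param ann A [genome_annotation()] object.
#' @return `records` with the `compartment` column filled in.
#' @export
assign_compartment <- function(records, ann) {
  stopifnot(inherits(ann, "GenomeAnnotation"))
  if (nrow(records) == 0) return(records)
  records$compartment <- "unassigned"
  known <- records$seq_id %in% names(ann$seq_lengths)
  if (any(!known)) {
    warning(sum(!known), " TE cop",
            if (sum(!known) == 1) "y" else "ies",
            " on sequences absent from the annotation left unassigned")
  }
  mid <- (records$start + records$end) %/% 2L
  for (sid in unique(records$seq_id[known])) {
    sel <- which(records$seq_id == sid)
    g <- ann$genes[ann$genes$seq_id == sid, , drop = FALSE]
    if (nrow(g) == 0) {
      records$compartment[sel] <- "intergenic"
      next
    }
    genic <- IRanges::reduce(IRanges::IRanges(start = g$start, end = g$end))
    hit <- IRanges::overlapsAny(
      IRanges::IRanges(start = mid[sel], width = 1L), genic)
    records$compartment[sel] <- ifelse(hit, "genic", "intergenic")
  }
  records
}

#' TE divergence landscape
#'
#' Sums copy base pairs per (class, divergence bin); bins are half-open
#' `[i*w, (i+1)*w)`. The matrix total equals the total bp of the retained
#' copies, so no sequence is lost or double counted.
#'
#' @param records TE copy records.
#' @param bin_width Divergence bin width (default 0.01).
#' @param classes TE classes to keep (default DNA/LINE/LTR/SINE).
#' @return Numeric matrix, rows = classes, columns = divergence bins labelled
#'   by their left edge.
#' @export
divergence_landscape <- function(records, bin_width = 0.01,
                                 classes = te_classes) {
  stopifnot(bin_width > 0)
  rec <- records[records$te_class %in% classes, , drop = FALSE]
  n_bins <- if (nrow(rec) > 0)
    max(floor(rec$divergence_d / bin_width)) + 1L else 1L
  m <- matrix(0, nrow = length(classes), ncol = n_bins,
              dimnames = list(classes,
                              formatC(bin_width * (seq_len(n_bins) - 1L),
                                      format = "g")))
  if (nrow(rec) == 0) return(m)
  bin <- floor(rec$divergence_d / bin_width) + 1L
  len <- rec$end - rec$start + 1
  for (i in seq_len(nrow(rec))) {
    m[rec$te_class[i], bin[i]] <- m[rec$te_class[i], bin[i]] + len[i]
  }
  m
}

#' Jukes-Cantor distance correction
#'
#' Converts an observed mismatch proportion d into the substitutions-per-site
#' estimate K = -(3/4) ln(1 - 4d/3), correcting for multiple hits. Undefined
#' at or beyond saturation (d >= 0.75).
#'
#' @param divergence_d Observed mismatch proportion(s) in `[0, 0.75)`.
#' @return K, same length as the input.
#' @export
jc_correct <- function(divergence_d) {
  if (any(divergence_d < 0) || any(divergence_d >= 0.75)) {
    stop("Jukes-Cantor correction requires 0 <= d < 0.75 (saturation)")
  }
  -0.75 * log(1 - 4 * divergence_d / 3)
}

#' TE insertion time from corrected distance
#'
#' T = K / (2 r): the copy diverged from the family consensus along two
#' lineages, each accumulating substitutions at rate r per site per million
#' years.
#'
#' @param K Jukes-Cantor-corrected substitutions per site (>= 0).
#' @param rate_r Lineage substitution rate, substitutions/site/MY (> 0).
#' @return Insertion time in million years.
#' @export
insertion_time <- function(K, rate_r) {
  if (any(K < 0)) stop("K must be non-negative")
  if (any(rate_r <= 0)) stop("substitution rate must be positive")
  K / (2 * rate_r)
}

#' Per-class TE content of a genome and its intergenic compartment
#'
#' @param records TE copy records with compartments assigned.
#' @param part A `PartitionSummary` for the same species.
#' @return data.frame with per-class bp and percentages of the genome and of
#'   the intergenic compartment (overlapping copies counted as given).
#' @export
te_content_summary <- function(records, part) {
  stopifnot(inherits(part, "PartitionSummary"))
  cls <- te_classes
  len <- records$end - records$start + 1
  bp <- vapply(cls, function(cl) sum(len[records$te_class == cl]), numeric(1))
  bp_inter <- vapply(cls, function(cl) {
    sum(len[records$te_class == cl & records$compartment == "intergenic"])
  }, numeric(1))
  data.frame(te_class = cls,
             bp = bp,
             pct_genome = 100 * bp / part$genome_size,
             intergenic_bp = bp_inter,
             pct_intergenic = if (part$intergenic_size > 0)
               100 * bp_inter / part$intergenic_size else NA_real_,
             stringsAsFactors = FALSE)
}

#' Percent reduction of a focal quantity relative to a reference
#'
#' Returns `100 * (reference - focal) / reference`; negative values signal an
#' increase rather than a reduction.
#'
#' @param focal_value Focal quantity.
#' @param reference_value Reference quantity (> 0).
#' @return Percent reduction.
#' @export
percent_reduction <- function(focal_value, reference_value) {
  if (any(reference_value <= 0)) stop("reference value must be positive")
  100 * (reference_value - focal_value) / reference_value
}
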