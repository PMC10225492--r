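# Internal helpers shared across modules.

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so generators never perturb the global random stream.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write.table with the fixed conventions every writer in the package uses,
# so that identical inputs give byte-identical files.
write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

read_tsv_plain <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
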