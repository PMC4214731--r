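#' @import methods
#' @importFrom stats median predict setNames runif
#' @importFrom utils read.delim write.table head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible 31-bit sub-seed from a master seed and a stream index.
deriveSeed <- function(seed, stream) {
  (as.double(seed) * 7919 + as.double(stream) * 104729) %% 2147483647
}

pairKey <- function(drug, disease) paste(drug, disease, sep = "\t")

# Read a 2-3 column TSV allowing '#' comment/header lines; keeps everything
# as character. `path` may already be a data.frame.
readTsv <- function(path, what = "table") {
  if (is.data.frame(path)) {
    df <- path
    for (j in seq_along(df)) df[[j]] <- as.character(df[[j]])
    names(df) <- paste0("V", seq_along(df))
    return(df)
  }
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  lineNo <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(data.frame(V1 = character(), V2 = character(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 2L)) {
    bad <- lineNo[which(ncols < 2L)[1L]]
    stop("malformed ", what, " row at line ", bad, ": expected >= 2 columns")
  }
  nmax <- max(ncols)
  cols <- lapply(seq_len(nmax), function(j)
    vapply(parts, function(p) if (length(p) >= j) p[[j]] else NA_character_,
           character(1L)))
  df <- as.data.frame(cols, stringsAsFactors = FALSE)
  names(df) <- paste0("V", seq_len(nmax))
  df
}

writeTsvFile <- function(df, path, col.names = FALSE) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = col.names, eol = "\n")
}
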