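#' One-sided Fisher exact test of a 2x2 contingency table
#'
#' Upper-tail (enrichment) probability of observing at least the top-left
#' overlap given the table margins, i.e. the hypergeometric tail
#' \eqn{P(X \ge a)}. Computed through log-space hypergeometric
#' probabilities, so it is stable for large margins.
#'
#' @param m 2x2 matrix (or length-4 vector, row-major) of non-negative
#'   integer counts \code{[[a, b], [c, d]]}.
#' @return the one-sided p-value.
#' @examples
#' fisherExactOneSided(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))  # 17/70
#' @export
fisherExactOneSided <- function(m) {
  m <- matrix(as.numeric(m), 2L, 2L, byrow = !is.matrix(m))
  if (any(is.na(m)) || any(m < 0) || any(m != round(m)))
    stop("table entries must be non-negative integers")
  a <- m[1L, 1L]; b <- m[1L, 2L]; c <- m[2L, 1L]; d <- m[2L, 2L]
  if (a + c == 0 || a + b == 0) return(1)
  # P(X >= a), X ~ Hypergeometric(white = a+b, black = c+d, drawn = a+c)
  stats::phyper(a - 1, a + b, c + d, a + c, lower.tail = FALSE)
}

#' Coverage of an external validation set by predicted associations
#'
#' Builds the 2x2 table of predicted-status against
#' validation-set-membership over a candidate universe, reports the
#' coverage — the fraction of validation pairs recovered by the predictions
#' — and the one-sided Fisher exact enrichment p-value.
#'
#' @param predicted,validation,universe data.frames with \code{drug},
#'   \code{disease} columns; \code{predicted} and \code{validation} must be
#'   subsets of \code{universe}.
#' @param path optional path to also write the report as JSON.
#' @return a list with \code{table} (2x2 integer matrix), \code{coverage}
#'   and \code{pValue}.
#' @export
coverageReport <- function(predicted, validation, universe, path = NULL) {
  toKey <- function(df) unique(pairKey(df$drug, df$disease))
  u <- toKey(universe); p <- toKey(predicted); v <- toKey(validation)
  if (!all(p %in% u) || !all(v %in% u))
    stop("'predicted' and 'validation' must lie within 'universe'")
  inP <- u %in% p; inV <- u %in% v
  tab <- matrix(c(sum(inP & inV), sum(inP & !inV),
                  sum(!inP & inV), sum(!inP & !inV)),
                2L, 2L, byrow = TRUE,
                dimnames = list(predicted = c("yes", "no"),
                                validated = c("yes", "no")))
  cov <- if (sum(inV) == 0L) NA_real_ else sum(inP & inV) / sum(inV)
  out <- list(table = tab, coverage = cov,
              pValue = fisherExactOneSided(tab))
  if (!is.null(path))
    jsonlite::write_json(list(table = tab, coverage = cov,
                              p_value = out$pValue),
                         path, auto_unbox = TRUE, digits = NA)
  out
}

#' Tanimoto coefficient between two fingerprint bitsets
#'
#' \code{|A intersect B| / |A union B|} over the positions of set bits.
#'
#' @param a,b integer vectors of set-bit positions; not both empty.
#' @return a number in \code{[0, 1]}.
#' @export
tanimoto <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L && length(b) == 0L)
    stop("at least one bitset must be non-empty")
  length(intersect(a, b)) / length(union(a, b))
}

#' Fraction of drug pairs that are chemically similar
#'
#' The fraction of the given drug pairs whose fingerprint Tanimoto
#' coefficient strictly exceeds the threshold (default 0.7, the usual
#' structural-similarity cutoff). Used to check that network-based
#' predictions are not merely rediscovering chemical analogues.
#'
#' @param pairs data.frame with two columns of drug identifiers.
#' @param fps named list: drug id -> integer vector of set-bit positions.
#' @param threshold similarity cutoff (strict inequality).
#' @return the fraction in \code{[0, 1]}.
#' @export
fractionSimilar <- function(pairs, fps, threshold = 0.7) {
  ids <- unique(c(pairs[[1L]], pairs[[2L]]))
  missing <- ids[!ids %in% names(fps)]
  if (length(missing))
    stop("missing fingerprint for drug(s): ",
         paste(head(missing, 5L), collapse = ", "))
  sims <- vapply(seq_len(nrow(pairs)), function(i)
    tanimoto(fps[[pairs[[1L]][i]]], fps[[pairs[[2L]][i]]]), numeric(1L))
  mean(sims > threshold)
}

#' Read drug fingerprints from TSV
#'
#' Default dialect: \code{drug_id TAB comma-separated set-bit indices}.
#' With \code{hex = TRUE} the second column is a hexadecimal bit-string
#' whose set bits are extracted (bit 1 = most significant bit of the first
#' hex digit).
#'
#' @param path TSV path or data.frame.
#' @param hex logical; interpret the second column as a hex string.
#' @return named list of integer vectors.
#' @export
readFingerprints <- function(path, hex = FALSE) {
  df <- readTsv(path, "fingerprint")
  bits <- if (hex) lapply(df$V2, hexToBits) else
    lapply(strsplit(df$V2, ",", fixed = TRUE),
           function(x) sort(unique(as.integer(x))))
  setNames(bits, df$V1)
}

hexToBits <- function(s) {
  digits <- strtoi(strsplit(tolower(s), "")[[1L]], base = 16L)
  bits <- unlist(lapply(digits, function(d)
    as.integer(intToBits(d))[4:1]))
  which(bits == 1L)
}
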