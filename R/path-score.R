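#' Construct a path-score configuration
#'
#' In \code{"fixed"} mode the R0 base score is 1/6, the reciprocal median
#' degree of the integrative network the method was calibrated on. In
#' \code{"auto"} mode the base is 1/medianDegree of the supplied network.
#' R1 and R2 paths score the square and cube of the base; longer paths
#' score 0.
#'
#' @param mode \code{"fixed"} (base 1/6) or \code{"auto"} (requires
#'   \code{net}).
#' @param net a \linkS4class{GeneNetwork}, needed for \code{"auto"}.
#' @param allowedLengths subset of \code{0:2}; excluded path lengths score 0
#'   (single-path-type ablation).
#' @param combineWeights two non-negative weights summing to 1 for the
#'   weighted geometric mean combining drug-side and disease-side scores.
#' @return a \linkS4class{PathScoreConfig}.
#' @examples
#' cfg <- pathScoreConfig()
#' pathScore(cfg, 0:3)  # 1/6, 1/36, 1/216, 0
#' @export
pathScoreConfig <- function(mode = c("fixed", "auto"), net = NULL,
                            allowedLengths = 0:2,
                            combineWeights = c(0.5, 0.5)) {
  mode <- match.arg(mode)
  base <- if (mode == "fixed") 1 / 6 else {
    if (is.null(net)) stop("'auto' mode requires the loaded network")
    1 / medianDegree(net)
  }
  new("PathScoreConfig", base = base, mode = mode, maxPathLen = 2L,
      allowedLengths = sort(unique(as.integer(allowedLengths))),
      combineWeights = as.numeric(combineWeights))
}

#' Score of a bounded shortest path
#'
#' A path of length \eqn{\ell} scores \eqn{base^{\ell+1}} for
#' \eqn{\ell \in \{0,1,2\}} (the R0, R1, R2 path types) and 0 for longer or
#' absent paths (\code{NA} lengths). Lengths outside the configuration's
#' \code{allowedLengths} also score 0.
#'
#' @param cfg a \linkS4class{PathScoreConfig}.
#' @param len integer vector of path lengths (NA = unreachable).
#' @return numeric vector of scores.
#' @export
pathScore <- function(cfg, len) {
  stopifnot(is(cfg, "PathScoreConfig"))
  ok <- !is.na(len) & len >= 0 & len <= cfg@maxPathLen &
    len %in% cfg@allowedLengths
  ifelse(ok, cfg@base^(len + 1), 0)
}

setMethod("show", "PathScoreConfig", function(object) {
  cat(sprintf("PathScoreConfig: mode=%s base=%.6g (R0=%.6g R1=%.6g R2=%.6g)\n",
              object@mode, object@base, object@base, object@base^2,
              object@base^3))
  cat("  allowed path lengths:",
      paste(object@allowedLengths, collapse = ", "), "\n")
  cat("  combine weights:",
      paste(format(object@combineWeights), collapse = "/"), "\n")
})
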