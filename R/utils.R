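#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cutree dist hclust p.adjust phyper rbinom rlnorm
#'   rmultinom rnorm runif sd t.test var wilcox.test setNames
#' @importFrom utils read.delim write.table modifyList
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The four diet groups of the 2x2 protein/fat design
#'
#' Diet codes combine protein level (NP normal, HP high) with fat level
#' (LF low, HF high).
#' @return Character vector `c("NPLF", "NPHF", "HPLF", "HPHF")`.
#' @export
diet_levels <- function() c("NPLF", "NPHF", "HPLF", "HPHF")

#' The six measured caecal fatty acids
#'
#' Straight-chain short-chain fatty acids plus the two branched acids
#' (markers of branched-chain amino-acid fermentation).
#' @return Character vector of acid names.
#' @export
scfa_acids <- function() {
  c("acetate", "propionate", "butyrate", "valerate",
    "iso-butyrate", "iso-valerate")
}

protein_level_of <- function(diet) {
  substr(as.character(diet), 1L, 2L)
}

fat_level_of <- function(diet) {
  substr(as.character(diet), 3L, 4L)
}

mtx_log <- function(...) {
  message(format(Sys.time(), "%H:%M:%S"), " [mtxprof] ", ...)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}
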