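#' @importFrom rlang .data
#' @importFrom stats median quantile runif rgeom
#' @importFrom utils head
NULL

#' Normalise free text for rule matching
#'
#' Upper-cases and collapses internal whitespace to single spaces, trimming the
#' ends. All keyword, brand and strength matching in the package operates on
#' this normalised form, so matching is invariant to letter case and spacing.
#'
#' @param x character vector (NA allowed).
#' @return character vector of the same length.
#' @export
#' @examples
#' norm_text("  take Two  puffs Twice daily ")
norm_text <- function(x) {
  x <- toupper(as.character(x))
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

# statistical mode with smallest-value tie-break; x must be non-empty, no NA
mode_smallest <- function(x) {
  tab <- table(x)
  vals <- as.numeric(names(tab))
  min(vals[tab == max(tab)])
}

# split "a;b;c" fields from config CSVs
split_semi <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(character(0))
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

split_semi_num <- function(x) {
  out <- suppressWarnings(as.numeric(split_semi(x)))
  out[!is.na(out)]
}

# evaluate expr with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

sys_file <- function(...) {
  path <- system.file(..., package = "asthmasteps", mustWork = TRUE)
  path
}
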