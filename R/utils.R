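#' Binary scanner-site encoding
#'
#' Maps site labels to the binary code used throughout the models:
#' 1 for MGH, 0 for BU. Inputs already coded 0/1 pass through.
#'
#' @param site character/factor of `"MGH"`/`"BU"` labels, or a 0/1 vector.
#' @return integer vector of 0/1 codes.
#' @examples siteBinary(c("MGH", "BU", "MGH"))
#' @export
siteBinary <- function(site) {
  if (is.numeric(site)) {
    if (!all(site %in% c(0, 1))) stop("numeric site codes must be 0/1")
    return(as.integer(site))
  }
  site <- toupper(as.character(site))
  if (!all(site %in% c("MGH", "BU")))
    stop("site labels must be 'MGH' or 'BU' (multi-site inputs are not supported); got: ",
         paste(unique(setdiff(site, c("MGH", "BU"))), collapse = ", "))
  as.integer(site == "MGH")
}

# evaluate `expr` under `seed` when non-NULL, else in the current RNG stream
withSeedIf <- function(seed, expr) {
  if (is.null(seed)) expr
  else withr::with_seed(as.integer(seed), expr)
}

# derive the per-iteration seed: base xor iteration index, kept non-negative
iterSeed <- function(seed, b) {
  bitwXor(as.integer(seed), as.integer(b))
}

assertCount <- function(x, name, minimum = 0L) {
  if (length(x) != 1L || !is.finite(x) || x < minimum || x != floor(x))
    stop(name, " must be a single integer >= ", minimum)
  as.integer(x)
}
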