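#' @keywords internal
"_PACKAGE"

# Compartment vocabulary and the id suffixes used by the shipped models.
COMPARTMENTS <- c(extracellular = "e", cytosol = "c",
                  peroxisome = "p", mitochondrion = "m")

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Convolve two mass distribution vectors
#'
#' The mass distribution of a molecule assembled from two independent
#' carbon units is the discrete convolution of the two unit distributions.
#'
#' @param x,y numeric vectors of mass-isotopomer fractions (m0..mn).
#' @return numeric vector of length `length(x) + length(y) - 1`.
#' @export
mdv_convolve <- function(x, y) {
  n <- length(x) + length(y) - 1L
  out <- numeric(n)
  for (i in seq_along(x)) {
    idx <- i + seq_along(y) - 1L
    out[idx] <- out[idx] + x[i] * y
  }
  out
}

mdv_convolve_all <- function(lst) Reduce(mdv_convolve, lst)

# Parse an elemental formula such as "C7H16O13P2" into a named count vector.
parse_formula <- function(formula) {
  if (is.null(formula) || is.na(formula) || !nzchar(formula)) return(NULL)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (!nzchar(paste(parts, collapse = "")) ||
      nchar(paste(parts, collapse = "")) != nchar(formula))
    stopf("cannot parse formula '%s'", formula)
  el <- sub("[0-9]*$", "", parts)
  ct <- as.integer(ifelse(grepl("[0-9]+$", parts),
                          sub("^[A-Za-z]+", "", parts), "1"))
  tapply(ct, el, sum)
}

# Deterministic child seed: small integer derived from (seed, stage label),
# kept below 2^31 so it is a valid R integer.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
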