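# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# nucleotide channels, fixed on-disk and in-memory order
CHANNELS <- c("A_fwd", "T_fwd", "G_fwd", "C_fwd", "X_fwd",
              "A_rev", "T_rev", "G_rev", "C_rev", "X_rev")
NUCLEOTIDES <- c("A", "T", "G", "C")

RESPONSE_CATEGORIES <- c("response", "resistance", "acquired_resistance")
CONSEQUENCES <- c("stopgain", "frameshift", "missense", "synonymous", "other")
GENE_ROLES <- c("tumor_suppressor", "oncogene", "both", "other")

#' Canonical variant key
#'
#' \code{"<chromosome>:<coordinate>:<ref>><alt>"}, used to join calls, truth
#' records and annotation.
#'
#' @param chromosome,coordinate,ref,alt variant coordinates and alleles.
#' @return character vector of keys.
#' @export
variant_key <- function(chromosome, coordinate, ref, alt) {
  if (length(chromosome) == 0L) return(character(0))
  paste0(chromosome, ":", coordinate, ":", ref, ">", alt)
}

stop_parse <- function(path, line, field, msg) {
  stop(sprintf("%s: line %s, field '%s': %s", path, line, field, msg),
       call. = FALSE)
}

# local RNG scope: run expr under set.seed(seed) and restore global state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# sample from the elements of x (never from 1:x when x is scalar)
sample_from <- function(x, size = length(x), replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

# seed substreams derived from one master seed, kept below 2^31
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 1009 + stream * 9973) %% 2147483647
}
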