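#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical key for a mutation call
#'
#' Mutations are identified throughout the package by the string
#' `"<position>:<ref)><alt>"`, e.g. `"1234:A>G"`.  The key is what
#' frequency tracking, Levenshtein strings and ground-truth histories
#' operate on.
#'
#' @param position 1-based genomic coordinate(s).
#' @param ref,alt reference / alternative allele strings (empty-capable
#'   for indels).
#' @return character vector of keys.
#' @export
mutation_key <- function(position, ref, alt) {
  paste0(position, ":", ref, ">", alt)
}

## parse positions back out of keys; returns NA where a key is not in the
## canonical format (then callers fall back to plain lexicographic order)
.key_position <- function(key) {
  suppressWarnings(as.numeric(sub("^([0-9]+):.*$", "\\1", key)))
}

## canonical ordering of a set of mutation keys: genomic position, then the
## full key string (which disambiguates by alleles).  Non-parseable symbols
## sort lexicographically after parseable ones.
canonical_sort_keys <- function(keys) {
  if (length(keys) == 0L) return(character(0))
  pos <- .key_position(keys)
  pos[is.na(pos)] <- Inf
  keys[order(pos, keys, method = "radix")]
}

## unordered pair identifier, symmetric in its arguments
pair_id <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\t")
}

## run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## reverse complement for plain character DNA (used in hot paths; I/O goes
## through Biostrings)
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTacgt", "TGCAtgca",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

.complement <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

stop_input <- function(...) stop(..., call. = FALSE)
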