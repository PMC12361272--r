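#' @keywords internal
"_PACKAGE"

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL runs expr as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
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

#' Canonical key for an unordered haplotype pair
#'
#' Haplogenotypes are unordered pairs of haplotype labels; every lookup table
#' in the package stores them under the lexicographically sorted key
#' `"A|B"` so that `(A,B)` and `(B,A)` resolve identically.
#'
#' @param a,b Character haplotype labels (vectorised).
#' @return Character vector of canonical keys.
#' @export
pair_key <- function(a, b) {
  ifelse(a <= b, paste(a, b, sep = "|"), paste(b, a, sep = "|"))
}

split_pair_key <- function(key) {
  parts <- strsplit(key, "|", fixed = TRUE)
  do.call(rbind, lapply(parts, function(p) p[1:2]))
}

# expit, kept explicit for readability at call sites
expit <- function(x) stats::plogis(x)

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}
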