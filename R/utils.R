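## Shared low-level helpers: IUPAC tables, rounding, seed derivation.

# Two-base ambiguity codes used for heterozygous calls (W=A/T, M=A/C, R=A/G,
# Y=C/T, S=C/G, K=G/T). Single bases map to themselves.
IUPAC_PAIRS <- list(
  A = "A", C = "C", G = "G", T = "T",
  W = c("A", "T"), M = c("A", "C"), R = c("A", "G"),
  Y = c("C", "T"), S = c("C", "G"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T")
)

#' IUPAC code for a pair of bases
#'
#' Returns the single-letter ambiguity code for an unordered pair of bases
#' (`het_code("A", "G")` is `"R"`); a pair of identical bases returns that base.
#'
#' @param a,b single bases in `A,C,G,T`.
#' @return A single character.
#' @export
het_code <- function(a, b) {
  pair <- sort(unique(c(a, b)))
  if (length(pair) == 1L) return(pair)
  hit <- vapply(IUPAC_PAIRS, function(p) length(p) == 2L && all(p == pair),
                logical(1))
  code <- names(IUPAC_PAIRS)[hit]
  if (length(code) != 1L) stop("no two-base IUPAC code for: ", a, "/", b)
  code
}

#' Expand an IUPAC symbol to its base set
#' @param x character vector of IUPAC symbols.
#' @return A list of character vectors of bases.
#' @export
iupac_expand <- function(x) {
  out <- IUPAC_PAIRS[x]
  if (anyNA(names(out))) stop("unknown IUPAC symbol in: ",
                              paste(setdiff(x, names(IUPAC_PAIRS)), collapse = ","))
  out
}

# 16x16 compatibility lookup (shared base => compatible), indexed by symbol.
.iupac_compat_matrix <- local({
  syms <- names(IUPAC_PAIRS)
  m <- matrix(FALSE, length(syms), length(syms), dimnames = list(syms, syms))
  for (i in syms) for (j in syms)
    m[i, j] <- length(intersect(IUPAC_PAIRS[[i]], IUPAC_PAIRS[[j]])) > 0L
  m
})

#' Are two IUPAC symbols compatible (share at least one base)?
#' @param a,b character vectors of IUPAC symbols (recycled).
#' @return Logical vector.
#' @export
iupac_compatible <- function(a, b) {
  .iupac_compat_matrix[cbind(a, b)]
}

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  W = "W", S = "S", M = "K", K = "M", R = "Y", Y = "R",
  V = "B", B = "V", H = "D", D = "H", N = "N"
)

#' Reverse-complement an IUPAC nucleotide string
#' @param x character vector of sequences.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  comp <- chartr(paste(names(IUPAC_COMPLEMENT), collapse = ""),
                 paste(IUPAC_COMPLEMENT, collapse = ""), x)
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""),
         character(1))
}

#' Round half up
#'
#' `round()` in R rounds half to even; quality-control percentages here are
#' reported with conventional half-up rounding (96.551... -> 96.6).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return Numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Derive a reproducible per-stage seed from a master seed. Keeps results
# independent across stages while a single integer controls the whole run.
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

split_string <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
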