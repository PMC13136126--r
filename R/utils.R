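#' @import methods
#' @importFrom stats median optim runif setNames
#' @importFrom utils read.delim write.table head tail read.csv write.csv packageVersion
#' @importFrom tools md5sum
#' @importClassesFrom Biostrings AAStringSet
NULL

## 20-letter amino-acid alphabet; 'X' is tolerated in records but carries no
## scoring information.
AA_ALPHABET20 <- c("A","C","D","E","F","G","H","I","K","L",
                   "M","N","P","Q","R","S","T","V","W","Y")

## Uniform residue background used by the scoring engine and the decoy
## generator alike, so that decoys are drawn from the scoring null.
AA_BACKGROUND <- setNames(rep(1 / 20, 20), AA_ALPHABET20)

`%||%` <- function(a, b) if (is.null(a)) b else a

.checkAminoAcid <- function(x, what = "sequence") {
  bad <- grepl(paste0("[^", paste(AA_ALPHABET20, collapse = ""), "X]"), x)
  if (any(bad)) {
    stop(what, " contains characters outside the 20-letter alphabet plus X: ",
         paste(utils::head(names(x)[bad] %||% which(bad), 3), collapse = ", "))
  }
  invisible(TRUE)
}

## Split a semicolon-delimited lineage/domain string into a trimmed vector.
.splitSemi <- function(x) {
  out <- strsplit(as.character(x), ";", fixed = TRUE)
  lapply(out, function(v) {
    v <- trimws(v)
    v[nzchar(v)]
  })
}

.collapseSemi <- function(x) {
  vapply(x, paste, character(1), collapse = ";")
}

## Stable log10 of the Gumbel upper tail P(S >= s) with z = (s - mu) / beta.
## For large z, 1 - exp(-exp(-z)) ~ exp(-z).
.log10GumbelTail <- function(z) {
  out <- numeric(length(z))
  big <- z > 18
  out[big] <- -z[big] / log(10)
  p <- -expm1(-exp(-z[!big]))
  p[p < .Machine$double.xmin] <- .Machine$double.xmin
  out[!big] <- log10(p)
  out
}
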