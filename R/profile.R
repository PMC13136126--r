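## Built-in position-specific scoring engine.
##
## A profile is a 20 x L log-odds matrix (bits) over match columns of the
## family alignment. A query is scored by its best ungapped local segment
## against the model (maximum-sum contiguous diagonal run of at least
## `minOverlap` aligned positions), so a conserved domain scores the same
## whether it stands alone or is embedded in an unrelated protein.
## Statistical significance comes from an empirical null: best-segment
## scores of composition-preserving shuffles of the training sequences, to
## which a Gumbel distribution is fitted by maximum likelihood.

.encodeAA <- function(seq) {
  idx <- match(strsplit(seq, "")[[1]], AA_ALPHABET20)
  idx  # NA for X / unknowns: contributes 0 to every column score
}

## Best ungapped local segment (HSP-style): for every diagonal of the
## position x column score matrix, the maximum-sum contiguous run of at
## least `minOverlap` aligned positions. Returns score and the protein
## coordinates of the best segment.
.bestLocalSegment <- function(idx, pssm, minOverlap) {
  n <- length(idx)
  L <- ncol(pssm)
  if (n == 0L) return(list(score = -Inf, start = NA_integer_,
                           end = NA_integer_))
  sc <- matrix(0, nrow = n, ncol = L)
  known <- !is.na(idx)
  if (any(known)) sc[known, ] <- pssm[idx[known], , drop = FALSE]
  mo <- max(1L, min(minOverlap, n, L))
  best <- -Inf; bStart <- NA_integer_; bEnd <- NA_integer_
  for (d in (-(L - 1L)):(n - 1L)) {
    rows <- max(1L, d + 1L):min(n, d + L)
    len <- length(rows)
    if (len < mo) next
    v <- sc[cbind(rows, rows - d)]
    S <- cumsum(v)
    pre <- c(0, S)[seq_len(len - mo + 1L)]      # S_0 .. S_(len-mo)
    lo <- cummin(pre)
    cand <- S[mo:len] - lo
    k <- which.max(cand)
    if (cand[k] > best) {
      best <- cand[k]
      j <- k + mo - 1L                           # segment end (within diag)
      i <- which.max(pre[seq_len(k)] == lo[k])   # prefix index of the min
      bStart <- rows[i]; bEnd <- rows[j]
    }
  }
  list(score = best, start = bStart, end = bEnd)
}

.windowMaxScore <- function(idx, pssm, minOverlap) {
  .bestLocalSegment(idx, pssm, minOverlap)$score
}

.alignWithMafft <- function(seqs) {
  if (Sys.which("mafft") == "")
    stop("aligner failure: sequences have unequal lengths and the 'mafft' ",
         "executable is not on the PATH")
  fin <- tempfile(fileext = ".faa"); fout <- tempfile(fileext = ".afa")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  Biostrings::writeXStringSet(seqs, fin)
  status <- system2("mafft", c("--auto", "--anysymbol", "--quiet", fin),
                    stdout = fout, stderr = FALSE)
  if (status != 0L || !file.exists(fout))
    stop("aligner failure: mafft exited with status ", status)
  aln <- Biostrings::readAAStringSet(fout)
  names(aln) <- sub("\\s.*$", "", names(aln))
  aln[match(names(seqs), names(aln))]
}

#' Build a family profile from curated sequences
#'
#' Aligns the input (sequences of equal length are taken as already aligned;
#' otherwise the pluggable aligner, MAFFT by default, is invoked), selects
#' match columns (columns with less than 50\% gaps), derives a per-column
#' log-odds matrix with add-0.5 pseudocounts against a uniform background,
#' and calibrates an empirical Gumbel null from window-max scores of
#' \code{nNull} composition-preserving residue shuffles of the training
#' sequences. Deterministic for fixed input, engine and seed.
#'
#' With \code{engine = "external_hmm"} the model is built with HMMER's
#' \command{hmmbuild} and stored as profile-HMM text; scoring is delegated to
#' \command{hmmsearch} with the same report schema.
#'
#' @param x an \code{AAStringSet}/\code{ProteinSet} of at least 2 curated
#'   sequences.
#' @param family family label stored on the model (e.g. "LuxI").
#' @param engine "builtin_pssm" (default) or "external_hmm".
#' @param inclusionCutoff e-value inclusion cutoff contract (default 1e-10).
#' @param nNull number of shuffled null sequences (default 200).
#' @param pseudocount added per residue per column (default 0.5).
#' @param minOverlap minimum scored model/query overlap in columns.
#' @param seed RNG seed for the null shuffles.
#' @param alignmentId free-text identifier recorded on the model.
#' @return a \code{\link{ProfileModel}}.
#' @examples
#' fam <- generateFamily(10, length = 80, mutationRate = 0.05, seed = 1)
#' m <- buildProfile(fam, family = "LuxI")
#' modelLength(m)
#' @export
buildProfile <- function(x, family = "LuxI", engine = c("builtin_pssm",
                         "external_hmm"), inclusionCutoff = 1e-10,
                         nNull = 200L, pseudocount = 0.5, minOverlap = 30L,
                         seed = 101L, alignmentId = "curated") {
  engine <- match.arg(engine)
  if (!is(x, "AAStringSet")) x <- Biostrings::AAStringSet(x)
  if (length(x) < 2L)
    stop("at least 2 curated sequences are required to build a profile")
  if (is.null(names(x))) names(x) <- sprintf("seq%03d", seq_along(x))

  aln <- if (length(unique(Biostrings::width(x))) == 1L) x
         else .alignWithMafft(x)

  if (engine == "external_hmm")
    return(.buildHmmerProfile(aln, family, inclusionCutoff, alignmentId))

  M <- do.call(rbind, strsplit(as.character(aln), ""))
  gapFrac <- colMeans(M == "-" | M == ".")
  match_cols <- which(gapFrac < 0.5)
  if (!length(match_cols)) stop("alignment has no match columns")
  M <- M[, match_cols, drop = FALSE]

  counts <- apply(M, 2, function(col)
    tabulate(match(col, AA_ALPHABET20), nbins = 20))
  freqs <- sweep(counts + pseudocount, 2,
                 colSums(counts) + 20 * pseudocount, "/")
  pssm <- log2(freqs / AA_BACKGROUND)
  rownames(pssm) <- AA_ALPHABET20

  model <- new("ProfileModel", family = family, alignmentId = alignmentId,
               engine = "builtin_pssm", modelLength = ncol(pssm),
               inclusionCutoff = inclusionCutoff, pssm = pssm,
               background = AA_BACKGROUND, nullMu = 0, nullBeta = 1,
               nullWindows = 1, minOverlap = as.integer(minOverlap),
               hmmText = character(0))

  ## Empirical null: shuffle residues of (recycled) training sequences.
  set.seed(seed)
  src <- as.character(x)[rep_len(seq_along(x), nNull)]
  nullScores <- vapply(src, function(s) {
    shuffled <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
    .windowMaxScore(.encodeAA(shuffled), pssm, model@minOverlap)
  }, numeric(1), USE.NAMES = FALSE)
  nullScores <- nullScores[is.finite(nullScores)]
  fit <- .fitGumbel(nullScores)
  model@nullMu <- fit[["mu"]]
  model@nullBeta <- fit[["beta"]]
  refLen <- stats::median(Biostrings::width(x))
  model@nullWindows <- max(1, refLen + ncol(pssm) - 2 * model@minOverlap + 1)
  model
}

## ML fit of a Gumbel (max) distribution; moment estimates as start values.
.fitGumbel <- function(x) {
  beta0 <- max(stats::sd(x) * sqrt(6) / pi, 1e-3)
  mu0 <- mean(x) - 0.5772156649 * beta0
  nll <- function(p) {
    beta <- exp(p[2]); z <- (x - p[1]) / beta
    sum(log(beta) + z + exp(-z))
  }
  fit <- stats::optim(c(mu0, log(beta0)), nll, method = "Nelder-Mead")
  c(mu = fit$par[1], beta = exp(fit$par[2]))
}

#' Score sequences against a profile
#'
#' Returns per-sequence bit scores and e-values. For the built-in engine the
#' e-value is \code{z * nWindows/nWindowsRef * P(nullMax >= score)} under the
#' fitted Gumbel null, where \code{z} is the search-space size (default 1, a
#' per-query e-value; \code{\link{calibrate}} and \code{\link{scanProteome}}
#' pass the size of the scanned set, the usual database-search convention).
#' E-values are monotone decreasing in bit score for a fixed query length.
#'
#' @param model a \code{\link{ProfileModel}}.
#' @param seqs an \code{AAStringSet} or named character vector.
#' @param z search-space scaling of the e-value.
#' @return \code{DataFrame} with columns \code{accession}, \code{bitscore},
#'   \code{log10Evalue}, \code{evalue}, sorted in input order.
#' @export
scoreSequences <- function(model, seqs, z = 1) {
  stopifnot(is(model, "ProfileModel"))
  if (!is(seqs, "AAStringSet")) seqs <- Biostrings::AAStringSet(seqs)
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%03d", seq_along(seqs))
  if (model@engine == "external_hmm")
    return(.hmmerScore(model, seqs, z))
  n <- Biostrings::width(seqs)
  scores <- vapply(as.character(seqs), function(s)
    .windowMaxScore(.encodeAA(s), model@pssm, model@minOverlap),
    numeric(1), USE.NAMES = FALSE)
  nWin <- pmax(1, n + model@modelLength - 2 * model@minOverlap + 1)
  zz <- (scores - model@nullMu) / model@nullBeta
  log10e <- .log10GumbelTail(zz) + log10(nWin / model@nullWindows) + log10(z)
  S4Vectors::DataFrame(accession = names(seqs), bitscore = scores,
                       log10Evalue = log10e,
                       evalue = 10^pmax(log10e, -320))
}

#' Serialize / restore a built-in profile as versioned JSON
#' @param model a builtin-engine \code{ProfileModel}.
#' @param path JSON file path.
#' @export
writeProfile <- function(model, path) {
  stopifnot(is(model, "ProfileModel"))
  obj <- list(format = "ahlqs-profile", version = 1L,
              family = model@family, alignmentId = model@alignmentId,
              engine = model@engine, modelLength = model@modelLength,
              inclusionCutoff = model@inclusionCutoff,
              pssm = model@pssm, background = model@background,
              nullMu = model@nullMu, nullBeta = model@nullBeta,
              nullWindows = model@nullWindows,
              minOverlap = model@minOverlap,
              hmmText = model@hmmText)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeProfile
#' @export
readProfile <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "ahlqs-profile"))
    stop("not an ahlqs profile container: ", path)
  pssm <- if (length(obj$pssm)) {
    m <- as.matrix(obj$pssm); rownames(m) <- AA_ALPHABET20
    colnames(m) <- NULL
    m
  } else matrix(0, 20, max(1L, obj$modelLength))
  new("ProfileModel", family = obj$family, alignmentId = obj$alignmentId,
      engine = obj$engine, modelLength = as.integer(obj$modelLength),
      inclusionCutoff = obj$inclusionCutoff, pssm = pssm,
      background = setNames(as.numeric(obj$background), AA_ALPHABET20),
      nullMu = obj$nullMu, nullBeta = obj$nullBeta,
      nullWindows = obj$nullWindows, minOverlap = as.integer(obj$minOverlap),
      hmmText = as.character(obj$hmmText %||% character(0)))
}

## ---- external engine (HMMER) ----

.buildHmmerProfile <- function(aln, family, inclusionCutoff, alignmentId) {
  if (Sys.which("hmmbuild") == "")
    stop("engine 'external_hmm' requires HMMER's hmmbuild on the PATH")
  fa <- tempfile(fileext = ".afa"); hmm <- tempfile(fileext = ".hmm")
  on.exit(unlink(c(fa, hmm)), add = TRUE)
  Biostrings::writeXStringSet(aln, fa)
  status <- system2("hmmbuild", c("--amino", hmm, fa), stdout = FALSE,
                    stderr = FALSE)
  if (status != 0L) stop("hmmbuild failed with status ", status)
  txt <- readLines(hmm)
  L <- as.integer(sub("^LENG\\s+", "", grep("^LENG", txt, value = TRUE)[1]))
  new("ProfileModel", family = family, alignmentId = alignmentId,
      engine = "external_hmm", modelLength = L,
      inclusionCutoff = inclusionCutoff,
      pssm = matrix(0, 20, 1), background = AA_BACKGROUND,
      nullMu = 0, nullBeta = 1, nullWindows = 1, minOverlap = 1L,
      hmmText = txt)
}

.hmmerScore <- function(model, seqs, z) {
  if (Sys.which("hmmsearch") == "")
    stop("engine 'external_hmm' requires HMMER's hmmsearch on the PATH")
  hmm <- tempfile(fileext = ".hmm"); fa <- tempfile(fileext = ".faa")
  tbl <- tempfile(fileext = ".tbl")
  on.exit(unlink(c(hmm, fa, tbl)), add = TRUE)
  writeLines(model@hmmText, hmm)
  Biostrings::writeXStringSet(seqs, fa)
  status <- system2("hmmsearch",
                    c("--tblout", tbl, "-E", "1e6", "--max",
                      "-Z", format(max(z, 1)), hmm, fa),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("hmmsearch failed with status ", status)
  lines <- grep("^#", readLines(tbl), value = TRUE, invert = TRUE)
  hitAcc <- character(0); hitE <- numeric(0); hitB <- numeric(0)
  if (length(lines)) {
    f <- strsplit(trimws(lines), "\\s+")
    hitAcc <- vapply(f, `[`, character(1), 1)
    hitE <- as.numeric(vapply(f, `[`, character(1), 5))
    hitB <- as.numeric(vapply(f, `[`, character(1), 6))
  }
  i <- match(names(seqs), hitAcc)
  evalue <- ifelse(is.na(i), 1e6, hitE[i])
  S4Vectors::DataFrame(accession = names(seqs),
                       bitscore = ifelse(is.na(i), -Inf, hitB[i]),
                       log10Evalue = log10(evalue), evalue = evalue)
}
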