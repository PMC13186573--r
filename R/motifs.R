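## MAST-style motif scanning: integer-scaled log-odds scores, exact score
## distributions under the background by dynamic-programming convolution,
## per-site and best-site p-values, and QFAST combination across motifs.

#' Integer-scaled log-odds score matrix for a motif
#'
#' `score(i, a) = round(scale * log2((ppm(i, a) + pseudocount * bg(a)) /
#' ((1 + pseudocount) * bg(a))))`. Integer scaling makes the exact
#' score-distribution convolution finite; `scale = 100` gives centibit
#' resolution.
#'
#' @param motif a [MotifMatrix-class].
#' @param pseudocount background-proportional pseudocount (default 0.01).
#' @param scale integer score scale (default 100).
#' @return An integer matrix, width x 20, columns in alphabet order.
#' @export
logOddsMatrix <- function(motif, pseudocount = 0.01, scale = 100) {
  bg <- motif@background
  if (any(bg <= 0 & colSums(motif@ppm) > 0))
    stop("background frequency of 0 for a residue with non-zero ppm mass")
  lom <- log2(sweep(motif@ppm + pseudocount * rep(bg, each = nrow(motif@ppm)),
                    2, (1 + pseudocount) * bg, "/"))
  m <- matrix(as.integer(round(scale * lom)), nrow = nrow(motif@ppm))
  colnames(m) <- AA_ALPHABET
  m
}

#' Exact survival function of the background site score
#'
#' Computes, by convolution over motif positions, the exact distribution
#' of the site score when each position's residue is drawn independently
#' from the background, and returns the survival function
#' `P(score >= s)`.
#'
#' @param score_matrix integer score matrix from [logOddsMatrix()].
#' @param background length-20 background frequency vector.
#' @return A list with `scores` (all achievable total scores, ascending),
#'   `survival` (non-increasing, `P(score >= s)` for each), and the
#'   convenience function `pvalue(s)` giving `P(score >= s)` for arbitrary
#'   `s` (1 at or below the minimum achievable score).
#' @export
sitePvalueTable <- function(score_matrix, background) {
  w <- nrow(score_matrix)
  lo <- sum(apply(score_matrix, 1L, min))
  hi <- sum(apply(score_matrix, 1L, max))
  probs <- numeric(hi - lo + 1L)  # index = total score - lo + 1
  ## running support after i positions: offset by running minimum
  run_lo <- 0L
  cur <- 1
  for (i in seq_len(w)) {
    row <- score_matrix[i, ]
    rmin <- min(row)
    new_lo <- run_lo + rmin
    new <- numeric(length(cur) + max(row) - rmin)
    for (a in seq_len(20L)) {
      off <- row[a] - rmin
      idx <- seq_along(cur) + off
      new[idx] <- new[idx] + cur * background[a]
    }
    cur <- new
    run_lo <- new_lo
  }
  scores <- run_lo + seq_along(cur) - 1L
  keep <- cur > 0
  scores <- scores[keep]
  p <- cur[keep]
  surv <- rev(cumsum(rev(p)))
  surv <- pmin(surv, 1)
  pvalue <- function(s) {
    i <- findInterval(s - 1L, scores) + 1L  # first achievable score >= s
    ifelse(i > length(scores), 0, surv[pmax(i, 1L)])
  }
  list(scores = scores, survival = surv, pvalue = pvalue)
}

#' QFAST combined p-value
#'
#' Tail probability that a product of `k` independent uniform p-values is
#' at most the observed product `q = prod(p)`:
#' `q * sum_{i=0}^{k-1} (-ln q)^i / i!`.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return Combined p-value in (0, 1].
#' @examples
#' combinePvaluesQfast(c(0.1, 0.1))  # 0.01 * (1 + log(100))
#' @export
combinePvaluesQfast <- function(pvalues) {
  if (!length(pvalues)) stop("need at least one p-value")
  if (any(pvalues <= 0)) stop("p-values must be > 0")
  if (any(pvalues > 1)) stop("p-values must be <= 1")
  k <- length(pvalues)
  lq <- sum(log(pvalues))
  if (lq == 0) return(1)
  ## q * sum_{i=0}^{k-1} (-lq)^i / i!, accumulated in log space for safety
  term <- 1
  s <- 1
  for (i in seq_len(k - 1L)) {
    term <- term * (-lq) / i
    s <- s + term
  }
  min(1, exp(lq) * s)
}

## Encode a protein sequence as alphabet indices; ambiguity codes are
## handled by scoring as background-weighted averages of their expansions.
AA_AMBIGUITY <- list(B = c("D", "N"), Z = c("E", "Q"), J = c("I", "L"),
                     U = "C", O = "K", X = AA_ALPHABET)

encodeSequence <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  idx <- match(chars, AA_ALPHABET)
  amb <- match(chars, names(AA_AMBIGUITY))
  amb[is.na(idx) & is.na(amb)] <- match("X", names(AA_AMBIGUITY))
  list(idx = idx, amb = amb)
}

## Extend a score matrix with columns for ambiguity codes (background-
## weighted average of the expansion's scores, rounded to integer).
extendScoreMatrix <- function(sm, background) {
  ext <- vapply(names(AA_AMBIGUITY), function(code) {
    cols <- match(AA_AMBIGUITY[[code]], AA_ALPHABET)
    wts <- background[cols] / sum(background[cols])
    as.integer(round(as.matrix(sm[, cols, drop = FALSE]) %*% wts))
  }, integer(nrow(sm)))
  ext <- matrix(ext, nrow = nrow(sm),
                dimnames = list(NULL, names(AA_AMBIGUITY)))
  cbind(sm, ext)
}

#' Scan one protein sequence against a set of motifs
#'
#' For every motif, scores all `length - width + 1` sites with the
#' integer log-odds matrix, converts the best site score to an exact
#' p-value under the background (`site_pvalue`) and to the best-of-m
#' p-value `1 - (1 - site_pvalue)^m`. Best-site p-values of the required
#' motifs are combined with QFAST. The sequence passes the filter when
#' every required motif has `best_pvalue <= site_p` and the combined
#' p-value is `<= combined_p`.
#'
#' @param seq protein sequence (character scalar); ambiguity codes
#'   B/Z/J/U/O/X score as background-weighted averages of their
#'   expansions.
#' @param motifs named list of [MotifMatrix-class] objects.
#' @param required names of motifs that must individually pass; default
#'   `NULL` means motifs `PAL-1`..`PAL-5` when present, otherwise all.
#' @param site_p per-motif best-p-value threshold (default 1e-4).
#' @param combined_p QFAST combined threshold (default 1e-5).
#' @param tables optional precomputed scan tables from [motifScanTables()]
#'   (reuse these when scanning many sequences).
#' @return A list: `sequence_id`-less per-motif hit table `hits`
#'   (motif_id, position, site_score, site_pvalue, best_pvalue),
#'   `combined_pvalue`, `passes_filter`.
#' @export
scanSequence <- function(seq, motifs, required = NULL,
                         site_p = 1e-4, combined_p = 1e-5,
                         tables = NULL) {
  if (is.null(tables)) tables <- motifScanTables(motifs)
  required <- resolveRequired(required, names(tables))
  enc <- encodeSequence(seq)
  n <- length(enc$idx)
  hits <- lapply(names(tables), function(id) {
    tb <- tables[[id]]
    w <- nrow(tb$sm)
    m <- n - w + 1L
    if (m < 1L)
      return(data.frame(motif_id = id, position = NA_integer_,
                        site_score = NA_real_, site_pvalue = NA_real_,
                        best_pvalue = NA_real_))
    s <- numeric(m)
    for (i in seq_len(w)) {
      col <- enc$idx[i:(i + m - 1L)]
      sc <- numeric(m)
      ok <- !is.na(col)
      sc[ok] <- tb$sm[i, ][col[ok]]
      if (any(!ok)) {
        amb <- enc$amb[i:(i + m - 1L)][!ok]
        sc[!ok] <- tb$sm_ext[i, ][amb]
      }
      s <- s + sc
    }
    best <- which.max(s)
    sp <- tb$table$pvalue(s[best])
    sp <- max(sp, .Machine$double.xmin)
    bp <- -expm1(m * log1p(-min(sp, 1)))
    data.frame(motif_id = id, position = best,
               site_score = s[best] / tb$scale,
               site_pvalue = sp, best_pvalue = max(bp, .Machine$double.xmin))
  })
  hits <- do.call(rbind, hits)
  req_p <- hits$best_pvalue[match(required, hits$motif_id)]
  if (anyNA(req_p)) {
    combined <- 1
    passes <- FALSE
  } else {
    combined <- combinePvaluesQfast(pmin(req_p, 1))
    passes <- all(req_p <= site_p) && combined <= combined_p
  }
  list(hits = hits, combined_pvalue = combined, passes_filter = passes)
}

resolveRequired <- function(required, ids) {
  if (!is.null(required)) {
    if (!all(required %in% ids))
      stop("required motifs absent: ",
           paste(setdiff(required, ids), collapse = ", "))
    return(required)
  }
  core <- paste0("PAL-", 1:5)
  if (all(core %in% ids)) core else ids
}

#' Precompute per-motif scanning tables
#'
#' @inheritParams scanSequence
#' @param pseudocount,scale passed to [logOddsMatrix()].
#' @return Named list of per-motif tables for [scanSequence()].
#' @export
motifScanTables <- function(motifs, pseudocount = 0.01, scale = 100) {
  out <- lapply(motifs, function(m) {
    sm <- logOddsMatrix(m, pseudocount = pseudocount, scale = scale)
    sm_ext <- extendScoreMatrix(sm, m@background)[, names(AA_AMBIGUITY),
                                                  drop = FALSE]
    list(sm = sm, sm_ext = sm_ext,
         table = sitePvalueTable(sm, m@background),
         scale = scale)
  })
  names(out) <- vapply(motifs, motifId, character(1))
  out
}

#' Scan many sequences and build motif profiles
#'
#' @param seqs named character vector of protein sequences, or a
#'   `Biostrings::AAStringSet`.
#' @inheritParams scanSequence
#' @return A list with `profiles` (data.frame: sequence_id,
#'   combined_pvalue, passes_filter) and `hits` (per sequence/motif best
#'   hits).
#' @export
scanSequences <- function(seqs, motifs, required = NULL,
                          site_p = 1e-4, combined_p = 1e-5) {
  if (methods::is(seqs, "XStringSet")) {
    nm <- names(seqs)
    seqs <- as.character(seqs)
    names(seqs) <- nm
  }
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named")
  tables <- motifScanTables(motifs)
  res <- lapply(names(seqs), function(id) {
    r <- scanSequence(seqs[[id]], motifs, required = required,
                      site_p = site_p, combined_p = combined_p,
                      tables = tables)
    r$hits$sequence_id <- id
    r
  })
  profiles <- data.frame(
    sequence_id = names(seqs),
    combined_pvalue = vapply(res, `[[`, numeric(1), "combined_pvalue"),
    passes_filter = vapply(res, `[[`, logical(1), "passes_filter"),
    stringsAsFactors = FALSE)
  hits <- do.call(rbind, lapply(res, `[[`, "hits"))
  list(profiles = profiles, hits = hits)
}

#' Scan a FASTA file of proteins against MEME motifs
#'
#' @param fasta path to a protein FASTA file.
#' @param meme path to a MEME-format motif file.
#' @inheritParams scanSequence
#' @return See [scanSequences()].
#' @export
scanFasta <- function(fasta, meme, required = NULL,
                      site_p = 1e-4, combined_p = 1e-5) {
  seqs <- Biostrings::readAAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  motifs <- readMemeMotifs(meme)
  scanSequences(seqs, motifs, required = required,
                site_p = site_p, combined_p = combined_p)
}
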