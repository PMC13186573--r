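#' Read HMMER3 per-domain tabular output (domtblout)
#'
#' Parses the whitespace-delimited per-domain table written by
#' `hmmscan --domtblout`. Only the fields the architecture stage needs are
#' retained. Alignment coordinates are taken from the `ali from`/`ali to`
#' columns (1-based, inclusive); the query length column is kept so the
#' protein length is available downstream.
#'
#' @param path path to a domtblout file.
#' @return A data.frame with columns `protein_id`, `protein_length`,
#'   `domain_name`, `domain_accession`, `ali_start`, `ali_end`,
#'   `i_evalue`, `bit_score` — one row per domain hit. An empty file (or a
#'   file with only comments) yields a zero-row data.frame.
#' @export
readDomtblout <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  out <- emptyDomainHits()
  if (!length(keep)) return(out)
  rows <- lapply(keep, function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 22L)
      stop("malformed domtblout row at line ", i, ": expected >= 22 fields, got ",
           length(f))
    num <- suppressWarnings(as.numeric(f[c(6, 13, 14, 18, 19)]))
    if (anyNA(num))
      stop("malformed domtblout row at line ", i, ": non-numeric field")
    data.frame(protein_id = f[4], protein_length = as.integer(num[1]),
               domain_name = f[1], domain_accession = sub("\\..*$", "", f[2]),
               ali_start = as.integer(num[4]), ali_end = as.integer(num[5]),
               i_evalue = num[2], bit_score = num[3],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  bad <- which(out$ali_start > out$ali_end)
  if (length(bad))
    stop("malformed domtblout row at line ", keep[bad[1]],
         ": ali_start > ali_end")
  rownames(out) <- NULL
  out
}

emptyDomainHits <- function() {
  data.frame(protein_id = character(), protein_length = integer(),
             domain_name = character(), domain_accession = character(),
             ali_start = integer(), ali_end = integer(),
             i_evalue = numeric(), bit_score = numeric(),
             stringsAsFactors = FALSE)
}

#' Write domain hits in HMMER3 domtblout layout
#'
#' Emits a table that [readDomtblout()] parses back bit-identically for the
#' retained fields. Columns not tracked by the package (biases, envelope and
#' HMM coordinates) are filled with placeholder values in the correct
#' positions.
#'
#' @param hits data.frame as returned by [readDomtblout()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeDomtblout <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target"),
    con)
  if (nrow(hits)) {
    lens <- hits$ali_end - hits$ali_start + 1L
    lines <- sprintf(
      "%s %s %d %s - %d %.17g %.17g 0.0 1 1 %.17g %.17g %.17g 0.0 1 %d %d %d %d %d 0.90 -",
      hits$domain_name, hits$domain_accession, lens,
      hits$protein_id, hits$protein_length,
      hits$i_evalue, hits$bit_score, hits$i_evalue, hits$i_evalue,
      hits$bit_score, lens, hits$ali_start, hits$ali_end,
      hits$ali_start, hits$ali_end)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read motifs in MEME minimal text format
#'
#' Supports the minimal motif format (a `MEME version` line, `ALPHABET`,
#' optional `Background letter frequencies` block, and one
#' `MOTIF` / `letter-probability matrix` block per motif). Only the protein
#' alphabet is accepted. When no background block is present a uniform
#' background over the 20 residues is attached.
#'
#' @param path path to a MEME-format motif file.
#' @return A named list of [MotifMatrix-class] objects.
#' @export
readMemeMotifs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^MEME version", lines)))
    stop("not a MEME motif file (missing 'MEME version' line): ", path)
  al <- grep("^ALPHABET\\s*=", lines, value = TRUE)
  if (length(al)) {
    alph <- gsub("\\s", "", sub("^ALPHABET\\s*=", "", al[1]))
    if (!setequal(strsplit(alph, "")[[1]], AA_ALPHABET))
      stop("alphabet is not the 20-letter protein alphabet")
  }
  background <- rep(1 / 20, 20)
  names(background) <- AA_ALPHABET
  bgi <- grep("^Background letter frequencies", lines)
  if (length(bgi)) {
    j <- bgi[1] + 1L
    toks <- character()
    while (j <= length(lines) && !grepl("^\\s*(MOTIF|$)", lines[j])) {
      toks <- c(toks, strsplit(trimws(lines[j]), "\\s+")[[1]])
      j <- j + 1L
    }
    if (length(toks) %% 2L != 0L) stop("malformed background block")
    lett <- toks[seq(1, length(toks), 2)]
    freq <- as.numeric(toks[seq(2, length(toks), 2)])
    if (anyNA(freq)) stop("malformed background block")
    background[lett] <- freq
    if (abs(sum(background) - 1) > 1e-4)
      stop("background frequencies do not sum to 1")
    background <- background / sum(background)
  }
  starts <- grep("^MOTIF\\b", lines)
  motifs <- list()
  for (s in starts) {
    id <- strsplit(trimws(lines[s]), "\\s+")[[1]][2]
    h <- grep("^letter-probability matrix", lines[s:length(lines)])[1]
    if (is.na(h)) stop("motif ", id, ": missing letter-probability matrix")
    h <- s + h - 1L
    hdr <- lines[h]
    w <- as.integer(sub(".*w\\s*=\\s*(\\d+).*", "\\1", hdr))
    ns <- if (grepl("nsites\\s*=", hdr))
      as.integer(sub(".*nsites\\s*=\\s*(\\d+).*", "\\1", hdr)) else 0L
    if (is.na(w)) stop("motif ", id, ": cannot parse matrix width")
    rows <- lines[(h + 1L):(h + w)]
    ppm <- t(vapply(seq_along(rows), function(k) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(rows[k]), "\\s+")[[1]]))
      if (length(v) != 20L || anyNA(v))
        stop("motif ", id, ", matrix line ", k, " (file line ", h + k,
             "): expected 20 probabilities")
      v
    }, numeric(20)))
    colnames(ppm) <- AA_ALPHABET
    ## MEME prints 6 decimals, so written rows can be ~1e-5 off; accept
    ## within 1e-4 and renormalise to the exact in-memory invariant.
    if (any(abs(rowSums(ppm) - 1) > 1e-4))
      stop("motif ", id, ": a matrix row does not sum to 1")
    ppm <- ppm / rowSums(ppm)
    motifs[[id]] <- new("MotifMatrix", motif_id = id, ppm = ppm,
                        background = unname(background), nsites = ns)
  }
  motifs
}

#' Write motifs in MEME minimal text format
#'
#' @param motifs named list of [MotifMatrix-class] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMemeMotifs <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "",
               paste0("ALPHABET= ", paste(AA_ALPHABET, collapse = "")), ""), con)
  bg <- motifs[[1]]@background
  writeLines("Background letter frequencies", con)
  writeLines(paste(sprintf("%s %.6f", AA_ALPHABET, bg), collapse = " "), con)
  writeLines("", con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s", m@motif_id), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 20 w= %d nsites= %d E= 0",
      nrow(m@ppm), m@nsites), con)
    apply(m@ppm, 1L, function(r)
      writeLines(paste(sprintf("%.10f", r), collapse = " "), con))
    writeLines("", con)
  }
  invisible(path)
}

#' Read a Newick tree with validation
#'
#' Thin wrapper around [ape::read.tree()] enforcing the invariants the
#' cophylogeny stage needs: a single tree, unique tip labels and branch
#' lengths on every edge.
#'
#' @param path path to a Newick file containing one tree.
#' @param zero_missing when `TRUE`, edges without a length are assigned 0
#'   instead of raising an error.
#' @return An [ape::phylo] object.
#' @export
readNewickTree <- function(path, zero_missing = FALSE) {
  tr <- tryCatch(ape::read.tree(path), error = function(e)
    stop("cannot parse Newick file ", path, ": ", conditionMessage(e)))
  if (is.null(tr)) stop("cannot parse Newick file ", path)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L) stop("expected a single tree in ", path)
    tr <- tr[[1]]
  }
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels in ", path, ": ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (is.null(tr$edge.length) || anyNA(tr$edge.length)) {
    if (!zero_missing)
      stop("tree in ", path, " has missing branch lengths ",
           "(set zero_missing = TRUE to substitute 0)")
    if (is.null(tr$edge.length))
      tr$edge.length <- rep(0, nrow(tr$edge))
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  if (any(tr$edge.length < 0))
    stop("tree in ", path, " has negative branch lengths")
  tr
}

GENE_TABLE_COLS <- c("genome_id", "replicon_id", "position_index",
                     "strand", "gene_id", "protein_id")

validateGeneTable <- function(genes, where = "gene table") {
  if (!all(GENE_TABLE_COLS %in% names(genes)))
    stop(where, ": missing columns ",
         paste(setdiff(GENE_TABLE_COLS, names(genes)), collapse = ", "))
  if (nrow(genes) && !all(genes$strand %in% c("+", "-")))
    stop(where, ": strand must be '+' or '-'")
  for (g in unique(genes$genome_id)) {
    sub <- genes[genes$genome_id == g, ]
    if (anyDuplicated(sub$gene_id))
      stop(where, ": duplicated gene_id within genome ", g)
    for (r in unique(sub$replicon_id)) {
      p <- sort(sub$position_index[sub$replicon_id == r])
      if (!identical(as.integer(p), seqize(length(p))))
        stop(where, ": position_index not contiguous 0..n-1 on ",
             g, "/", r)
    }
  }
  genes
}

seqize <- function(n) if (n == 0L) integer() else 0:(n - 1L)

#' Read or write a gene-order table
#'
#' A gene table is a TSV with columns `genome_id`, `replicon_id`,
#' `position_index`, `strand`, `gene_id`, `protein_id`. `position_index`
#' is a 0-based gene ordinal, contiguous within each replicon; it is an
#' ordering, not a nucleotide coordinate.
#'
#' @param path path to a TSV file.
#' @return `readGeneTable` returns the validated data.frame.
#' @export
readGeneTable <- function(path) {
  genes <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = c(position_index = "integer"))
  validateGeneTable(genes, where = path)
}

#' @rdname readGeneTable
#' @param genes a gene table data.frame.
#' @return `writeGeneTable` returns `path`, invisibly.
#' @export
writeGeneTable <- function(genes, path) {
  validateGeneTable(genes)
  utils::write.table(genes[, GENE_TABLE_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Derive a gene table from a GFF3 file
#'
#' Convenience reader: gene features are ordered by ascending start
#' coordinate within each seqid to assign `position_index`; strand is taken
#' from the GFF strand column. Requires the `rtracklayer` package.
#'
#' @param path path to a GFF3 file.
#' @param genome_id genome identifier to record (default: file base name).
#' @param feature_type GFF3 feature type to keep (default `"gene"`).
#' @return A validated gene table data.frame.
#' @export
gff3ToGeneTable <- function(path, genome_id = NULL, feature_type = "gene") {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("gff3ToGeneTable requires the rtracklayer package")
  if (is.null(genome_id))
    genome_id <- sub("\\.gff3?$", "", basename(path))
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == feature_type]
  if (!length(gr)) stop("no '", feature_type, "' features in ", path)
  ids <- if (!is.null(gr$ID)) gr$ID else gr$Name
  if (is.null(ids) || anyNA(ids)) stop("gene features must carry an ID attribute")
  df <- data.frame(
    genome_id = genome_id,
    replicon_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = as.character(ids),
    stringsAsFactors = FALSE)
  df$strand[!df$strand %in% c("+", "-")] <- "+"
  df <- df[order(df$replicon_id, df$start), ]
  df$position_index <- stats::ave(df$start, df$replicon_id,
                                  FUN = function(x) seq_along(x) - 1L)
  df$position_index <- as.integer(df$position_index)
  df$protein_id <- df$gene_id
  validateGeneTable(df[, GENE_TABLE_COLS], where = path)
}

#' Read a tip-association (link) table
#'
#' A link table pairs tips of two phylogenies (columns `tip_a`, `tip_b`).
#' With `trees` supplied, every `tip_a` must exist in the first tree and
#' every `tip_b` in the second.
#'
#' @param path path to a TSV file with columns `tip_a` and `tip_b`.
#' @param tree_a,tree_b optional [ape::phylo] trees to validate against.
#' @return data.frame with columns `tip_a`, `tip_b`.
#' @export
readLinkTable <- function(path, tree_a = NULL, tree_b = NULL) {
  links <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("tip_a", "tip_b") %in% names(links)))
    stop(path, ": link table needs columns tip_a, tip_b")
  if (!is.null(tree_a) && !all(links$tip_a %in% tree_a$tip.label))
    stop(path, ": tip_a values absent from tree A: ",
         paste(setdiff(links$tip_a, tree_a$tip.label), collapse = ", "))
  if (!is.null(tree_b) && !all(links$tip_b %in% tree_b$tip.label))
    stop(path, ": tip_b values absent from tree B: ",
         paste(setdiff(links$tip_b, tree_b$tip.label), collapse = ", "))
  links[, c("tip_a", "tip_b")]
}
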