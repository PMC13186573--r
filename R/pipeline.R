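## End-to-end orchestration: the detection funnel (architectures ->
## motifs -> contexts -> configurations) and the coevolution chain
## (trees -> PACo -> bands -> association), each with a run manifest.

runManifest <- function(stage, seeds = list(), counts = list(),
                        files = character()) {
  list(stage = stage,
       tool_version = as.character(utils::packageVersion("PAApipe")),
       timestamp = format(Sys.time(), tz = "UTC"),
       seeds = seeds, counts = counts,
       files = if (length(files))
         data.frame(path = files, md5 = unname(tools::md5sum(files)),
                    stringsAsFactors = FALSE)
       else data.frame(path = character(), md5 = character()))
}

#' Run the PAL detection funnel
#'
#' Executes the three evidence stages in order — architecture
#' recognition, motif scanning, genomic-context classification — and
#' reports the funnel counts at each stage together with a run manifest.
#'
#' @param hits domain-hit data.frame ([readDomtblout()] layout).
#' @param genes gene table ([readGeneTable()] layout).
#' @param sequences named character vector (or `AAStringSet`) of the
#'   protein sequences to motif-scan; proteins without a sequence are
#'   scanned as failures. Scanning is restricted to PAL-architecture
#'   candidates.
#' @param motifs named list of [MotifMatrix-class].
#' @param role_map see [defaultRoleMap()].
#' @param rules see [defaultConfigurationRules()].
#' @param W context half-window (default 20).
#' @param site_p,combined_p motif thresholds, see [scanSequence()].
#' @param out_dir optional directory; when given, the configuration and
#'   co-occurrence tables are written there as TSV and checksummed in the
#'   manifest.
#' @return list with `candidates` (the [palCandidatePipeline()] table),
#'   `funnel` (named counts: architecture_pal, motif_pass,
#'   context_retained), `cooccurrence`, `arch_table`, `profiles`,
#'   `manifest`.
#' @export
runDetect <- function(hits, genes, sequences, motifs,
                      role_map = defaultRoleMap(),
                      rules = defaultConfigurationRules(),
                      W = 20L, site_p = 1e-4, combined_p = 1e-5,
                      out_dir = NULL) {
  arch <- architectureTable(hits, role_map = role_map)
  pal_ids <- arch$protein_id[arch$is_pal]
  if (methods::is(sequences, "XStringSet")) {
    nm <- names(sequences)
    sequences <- as.character(sequences)
    names(sequences) <- nm
  }
  scan_ids <- intersect(pal_ids, names(sequences))
  profiles <- if (length(scan_ids)) {
    scanSequences(sequences[scan_ids], motifs,
                  site_p = site_p, combined_p = combined_p)$profiles
  } else {
    data.frame(sequence_id = character(), combined_pvalue = numeric(),
               passes_filter = logical(), stringsAsFactors = FALSE)
  }
  missing_seq <- setdiff(pal_ids, names(sequences))
  if (length(missing_seq))
    profiles <- rbind(profiles,
                      data.frame(sequence_id = missing_seq,
                                 combined_pvalue = 1,
                                 passes_filter = FALSE,
                                 stringsAsFactors = FALSE))
  candidates <- palCandidatePipeline(arch, profiles, genes,
                                     rules = rules, W = W)
  genes$role <- arch$role[match(genes$protein_id, arch$protein_id)]
  contexts <- lapply(candidates$gene_id[candidates$retained],
                     function(a) extractContext(genes, a, W = W))
  cooc <- if (length(contexts)) coOccurrenceSummary(contexts, genes)
          else NULL
  funnel <- c(architecture_pal = length(pal_ids),
              motif_pass = sum(profiles$passes_filter),
              context_retained = sum(candidates$retained))
  files <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    f1 <- file.path(out_dir, "configurations.tsv")
    utils::write.table(candidates, f1, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- f1
    if (!is.null(cooc)) {
      f2 <- file.path(out_dir, "cooccurrence.tsv")
      utils::write.table(cooc$combinations, f2, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      files <- c(files, f2)
    }
  }
  list(candidates = candidates, funnel = funnel, cooccurrence = cooc,
       arch_table = arch, profiles = profiles,
       manifest = runManifest("detect",
                              counts = as.list(funnel), files = files))
}

#' Run the coevolution chain
#'
#' PACo on the two marker trees, residual banding, and (when a
#' configuration label per link is supplied) the categorical association
#' between configuration and residual band.
#'
#' @param tree_a,tree_c the two gene trees ([ape::phylo]).
#' @param links link table (columns `tip_a`, `tip_b`); default identity
#'   over shared tips.
#' @param configurations optional character vector, one configuration
#'   label per link (in link order), enabling the association stage.
#' @param nperm,seed PACo permutations and seed (defaults 1000 / 42).
#' @param assoc_nperm permutations for the independence test (default
#'   9999).
#' @param band_thresholds optional fixed band thresholds, see
#'   [classifyResiduals()].
#' @param out_prefix optional path prefix for a tanglegram bundle.
#' @return list with `paco` ([PACoResult-class]), `bands`
#'   ([ResidualBands-class]), `rf` (normalized Robinson-Foulds, when tip
#'   sets match), `association` (or `NULL`), `manifest`.
#' @export
runCoevolution <- function(tree_a, tree_c, links = NULL,
                           configurations = NULL,
                           nperm = 1000L, seed = 42L,
                           assoc_nperm = 9999L,
                           band_thresholds = NULL,
                           out_prefix = NULL) {
  pr <- paco(tree_a, tree_c, links = links, nperm = nperm, seed = seed)
  bands <- classifyResiduals(pr, thresholds = band_thresholds)
  rf <- if (setequal(tree_a$tip.label, tree_c$tip.label))
    normalizedRF(tree_a, tree_c) else NA_real_
  association <- NULL
  if (!is.null(configurations)) {
    if (length(configurations) != length(pr@residuals))
      stop("need one configuration label per link")
    tab <- table(configuration = configurations,
                 band = as.character(bandOf(bands)))
    association <- list(
      table = tab,
      cramers_v = cramersV(tab, drop_empty = TRUE),
      chi2 = chi2Test(tab, drop_empty = TRUE),
      permutation = permutationIndependence(configurations,
                                            as.character(bandOf(bands)),
                                            nperm = assoc_nperm,
                                            seed = seed),
      std_residuals = standardizedResiduals(tab, drop_empty = TRUE))
  }
  files <- character()
  if (!is.null(out_prefix))
    files <- exportTanglegram(tree_a, tree_c, pr, bands, out_prefix)
  list(paco = pr, bands = bands, rf = rf, association = association,
       manifest = runManifest("coevolution",
                              seeds = list(paco = seed),
                              counts = list(links = length(pr@residuals)),
                              files = files))
}
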