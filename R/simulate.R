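## Synthetic-data generator: emulates every input the pipeline consumes
## (gene tables with planted paa clusters, domain-hit tables, protein
## sequences with planted motifs, codiverging tree pairs, paired
## configuration/band labels), with truth labels for every planted item.

#' Average amino-acid composition used as the simulation background
#'
#' A fixed, published-style average protein composition (Robinson &
#' Robinson-type frequencies, normalised to sum to 1), shipped as data so
#' simulations are reproducible without any download.
#'
#' @return named numeric vector over the 20 residues.
#' @export
aaBackground <- function() {
  f <- c(A = 0.0785, C = 0.0152, D = 0.0535, E = 0.0668, F = 0.0397,
         G = 0.0695, H = 0.0229, I = 0.0590, K = 0.0590, L = 0.0962,
         M = 0.0239, N = 0.0426, P = 0.0483, Q = 0.0393, R = 0.0514,
         S = 0.0715, T = 0.0553, V = 0.0667, W = 0.0110, Y = 0.0297)
  f / sum(f)
}

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-data generator. The
#' defaults describe the conditions the pipeline is meant to work under:
#' 200-gene replicons with one planted paa cluster per genome, a
#' configuration mixture dominated by complete pathways, mild cluster
#' interruption, clean coordinates, ten motifs of width 6-30 planted in
#' every positive sequence, and 30-tip codiverging tree pairs with two
#' discordant tip swaps and mild branch-length noise.
#'
#' @param seed integer RNG seed.
#' @param n_genomes number of genomes to simulate.
#' @param genes_per_replicon background replicon size in genes.
#' @param configuration_mix named probabilities over FP/UP/EM/PM/OC.
#' @param regulator_mix named probabilities over PaaR-X/PaaX/PaaR/NP.
#' @param paaY_prob probability a planted cluster carries PaaY.
#' @param decoy_rate expected AMP-binding-only decoy genes per genome
#'   (Poisson).
#' @param interruption_prob probability that a background gene interrupts
#'   a planted cluster.
#' @param gene_deletion_prob per-gene probability of deleting a planted
#'   cluster gene (0 = clean clusters).
#' @param overlap_noise_rate per-gene probability of a spurious
#'   overlapping domain hit.
#' @param n_motifs,motif_width_range number and width range of simulated
#'   motifs. The default 12-30 reflects that family-discriminating motifs
#'   reported by MEME embed their short (6-residue) conserved cores in
#'   wider motifs; a 6-wide motif cannot, even at consensus, clear the
#'   default site p-value threshold in a 500-residue sequence.
#' @param anchor_prob probability mass of each motif column's anchor
#'   residue (controls information content; 0.95 models the
#'   near-invariant columns of conserved catalytic motifs).
#' @param seq_length,plant_prob background sequence length and the
#'   probability a sequence is a positive (receives all motifs).
#' @param n_tips,birth_rate,n_tip_swaps,bl_sigma tree-pair parameters:
#'   tips, Yule birth rate, discordant tip-pair swaps, lognormal sdlog of
#'   multiplicative branch-length noise.
#' @return validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(seed = 1L,
                             n_genomes = 20L,
                             genes_per_replicon = 200L,
                             configuration_mix = c(FP = 0.35, UP = 0.20,
                                                   EM = 0.15, PM = 0.15,
                                                   OC = 0.15),
                             regulator_mix = c(`PaaR-X` = 0.10,
                                               PaaX = 0.35,
                                               PaaR = 0.30, NP = 0.25),
                             paaY_prob = 0.30,
                             decoy_rate = 1.0,
                             interruption_prob = 0.10,
                             gene_deletion_prob = 0,
                             overlap_noise_rate = 0.10,
                             n_motifs = 10L,
                             motif_width_range = c(12L, 30L),
                             anchor_prob = 0.95,
                             seq_length = 500L,
                             plant_prob = 0.5,
                             n_tips = 30L,
                             birth_rate = 1,
                             n_tip_swaps = 2L,
                             bl_sigma = 0.05) {
  cfg <- list(seed = as.integer(seed), n_genomes = as.integer(n_genomes),
              genes_per_replicon = as.integer(genes_per_replicon),
              configuration_mix = configuration_mix,
              regulator_mix = regulator_mix,
              paaY_prob = paaY_prob, decoy_rate = decoy_rate,
              interruption_prob = interruption_prob,
              gene_deletion_prob = gene_deletion_prob,
              overlap_noise_rate = overlap_noise_rate,
              n_motifs = as.integer(n_motifs),
              motif_width_range = as.integer(motif_width_range),
              anchor_prob = anchor_prob,
              seq_length = as.integer(seq_length),
              plant_prob = plant_prob,
              n_tips = as.integer(n_tips), birth_rate = birth_rate,
              n_tip_swaps = as.integer(n_tip_swaps), bl_sigma = bl_sigma)
  probs <- c(cfg$paaY_prob, cfg$interruption_prob, cfg$gene_deletion_prob,
             cfg$overlap_noise_rate, cfg$plant_prob, cfg$anchor_prob)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (abs(sum(configuration_mix) - 1) > 1e-6)
    stop("configuration_mix must sum to 1")
  if (!setequal(names(configuration_mix), c("FP", "UP", "EM", "PM", "OC")))
    stop("configuration_mix must name FP, UP, EM, PM, OC")
  if (abs(sum(regulator_mix) - 1) > 1e-6)
    stop("regulator_mix must sum to 1")
  if (!setequal(names(regulator_mix), c("PaaR-X", "PaaX", "PaaR", "NP")))
    stop("regulator_mix must name PaaR-X, PaaX, PaaR, NP")
  if (cfg$motif_width_range[1] < 6L || cfg$motif_width_range[2] > 30L ||
      cfg$motif_width_range[1] > cfg$motif_width_range[2])
    stop("motif widths must lie within [6, 30]")
  structure(cfg, class = "SimulationConfig")
}

## Cluster layout templates per configuration, modelled on the gene
## organisation of experimentally characterised clusters (E. coli-style
## order for FP). PaaG_PaaF appears twice in FP (one copy acts as PaaG,
## one as PaaF); regulators and PaaY are appended by the caller.
configurationTemplate <- function(configuration) {
  switch(configuration,
    FP = c("PaaZ", "PaaA_PaaC", "PaaB", "PaaA_PaaC", "PaaD", "PaaE",
           "PaaG_PaaF", "PaaG_PaaF", "PaaH", "PaaI", "PaaJ", "PAL"),
    UP = c("PaaZ", "PaaA_PaaC", "PaaB", "PaaA_PaaC", "PaaD", "PaaE",
           "PaaG_PaaF", "PAL"),
    EM = c("PaaA_PaaC", "PaaB", "PaaA_PaaC", "PaaD", "PaaE", "PAL"),
    PM = c("PaaA_PaaC", "PaaA_PaaC", "PAL"),
    OC = c("PaaI", "PaaH", "PAL"),
    stop("unknown configuration ", configuration))
}

regulatorGenes <- function(state) {
  switch(state,
    `PaaR-X` = c("PaaX", "PaaR"),
    PaaX = "PaaX", PaaR = "PaaR", NP = character())
}

#' Simulate genomes with planted paa clusters
#'
#' Each genome is one replicon of background genes with one planted paa
#' cluster drawn from the configuration mixture, laid out from
#' experimentally motivated templates, with regulators and PaaY appended
#' per the regulator mixture and `paaY_prob`, optional interrupting
#' background genes inside the cluster, optional deletions of planted
#' genes, and Poisson-many AMP-binding-only decoy genes elsewhere.
#'
#' @param cfg a [simulationConfig()].
#' @return list with `genes` (gene table incl. a hidden truth `role`
#'   column NA for background), and `truth` (data.frame: genome_id,
#'   anchor gene, intended configuration, regulator state, PaaY flag).
#' @export
simulateGenomes <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  withSeed(cfg$seed + 101L, {
    genes_list <- list(); truth_list <- list()
    for (g in seq_len(cfg$n_genomes)) {
      gid <- sprintf("gen%03d", g)
      configuration <- sample(names(cfg$configuration_mix), 1L,
                              prob = cfg$configuration_mix)
      reg <- sample(names(cfg$regulator_mix), 1L, prob = cfg$regulator_mix)
      paaY <- stats::runif(1) < cfg$paaY_prob
      roles <- configurationTemplate(configuration)
      roles <- c(roles, regulatorGenes(reg), if (paaY) "PaaY")
      if (cfg$gene_deletion_prob > 0) {
        keep <- stats::runif(length(roles)) >= cfg$gene_deletion_prob |
          roles == "PAL"  # the anchor itself is never deleted
        roles <- roles[keep]
      }
      ## interruptions: background genes inserted inside the cluster
      cluster <- character()
      for (r in roles) {
        if (length(cluster) &&
            stats::runif(1) < cfg$interruption_prob)
          cluster <- c(cluster, NA_character_)
        cluster <- c(cluster, r)
      }
      n_bg <- cfg$genes_per_replicon
      n_decoy <- stats::rpois(1, cfg$decoy_rate)
      total_bg <- n_bg
      insert_at <- sample.int(total_bg - 1L, 1L)
      role_vec <- c(rep(NA_character_, insert_at), cluster,
                    rep(NA_character_, total_bg - insert_at))
      if (n_decoy > 0) {
        bg_pos <- which(is.na(role_vec))
        dec <- sample(bg_pos, min(n_decoy, length(bg_pos)))
        role_vec[dec] <- "decoy_ANL"
      }
      n <- length(role_vec)
      gene_ids <- sprintf("%s_g%04d", gid, seq_len(n))
      df <- data.frame(
        genome_id = gid, replicon_id = "chr1",
        position_index = seqize(n),
        strand = sample(c("+", "-"), n, replace = TRUE),
        gene_id = gene_ids,
        protein_id = sprintf("%s_p%04d", gid, seq_len(n)),
        role = role_vec,
        stringsAsFactors = FALSE)
      anchor <- df$gene_id[which(df$role == "PAL")[1]]
      genes_list[[g]] <- df
      truth_list[[g]] <- data.frame(
        genome_id = gid, anchor = anchor,
        configuration = configuration, regulator_state = reg,
        paaY_present = paaY, stringsAsFactors = FALSE)
    }
    list(genes = do.call(rbind, genes_list),
         truth = do.call(rbind, truth_list))
  })
}

## Canonical domain-hit layouts per role: accession, name, start, end,
## protein length. Coordinates are jittered at emission.
roleHitTemplates <- function() {
  list(
    PAL = list(len = 440L, hits = list(
      c("PF00501", "AMP-binding", 8, 330),
      c("PF14535", "AMP-binding_C_2", 350, 425))),
    decoy_ANL = list(len = 540L, hits = list(
      c("PF00501", "AMP-binding", 10, 420))),
    PaaA_PaaC = list(len = 300L, hits = list(
      c("PF05138", "PaaA_PaaC", 15, 280))),
    PaaB = list(len = 95L, hits = list(
      c("PF06243", "PaaB", 5, 90))),
    PaaD = list(len = 165L, hits = list(
      c("PF01883", "FeS_assembly_P", 10, 150))),
    PaaE = list(len = 356L, hits = list(
      c("PF00970", "FAD_binding_6", 8, 105),
      c("PF00175", "NAD_binding_1", 120, 230))),
    PaaG_PaaF = list(len = 262L, hits = list(
      c("PF00378", "ECH_1", 10, 240))),
    PaaH = list(len = 475L, hits = list(
      c("PF02737", "3HCDH_N", 8, 185),
      c("PF00725", "3HCDH", 200, 380))),
    PaaI = list(len = 140L, hits = list(
      c("PF03061", "4HBT", 15, 125))),
    PaaJ = list(len = 401L, hits = list(
      c("PF00108", "Thiolase_N", 5, 260),
      c("PF02803", "Thiolase_C", 270, 395))),
    PaaZ = list(len = 681L, hits = list(
      c("PF00171", "Aldedh", 10, 450),
      c("PF00378", "ECH_1", 470, 650))),
    PaaY = list(len = 196L, hits = list(
      c("PF00132", "Hexapep", 30, 160))),
    PaaX = list(len = 316L, hits = list(
      c("PF07848", "PaaX", 20, 180),
      c("PF08223", "PaaX_C", 200, 300))),
    PaaR = list(len = 210L, hits = list(
      c("PF00440", "TetR_N", 10, 70)))
  )
}

#' Simulate a domain-hit table for simulated genomes
#'
#' Every gene with a pathway role emits its architecture's hits with
#' jittered coordinates and small i-Evalues; spurious overlapping hits
#' are added at `overlap_noise_rate`, half above the 0.001 e-value
#' threshold (so the filter must remove them) and half below but strictly
#' nested inside a true tile (so maximal-coverage tiling must exclude
#' them). Background genes receive a generic non-pathway hit.
#'
#' @param genes gene table from [simulateGenomes()] (with `role` column).
#' @param cfg a [simulationConfig()].
#' @return domain-hit data.frame in [readDomtblout()] layout.
#' @export
simulateDomainHits <- function(genes, cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  tpl <- roleHitTemplates()
  withSeed(cfg$seed + 202L, {
    rows <- list()
    for (i in seq_len(nrow(genes))) {
      role <- genes$role[i]
      pid <- genes$protein_id[i]
      if (is.na(role)) {
        if (stats::runif(1) < 0.3) {
          rows[[length(rows) + 1L]] <- data.frame(
            protein_id = pid, protein_length = 320L,
            domain_name = "DUF1234", domain_accession = "PF91234",
            ali_start = 20L, ali_end = 300L,
            i_evalue = 10^stats::runif(1, -30, -5), bit_score = 80,
            stringsAsFactors = FALSE)
        }
        next
      }
      t <- tpl[[role]]
      for (h in t$hits) {
        jit <- sample(-3:3, 2L, replace = TRUE)
        a <- max(1L, as.integer(h[3]) + jit[1])
        b <- min(t$len, as.integer(h[4]) + jit[2])
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = pid, protein_length = t$len,
          domain_name = h[2], domain_accession = h[1],
          ali_start = a, ali_end = b,
          i_evalue = 10^stats::runif(1, -60, -10),
          bit_score = round(stats::runif(1, 50, 400), 1),
          stringsAsFactors = FALSE)
      }
      if (stats::runif(1) < cfg$overlap_noise_rate) {
        ## spurious hit nested inside the first true tile
        h1 <- t$hits[[1]]
        a0 <- as.integer(h1[3]); b0 <- as.integer(h1[4])
        span <- b0 - a0
        a <- a0 + sample.int(max(1L, span %/% 4L), 1L)
        b <- a + max(5L, span %/% 3L)
        above <- stats::runif(1) < 0.5
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = pid, protein_length = t$len,
          domain_name = "Spurious", domain_accession = "PF99999",
          ali_start = a, ali_end = min(b, b0 - 1L),
          i_evalue = if (above) 10^stats::runif(1, -2.5, -0.5)
                     else 10^stats::runif(1, -8, -4),
          bit_score = round(stats::runif(1, 5, 25), 1),
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

## Sample a motif PPM with one anchor residue per column.
sampleMotif <- function(id, width, anchor_prob, background) {
  anchors <- sample.int(20L, width, replace = TRUE, prob = background)
  ppm <- matrix((1 - anchor_prob) / 19, nrow = width, ncol = 20L)
  ppm[cbind(seq_len(width), anchors)] <- anchor_prob
  colnames(ppm) <- AA_ALPHABET
  new("MotifMatrix", motif_id = id, ppm = ppm,
      background = unname(background), nsites = 50L)
}

#' Simulate protein sequences with planted motifs
#'
#' Samples `n_motifs` motifs (widths within the configured range, one
#' anchor residue per column at `anchor_prob`), then generates sequences
#' from the background composition; positives additionally receive one
#' sampled site of every motif at random non-overlapping positions.
#'
#' @param cfg a [simulationConfig()].
#' @param n_sequences number of sequences to generate.
#' @return list with `sequences` (named character vector), `motifs`
#'   (named [MotifMatrix-class] list, ids `PAL-1`..), and `truth`
#'   (data.frame: sequence_id, positive).
#' @export
simulateSequencesWithMotifs <- function(cfg, n_sequences = 100L) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  bg <- aaBackground()
  withSeed(cfg$seed + 303L, {
    widths <- sample(cfg$motif_width_range[1]:cfg$motif_width_range[2],
                     cfg$n_motifs, replace = TRUE)
    motifs <- lapply(seq_len(cfg$n_motifs), function(i)
      sampleMotif(paste0("PAL-", i), widths[i], cfg$anchor_prob, bg))
    names(motifs) <- paste0("PAL-", seq_len(cfg$n_motifs))
    seqs <- character(n_sequences)
    positive <- stats::runif(n_sequences) < cfg$plant_prob
    for (s in seq_len(n_sequences)) {
      chars <- sample(AA_ALPHABET, cfg$seq_length, replace = TRUE,
                      prob = bg)
      if (positive[s]) {
        ## place every motif at non-overlapping positions (greedy)
        taken <- rep(FALSE, cfg$seq_length)
        for (m in motifs) {
          w <- motifWidth(m)
          ok <- which(vapply(seq_len(cfg$seq_length - w + 1L), function(p)
            !any(taken[p:(p + w - 1L)]), logical(1)))
          if (!length(ok)) next
          p <- sample(ok, 1L)
          site <- vapply(seq_len(w), function(i)
            sample(AA_ALPHABET, 1L, prob = motifPPM(m)[i, ]), character(1))
          chars[p:(p + w - 1L)] <- site
          taken[p:(p + w - 1L)] <- TRUE
        }
      }
      seqs[s] <- paste(chars, collapse = "")
    }
    names(seqs) <- sprintf("seq%04d", seq_len(n_sequences))
    list(sequences = seqs, motifs = motifs,
         truth = data.frame(sequence_id = names(seqs),
                            positive = positive,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate a codiverging tree pair with planted discordance
#'
#' Tree A is a Yule tree; tree C is a copy whose branch lengths receive
#' multiplicative lognormal noise and in which `n_tip_swaps` disjoint
#' random tip pairs exchange labels. The swapped tips are the planted
#' discordant links.
#'
#' @param cfg a [simulationConfig()].
#' @param seed optional seed overriding `cfg$seed` (useful for
#'   replicates).
#' @return list with `tree_a`, `tree_c` ([ape::phylo]) and `swapped`
#'   (character vector of tips involved in swaps).
#' @export
simulateTreePair <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  seed <- if (is.null(seed)) cfg$seed + 404L else as.integer(seed)
  withSeed(seed, {
    tree_a <- ape::rphylo(cfg$n_tips, birth = cfg$birth_rate, death = 0)
    tree_a$tip.label <- sprintf("t%03d", seq_len(cfg$n_tips))
    tree_c <- tree_a
    if (cfg$bl_sigma > 0)
      tree_c$edge.length <- tree_c$edge.length *
        stats::rlnorm(length(tree_c$edge.length), 0, cfg$bl_sigma)
    swapped <- character()
    if (cfg$n_tip_swaps > 0) {
      ## Swap only tips at least the median patristic distance apart:
      ## exchanging sister (or near-sister) tips relabels the tree without
      ## creating any discordance, so such "swaps" would carry a false
      ## truth label. Distant exchanges emulate transfer between
      ## lineages and give every planted link a real signal.
      D <- ape::cophenetic.phylo(tree_a)
      dmin <- stats::median(D[upper.tri(D)])
      pool <- sample(tree_c$tip.label)
      for (k in seq_len(cfg$n_tip_swaps)) {
        if (length(pool) < 2L) break
        a <- pool[1L]
        far <- pool[-1L][D[a, pool[-1L]] >= dmin]
        if (!length(far)) { pool <- pool[-1L]; next }
        b <- far[1L]
        pool <- setdiff(pool, c(a, b))
        i <- match(c(a, b), tree_c$tip.label)
        tree_c$tip.label[i] <- c(b, a)
        swapped <- c(swapped, a, b)
      }
    }
    list(tree_a = tree_a, tree_c = tree_c, swapped = swapped)
  })
}

#' Simulate paired configuration / residual-band labels
#'
#' Configuration labels are drawn from a fixed marginal; the residual
#' band is drawn, with probability `effect`, from a configuration-specific
#' point distribution (each configuration preferring its own band; five
#' bands including `extreme` so supports can be disjoint) and otherwise
#' from the pooled band marginal. `effect = 0` gives exact independence;
#' `effect = 1` gives a deterministic configuration-to-band map.
#'
#' @param effect association strength in [0, 1].
#' @param n number of pairs.
#' @param seed RNG seed.
#' @param config_marginal named probabilities over the five
#'   configurations.
#' @param band_marginal named probabilities over the five bands used for
#'   the independent draws.
#' @return data.frame with columns `configuration`, `band`.
#' @export
simulateConfigResidualPairs <- function(effect, n, seed = 1L,
    config_marginal = c(FP = 0.40, UP = 0.20, EM = 0.15, PM = 0.15,
                        OC = 0.10),
    band_marginal = c(low = 0.25, medium = 0.40, `upper-medium` = 0.15,
                      high = 0.12, extreme = 0.08)) {
  stopifnot(effect >= 0, effect <= 1)
  bands <- names(band_marginal)
  configs <- names(config_marginal)
  preferred <- stats::setNames(bands[seq_along(configs)], configs)
  withSeed(as.integer(seed), {
    configuration <- sample(configs, n, replace = TRUE,
                            prob = config_marginal)
    from_effect <- stats::runif(n) < effect
    band <- character(n)
    band[from_effect] <- preferred[configuration[from_effect]]
    band[!from_effect] <- sample(bands, sum(!from_effect), replace = TRUE,
                                 prob = band_marginal)
    data.frame(configuration = configuration, band = band,
               stringsAsFactors = FALSE)
  })
}
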