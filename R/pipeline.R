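# Orchestration: validated run configuration and the end-to-end
# simulate -> scan -> classify -> idmatrix/phylo -> tandem/synteny -> expr
# pipeline with a machine-readable run report.

.CONFIG_DEFAULTS <- function() list(
  seed = 1,
  scan = list(pairing_window_min = 10, pairing_window_max = 60,
              min_coverage = 0.60, max_evalue = 1e-5),
  classify = list(gly_threshold = 0.20),
  phylo = list(min_occupancy = 0.70, dist_model = "poisson", boot_reps = 1000),
  tandem = list(max_intervening = 10, max_bp = 200000),
  synteny = list(flank_k = 10, min_support = 2, prescreen_kmer = 4),
  expression = list(calibrator = "leaf"),
  simulate = list(n_iva = 5, n_ivb = 3, n_ivc = 2, n_ivd = 3,
                  n_background = 50, gly_members = 0.45, gly_background = 0.10,
                  chrom_count = 3, genes_per_chrom = 65,
                  synteny_block_len = 20, rearrangement_rate = 0.05,
                  relocated_members = 0, substitution_rate = 0.05,
                  ct_noise_sd = 0.2)
)

#' Validate a raw pipeline configuration
#'
#' Fills defaults (domain-filter coverage 0.60 and E-value 1e-5, glycine
#' threshold 0.20, tandem rule 10 genes / 200 kb, 1000 bootstrap replicates,
#' 0.70 column occupancy, ...), rejects unknown keys, and reports every
#' violation at once.
#'
#' @param raw Possibly-nested list of overrides (may be empty).
#' @return Fully populated configuration list of class \code{RunConfig}.
#' @export
validateConfig <- function(raw = list()) {
  cfg <- .CONFIG_DEFAULTS()
  errs <- character()
  for (key in names(raw)) {
    if (!key %in% names(cfg)) {
      errs <- c(errs, paste0("unknown key '", key, "'"))
      next
    }
    if (key == "seed") { cfg$seed <- raw$seed; next }
    for (sub in names(raw[[key]])) {
      if (!sub %in% names(cfg[[key]]))
        errs <- c(errs, paste0("unknown key '", key, ".", sub, "'"))
      else cfg[[key]][[sub]] <- raw[[key]][[sub]]
    }
  }
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1, "seed must be a number")
  chk(cfg$scan$min_coverage >= 0 && cfg$scan$min_coverage <= 1,
      "scan.min_coverage must be in [0,1]")
  chk(cfg$scan$max_evalue >= 0, "scan.max_evalue must be >= 0")
  chk(cfg$scan$pairing_window_min <= cfg$scan$pairing_window_max,
      "scan.pairing_window_min must not exceed scan.pairing_window_max")
  chk(cfg$classify$gly_threshold >= 0 && cfg$classify$gly_threshold <= 1,
      "classify.gly_threshold must be in [0,1]")
  chk(cfg$phylo$min_occupancy > 0 && cfg$phylo$min_occupancy <= 1,
      "phylo.min_occupancy must be in (0,1]")
  chk(cfg$phylo$dist_model %in% c("poisson", "p"),
      "phylo.dist_model must be 'poisson' or 'p'")
  chk(cfg$phylo$boot_reps >= 0, "phylo.boot_reps must be >= 0")
  chk(cfg$tandem$max_intervening >= 0, "tandem.max_intervening must be >= 0")
  chk(cfg$tandem$max_bp > 0, "tandem.max_bp must be > 0")
  chk(cfg$synteny$flank_k >= 1, "synteny.flank_k must be >= 1")
  chk(cfg$synteny$min_support >= 0, "synteny.min_support must be >= 0")
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  class(cfg) <- "RunConfig"
  cfg
}

.simConfigFromRun <- function(cfg) {
  s <- cfg$simulate
  simulationConfig(seed = cfg$seed, nIVa = s$n_iva, nIVb = s$n_ivb,
                   nIVc = s$n_ivc, nIVd = s$n_ivd,
                   nBackground = s$n_background, glyMembers = s$gly_members,
                   glyBackground = s$gly_background,
                   chromCount = s$chrom_count,
                   genesPerChrom = s$genes_per_chrom,
                   syntenyBlockLen = s$synteny_block_len,
                   rearrangementRate = s$rearrangement_rate,
                   relocatedMembers = s$relocated_members,
                   substitutionRate = s$substitution_rate,
                   ctNoiseSd = s$ct_noise_sd)
}

#' Run the full pipeline on synthetic data
#'
#' Executes simulate, scan, classify, identity/similarity, MSA + NJ tree with
#' bootstrap, tandem and synteny detection, and expression profiling in
#' dependency order, writing every artifact under \code{outDir}. Reruns with
#' the same configuration and seed are byte-identical.
#'
#' @param config Raw configuration list (see \code{\link{validateConfig}}).
#' @param outDir Output directory.
#' @param force Overwrite an existing non-empty \code{outDir}.
#' @return The run report (also written as \code{report.json}), invisibly.
#' @export
runAll <- function(config = list(), outDir, force = FALSE) {
  cfg <- validateConfig(config)
  if (dir.exists(outDir) && length(dir(outDir)) && !force)
    stop("output directory exists and is not empty (use force = TRUE)",
         call. = FALSE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outDir, ...)

  # -- simulate ---------------------------------------------------------
  simcfg <- .simConfigFromRun(cfg)
  gp <- makeGenomePair(simcfg)
  writeProteome(gp$proteomeA, p("proteome_a.fasta"))
  writeProteome(gp$proteomeB, p("proteome_b.fasta"))
  writeGeneLoci(gp$lociA, p("genes_a.gff3"))
  writeGeneLoci(gp$lociB, p("genes_b.gff3"))

  # -- scan + classify --------------------------------------------------
  fam <- classifyProteome(gp$proteomeA, loci = gp$lociA,
                          glyThreshold = cfg$classify$gly_threshold,
                          pairingWindow = c(cfg$scan$pairing_window_min,
                                            cfg$scan$pairing_window_max))
  utils::write.table(domainProfiles(fam), p("profiles.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  famTab <- merge(familyCalls(fam), proteinProperties(fam), by = "protein_id")
  famTab <- famTab[order(famTab$protein_id), ]
  utils::write.table(famTab, p("family.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  members <- sort(familyMembers(fam))

  # -- identity/similarity + phylogeny ---------------------------------
  treeWritten <- FALSE
  if (length(members) >= 2) {
    mseqs <- gp$proteomeA[members]
    ism <- identitySimilarityMatrix(mseqs)
    writeMatrixTSV(round(ism$identity, 4), p("identity.tsv"))
    writeMatrixTSV(round(ism$similarity, 4), p("similarity.tsv"))
    if (length(members) >= 3) {
      msa <- centerStarMSA(mseqs)
      masked <- maskLowCoverageColumns(msa, cfg$phylo$min_occupancy)
      tree <- bootstrapSupport(masked, nReps = cfg$phylo$boot_reps,
                               seed = stageSeed(cfg$seed, "bootstrap"),
                               model = cfg$phylo$dist_model)
      writeNewick(tree, p("tree.nwk"))
      treeWritten <- TRUE
    }
  }

  # -- tandem + synteny -------------------------------------------------
  tandem <- findTandem(gp$lociA, members,
                       maxIntervening = cfg$tandem$max_intervening,
                       maxBp = cfg$tandem$max_bp)
  utils::write.table(tandem, p("tandem.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  bh <- bestHits(gp$proteomeA, gp$proteomeB,
                 prescreenKmer = cfg$synteny$prescreen_kmer)
  syn <- syntenicOrthologs(bh, gp$lociA, gp$lociB,
                           flankK = cfg$synteny$flank_k,
                           minSupport = cfg$synteny$min_support)
  synMembers <- syn[syn$gene_a %in% members, , drop = FALSE]
  utils::write.table(synMembers, p("synteny.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  dup <- classifyDuplication(members, tandem, synMembers)
  utils::write.table(dup, p("duplication.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # -- expression -------------------------------------------------------
  samples <- c(cfg$expression$calibrator, "flower", "stem", "curd", "root")
  ctd <- makeCtDataset(simcfg, genes = members, samples = samples)
  utils::write.table(ctd$ct, p("ct_tissues.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expr <- deltaDeltaCt(ctd$ct, ctd$calibrator)
  writeMatrixTSV(round(log2FoldChanges(expr), 6), p("expression.tsv"))
  ord <- if (length(members) >= 2) clusterOrder(expr)$order else members

  # -- truth + report ---------------------------------------------------
  truth <- gp$truth
  jsonlite::write_json(list(
    members = truth@members, tandem_pairs = truth@tandemPairs,
    ortholog_pairs = truth@orthologPairs, planted_log2fc = ctd$log2fc),
    p("truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cnt <- subclassCounts(fam)
  report <- list(
    package_version = as.character(utils::packageVersion("rbgminer")),
    seed = cfg$seed,
    parameters = unclass(cfg),
    counts = list(
      proteins_scanned = length(gp$proteomeA),
      members = sum(cnt),
      subclass = as.list(cnt),
      ivc_excluded = sum(familyCalls(fam)$subclass == "IVc_excluded"),
      tandem_pairs = nrow(tandem),
      synteny_pairs = nrow(synMembers),
      expression_genes = nrow(expr)),
    cluster_order = ord,
    tree_written = treeWritten)
  stopifnot(report$counts$members == sum(unlist(report$counts$subclass)))
  jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(report)
}
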