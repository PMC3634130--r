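## cli_pipeline: flat configuration, end-to-end orchestration with staged
## logging, and a one-command synthetic demo input set.

#' Pipeline configuration
#'
#' A flat key-value configuration holding every path, parameter and flag
#' the pipeline uses; all defaults match the package-wide choices
#' documented on the individual functions.  Serializes losslessly to YAML
#' via [writeConfig()] / [readConfig()].
#'
#' @param ensembleDir directory of ensemble PDB files.
#' @param referenceModel reference model PDB file.
#' @param msa aligned FASTA of receptor sequences.
#' @param ligandTable two-column tab-separated file (receptor_id,
#'   ligand_sequence), with header.
#' @param outputDir output directory (created if absent).
#' @param referenceId reference sequence id in the MSA (default: first).
#' @param cutoff contact cutoff, Angstrom.
#' @param binLow,binHigh frequency bin edges.
#' @param minCoverage completeness threshold for [filterIncomplete()].
#' @param distanceModel \code{"p"} or \code{"similarity"}.
#' @param nPermutations covariation permutations.
#' @param seed master seed (covariation permutation seeds derive from it).
#' @param wholeResidueContacts,crystalSideContacts pocket-mapping flags.
#' @param covariationMode \code{"identity"} or \code{"class"}.
#' @param receptorPositions receptor positions for the covariation screen
#'   (\code{NULL}: the classical covarying candidates that fit the
#'   alignment).
#' @param ligandPositions ligand positions for the covariation screen.
#' @param logoWindows list of reference-position vectors for PFM export.
#' @return list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(ensembleDir, referenceModel, msa, ligandTable,
                           outputDir, referenceId = NULL, cutoff = 4.5,
                           binLow = 0.25, binHigh = 0.75,
                           minCoverage = 0.8,
                           distanceModel = c("p", "similarity"),
                           nPermutations = 999L, seed = 1L,
                           wholeResidueContacts = FALSE,
                           crystalSideContacts = FALSE,
                           covariationMode = c("class", "identity"),
                           receptorPositions = NULL,
                           ligandPositions = c(2L, 3L, 4L, 5L, 8L),
                           logoWindows = NULL) {
  structure(list(
    ensembleDir = ensembleDir, referenceModel = referenceModel, msa = msa,
    ligandTable = ligandTable, outputDir = outputDir,
    referenceId = referenceId, cutoff = cutoff, binLow = binLow,
    binHigh = binHigh, minCoverage = minCoverage,
    distanceModel = match.arg(distanceModel),
    nPermutations = as.integer(nPermutations), seed = as.integer(seed),
    wholeResidueContacts = wholeResidueContacts,
    crystalSideContacts = crystalSideContacts,
    covariationMode = match.arg(covariationMode),
    receptorPositions = receptorPositions,
    ligandPositions = as.integer(ligandPositions),
    logoWindows = logoWindows), class = "PipelineConfig")
}

#' @rdname pipelineConfig
#' @param config a \code{PipelineConfig}.
#' @param path YAML file.
#' @export
writeConfig <- function(config, path) {
  stopifnot(inherits(config, "PipelineConfig"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipelineConfig
#' @export
readConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(pipelineConfig, raw[!vapply(raw, is.null, logical(1))])
  cfg[names(raw)[vapply(raw, is.null, logical(1))]] <- list(NULL)
  cfg
}

.stage <- function(name, files, expr) {
  message("[", name, "] ...")
  tryCatch(expr, error = function(e) {
    for (f in files) if (file.exists(f)) unlink(f)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Stages: input parsing; completeness filter; distance matrix +
#' neighbor-joining tree; conservation profile; PFM export for the logo
#' windows; ensemble superposition, ligand transfer and contact detection;
#' frequency aggregation, consensus site and compactness check; B-factor
#' annotated models (frequency and conservation variants); covariation
#' screen; run manifest.  Any stage failure aborts with the stage name and
#' removes that stage's partial outputs.  Outputs are deterministic given
#' the configuration (including its seed).
#'
#' @param config a [pipelineConfig()].
#' @return invisibly, a report list (tables, consensus site, tree, file
#'   paths).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  for (p in c(config$referenceModel, config$msa, config$ligandTable))
    if (!file.exists(p)) stop("input not found: ", p)
  if (!dir.exists(config$ensembleDir))
    stop("input not found: ", config$ensembleDir)
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outputDir, f)
  tsv <- function(d, f) utils::write.table(
    d, out(f), sep = "\t", quote = FALSE, row.names = FALSE)

  inputs <- .stage("read-inputs", character(), {
    seqs <- readFasta(config$msa)
    aln <- referenceAlignment(seqs, config$referenceId %||% names(seqs)[1L])
    ligTab <- utils::read.delim(config$ligandTable,
                                stringsAsFactors = FALSE)
    ligands <- setNames(toupper(ligTab[[2L]]), ligTab[[1L]])
    ref <- readPDB(config$referenceModel)
    files <- sort(list.files(config$ensembleDir, pattern = "\\.pdb$",
                             full.names = TRUE))
    if (!length(files)) stop("no PDB files in ", config$ensembleDir)
    ensemble <- lapply(files, readPDB)
    message(sprintf("  %d sequences, %d ligands, %d ensemble structures",
                    length(seqs), length(ligands), length(ensemble)))
    list(aln = aln, ligands = ligands, ref = ref, ensemble = ensemble)
  })

  filt <- .stage("completeness-filter", out("coverage.tsv"), {
    f <- filterIncomplete(inputs$aln, config$minCoverage)
    message(sprintf("  kept %d, excluded %d (min coverage %.2f)",
                    length(f$kept), length(f$excluded), config$minCoverage))
    tsv(data.frame(id = names(f$coverage), coverage = f$coverage,
                   kept = names(f$coverage) %in% f$kept), "coverage.tsv")
    f
  })
  keptAln <- referenceAlignment(
    alnSequences(inputs$aln)[filt$kept],
    referenceId(inputs$aln))

  tree <- .stage("phylogeny", out("tree.nwk"), {
    d <- pairwiseDistances(keptAln, model = config$distanceModel)
    t <- neighborJoining(d)
    writeNewick(t, out("tree.nwk"))
    t
  })

  cons <- .stage("conservation", out("conservation.tsv"), {
    pr <- conservationProfile(keptAln)
    tsv(pr, "conservation.tsv")
    pr
  })

  .stage("logo-pfms", out("pfm.tsv"), {
    windows <- config$logoWindows %||%
      list(intersect(keyPositions()$commonContacts,
                     seq_along(refToColumn(keptAln))))
    rows <- NULL
    for (w in windows) {
      if (!length(w)) next
      pfm <- buildPFM(keptAln, w)
      f <- pfm$frequencies
      rows <- rbind(rows, data.frame(
        position = rep(pfm$positions, each = nrow(f)),
        residue = rownames(f), frequency = as.vector(f)))
    }
    tsv(rows, "pfm.tsv")
  })

  contacts <- .stage("contact-mapping",
                     c(out("contact_sets.tsv"), out("contact_frequency.tsv"),
                       out("consensus_site.tsv")), {
    sets <- mapAndDetect(inputs$ensemble, inputs$ref,
                         cutoff = config$cutoff,
                         wholeResidue = config$wholeResidueContacts,
                         crystalSide = config$crystalSideContacts)
    message(sprintf("  %d of %d structures contributed",
                    length(sets), length(inputs$ensemble)))
    tsv(data.frame(
      structure_id = vapply(sets, `[[`, "", "structureId"),
      ligand_id = vapply(sets, `[[`, "", "ligandId"),
      positions = vapply(sets, function(s)
        paste(s$positions, collapse = ","), "")), "contact_sets.tsv")
    tab <- aggregateFrequency(sets)
    tsv(as.data.frame(tab), "contact_frequency.tsv")
    site <- consensusSite(tab)
    tsv(data.frame(position = site), "consensus_site.tsv")
    comp <- if (length(site) >= 1L) compactnessCheck(inputs$ref, site)
            else list(maxDistance = NA_real_, within = NA)
    list(sets = sets, table = tab, site = site, compactness = comp)
  })

  .stage("annotate-models",
         c(out("model_frequency.pdb"), out("model_conservation.pdb")), {
    annotateStructure(inputs$ref, table = contacts$table,
                      path = out("model_frequency.pdb"))
    annotateStructure(inputs$ref, profile = cons,
                      what = "conservation",
                      path = out("model_conservation.pdb"))
  })

  covar <- .stage("covariation", out("covariation.tsv"), {
    ligKept <- inputs$ligands[filt$kept]
    ds <- pairedDataset(keptAln, ligKept)
    rp <- config$receptorPositions %||%
      intersect(keyPositions()$covarying, seq_along(refToColumn(keptAln)))
    res <- screenAll(ds, rp, config$ligandPositions,
                     mode = config$covariationMode,
                     nPermutations = config$nPermutations,
                     seed = config$seed)
    tsv(res, "covariation.tsv")
    res
  })

  manifest <- .stage("manifest", out("manifest.json"), {
    cfgFile <- out("config.yaml")
    writeConfig(config, cfgFile)
    m <- list(
      package = "consite",
      version = as.character(utils::packageVersion("consite")),
      seed = config$seed,
      configHash = unname(tools::md5sum(cfgFile)),
      nSequences = length(alnSequences(inputs$aln)),
      nKept = length(filt$kept),
      nStructures = length(inputs$ensemble),
      nContributing = length(contacts$sets),
      consensusSite = contacts$site,
      compactnessMaxDistance = contacts$compactness$maxDistance,
      compactnessWithin16 = contacts$compactness$within)
    jsonlite::write_json(m, out("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    m
  })

  invisible(list(alignment = inputs$aln, kept = filt, tree = tree,
                 conservation = cons, contacts = contacts$sets,
                 frequencyTable = contacts$table,
                 consensusSite = contacts$site,
                 compactness = contacts$compactness,
                 covariation = covar, manifest = manifest,
                 outputDir = config$outputDir))
}

#' Generate a complete synthetic demo input set
#'
#' Writes everything [runPipeline()] needs, with known ground truth: a
#' reference bundle model, an ensemble of 22 perturbed, rigidly scattered
#' members with a planted 9-position pocket, and a 40-pair receptor/ligand
#' family with a planted invariant site and covarying pair.  Returns a
#' ready [pipelineConfig()] pointing at the files.
#'
#' @param seed master seed.
#' @param outputDir directory to create the inputs in.
#' @param nStructures ensemble size.
#' @param nPairs family size.
#' @return list with \code{config}, \code{pocketPositions},
#'   \code{covaryingPair}, \code{invariantSites}, \code{truth} and
#'   \code{files}.
#' @export
makeDemo <- function(seed = 1L, outputDir, nStructures = 22L,
                     nPairs = 40L) {
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(outputDir, 2L) != 0L)
    stop("output directory not writable: ", outputDir)
  bundle <- makeBundle(bundleSpec(seed = seed))
  # nine pocket positions spread over the central placeable inventory
  inv <- placeablePositions(bundle, zWindow = 8)
  if (length(inv) < 9L) stop("bundle offers fewer than 9 placeable positions")
  picks <- inv[round(seq(1L, length(inv), length.out = 9L))]
  ens <- plantLigandEnsemble(bundle, plantedPocket(picks),
                             nStructures = nStructures, seed = seed + 1L)
  edir <- file.path(outputDir, "ensemble")
  dir.create(edir, showWarnings = FALSE)
  for (s in ens$structures)
    writePDB(s, file.path(edir, paste0(structureId(s), ".pdb")))
  refFile <- file.path(outputDir, "reference_model.pdb")
  writePDB(bundle$structure, refFile)

  fam <- simulateFamily(familySpec(nLeaves = nPairs, seed = seed + 2L))
  msaFile <- file.path(outputDir, "receptors.fasta")
  writeFasta(alnSequences(fam$alignment), msaFile)
  ligFile <- file.path(outputDir, "ligands.tsv")
  utils::write.table(
    data.frame(receptor_id = names(ligands(fam$data)),
               ligand_sequence = unname(ligands(fam$data))),
    ligFile, sep = "\t", quote = FALSE, row.names = FALSE)

  cfg <- pipelineConfig(
    ensembleDir = edir, referenceModel = refFile, msa = msaFile,
    ligandTable = ligFile, outputDir = file.path(outputDir, "results"),
    seed = seed,
    receptorPositions = c(40L, 60L, 98L, 110L))
  writeConfig(cfg, file.path(outputDir, "config.yaml"))
  list(config = cfg, pocketPositions = ens$pocket$positions,
       covaryingPair = c(receptor = 98L, ligand = 8L),
       invariantSites = fam$spec$invariantSites,
       truth = ens$truth,
       files = c(refFile, msaFile, ligFile,
                 file.path(outputDir, "config.yaml"),
                 list.files(edir, full.names = TRUE)))
}
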