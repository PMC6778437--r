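# End-to-end orchestration: (optionally simulate) -> curate -> assign ->
# profile, with deterministic, fixed-precision outputs and a machine-readable
# run report.

#' Pipeline configuration
#'
#' @param treeDir directory of newick gene trees (one tree per file); ignored
#'   when \code{simulate} is TRUE.
#' @param taxonomyFile taxonomy TSV path; ignored when \code{simulate} is TRUE.
#' @param outDir output directory.
#' @param queryCode species code marking query leaves (default "DCMF").
#' @param supportThreshold clade support threshold in percent (default 50).
#' @param exclusionThreshold profile exclusion threshold (default 1.0).
#' @param nrThreshold redundancy threshold in percent (default 99).
#' @param seed integer seed (used by the simulate stage).
#' @param simulate generate inputs with [simulateDataset()] instead of
#'   reading them (default FALSE).
#' @param sim a [simConfig()] list used when \code{simulate} is TRUE.
#' @param midpointRootTrees midpoint-root unrooted input trees (default TRUE).
#' @param filterParalogs apply [filterInparalogs()] per tree (default TRUE).
#' @param resplit exclusion re-split behaviour, see [combineRank()].
#' @return A validated list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(treeDir = NULL, taxonomyFile = NULL, outDir,
                           queryCode = "DCMF", supportThreshold = 50,
                           exclusionThreshold = 1, nrThreshold = 99,
                           seed = 1L, simulate = FALSE,
                           sim = simConfig(seed = seed, queryCode = queryCode),
                           midpointRootTrees = TRUE, filterParalogs = TRUE,
                           resplit = TRUE) {
  if (supportThreshold < 0 || supportThreshold > 100)
    stop("supportThreshold must lie in [0, 100]")
  if (nrThreshold < 0 || nrThreshold > 100)
    stop("nrThreshold must lie in [0, 100]")
  if (exclusionThreshold < 0) stop("exclusionThreshold must be >= 0")
  if (!simulate && (is.null(treeDir) || is.null(taxonomyFile)))
    stop("treeDir and taxonomyFile are required unless simulate = TRUE")
  cfg <- list(treeDir = treeDir, taxonomyFile = taxonomyFile, outDir = outDir,
              queryCode = queryCode, supportThreshold = supportThreshold,
              exclusionThreshold = exclusionThreshold,
              nrThreshold = nrThreshold, seed = as.integer(seed),
              simulate = isTRUE(simulate), sim = sim,
              midpointRootTrees = isTRUE(midpointRootTrees),
              filterParalogs = isTRUE(filterParalogs),
              resplit = isTRUE(resplit))
  class(cfg) <- "PipelineConfig"
  cfg
}

.serialiseValue <- function(v) {
  if (is.logical(v)) return(ifelse(v, "true", "false"))
  if (is.numeric(v)) return(paste(sprintf("%.10g", v), collapse = ","))
  paste(as.character(v), collapse = ",")
}

#' Write a pipeline configuration as key = value text
#'
#' Nested simulation fields are written with a \code{sim.} prefix. The format
#' round-trips through [readPipelineConfig()] unchanged.
#'
#' @param config a [pipelineConfig()] list.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writePipelineConfig <- function(config, path) {
  stopifnot(inherits(config, "PipelineConfig"))
  lines <- character(0)
  flat <- config[setdiff(names(config), "sim")]
  for (nm in names(flat))
    if (!is.null(flat[[nm]]))
      lines <- c(lines, sprintf("%s = %s", nm, .serialiseValue(flat[[nm]])))
  simFlat <- config$sim[!vapply(config$sim, is.null, logical(1))]
  for (nm in names(simFlat))
    lines <- c(lines, sprintf("sim.%s = %s", nm, .serialiseValue(simFlat[[nm]])))
  writeLines(lines, path)
  invisible(path)
}

.coerceLike <- function(txt, template) {
  parts <- strsplit(txt, ",", fixed = TRUE)[[1]]
  if (is.logical(template)) return(parts == "true")
  if (is.numeric(template)) {
    v <- as.numeric(parts)
    if (is.integer(template)) v <- as.integer(v)
    return(v)
  }
  parts
}

#' Read a pipeline configuration from key = value text
#'
#' @param path path written by [writePipelineConfig()].
#' @return A \code{PipelineConfig} list.
#' @export
readPipelineConfig <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  pos <- regexpr("=", lines, fixed = TRUE)
  if (any(pos < 0)) stop("malformed config line (expected 'key = value')")
  keys <- trimws(substr(lines, 1, pos - 1))
  vals <- trimws(substring(lines, pos + 1))
  defaults <- pipelineConfig(outDir = ".", simulate = TRUE)
  simDefaults <- defaults$sim
  cfg <- defaults
  cfg$treeDir <- NULL; cfg$taxonomyFile <- NULL
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (startsWith(k, "sim.")) {
      f <- sub("^sim\\.", "", k)
      template <- simDefaults[[f]]
      cfg$sim[[f]] <- if (is.null(template)) vals[i]
                      else .coerceLike(vals[i], template)
    } else {
      template <- defaults[[f <- k]]
      cfg[[f]] <- if (is.null(template)) vals[i] else .coerceLike(vals[i], template)
    }
  }
  class(cfg$sim) <- "SimConfig"
  class(cfg) <- "PipelineConfig"
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s stage] %s", name, conditionMessage(e)), call. = FALSE))
}

.fmt6 <- function(x) sprintf("%.6f", x)

#' Run the full assignment pipeline
#'
#' Stages, each aborting the run with a stage-named error on failure:
#' \describe{
#'   \item{simulate}{(optional) generate trees, taxonomy and sequences with
#'     [simulateDataset()] and write them under \code{outDir/inputs}.}
#'   \item{assign}{read the gene trees (one newick file per tree) and the
#'     taxonomy; midpoint-root unrooted trees; filter in-paralogues; run
#'     [assignClade()] from the first query leaf of each tree and
#'     [mapToRanks()]. Every tree yields exactly one assignment row,
#'     including None rows.}
#'   \item{profile}{combine assignments into six rank profiles with
#'     [combineAssignments()].}
#'   \item{write}{write \code{assignments.tsv}, one \code{profile_<rank>.tsv}
#'     per rank and \code{report.json}, all floating numbers at fixed
#'     6-decimal precision so identical runs are byte-identical.}
#' }
#'
#' @param config a [pipelineConfig()] list.
#' @return Invisibly, the run report (also written as JSON).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  warningsSeen <- character(0)
  treeDir <- config$treeDir
  taxonomyFile <- config$taxonomyFile

  if (config$simulate) {
    .stage("simulate", {
      ds <- simulateDataset(config$sim)
      writeSimulation(ds, file.path(config$outDir, "inputs"))
    })
    treeDir <- file.path(config$outDir, "inputs", "trees")
    taxonomyFile <- file.path(config$outDir, "inputs", "taxonomy.tsv")
  }

  res <- .stage("assign", {
    files <- sort(list.files(treeDir, pattern = "\\.(nwk|newick|nh|tre|txt)$",
                             full.names = TRUE))
    if (!length(files))
      stop(sprintf("no gene tree files found in '%s'", treeDir))
    taxonomy <- readTaxonomy(taxonomyFile)
    assignments <- list()
    ranked <- list()
    for (f in files) {
      id <- sub("\\.[^.]*$", "", basename(f))
      tree <- readGeneTrees(f)[[1]]
      if (!ape::is.rooted(tree)) {
        if (!config$midpointRootTrees)
          stop(sprintf("tree '%s' is unrooted", id))
        tree <- midpointRoot(tree)
      }
      codes <- leafSpeciesCodes(tree$tip.label)
      qleaves <- sort(tree$tip.label[codes == config$queryCode])
      if (!length(qleaves))
        stop(sprintf("tree '%s' has no leaf with query code '%s'",
                     id, config$queryCode))
      if (config$filterParalogs && length(tree$tip.label) > 2L)
        tree <- filterInparalogs(tree, config$queryCode)
      a <- assignClade(tree, qleaves[1], config$supportThreshold,
                       config$queryCode, protein = id)
      r <- withCallingHandlers(
        mapToRanks(a, taxonomy),
        warning = function(w) {
          warningsSeen <<- c(warningsSeen, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      assignments[[id]] <- a
      ranked[[id]] <- r
    }
    list(assignments = assignments, ranked = ranked)
  })

  profiles <- .stage("profile", {
    combineAssignments(res$assignments, res$ranked,
                       exclusionThreshold = config$exclusionThreshold,
                       resplit = config$resplit)
  })

  report <- .stage("write", {
    adf <- do.call(rbind, lapply(res$assignments, function(a) {
      r <- res$ranked[[a@protein]]
      data.frame(
        protein_id = a@protein,
        support = ifelse(is.na(a@support), "", .fmt6(a@support)),
        fallback = tolower(a@rootFallback), none = tolower(a@noneFlag),
        species_codes = paste(a@species, collapse = ";"),
        species = paste(r@taxa$species, collapse = ";"),
        genus = paste(r@taxa$genus, collapse = ";"),
        family = paste(r@taxa$family, collapse = ";"),
        order = paste(r@taxa$order, collapse = ";"),
        class = paste(r@taxa$class, collapse = ";"),
        phylum = paste(r@taxa$phylum, collapse = ";"),
        stringsAsFactors = FALSE)
    }))
    adf <- adf[order(adf$protein_id), , drop = FALSE]
    utils::write.table(adf, file.path(config$outDir, "assignments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    rankSummaries <- list()
    for (r in taxRanks()) {
      df <- profileTable(profiles[[r]])
      for (cl in c("unweighted", "weighted", "percent_weighted",
                   "percent_unweighted"))
        df[[cl]] <- .fmt6(df[[cl]])
      utils::write.table(df,
                         file.path(config$outDir, sprintf("profile_%s.tsv", r)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      top <- profileTable(profiles[[r]])[1, ]
      rankSummaries[[r]] <- list(nTaxa = length(profiles[[r]]@taxa),
                                 topTaxon = top$taxon,
                                 topPercentWeighted =
                                   round(top$percent_weighted, 6))
    }
    rep <- list(
      seed = config$seed, queryCode = config$queryCode,
      supportThreshold = config$supportThreshold,
      exclusionThreshold = config$exclusionThreshold,
      nTrees = length(res$assignments),
      nAssigned = sum(vapply(res$assignments, function(a)
        !a@noneFlag && !a@rootFallback, logical(1))),
      nFallback = sum(vapply(res$assignments, slot, logical(1), "rootFallback")),
      nNone = sum(vapply(res$assignments, slot, logical(1), "noneFlag")),
      ranks = rankSummaries,
      warnings = warningsSeen)
    jsonlite::write_json(rep, file.path(config$outDir, "report.json"),
                         auto_unbox = TRUE, digits = 6, pretty = TRUE)
    rep
  })
  invisible(report)
}
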