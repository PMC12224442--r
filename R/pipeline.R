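## Pipeline driver and strategy-grid evaluation.

#' Pipeline configuration
#'
#' Collects the tunable parameters of an end-to-end run with the package
#' defaults: term/topic frequency thresholds, segment range, permutation
#' count and FDR level.
#'
#' @param outDir artifact directory.
#' @param seed root seed; all stage seeds derive from it deterministically.
#' @param nVertices,nStudies,nTopics,vocabSize synthetic world dimensions.
#' @param methods segmentation approaches to run.
#' @param mapSource \code{"topic"}, \code{"term"} or \code{"external"}.
#' @param kRange segment solutions to compute.
#' @param nComponents gradients retained by the embedding.
#' @param nPerm spin permutations for decoding.
#' @param alpha FDR level.
#' @param termThreshold,topicThreshold study-selection frequency thresholds.
#' @param radius MA kernel radius (mm).
#' @param verbose emit per-stage log lines.
#' @return Named list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(outDir = tempfile("gradient-run-"), seed = 1,
                           nVertices = 2000, nStudies = 500, nTopics = 20,
                           vocabSize = 400, methods = c("PCT", "KMeans", "KDE"),
                           mapSource = "topic", kRange = 2:32,
                           nComponents = 9, nPerm = 1000, alpha = 0.05,
                           termThreshold = 0.001, topicThreshold = 0.05,
                           radius = 10, verbose = TRUE) {
  cfg <- list(outDir = outDir, seed = seed, nVertices = nVertices,
              nStudies = nStudies, nTopics = nTopics, vocabSize = vocabSize,
              methods = match.arg(methods, c("PCT", "KMeans", "KDE"),
                                  several.ok = TRUE),
              mapSource = match.arg(mapSource, c("topic", "term", "external")),
              kRange = kRange, nComponents = nComponents, nPerm = nPerm,
              alpha = alpha, termThreshold = termThreshold,
              topicThreshold = topicThreshold, radius = radius,
              verbose = verbose)
  if (any(cfg$kRange < 2)) stopUser("kRange must start at 2 or above")
  if (alpha <= 0 || alpha >= 1) stopUser("alpha must lie in (0, 1)")
  class(cfg) <- "pipelineConfig"
  cfg
}

logStage <- function(cfg, stage, t0) {
  if (isTRUE(cfg$verbose))
    message(sprintf("[%s] seed=%d elapsed=%.1fs", stage, cfg$seed,
                    as.numeric(Sys.time()) - t0))
}

segmentAxis <- function(values, method, k, seed) {
  switch(method,
         PCT = segmentPct(values, k),
         KMeans = segmentKmeans(values, k, seed = seed),
         KDE = segmentKde(values, k))
}

#' Run the synthetic end-to-end pipeline
#'
#' Simulates a coupled world, runs the gradient decomposition, segments the
#' principal gradient for every requested method and k, builds pseudo-
#' activation and meta-analytic maps, decodes with spin-permutation
#' inference, and writes all artifacts plus a machine-readable manifest. The
#' run is idempotent for an identical configuration.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @return Invisibly, a list with the in-memory results (world, gradients,
#'   segmentations, decoding tables, profile) and the manifest.
#' @export
runPipeline <- function(config = pipelineConfig()) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  t0 <- as.numeric(Sys.time())
  files <- character(0)
  put <- function(name) {
    p <- file.path(config$outDir, name); files <<- c(files, p); p
  }

  ## simulate
  world <- synthWorld(nVertices = config$nVertices,
                      nStudies = config$nStudies, nTopics = config$nTopics,
                      vocabSize = config$vocabSize, seed = config$seed)
  cortex <- which(cortexMask(world$mesh))
  writeTsv(data.frame(vertex = seq_len(config$nVertices),
                      hemisphere = hemisphere(world$mesh),
                      in_cortex = as.integer(cortexMask(world$mesh)),
                      meshCoordinates(world$mesh)),
           put("vertices.tsv"))
  writeTsv(studyCoordinates(world$db), put("study_coordinates.tsv"))
  jsonlite::write_json(list(latentAxis = world$truth$latentAxis,
                            endTopics = world$truth$endTopics),
                       put("truth.json"), auto_unbox = TRUE, digits = NA)
  logStage(config, "simulate", t0)

  ## gradient
  grads <- connectomeGradients(world$connectome,
                               nComponents = config$nComponents)
  g1 <- gradientComponents(grads)[, 1]
  gfull <- rep(0, config$nVertices); gfull[cortex] <- g1
  writeGifti(gfull, put("gradient1.func.gii"))
  writeTsv(data.frame(component = seq_along(gradientEigenvalues(grads)),
                      eigenvalue = gradientEigenvalues(grads),
                      explained_variance = explainedVariance(grads)),
           put("gradient_variance.tsv"))
  logStage(config, "gradient", t0)

  ## segment
  segRows <- list(); qualRows <- list(); segs <- list()
  for (method in config$methods) {
    for (k in config$kRange) {
      seg <- segmentAxis(g1, method, k, deriveSeed(config$seed,
                                                   paste(method, k)))
      segs[[paste(method, k, sep = "_")]] <- seg
      segRows[[length(segRows) + 1L]] <-
        data.frame(vertex = cortex, method = method, k = k,
                   label = segmentLabels(seg))
      q <- clusterQuality(segmentPoints(seg), segmentLabels(seg))
      qualRows[[length(qualRows) + 1L]] <-
        data.frame(method = method, k = k,
                   mean_silhouette = q$meanSilhouette,
                   variance_ratio = q$varianceRatio,
                   cluster_separation = q$clusterSeparation)
    }
  }
  writeTsv(do.call(rbind, segRows), put("segmentations.tsv"))
  quality <- do.call(rbind, qualRows)
  writeTsv(quality, put("segmentation_quality.tsv"))
  logStage(config, "segment", t0)

  ## maps (meta-analytic), on cortex vertices
  centers <- meshCoordinates(world$mesh)[cortex, , drop = FALSE]
  studyMaps <- studyActivationMaps(world$db, centers, radius = config$radius)
  metaMaps <- if (config$mapSource == "term") {
    sig <- vapply(world$truth$signatureWords, `[`, character(1), 1)
    buildTermMaps(world$db, centers, terms = sig,
                  threshold = config$termThreshold, studyMaps = studyMaps)
  } else {
    buildTopicMaps(world$db,
                   list(docTopic = world$truth$docTopic,
                        wordTopic = world$truth$wordTopic),
                   centers, threshold = config$topicThreshold,
                   studyMaps = studyMaps)
  }
  logStage(config, "maps", t0)

  ## decode
  nulls <- spinNulls(world$mesh, nPerm = config$nPerm,
                     seed = deriveSeed(config$seed, "spin"))
  tables <- list(); entries <- list()
  for (nm in names(segs)) {
    seg <- segs[[nm]]
    maps <- buildMapSet(seg)
    tab <- decode(maps, metaMaps, world$mesh, seed = NULL,
                  alpha = config$alpha, nulls = nulls)
    tab$method <- segmentMethod(seg); tab$k <- nSegments(seg)
    tables[[nm]] <- tab
    entries[[nm]] <- list(k = nSegments(seg), table = tab,
                          peaks = computePeaks(seg))
  }
  allTabs <- do.call(rbind, tables)
  writeTsv(allTabs, put("decoding_table.tsv"))
  profile <- correlationProfile(entries)
  writeTsv(profile$points, put("correlation_profile.tsv"))
  logStage(config, "decode", t0)

  ## manifest
  cfgJson <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE)
  manifest <- list(
    package = "gradientDecoding",
    version = as.character(utils::packageVersion("gradientDecoding")),
    seed = config$seed,
    configHash = stringHash(as.character(cfgJson)),
    config = unclass(config),
    files = basename(files),
    nSegmentations = length(segs))
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logStage(config, "manifest", t0)
  invisible(list(world = world, gradients = grads, segmentations = segs,
                 quality = quality, metaMaps = metaMaps, tables = tables,
                 profile = profile, manifest = manifest))
}

#' Strategy grid for an evaluation run
#'
#' Cartesian product of segmentation approaches, meta-analytic map sources
#' and databases; entries are unique.
#'
#' @param methods segmentation approaches.
#' @param sources meta-analytic map sources.
#' @param databases database names.
#' @return data.frame with one row per strategy.
#' @export
strategyGrid <- function(methods = c("PCT", "KMeans", "KDE"),
                         sources = c("term", "topic"),
                         databases = "synthetic") {
  g <- expand.grid(method = unique(methods), source = unique(sources),
                   database = unique(databases), stringsAsFactors = FALSE)
  unique(g)
}

topLabelSemantics <- function(tab, metaMaps, world, annModel) {
  # per segment: top label's IC, TFIDF and category
  segs <- sort(unique(tab$segment))
  out <- lapply(segs, function(s) {
    sub <- tab[tab$segment == s, ]
    top <- sub[which.max(sub$r), ]
    mm <- metaMaps[[top$label]]
    words <- mapLabels(mm)
    isTopic <- length(words) > 1 || startsWith(top$label, "topic")
    sel <- if (isTopic) {
      t <- as.integer(sub("topic", "", top$label))
      selectByTopic(world$truth$docTopic, t)
    } else selectByTerm(world$db, words[1])
    ic <- tryCatch(
      if (isTopic) icTopic(world$corpus, words, sel)
      else icWord(world$corpus, words[1], sel),
      error = function(e) NA_real_)
    tfidf <- if (isTopic) tfidfTopic(world$corpus, words, sel)
             else tfidfWord(world$corpus, words[1], sel)
    category <- if (isTopic) {
      t <- as.integer(sub("topic", "", top$label))
      classifyTopic(annModel, world$truth$wordTopic[t, ])
    } else classifyWord(annModel, words[1])
    data.frame(segment = s, ic = ic, tfidf = tfidf, category = category,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Evaluate a grid of decoding strategies
#'
#' Runs every (segmentation method, map source) strategy over the requested
#' segment solutions on a synthetic world and summarizes: mean top
#' correlation, mean IC and TFIDF of the top labels, normalized SNR, and the
#' clustering-quality metrics. Top performers are marked by thresholding each
#' metric at a configurable percentile of its grid values (90th for
#' correlation and SNR, 70th for IC and TFIDF, 90th for silhouette); the
#' overall score per cell is the sum of the five binary indicators (max 5).
#'
#' @param world a \code{\link{synthWorld}} result.
#' @param config a \code{\link{pipelineConfig}}; \code{methods} and
#'   \code{kRange} define the grid rows and columns.
#' @param sources map sources to cross with the methods.
#' @param percentiles named thresholds for marking top performers.
#' @return List with \code{summary} (one row per strategy and k),
#'   \code{indicators} (five binary matrices), \code{overall} (score matrix)
#'   and \code{grid}.
#' @export
evaluateGrid <- function(world, config, sources = c("term", "topic"),
                         percentiles = c(correlation = 0.9, snr = 0.9,
                                         ic = 0.7, tfidf = 0.7,
                                         silhouette = 0.9)) {
  grid <- strategyGrid(config$methods, sources)
  cortex <- which(cortexMask(world$mesh))
  grads <- connectomeGradients(world$connectome,
                               nComponents = config$nComponents)
  g1 <- gradientComponents(grads)[, 1]
  centers <- meshCoordinates(world$mesh)[cortex, , drop = FALSE]
  studyMaps <- studyActivationMaps(world$db, centers, radius = config$radius)
  mapsBySource <- list()
  for (src in unique(grid$source)) {
    mapsBySource[[src]] <- if (src == "term") {
      sig <- vapply(world$truth$signatureWords, `[`, character(1), 1)
      buildTermMaps(world$db, centers, terms = sig,
                    threshold = config$termThreshold, studyMaps = studyMaps)
    } else {
      buildTopicMaps(world$db,
                     list(docTopic = world$truth$docTopic,
                          wordTopic = world$truth$wordTopic),
                     centers, threshold = config$topicThreshold,
                     studyMaps = studyMaps)
    }
  }
  annModel <- categoryModel(world$annotations)
  nulls <- spinNulls(world$mesh, nPerm = config$nPerm,
                     seed = deriveSeed(config$seed, "spin"))
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    method <- grid$method[i]; src <- grid$source[i]
    for (k in config$kRange) {
      seg <- segmentAxis(g1, method, k,
                         deriveSeed(config$seed, paste(method, k)))
      q <- clusterQuality(segmentPoints(seg), segmentLabels(seg))
      tab <- decode(buildMapSet(seg), mapsBySource[[src]], world$mesh,
                    alpha = config$alpha, nulls = nulls)
      sem <- topLabelSemantics(tab, mapsBySource[[src]], world, annModel)
      topR <- vapply(split(tab, tab$segment),
                     function(d) max(d$r), numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        method = method, source = src, k = k,
        meanTopR = mean(topR), meanIC = mean(sem$ic, na.rm = TRUE),
        meanTFIDF = mean(sem$tfidf), snr = snr(sem$category)$normalizedSnr,
        meanSilhouette = q$meanSilhouette, varianceRatio = q$varianceRatio,
        clusterSeparation = q$clusterSeparation,
        stringsAsFactors = FALSE)
    }
  }
  summary <- do.call(rbind, rows)
  metricCols <- c(correlation = "meanTopR", snr = "snr", ic = "meanIC",
                  tfidf = "meanTFIDF", silhouette = "meanSilhouette")
  indicators <- lapply(names(metricCols), function(mn) {
    v <- summary[[metricCols[mn]]]
    thr <- stats::quantile(v, percentiles[mn], na.rm = TRUE, names = FALSE)
    as.integer(v >= thr)
  })
  names(indicators) <- names(metricCols)
  overall <- Reduce(`+`, indicators)
  summary$overall <- overall
  list(summary = summary, indicators = indicators, overall = overall,
       grid = grid)
}
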