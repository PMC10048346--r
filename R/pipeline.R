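#' @include synthetic.R
NULL

#' Run the full prediction pipeline
#'
#' Chains every stage: load (or generate) sequences, optional redundancy
#' filtering, class balancing, stratified splitting, k-mer tokenization,
#' CBOW embedding, the multilayer dynamic cascade, and the metric suite.
#' All stage seeds are derived deterministically from the single
#' `config$seed`, and when `outDir` is set the resolved configuration is
#' written to a manifest alongside the artifacts, so a run is reproducible
#' from its manifest alone.
#'
#' @param config A list (e.g. parsed from YAML) with entries:
#'   \describe{
#'     \item{posFasta, negFasta}{FASTA paths for the two classes, or}
#'     \item{synthetic}{a list of [syntheticSpec()] arguments;}
#'     \item{k}{k-mer width (default 3);}
#'     \item{embedding}{list of [embeddingParams()] overrides;}
#'     \item{embedOnTrainOnly}{train the embedding on the training split
#'       only instead of the full dataset (default `FALSE`, the
#'       conventional — leaky — corpus choice for this method);}
#'     \item{learners}{`"cnn"` (the three presets), `"reference"` (three
#'       pooled-logistic stand-ins), or a list of classifier objects;}
#'     \item{epochs}{CNN training epochs (default 20);}
#'     \item{redundancyThreshold}{identity cutoff for
#'       [redundancyFilter()], `NULL` to skip;}
#'     \item{trainFraction, gridStep, threshold, maxLayers, mode,
#'       ensemble, seed}{as in [stratifiedSplit()] / [runMLDS()].}
#'   }
#' @param outDir Output directory (created if needed); `NULL` writes
#'   nothing.
#' @return Invisibly, a list with the dataset, split, [MLDSResult-class],
#'   aggregate confusion counts, metric vector, ROC, and artifact paths.
#' @export
runPipeline <- function(config, outDir = config$outDir) {
  cfg <- .resolvePipelineConfig(config)

  if (!is.null(cfg$synthetic)) {
    spec <- do.call(syntheticSpec, cfg$synthetic)
    ds <- generateDataset(spec)
  } else {
    pos <- readFastaDataset(cfg$posFasta, label = 1L)
    neg <- readFastaDataset(cfg$negFasta, label = 0L)
    ds <- combineDatasets(pos, neg)
  }
  if (!is.null(cfg$redundancyThreshold)) {
    ds <- redundancyFilter(ds, cfg$redundancyThreshold)
  }
  ds <- balanceDataset(ds, seed = .deriveSeed(cfg$seed, 3L))
  sp <- stratifiedSplit(ds, cfg$trainFraction,
                        seed = .deriveSeed(cfg$seed, 4L))

  ep <- do.call(embeddingParams,
                c(cfg$embedding, list(seed = .deriveSeed(cfg$seed, 5L))))
  corpusSet <- if (isTRUE(cfg$embedOnTrainOnly)) sp$train else ds
  emb <- trainEmbedding(buildCorpus(corpusSet, cfg$k), ep)

  learners <- cfg$learners
  if (is.character(learners)) {
    learners <- switch(match.arg(learners, c("cnn", "reference")),
      cnn = cnnPresets(epochs = cfg$epochs, seed = cfg$seed),
      reference = lapply(1:3, function(j)
        referenceLearner(seed = .deriveSeed(cfg$seed, 6L, j),
                         lambda = 10 ^ -j)))
  }

  res <- runMLDS(sp$train, sp$test, learners = learners, k = cfg$k,
                 embedding = emb, gridStep = cfg$gridStep,
                 threshold = cfg$threshold, maxLayers = cfg$maxLayers,
                 mode = cfg$mode, ensemble = cfg$ensemble, seed = cfg$seed,
                 verbose = cfg$verbose)
  cc <- cascadeConfusion(res)
  mr <- computeMetrics(cc)
  roc <- rocCurveAuc(res@assignments$prob_layer1, res@assignments$label)

  paths <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      ledger = file.path(outDir, "ledger.tsv"),
      metrics = file.path(outDir, "metrics.json"),
      roc = file.path(outDir, "roc.tsv"),
      predictions = file.path(outDir, "predictions.tsv"),
      manifest = file.path(outDir, "manifest.json"))
    writeLedger(res, paths$ledger)
    jsonlite::write_json(
      list(metrics = as.list(mr),
           auc_layer1 = roc$auc,
           balanced_accuracy = balancedAccuracy(cc),
           total_accuracy = res@totalAccuracy,
           confusion = list(TP = cc@TP, TN = cc@TN, FP = cc@FP,
                            FN = cc@FN),
           n_layers = nrow(res@layers),
           initial_test_size = res@initialTestSize),
      paths$metrics, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.table(roc$points, paths$roc, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(res@assignments, paths$predictions, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest <- cfg
    manifest$learners <- if (is.character(cfg$learners)) cfg$learners else
      vapply(learners, function(l) class(l)[1L], "")
    manifest$versions <- list(
      R = R.version.string,
      methCascade = as.character(utils::packageVersion("methCascade")),
      Biostrings = as.character(utils::packageVersion("Biostrings")))
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
  }
  invisible(list(dataset = ds, split = sp, embedding = emb, result = res,
                 confusion = cc, metrics = mr, roc = roc, paths = paths))
}

.resolvePipelineConfig <- function(config) {
  stopifnot(is.list(config))
  defaults <- list(posFasta = NULL, negFasta = NULL, synthetic = NULL,
                   k = 3L, embedding = list(), embedOnTrainOnly = FALSE,
                   learners = "cnn", epochs = 20L,
                   redundancyThreshold = NULL, trainFraction = 0.8,
                   gridStep = 0.1, threshold = 0.5, maxLayers = 20L,
                   mode = "faithful", ensemble = "WAE", seed = 1L,
                   verbose = FALSE, outDir = NULL)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown config entr", if (length(unknown) > 1) "ies: " else "y: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  if (is.null(cfg$synthetic) &&
      (is.null(cfg$posFasta) || is.null(cfg$negFasta))) {
    stop("config needs either 'synthetic' or both 'posFasta' and ",
         "'negFasta'", call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}
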