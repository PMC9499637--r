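# End-to-end orchestration: simulate/load -> filter/normalize -> ecology ->
# clinical PCA & stratification -> univariate -> fusion/rDCV/permutation.

#' Default pipeline configuration
#'
#' All analysis thresholds are configuration, not code: the 1%-of-total /
#' 25%-prevalence feature filter, the FDR 0.1 and raw 0.05 univariate
#' thresholds, the VIP 1.15 selection rule, and the blood-pH 7.32 / 7.10 and
#' anti-GAD 1 U/mL clinical cut-offs.
#'
#' @param outDir output directory.
#' @param seed master seed (mandatory for a reproducible run).
#' @return nested configuration list; amend fields as needed or load one
#'   from YAML with [readPipelineConfig()].
#' @export
defaultPipelineConfig <- function(outDir = file.path(tempdir(), "mbfuse_run"),
                                  seed = 1) {
  list(
    input = NULL,                    # list(counts=, metabolites=, clinical=)
    simulate = list(),               # overrides for simulationParams()
    groupColumn = "group",
    filter = list(minTotalFraction = 0.01, minPrevalence = 0.25),
    css = list(quantile = NULL, scale = 1000),   # NULL = adaptive
    diversity = list(metrics = c("shannon", "simpson", "chao1"), base = 2),
    permanova = list(nPerm = 999),
    clinical = list(caseGroup = "T1D",
                    pcaVariables = c("anti_GAD", "IAA", "IA2", "HbA1c",
                                     "cholesterol", "insulin_need",
                                     "blood_pH", "age", "c_peptide")),
    univariate = list(adjust = "bh_fdr", alpha = 0.1, alphaRaw = 0.05),
    contrasts = list(list(name = "T1D_vs_CTRL",
                          a = list(group = "T1D"),
                          b = list(group = "CTRL"))),
    rdcv = list(outerFolds = 5, innerFolds = 5, repeats = 10, maxComp = 10,
                vipThreshold = 1.15, vipConsistency = 0.5),
    permutation = list(nPerm = 0, permRepeats = 1),   # 0 = skip
    outDir = outDir,
    seed = seed)
}

#' Read a pipeline configuration from YAML
#'
#' Fields present in the file override the defaults of
#' [defaultPipelineConfig()].
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
readPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- defaultPipelineConfig()
  mergeLists <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(base[[nm]]) && is.list(over[[nm]]) &&
          !is.null(names(over[[nm]])))
        base[[nm]] <- mergeLists(base[[nm]], over[[nm]])
      else base[[nm]] <- over[[nm]]
    }
    base
  }
  mergeLists(cfg, user)
}

#' The four standard case/control contrasts
#'
#' Case vs control, each blood-pH severity side of the case group vs
#' control, and the two pH sides against each other.
#'
#' @param caseGroup,controlGroup group labels.
#' @export
standardContrasts <- function(caseGroup = "T1D", controlGroup = "CTRL") {
  list(
    list(name = paste0(caseGroup, "_vs_", controlGroup),
         a = list(group = caseGroup), b = list(group = controlGroup)),
    list(name = paste0("pHlow_vs_", controlGroup),
         a = list(group = caseGroup, ph = "pH<7.32"),
         b = list(group = controlGroup)),
    list(name = paste0("pHnormal_vs_", controlGroup),
         a = list(group = caseGroup, ph = "pH>=7.32"),
         b = list(group = controlGroup)),
    list(name = "pHnormal_vs_pHlow",
         a = list(group = caseGroup, ph = "pH>=7.32"),
         b = list(group = caseGroup, ph = "pH<7.32")))
}

# Sample IDs matched by one contrast side (group and/or binary pH stratum).
resolveSide <- function(clinical, side, groupColumn = "group") {
  ids <- rownames(clinical)
  keep <- rep(TRUE, nrow(clinical))
  if (!is.null(side$group)) {
    if (!groupColumn %in% colnames(clinical))
      stop("metadata column '", groupColumn, "' not found", call. = FALSE)
    keep <- keep & clinical[[groupColumn]] == side$group
  }
  if (!is.null(side$ph)) {
    ph <- stratifySamples(clinical, "blood_pH", phBinaryScheme())
    lab <- rep(NA_character_, nrow(clinical))
    lab[match(names(ph), ids)] <- as.character(ph)
    keep <- keep & !is.na(lab) & lab == side$ph
  }
  ids[keep]
}

# Two-class label factor over the union of both contrast sides.
resolveContrast <- function(clinical, contrast, groupColumn = "group") {
  a <- resolveSide(clinical, contrast$a, groupColumn)
  b <- resolveSide(clinical, contrast$b, groupColumn)
  if (!length(a) || !length(b))
    stop("contrast '", contrast$name, "' has an empty group", call. = FALSE)
  if (length(intersect(a, b)))
    stop("contrast '", contrast$name, "' sides overlap", call. = FALSE)
  ids <- c(a, b)
  nameOf <- function(s) paste(unlist(s), collapse = "&")
  lab <- factor(rep(c(nameOf(contrast$a), nameOf(contrast$b)),
                    c(length(a), length(b))),
                levels = c(nameOf(contrast$b), nameOf(contrast$a)))
  names(lab) <- ids
  lab          # positive class (second level) = side 'a', the case side
}

loadBundle <- function(config) {
  if (!is.null(config$input)) {
    counts <- readFeatureTable(config$input$counts)
    metabolites <- readFeatureTable(config$input$metabolites)
    cl <- utils::read.delim(config$input$clinical, check.names = FALSE)
    rownames(cl) <- cl[[1L]]
    cl[[1L]] <- NULL
    new("StudyBundle", counts = counts, metabolites = metabolites,
        clinical = cl, truth = list())
  } else {
    params <- do.call(simulationParams,
                      c(config$simulate, list(seed = config$seed)))
    generateStudy(params)
  }
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data simulation (or loading), feature filtering and
#' CSS normalization, diversity/ordination/PERMANOVA ecology, clinical PCA,
#' correlations and cut-off stratification, univariate differential testing,
#' and per-contrast multi-block rDCV classification with VIP-consistency
#' biomarker selection (plus permutation testing when configured). Every
#' stage writes TSV/JSON outputs under `config$outDir`, and a manifest with
#' parameters, seed, package version and content hashes is written last.
#'
#' @param config see [defaultPipelineConfig()] / [readPipelineConfig()].
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
runPipeline <- function(config = defaultPipelineConfig()) {
  if (is.null(config$seed)) stop("config$seed is mandatory", call. = FALSE)
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  files <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # -- data -----------------------------------------------------------
  bundle <- stage("data", loadBundle(config))
  clinical <- bundleClinical(bundle)
  if (!config$groupColumn %in% colnames(clinical))
    stop("stage 'data' failed: metadata column '", config$groupColumn,
         "' not found", call. = FALSE)
  groups <- clinical[[config$groupColumn]]
  files["counts"] <- writeFeatureTable(bundleCounts(bundle),
                                       file.path(config$outDir, "counts.tsv"))
  files["metabolites"] <- writeFeatureTable(
    bundleMetabolites(bundle), file.path(config$outDir, "metabolites.tsv"))
  files["clinical"] <- writeTsv(
    data.frame(sample_id = rownames(clinical), clinical,
               check.names = FALSE),
    file.path(config$outDir, "clinical.tsv"))

  # -- filter + CSS ---------------------------------------------------
  norm <- stage("normalize", {
    filtered <- filterFeatures(bundleCounts(bundle),
                               config$filter$minTotalFraction,
                               config$filter$minPrevalence)
    q <- config$css$quantile
    if (is.null(q))
      q <- suppressWarnings(cssReferenceQuantile(filtered))
    list(filtered = filtered, quantile = q,
         css = cssNormalize(filtered, q, config$css$scale))
  })
  out$normalize <- norm
  files["css_counts"] <- writeFeatureTable(
    norm$css, file.path(config$outDir, "counts_css.tsv"))

  # -- ecology --------------------------------------------------------
  out$ecology <- stage("ecology", {
    cm <- tableValues(norm$filtered)
    alpha <- vapply(config$diversity$metrics, function(m)
      apply(cm, 1L, alphaDiversity, metric = m,
            base = config$diversity$base), numeric(nrow(cm)))
    alphaTests <- lapply(as.data.frame(alpha), kruskalWallis,
                         labels = groups)
    dm <- brayCurtis(relativeAbundance(norm$filtered))
    ord <- pcoa(dm, k = 2)
    pmv <- permanova(dm, groups, nPerm = config$permanova$nPerm,
                     seed = deriveSeed(config$seed, 11L))
    intra <- intragroupDistances(dm, groups)
    files["alpha"] <- writeTsv(
      data.frame(sample_id = rownames(cm), alpha, check.names = FALSE),
      file.path(config$outDir, "alpha_diversity.tsv"))
    files["pcoa"] <- writeTsv(
      data.frame(sample_id = rownames(ord$coordinates), ord$coordinates),
      file.path(config$outDir, "pcoa_coordinates.tsv"))
    list(alpha = alpha, alphaTests = alphaTests, ordination = ord,
         permanova = pmv, intragroup = intra)
  })

  # -- clinical -------------------------------------------------------
  out$clinical <- stage("clinical", {
    caseRows <- clinical[groups == config$clinical$caseGroup, , drop = FALSE]
    vars <- intersect(config$clinical$pcaVariables, colnames(caseRows))
    mat <- as.matrix(caseRows[, vars, drop = FALSE])
    complete <- stats::complete.cases(mat)
    sc <- autoscale(mat[complete, , drop = FALSE])
    pca <- pcaFit(sc$scaled, k = min(2L, ncol(sc$scaled)))
    pairs <- utils::combn(vars, 2L, simplify = FALSE)
    cors <- do.call(rbind, lapply(pairs, function(pr) {
      ct <- tryCatch(pearsonCorrelation(mat[, pr[1L]], mat[, pr[2L]]),
                     error = function(e) list(r = NA_real_, p = NA_real_,
                                              n = NA_integer_))
      data.frame(var1 = pr[1L], var2 = pr[2L], r = ct$r, p = ct$p, n = ct$n)
    }))
    strata <- list(
      ph = stratifySamples(caseRows, "blood_pH", phStrataScheme()),
      phBinary = stratifySamples(caseRows, "blood_pH", phBinaryScheme()),
      antiGad = stratifySamples(caseRows, "anti_GAD", antiGadScheme()))
    files["clinical_correlations"] <- writeTsv(
      cors, file.path(config$outDir, "clinical_correlations.tsv"))
    list(pca = pca, nDropped = sum(!complete), correlations = cors,
         strata = strata)
  })

  # -- univariate -----------------------------------------------------
  out$univariate <- stage("univariate", {
    taxa <- differentialFeatures(relativeAbundance(norm$filtered), groups,
                                 test = "kruskal_wallis",
                                 adjust = config$univariate$adjust,
                                 alpha = config$univariate$alpha,
                                 alphaRaw = config$univariate$alphaRaw)
    metab <- differentialFeatures(bundleMetabolites(bundle), groups,
                                  test = "kruskal_wallis",
                                  adjust = config$univariate$adjust,
                                  alpha = config$univariate$alpha,
                                  alphaRaw = config$univariate$alphaRaw)
    files["univariate_taxa"] <- writeTsv(
      taxa, file.path(config$outDir, "univariate_taxa.tsv"))
    files["univariate_metabolites"] <- writeTsv(
      metab, file.path(config$outDir, "univariate_metabolites.tsv"))
    list(taxa = taxa, metabolites = metab)
  })

  # -- fusion / classification ---------------------------------------
  out$fusion <- stage("fusion", {
    lapply(config$contrasts, function(ct) {
      lab <- resolveContrast(clinical, ct, config$groupColumn)
      ids <- names(lab)
      blocks <- list(mb = tableValues(bundleMetabolites(bundle))[ids, ,
                                                                 drop = FALSE],
                     mg = tableValues(norm$css)[ids, , drop = FALSE])
      cfg <- do.call(rdcvConfig,
                     c(config$rdcv,
                       list(seed = deriveSeed(config$seed, 21L))))
      res <- rdcv(blocks, lab, cfg, positiveClass = levels(lab)[2L])
      sel <- selectFeaturesVip(res, cfg$vipThreshold, cfg$vipConsistency)
      confirmed <- confirmSelectedFeatures(blocks, lab,
                                           sel$feature[sel$selected])
      perm <- NULL
      if (config$permutation$nPerm > 0)
        perm <- permutationTest(blocks, lab, cfg,
                                nPerm = config$permutation$nPerm,
                                permRepeats = config$permutation$permRepeats,
                                positiveClass = levels(lab)[2L])
      files[paste0("vip_", ct$name)] <<- writeTsv(
        sel, file.path(config$outDir, paste0("vip_", ct$name, ".tsv")))
      jsonlite::write_json(
        list(contrast = ct$name, merits = as.list(rdcvMeritSummary(res)),
             chosenA = as.vector(rdcvChosenA(res)),
             permutation = if (!is.null(perm))
               list(p = as.list(perm@p), nPerm = perm@nPerm)),
        fp <- file.path(config$outDir, paste0("rdcv_", ct$name, ".json")),
        auto_unbox = TRUE, digits = NA, null = "null")
      files[paste0("rdcv_", ct$name)] <<- fp
      list(contrast = ct$name, rdcv = res, selection = sel,
           confirmed = confirmed, permutation = perm)
    })
  })

  # -- manifest -------------------------------------------------------
  manifest <- list(
    package = "mbfuse",
    version = as.character(utils::packageVersion("mbfuse")),
    seed = config$seed,
    parameters = config[setdiff(names(config), "outDir")],
    outputs = lapply(stats::setNames(nm = names(files)), function(k)
      list(file = basename(files[[k]]),
           md5 = unname(tools::md5sum(files[[k]])))))
  jsonlite::write_json(manifest,
                       file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  out$manifest <- manifest
  invisible(out)
}

#' Compare single-block and fused classifiers across contrasts
#'
#' For every contrast, fits the rDCV PLS-DA on the metabolite block alone,
#' the (CSS-normalized) taxa block alone, and the Frobenius-fused
#' combination, and tabulates the figures of merit side by side.
#'
#' @param bundle StudyBundle (or list with `metabolites`, `taxa` matrices
#'   and `clinical` data.frame).
#' @param contrasts list of contrast specs (see [standardContrasts()]).
#' @param config [rdcvConfig()].
#' @param cssQuantile CSS quantile for the taxa block (default adaptive).
#' @param filter logical: apply the default feature filter to the counts.
#' @return data.frame with one row per contrast x model.
#' @export
compareContrasts <- function(bundle, contrasts = standardContrasts(),
                             config = rdcvConfig(repeats = 10),
                             cssQuantile = NULL, filter = TRUE) {
  clinical <- bundleClinical(bundle)
  counts <- bundleCounts(bundle)
  if (filter) counts <- filterFeatures(counts)
  if (is.null(cssQuantile))
    cssQuantile <- suppressWarnings(cssReferenceQuantile(counts))
  css <- cssNormalize(counts, cssQuantile)
  mb <- tableValues(bundleMetabolites(bundle))
  mg <- tableValues(css)
  rows <- list()
  for (ct in contrasts) {
    lab <- resolveContrast(clinical, ct)
    ids <- names(lab)
    xs <- list(metabolites = mb[ids, , drop = FALSE],
               taxa = mg[ids, , drop = FALSE],
               fused = list(mb = mb[ids, , drop = FALSE],
                            mg = mg[ids, , drop = FALSE]))
    for (model in names(xs)) {
      res <- rdcv(xs[[model]], lab, config,
                  positiveClass = levels(lab)[2L])
      s <- rdcvMeritSummary(res)
      rows[[length(rows) + 1L]] <- data.frame(
        contrast = ct$name, model = model, n = length(lab),
        accuracy = s[["accuracy_mean"]], accuracy_sd = s[["accuracy_sd"]],
        sensitivity = s[["sensitivity_mean"]],
        sensitivity_sd = s[["sensitivity_sd"]],
        specificity = s[["specificity_mean"]],
        specificity_sd = s[["specificity_sd"]])
    }
  }
  do.call(rbind, rows)
}
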