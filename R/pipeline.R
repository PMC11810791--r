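#' Imaging-to-survival cohort analysis
#'
#' Runs the full rare-cell pipeline on a simulated cohort: renders every
#' patient slide, segments all channels (adaptive threshold; the preset's
#' segmentation offset), classifies cells, flags CTC-IGC per sample, and
#' aggregates per-compartment positivity and the marrow-positivity survival
#' comparison (Kaplan-Meier + log-rank).
#'
#' @param preset a [cohortPreset()].
#' @param seed integer seed for cohort simulation.
#' @param verbose print per-slide progress.
#' @return list: `samples` (per slide: patient, compartment, detected
#'   positivity, cell/CTC/IGC counts), `cohort` (with detected marrow
#'   positivity merged), `bloodPercent` / `marrowPercent` (among matched
#'   patients, one decimal), `logrank`, `km`.
#' @export
runCohortAnalysis <- function(preset, seed = 17L, verbose = FALSE) {
    sim <- simulateCohort(preset, seed)
    sl <- if (length(preset$slide)) preset$slide else .defaultSlideParams()
    off <- if (!is.null(sl$segmentOffset)) sl$segmentOffset else 10
    minArea <- if (!is.null(sl$segmentMinArea)) sl$segmentMinArea else 50
    rows <- list()
    for (nm in names(sim$slides)) {
        if (verbose) message("slide ", nm)
        rendered <- renderSlide(sim$slides[[nm]])
        seg <- segmentSlide(rendered$image, offset = off, minArea = minArea)
        th <- positivityThresholds(rendered$image, seg$cellMask)
        calls <- callCells(seg$records, th)
        calls <- flagIGC(calls, seg$records)
        parts <- strsplit(nm, "_")[[1]]
        rows[[nm]] <- data.frame(
            patient_id = parts[1], compartment = parts[2],
            n_cells = nrow(calls),
            n_ctc = sum(calls$class == "CTC"),
            n_igc = sum(calls$class == "CTC" & calls$igc),
            positive = samplePositivity(calls),
            stringsAsFactors = FALSE)
    }
    samples <- do.call(rbind, rows)
    rownames(samples) <- NULL
    cohort <- sim$cohort
    det <- function(comp) {
        s <- samples[samples$compartment == comp, ]
        s$positive[match(cohort$patient_id, s$patient_id)]
    }
    cohort$blood_igc_detected <- det("blood")
    cohort$marrow_igc_detected <- det("marrow")
    matched <- cohort$matched
    nMatch <- sum(matched)
    bloodPct <- round(100 * sum(cohort$blood_igc_detected[matched],
                                na.rm = TRUE) / nMatch, 1)
    marrowPct <- round(100 * sum(cohort$marrow_igc_detected[matched]) /
                           nMatch, 1)
    grp <- cohort$marrow_igc_detected
    lr <- if (length(unique(grp)) == 2)
        logrankTest(cohort$time_months, cohort$event, grp) else NULL
    km <- if (length(unique(grp)) == 2) {
        cg <- cohort; cg$group <- grp
        kmByGroup(cg)
    } else NULL
    list(samples = samples, cohort = cohort,
         bloodPercent = bloodPct, marrowPercent = marrowPct,
         logrank = lr, km = km)
}

#' Differential-expression intersection analysis
#'
#' Simulates single-cell counts from an RNA preset, runs the stratified
#' rank-sum DE test for every treated-vs-control comparison, intersects the
#' up-regulated sets per line and across lines, and summarizes the survivor
#' set's biotype composition and per-cell signature score separation.
#'
#' @param preset an [rnaPreset()].
#' @param seed integer seed.
#' @param lfcThresh,fdrThresh thresholds passed to [sharedUpregulated()].
#' @return list: `sets` (from [sharedUpregulated()]), `sizes`, `biotypes`,
#'   `scoreByCondition` (mean survivor-signature score per condition), `de`
#'   (per-comparison result tables), `sce`.
#' @export
runSignatureAnalysis <- function(preset, seed = 17L, lfcThresh = 1.5,
                                 fdrThresh = 0.01) {
    sce <- simulateRNACounts(preset, seed)
    cd <- SummarizedExperiment::colData(sce)
    conds <- preset$conditions
    de <- list()
    lines <- list()
    for (ln in unique(conds$line)) {
        ctrl <- conds$condition[conds$line == ln & !conds$treated]
        trts <- conds$condition[conds$line == ln & conds$treated]
        lines[[ln]] <- trts
        for (tr in trts) {
            ia <- which(cd$condition == ctrl)
            ib <- which(cd$condition == tr)
            de[[tr]] <- deTest(sce, ia, ib, batch = cd$batch)
        }
    }
    sets <- sharedUpregulated(de, lines, lfcThresh = lfcThresh,
                              fdrThresh = fdrThresh)
    biotype <- stats::setNames(
        SummarizedExperiment::rowData(sce)$biotype, rownames(sce))
    biotypes <- biotypeBreakdown(sets$survivorSet, biotype)
    score <- if (length(sets$survivorSet) >= 1) {
        sc <- signatureScore(normalizeCPM(sce), sets$survivorSet)
        tapply(sc, cd$condition, mean)
    } else NULL
    list(sets = sets, sizes = sets$sizes, biotypes = biotypes,
         scoreByCondition = score, de = de, sce = sce)
}

#' Copy-number concordance analysis on simulated cells
#'
#' Simulates two groups of cells from one planted copy-number truth — a
#' "typical" group and an "IGC-like" group whose states are uniformly
#' whole-genome doubled — then normalizes, segments and computes the
#' concordance structure. Since ratio profiles are invariant under WGD, the
#' cross-group concordance should match the within-group concordance.
#'
#' @param truth a [cnGroundTruth()] (default [pc3CNPreset()]).
#' @param nPerGroup cells per group.
#' @param seed integer seed.
#' @param nPerm segmentation permutations.
#' @return list: `profiles`, `matrix`, `test` (from
#'   [groupConcordanceTest()]), `medians`, `segmentMeans` (per-chromosome
#'   mean segment ratio of the first cell).
#' @export
runCNAnalysis <- function(truth = pc3CNPreset(), nPerGroup = 4, seed = 17L,
                          nPerm = 200) {
    typical <- simulateCNCells(truth, nPerGroup, seed = seed)
    doubled <- cnGroundTruth(truth$grid, truth$cnStates,
                             wgdFactor = truth$wgdFactor * 2L,
                             readsPerCell = truth$readsPerCell)
    igc <- simulateCNCells(doubled, nPerGroup, seed = .deriveSeed(seed, 99L))
    set.seed(.deriveSeed(seed, 100L))
    mk <- function(counts, tag) lapply(seq_len(nrow(counts)), function(i)
        segmentProfile(normalizeRatios(counts[i, ], truth$grid,
                                       cellId = paste0(tag, i)),
                       nPerm = nPerm))
    profiles <- c(mk(typical, "typ"), mk(igc, "igc"))
    labels <- rep(c("typical", "igc"), each = nPerGroup)
    cm <- concordanceMatrix(profiles)
    test <- groupConcordanceTest(cm, labels)
    chr <- as.character(GenomicRanges::seqnames(truth$grid))
    segMeans <- tapply(segmentRatio(profiles[[1]]), chr, mean)
    list(profiles = profiles, matrix = cm, test = test,
         medians = attr(test, "medians"), segmentMeans = segMeans)
}

.knownConfigKeys <- c("seed", "out_dir", "modules", "cohort_preset",
                      "rna_genes", "cn_bins", "cn_cells_per_group",
                      "lfc_thresh", "fdr_thresh")

#' Validate a pipeline run configuration
#'
#' @param config named list (or YAML path). Unknown keys are rejected with
#'   an error naming the key.
#' @return the normalized config list.
#' @export
validateRunConfig <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    stopifnot(is.list(config))
    unknown <- setdiff(names(config), .knownConfigKeys)
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    defaults <- list(seed = 17L, out_dir = NULL,
                     modules = c("cohort", "rna", "cn"),
                     cohort_preset = "cohort_preset_A",
                     rna_genes = 20000L, cn_bins = 5000L,
                     cn_cells_per_group = 4L,
                     lfc_thresh = 1.5, fdr_thresh = 0.01)
    for (nm in names(defaults))
        if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
    stopifnot(all(config$modules %in% c("cohort", "rna", "cn")))
    config
}

#' Run the end-to-end analysis and emit a report
#'
#' Chains generation, imaging, classification, copy-number, transcriptome
#' and survival stages per the configuration, and returns (and optionally
#' writes) a JSON-serializable report. The same config and seed always
#' produce an identical report.
#'
#' @param config named list or YAML path; see [validateRunConfig()].
#' @return report list (invisibly written to `<out_dir>/report.json` and
#'   `<out_dir>/report.txt` when `out_dir` is set, alongside the echoed
#'   config).
#' @export
runPipeline <- function(config = list()) {
    config <- validateRunConfig(config)
    report <- list(config = config[setdiff(names(config), "out_dir")],
                   seed = config$seed)
    if ("cohort" %in% config$modules) {
        preset <- if (identical(config$cohort_preset, "cohort_preset_A"))
            cohortPresetA() else loadCohortPreset(config$cohort_preset)
        res <- tryCatch(runCohortAnalysis(preset, seed = config$seed),
                        error = function(e)
                            stop("stage cohort failed: ", conditionMessage(e)))
        report$cohort <- list(
            blood_percent = res$bloodPercent,
            marrow_percent = res$marrowPercent,
            n_matched = sum(res$cohort$matched),
            n_patients = nrow(res$cohort),
            marrow_positive_detected = sum(res$cohort$marrow_igc_detected),
            logrank_p = if (!is.null(res$logrank)) res$logrank$p.value else NA)
    }
    if ("rna" %in% config$modules) {
        preset <- signaturePresetA(nGenes = config$rna_genes)
        res <- tryCatch(
            runSignatureAnalysis(preset, seed = config$seed,
                                 lfcThresh = config$lfc_thresh,
                                 fdrThresh = config$fdr_thresh),
            error = function(e)
                stop("stage rna failed: ", conditionMessage(e)))
        bt <- res$biotypes
        report$rna <- list(
            line_set_sizes = as.list(res$sizes[names(res$sets$lineSets)]),
            survivor_set_size = length(res$sets$survivorSet),
            biotype_percent = stats::setNames(as.list(bt$percent),
                                              bt$biotype))
    }
    if ("cn" %in% config$modules) {
        truth <- pc3CNPreset(nBins = config$cn_bins)
        res <- tryCatch(
            runCNAnalysis(truth, nPerGroup = config$cn_cells_per_group,
                          seed = config$seed),
            error = function(e)
                stop("stage cn failed: ", conditionMessage(e)))
        report$cn <- list(
            medians = as.list(res$medians),
            chr1_mean_ratio = unname(res$segmentMeans["chr1"]),
            chr10_mean_ratio = unname(res$segmentMeans["chr10"]))
    }
    validateReport(report)
    if (!is.null(config$out_dir)) {
        dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
        jsonlite::write_json(report,
                             file.path(config$out_dir, "report.json"),
                             auto_unbox = TRUE, digits = 10, pretty = TRUE)
        yaml::write_yaml(config, file.path(config$out_dir, "config.yaml"))
        writeLines(utils::capture.output(utils::str(report, max.level = 3)),
                   file.path(config$out_dir, "report.txt"))
    }
    invisible(report)
}

#' Check a report against the shipped schema
#'
#' Verifies the required keys and value types declared in the package's
#' report schema (`inst/schema/report-schema.json`).
#'
#' @param report list from [runPipeline()].
#' @return TRUE invisibly; errors on violation.
#' @export
validateReport <- function(report) {
    schema <- jsonlite::read_json(system.file("schema", "report-schema.json",
                                              package = "polyCTC"))
    req <- unlist(schema$required)
    missing <- setdiff(req, names(report))
    if (length(missing))
        stop("report missing required field(s): ",
             paste(missing, collapse = ", "))
    if (!is.numeric(report$seed) && !is.integer(report$seed))
        stop("report seed must be numeric")
    invisible(TRUE)
}
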