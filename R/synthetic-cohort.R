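#' Cohort simulation preset
#'
#' Parameters of a synthetic matched blood/bone-marrow cohort: how many
#' patients, how many of their slides carry planted CTC-IGC cells, and the
#' exponential progression hazards by positivity group. IGC-positive patients
#' progress faster (`hazardPos > hazardNeg`).
#'
#' @param nMatched patients with both a blood and a marrow slide.
#' @param nMarrowOnly additional marrow-only patients.
#' @param bloodIgcPositive matched patients whose blood slide carries planted
#'   IGC cells (subset of the marrow-positive patients).
#' @param marrowIgcPositive matched patients whose marrow slide carries
#'   planted IGC cells.
#' @param marrowOnlyIgcPositive marrow-only patients with planted IGC cells.
#' @param hazardPos,hazardNeg exponential PFS rates (per month) for
#'   IGC-positive / negative patients.
#' @param censorRate probability a patient is censored (uniformly before the
#'   true progression time).
#' @param slide list of slide-level parameters (dimensions, noise, per-class
#'   counts, diameters, intensities); see `cohortPresetA()` for the shipped
#'   values.
#' @return A `CohortPreset` list.
#' @export
cohortPreset <- function(nMatched, nMarrowOnly, bloodIgcPositive,
                         marrowIgcPositive, marrowOnlyIgcPositive = 0,
                         hazardPos = 0.25, hazardNeg = 1 / 12,
                         censorRate = 0.2, slide = list()) {
    stopifnot(nMatched >= 0, nMarrowOnly >= 0,
              bloodIgcPositive <= nMatched, marrowIgcPositive <= nMatched,
              bloodIgcPositive <= marrowIgcPositive,
              marrowOnlyIgcPositive <= nMarrowOnly,
              hazardPos > hazardNeg, censorRate >= 0, censorRate < 1)
    structure(list(nMatched = as.integer(nMatched),
                   nMarrowOnly = as.integer(nMarrowOnly),
                   bloodIgcPositive = as.integer(bloodIgcPositive),
                   marrowIgcPositive = as.integer(marrowIgcPositive),
                   marrowOnlyIgcPositive = as.integer(marrowOnlyIgcPositive),
                   hazardPos = hazardPos, hazardNeg = hazardNeg,
                   censorRate = censorRate, slide = slide),
              class = "CohortPreset")
}

.defaultSlideParams <- function() {
    list(width = 800L, height = 800L, pixelSize = 1, backgroundLevel = 500,
         noiseSd = 50,
         wbcPerSlide = 500L, ctcPerSlide = 8L, igcPerPositive = 2L,
         wbc = list(nucDiam = 7, nucSd = 0.4, cellDiam = 10, cellSd = 0.5,
                    intensity = c(DAPI = 8000, EPI = 0, CD45 = 9000, VAR = 0)),
         ctc = list(nucDiam = 12, nucSd = 0.5, cellDiam = 18, cellSd = 1,
                    intensity = c(DAPI = 8000, EPI = 9000, CD45 = 0, VAR = 0)),
         igc = list(nucDiam = 28, nucSd = 1, cellDiam = 36, cellSd = 1.5,
                    intensity = c(DAPI = 8000, EPI = 9000, CD45 = 0, VAR = 0)),
         segmentOffset = 2600, segmentMinArea = 20)
}

#' The matched-cohort preset
#'
#' 31 matched blood/marrow patients plus 13 marrow-only patients. Among the
#' matched patients, 3 blood slides and 25 marrow slides carry planted
#' CTC-IGC (3/31 = 9.7%, 25/31 = 80.6%); 10 of the 13 marrow-only patients
#' are positive. Loaded from the shipped YAML config.
#'
#' @return A `CohortPreset`.
#' @export
cohortPresetA <- function() {
    path <- system.file("extdata", "cohort_preset_A.yaml", package = "polyCTC")
    loadCohortPreset(path)
}

#' Read a cohort preset from YAML
#'
#' @param path YAML file with the fields of [cohortPreset()].
#' @return A `CohortPreset`.
#' @export
loadCohortPreset <- function(path) {
    y <- yaml::read_yaml(path)
    slide <- .defaultSlideParams()
    for (nm in names(y$slide)) {
        if (nm %in% c("wbc", "ctc", "igc")) {
            for (nm2 in names(y$slide[[nm]])) {
                v <- y$slide[[nm]][[nm2]]
                if (nm2 == "intensity") v <- unlist(v)
                slide[[nm]][[nm2]] <- v
            }
        } else slide[[nm]] <- y$slide[[nm]]
    }
    cohortPreset(nMatched = y$n_matched, nMarrowOnly = y$n_marrow_only,
                 bloodIgcPositive = y$blood_igc_positive,
                 marrowIgcPositive = y$marrow_igc_positive,
                 marrowOnlyIgcPositive = y$marrow_only_igc_positive,
                 hazardPos = y$hazard_pos, hazardNeg = y$hazard_neg,
                 censorRate = y$censor_rate, slide = slide)
}

.slideSpecFor <- function(sl, positive, seed) {
    mk <- function(p, label, count)
        cellClassSpec(label, count, p$nucDiam, p$nucSd, p$cellDiam, p$cellSd,
                      p$intensity)
    classes <- list(mk(sl$wbc, "WBC", sl$wbcPerSlide),
                    mk(sl$ctc, "CTC", sl$ctcPerSlide))
    if (positive)
        classes <- c(classes, list(mk(sl$igc, "CTC_IGC", sl$igcPerPositive)))
    slideSpec(sl$width, sl$height, pixelSize = sl$pixelSize,
              backgroundLevel = sl$backgroundLevel, noiseSd = sl$noiseSd,
              cellClasses = classes, seed = seed)
}

#' Simulate a matched blood/bone-marrow cohort
#'
#' Draws which patients carry planted CTC-IGC on each compartment's slide
#' (exactly the preset's positive counts; blood positives are a subset of
#' marrow positives), builds one [slideSpec()] per patient compartment, and
#' simulates progression-free survival: exponential by marrow-positivity
#' group, with independent uniform censoring at the preset's rate.
#'
#' @param preset a [cohortPreset()].
#' @param seed integer seed.
#' @return list with `cohort` (one row per patient: ids, planted positivity,
#'   `group`, `time_months`, `event`) and `slides` (named list of
#'   `SlideSpec`s, names `"<patient>_blood"` / `"<patient>_marrow"`).
#' @export
simulateCohort <- function(preset, seed = 17L) {
    stopifnot(inherits(preset, "CohortPreset"))
    set.seed(seed)
    sl <- if (length(preset$slide)) preset$slide else .defaultSlideParams()
    nM <- preset$nMatched; nO <- preset$nMarrowOnly
    ids <- sprintf("P%03d", seq_len(nM + nO))
    matched <- c(rep(TRUE, nM), rep(FALSE, nO))
    marrowPos <- rep(FALSE, nM + nO)
    if (nM > 0)
        marrowPos[sample(seq_len(nM), preset$marrowIgcPositive)] <- TRUE
    if (nO > 0)
        marrowPos[nM + sample(seq_len(nO), preset$marrowOnlyIgcPositive)] <- TRUE
    bloodPos <- rep(FALSE, nM + nO)
    mpMatched <- which(marrowPos[seq_len(nM)])
    if (preset$bloodIgcPositive > 0)
        bloodPos[sample(mpMatched, preset$bloodIgcPositive)] <- TRUE

    slides <- list()
    for (i in seq_len(nM + nO)) {
        if (matched[i])
            slides[[paste0(ids[i], "_blood")]] <-
                .slideSpecFor(sl, bloodPos[i], .deriveSeed(seed, 2L * i))
        slides[[paste0(ids[i], "_marrow")]] <-
            .slideSpecFor(sl, marrowPos[i], .deriveSeed(seed, 2L * i + 1L))
    }
    haz <- ifelse(marrowPos, preset$hazardPos, preset$hazardNeg)
    tTrue <- rexp(nM + nO, rate = haz)
    cens <- runif(nM + nO) < preset$censorRate
    time <- ifelse(cens, runif(nM + nO) * tTrue, tTrue)
    cohort <- data.frame(patient_id = ids, matched = matched,
                         blood_igc_planted = bloodPos,
                         marrow_igc_planted = marrowPos,
                         group = marrowPos,
                         time_months = time, event = as.integer(!cens),
                         stringsAsFactors = FALSE)
    list(cohort = cohort, slides = slides)
}
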