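## End-to-end driver: simulate -> preprocess -> quantify -> statistics,
## with every parameter echoed into the output provenance.

.cfgGet <- function(config, section, field, default = NULL,
                    required = FALSE) {
    v <- config[[section]][[field]]
    if (is.null(v)) {
        if (required)
            stop("config field ", section, "$", field, " is missing")
        return(default)
    }
    v
}

## the standard enrichment analysis for one simulated embryo: focus plane
## from the tubulin channel, 3-slice sum projection, slide-background
## subtraction, 2-um box ratio
.analyzeEnrichment <- function(sim, embryo = NA_character_) {
    ann <- sim$annotation
    px <- pixelSize(sim$marker)
    z <- selectFocusPlane(sim$tubulin, ann@gutBox)
    proj <- sumProject(sim$marker, z, 3L)
    bg <- estimateSlideBackground(proj, ann@bgRects, px)
    apicalEnrichment(proj, ann, px, slideBg = bg, embryo = embryo)
}

## gut/external box means for one embryo on the projected,
## slide-background-subtracted marker channel
.analyzeDepletionInputs <- function(sim, embryo = NA_character_) {
    ann <- sim$annotation
    px <- pixelSize(sim$marker)
    z <- selectFocusPlane(sim$tubulin, ann@gutBox)
    proj <- sumProject(sim$marker, z, 3L)
    bg <- estimateSlideBackground(proj, ann@bgRects, px)
    measureDepletionInputs(proj, ann, px, slideBg = bg, embryo = embryo)
}

#' Percent depletion for a simulated sibling cohort
#'
#' Runs the full still-image pipeline (focus-plane selection on the
#' tubulin channel, 3-slice sum projection, slide-background
#' subtraction) on every embryo of a [simulateDepletionCohort()] result,
#' estimates autofluorescence from the no-fluorophore controls, and
#' applies the percent-depletion formula.
#'
#' @param cohort result of [simulateDepletionCohort()].
#' @return As [percentDepletion()], plus `minus`/`plus` input tables.
#' @export
analyzeDepletionCohort <- function(cohort) {
    minus <- do.call(rbind, lapply(seq_along(cohort$minus), function(i)
        .analyzeDepletionInputs(cohort$minus[[i]], paste0("minus", i))))
    plus <- do.call(rbind, lapply(seq_along(cohort$plus), function(i)
        .analyzeDepletionInputs(cohort$plus[[i]], paste0("plus", i))))
    ctrl <- do.call(rbind, lapply(seq_along(cohort$controls), function(i)
        .analyzeDepletionInputs(cohort$controls[[i]], paste0("ctrl", i))))
    auto <- mean(ctrl$G)
    res <- percentDepletion(minus, plus, auto = auto)
    res$minus <- minus; res$plus <- plus; res$controls <- ctrl
    res
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes simulate, preprocess, quantify and statistics stages
#' according to a configuration (a YAML file path or an equivalent
#' nested list), writing CSV tables, a profile plot, a kymograph TIFF,
#' and a provenance record (full config echo, seed, package version)
#' into the output directory. Re-running with the same configuration is
#' bit-identical.
#'
#' Config sections: `scene` (must include `pixelSize`; other
#' [SceneParams()] arguments optional), `truth` ([GroundTruth()]
#' arguments), `run` with `seed`, `outputDir` and `analyses` (any of
#' `"enrichment"`, `"depletion"`, `"comets"`), plus optional sizes
#' `nEmbryos`, `nMinus`, `nPlus`, `nControls`, `duration`, `geometry`.
#'
#' @param config path to a YAML file, or a nested list.
#' @return Invisibly, a list of per-analysis results.
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- yaml::read_yaml(config)
    stopifnot(is.list(config))
    .cfgGet(config, "scene", "pixelSize", required = TRUE)
    scene <- do.call(SceneParams, config$scene)
    truth <- do.call(GroundTruth, if (is.null(config$truth)) list()
                     else config$truth)
    seed <- .cfgGet(config, "run", "seed", 1L)
    outDir <- .cfgGet(config, "run", "outputDir", required = TRUE)
    analyses <- .cfgGet(config, "run", "analyses", "enrichment")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    logFile <- file.path(outDir, "run.log")
    logLines <- character()
    note <- function(...) {
        msg <- paste0(...)
        logLines <<- c(logLines, msg)
        message(msg)
    }
    results <- list()

    if ("enrichment" %in% analyses) {
        n <- .cfgGet(config, "run", "nEmbryos", 10L)
        note("[enrichment] simulating and measuring ", n, " embryos")
        rows <- list(); profs <- list()
        for (i in seq_len(n)) {
            sim <- simulatePrimordium(scene, truth, seed = seed + i)
            rows[[i]] <- .analyzeEnrichment(sim, paste0("embryo", i))
            ann <- sim$annotation
            px <- pixelSize(sim$marker)
            z <- selectFocusPlane(sim$tubulin, ann@gutBox)
            proj <- sumProject(sim$marker, z, 3L)
            bg <- estimateSlideBackground(proj, ann@bgRects, px)
            profs[[i]] <- lineProfile(subtractScalar(proj, bg),
                                      midline(ann), px,
                                      embryo = paste0("embryo", i))
        }
        enr <- do.call(rbind, rows)
        summ <- summarizeProfiles(profs)
        write.csv(enr, file.path(outDir, "enrichment.csv"),
                  row.names = FALSE)
        write.csv(summ$profile, file.path(outDir, "profile_mean.csv"),
                  row.names = FALSE)
        grDevices::pdf(file.path(outDir, "profile_plot.pdf"), width = 5,
                       height = 4)
        with(summ$profile, {
            plot(distance, mean, type = "l",
                 xlab = "distance from midline (um)",
                 ylab = "intensity (a.u.)",
                 main = "cohort mean profile (+-SD)")
            graphics::polygon(c(distance, rev(distance)),
                              c(mean + sd, rev(mean - sd)),
                              border = NA,
                              col = grDevices::adjustcolor("grey", 0.5))
            graphics::lines(distance, mean)
        })
        grDevices::dev.off()
        note("[enrichment] cohort mean ratio = ",
             signif(mean(enr$ratio), 4))
        results$enrichment <- list(table = enr, profiles = summ)
    }

    if ("depletion" %in% analyses) {
        nM <- .cfgGet(config, "run", "nMinus", 12L)
        nP <- .cfgGet(config, "run", "nPlus", 12L)
        nC <- .cfgGet(config, "run", "nControls", 5L)
        note("[depletion] cohorts: ", nM, " gut(-), ", nP, " gut(+), ",
             nC, " controls")
        cohort <- simulateDepletionCohort(scene, truth, nM, nP, nC,
                                          seed = seed + 1000L)
        dep <- analyzeDepletionCohort(cohort)
        write.csv(rbind(cbind(cohort = "minus", dep$minus),
                        cbind(cohort = "plus", dep$plus),
                        cbind(cohort = "control", dep$controls)),
                  file.path(outDir, "depletion_inputs.csv"),
                  row.names = FALSE)
        write.csv(data.frame(percent = dep$percent,
                             signalMinus = dep$signalMinus,
                             signalPlus = dep$signalPlus, auto = dep$auto),
                  file.path(outDir, "depletion.csv"), row.names = FALSE)
        note("[depletion] percent depletion = ", signif(dep$percent, 4))
        results$depletion <- dep
    }

    if ("comets" %in% analyses) {
        n <- .cfgGet(config, "run", "nEmbryos", 10L)
        duration <- .cfgGet(config, "run", "duration", 10)
        geometry <- .cfgGet(config, "run", "geometry", "midline")
        note("[comets] simulating and measuring ", n, " movies (",
             geometry, ")")
        rows <- list()
        for (i in seq_len(n)) {
            sim <- simulateCometMovie(scene, truth, duration = duration,
                                      seed = seed + 2000L + i,
                                      geometry = geometry)
            mov <- bleachCorrect(sim$movie)
            speeds <- measureCometSpeeds(mov, sim$annotation,
                                         geometry = geometry)
            ems <- embryoMeanSpeed(speeds,
                                   context = if (geometry == "midline")
                                       "E16" else "two_cell")
            cr <- if (geometry == "midline")
                countCrossings(mov, midline(sim$annotation),
                               window = min(10, duration))$total
                else NA_integer_
            rows[[i]] <- data.frame(genotype = "sim",
                                    embryo = paste0("embryo", i),
                                    meanSpeed = ems$mean, nComets = ems$n,
                                    status = ems$status, crossings = cr)
            if (i == 1L) {
                ann <- sim$annotation
                ml <- midline(ann)
                mid <- (ml[1L, ] + ml[2L, ]) / 2
                fr <- .pathFrame(ml)
                reach <- scene@primordiumHalfWidth
                ky <- makeKymograph(mov, rbind(mid, mid + reach * fr$dplus))
                writeCalibrated(ky, file.path(outDir, "kymograph.tif"))
            }
        }
        comets <- do.call(rbind, rows)
        write.csv(comets, file.path(outDir, "comets.csv"),
                  row.names = FALSE)
        ok <- comets[comets$status == "ok", , drop = FALSE]
        summ <- if (nrow(ok)) suppressWarnings(genotypeSummary(ok))
                else data.frame()
        if (nrow(ok))
            note("[comets] mean of embryo means = ",
                 signif(mean(ok$meanSpeed), 4), " um/s; mean crossings = ",
                 signif(mean(ok$crossings), 4))
        results$comets <- list(table = comets, summary = summ)
    }

    prov <- list(config = config, seed = seed,
                 package = "mtocQuant",
                 version = as.character(packageVersion("mtocQuant")))
    jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(logLines, logFile)
    invisible(results)
}
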