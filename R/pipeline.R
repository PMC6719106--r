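#' Adjusted Rand index against planted module labels
#'
#' Compares recovered module labels with the generator's ground truth.
#' By default the index is computed over the features that carry a
#' planted module label, measuring how well the planted partition is
#' recovered.  With \code{background = TRUE} unplanted features are
#' included as one extra class (\code{background} in truth, \code{grey}
#' in recovery); that variant additionally penalises noise features
#' absorbed into module branches by the static cut.
#'
#' @param moduleSet a \linkS4class{ModuleSet}.
#' @param moduleOf named ground-truth labels (feature -> planted module or
#'   \code{background}).
#' @param background include unplanted features as one class.
#' @return the adjusted Rand index.
#' @export
plantedModuleARI <- function(moduleSet, moduleOf, background = FALSE) {
    feats <- names(moduleLabels(moduleSet))
    truth <- moduleOf[feats]
    if (anyNA(truth)) stop("ground truth missing for some features")
    if (!background) feats <- feats[truth[feats] != "background"]
    if (!length(feats)) stop("no planted features among the clustered set")
    mclust::adjustedRandIndex(unname(truth[feats]),
                              unname(moduleLabels(moduleSet)[feats]))
}

#' Match recovered modules to planted modules
#'
#' For each planted module, the recovered module holding the plurality of
#' its members, with the member overlap and whether the recovered temporal
#' class equals the planted one.
#'
#' @param moduleSet a \linkS4class{ModuleSet}.
#' @param design the \linkS4class{SimulationDesign} that planted the
#'   modules.
#' @param moduleOf named ground-truth labels.
#' @return data.frame: planted, plantedClass, recovered, overlap, size,
#'   recoveredClass, classCorrect.
#' @export
matchPlantedModules <- function(moduleSet, design, moduleOf) {
    labels <- moduleLabels(moduleSet)
    rows <- lapply(design@plantedModules, function(pm) {
        members <- intersect(names(moduleOf)[moduleOf == pm@label],
                             names(labels))
        rec <- if (length(members)) {
            tab <- sort(table(labels[members]), decreasing = TRUE)
            names(tab)[1]
        } else NA_character_
        recClass <- if (!is.na(rec) && rec != "grey")
            temporalClasses(moduleSet)[[rec]] else "none"
        data.frame(planted = pm@label, plantedClass = pm@temporalClass,
                   recovered = rec,
                   overlap = if (is.na(rec)) 0L else
                       sum(labels[members] == rec),
                   size = length(members),
                   recoveredClass = recClass,
                   classCorrect = identical(recClass, pm@temporalClass))
    })
    do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Run the full pipeline
#'
#' Orchestrates every stage on a synthetic bundle (generated from
#' \code{design} unless \code{bundle} is supplied): identification,
#' positional classification, conservation contrasts, stage-wise
#' differential expression, co-expression module detection with temporal
#' classification, target-network assembly with hub extraction, and
#' per-module enrichment.  Stages run in dependency order; \code{steps}
#' selects a prefix-closed subset.  All randomness derives from the design
#' seed, so identical inputs reproduce identical outputs.
#'
#' @param design a \linkS4class{SimulationDesign}.
#' @param config a \linkS4class{PipelineConfig}.
#' @param bundle optional pre-generated bundle (from
#'   \code{\link{simulateBundle}}).
#' @param steps stages to execute, in order.
#' @param outdir optional directory for tabular outputs.
#' @param beta optional fixed soft-threshold power.
#' @return a list of per-stage results plus a \code{manifest} echoing the
#'   configuration, seed and completion flags.
#' @export
runPipeline <- function(design = simulationDesign(),
                        config = pipelineConfig(), bundle = NULL,
                        steps = c("identify", "conserve", "de", "modules",
                                  "targets", "enrich"),
                        outdir = NULL, beta = NULL) {
    known <- c("identify", "conserve", "de", "modules", "targets",
               "enrich")
    bad <- setdiff(steps, known)
    if (length(bad)) stop("unknown step(s): ", paste(bad, collapse = ", "))
    if (is.null(bundle)) bundle <- simulateBundle(design, outdir = outdir)
    annot <- bundle$annotation
    se <- bundle$expression
    run <- list(design = design, config = config, bundle = bundle)
    done <- character()

    if ("identify" %in% steps) {
        idf <- applyIdentificationFilter(annot, bundle$verdicts, config)
        classes <- classifyLncrnaPosition(annot, idf$retained)
        run[["identify"]] <- list(
            filter = idf, classes = classes,
            composition = typeComposition(classes),
            venn = vennCodingPotential(bundle$verdicts))
        done <- c(done, "identify")
    }

    if ("conserve" %in% steps && "identify" %in% done) {
        retained <- run[["identify"]]$filter$retained
        hits <- bundle$hits[bundle$hits$query %in% retained, ,
                            drop = FALSE]
        species <- sort(unique(hits$species))
        per <- lapply(species, function(sp) {
            h <- hits[hits$species == sp, , drop = FALSE]
            loose <- filterHitsByEvalue(h, config@evalueLoose)
            strict <- filterHitsByEvalue(h, config@evalueStrict)
            list(species = sp, loose = loose, strict = strict,
                 fractionLoose = matchedFraction(length(retained),
                                                 length(loose)))
        })
        names(per) <- species
        bgSp <- if ("cow" %in% species) "cow" else species[1]
        contrasts <- lapply(setdiff(species, bgSp), function(sp)
            c(list(species = sp, background = bgSp),
              stringencyContrast(length(per[[sp]]$loose),
                                 length(per[[sp]]$strict),
                                 length(per[[bgSp]]$loose),
                                 length(per[[bgSp]]$strict))))
        run[["conserve"]] <- list(
            perSpecies = per, contrasts = contrasts,
            scoreRetained = filterByScore(bundle$scores,
                                          config@phastconsMin))
        done <- c(done, "conserve")
    }

    if ("de" %in% steps && "identify" %in% done) {
        retained <- run[["identify"]]$filter$retained
        meta <- transcriptMeta(annot)
        mrnaTx <- meta$transcript_id[meta$biotype == "mRNA"]
        seGene <- geneLevelFpkm(se[mrnaTx, ], annot)
        lncDe <- deUnion(se, config, features = retained)
        mrnaDe <- deUnion(seGene, config)
        detection <- stageDetectionSummary(se[retained, ], config)
        run[["de"]] <- list(lnc = lncDe, mrna = mrnaDe, detection = detection,
                       seGene = seGene)
        done <- c(done, "de")
    }

    if ("modules" %in% steps && "de" %in% done &&
        length(run[["de"]]$lnc$union) >= 2) {
        ms <- detectModules(se, features = run[["de"]]$lnc$union, config,
                            beta = beta)
        run[["modules"]] <- list(moduleSet = ms)
        if (!is.null(bundle$truth)) {
            run[["modules"]]$ari <- plantedModuleARI(ms, bundle$truth$moduleOf)
            run[["modules"]]$ariWithBackground <-
                plantedModuleARI(ms, bundle$truth$moduleOf,
                                 background = TRUE)
            run[["modules"]]$planted <- matchPlantedModules(ms, design,
                                                       bundle$truth$moduleOf)
        }
        done <- c(done, "modules")
    }

    if ("targets" %in% steps && "de" %in% done) {
        deLnc <- run[["de"]]$lnc$union
        deGenes <- run[["de"]]$mrna$union
        seNet <- StageExpression(
            rbind(fpkm(se)[deLnc, , drop = FALSE],
                  fpkm(run[["de"]]$seGene)[deGenes, , drop = FALSE]),
            as.character(stageOf(se)),
            stageLevels = levels(stageOf(se)))
        cis <- cisTargets(annot, deLnc, config)
        coex <- coexpressionTargets(seNet, deLnc, deGenes, config)
        net <- buildTargetNetwork(run[["de"]]$lnc$results, cis, coex, config)
        run[["targets"]] <- list(cis = cis, coexpression = coex, network = net,
                            hubs = hubLncrnas(net, config))
        done <- c(done, "targets")
    }

    if ("enrich" %in% steps && all(c("modules", "targets") %in% done)) {
        meta <- transcriptMeta(annot)
        population <- sort(unique(meta$gene_id[meta$biotype == "mRNA"]))
        labels <- moduleLabels(run[["modules"]]$moduleSet)
        edges <- networkEdges(run[["targets"]]$network)
        run[["enrich"]] <- lapply(run[["modules"]]$moduleSet@moduleOrder,
                             function(m) {
            lncs <- names(labels)[labels == m]
            study <- sort(unique(edges$gene[edges$lncrna %in% lncs]))
            if (!length(study)) return(NULL)
            hypergeometricEnrichment(study, population, bundle$term2genes)
        })
        names(run$enrich) <- run[["modules"]]$moduleSet@moduleOrder
        done <- c(done, "enrich")
    }

    run$manifest <- list(
        seed = design@seed,
        config = stats::setNames(
            lapply(slotNames(config), function(s) slot(config, s)),
            slotNames(config)),
        stepsCompleted = done)
    if (!is.null(outdir)) writeRunTables(run, outdir)
    run
}

## Tabular outputs for a completed run.
writeRunTables <- function(run, outdir) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(outdir, f)
    if (!is.null(run[["identify"]]))
        writeTsv(run[["identify"]]$filter$table, p("identification.tsv"))
    if (!is.null(run[["de"]]))
        writeTsv(run[["de"]]$lnc$pairCounts, p("de_pair_counts.tsv"))
    if (!is.null(run[["modules"]])) {
        ms <- run[["modules"]]$moduleSet
        writeTsv(data.frame(feature_id = names(moduleLabels(ms)),
                            module = unname(moduleLabels(ms))),
                 p("modules.tsv"))
        writeTsv(traitStats(ms), p("module_trait.tsv"))
    }
    if (!is.null(run[["targets"]])) {
        writeTsv(networkEdges(run[["targets"]]$network), p("target_edges.tsv"))
        writeTsv(run[["targets"]]$hubs$hubs, p("hub_lncrnas.tsv"))
    }
    jsonlite::write_json(run$manifest, p("run_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(outdir)
}

#' Summary report for a pipeline run
#'
#' Formats counts, percentages, the module table with temporal classes,
#' hubs and top enriched terms as plain text.
#'
#' @param run a \code{\link{runPipeline}} result.
#' @param topN enrichment rows per module.
#' @return character vector of report lines, invisibly printed with
#'   \code{cat}.
#' @export
pipelineReport <- function(run, topN = 10) {
    lines <- c("== lncTempo pipeline report ==",
               sprintf("seed: %d", run$manifest$seed),
               sprintf("steps: %s",
                       paste(run$manifest$stepsCompleted,
                             collapse = ", ")))
    if (!is.null(run[["identify"]])) {
        f <- run[["identify"]]$filter
        lines <- c(lines, "",
                   sprintf("lncRNA candidates retained: %d (dropped: %s)",
                           length(f$retained),
                           paste(names(f$drops), f$drops, sep = "=",
                                 collapse = ", ")))
        cm <- run[["identify"]]$composition
        lines <- c(lines, apply(cm, 1, function(r)
            sprintf("  %-18s %4s  (%.1f%%)", r[["class"]], r[["count"]],
                    100 * as.numeric(r[["proportion"]]))))
    }
    if (!is.null(run[["conserve"]])) {
        lines <- c(lines, "")
        for (sp in names(run[["conserve"]]$perSpecies)) {
            x <- run[["conserve"]]$perSpecies[[sp]]
            lines <- c(lines, sprintf(
                "matched to %-6s %4d (%.2f%%) loose, %d strict", sp,
                length(x$loose), x$fractionLoose$percent,
                length(x$strict)))
        }
    }
    if (!is.null(run[["de"]])) {
        lines <- c(lines, "",
                   sprintf("DE lncRNAs: %d, DE mRNA genes: %d",
                           length(run[["de"]]$lnc$union),
                           length(run[["de"]]$mrna$union)),
                   sprintf("detected in all stages: %d (%d%%)",
                           run[["de"]]$detection$nSharedAll,
                           run[["de"]]$detection$percentSharedAll))
    }
    if (!is.null(run[["modules"]])) {
        ms <- run[["modules"]]$moduleSet
        lines <- c(lines, "", sprintf("modules (beta = %g):", ms@beta))
        for (m in ms@moduleOrder)
            lines <- c(lines, sprintf(
                "  %-12s %4d features, class %s", m,
                sum(moduleLabels(ms) == m), temporalClasses(ms)[[m]]))
        if (!is.null(run[["modules"]]$ari))
            lines <- c(lines, sprintf(
                "  adjusted Rand index vs planted: %.3f",
                run[["modules"]]$ari))
    }
    if (!is.null(run[["targets"]])) {
        h <- run[["targets"]]$hubs$hubs
        lines <- c(lines, "",
                   sprintf("target network: %d edges, %d hub lncRNAs",
                           nrow(networkEdges(run[["targets"]]$network)),
                           nrow(h)))
        if (nrow(h))
            lines <- c(lines, utils::capture.output(print(
                utils::head(h, 10))))
    }
    if (!is.null(run[["enrich"]])) {
        for (m in names(run$enrich)) {
            e <- run$enrich[[m]]
            if (is.null(e)) next
            lines <- c(lines, "", sprintf("top terms, module %s:", m))
            lines <- c(lines, utils::capture.output(print(
                utils::head(e[, c("term_id", "k", "K", "p_value",
                                  "q_value")], topN))))
        }
    }
    cat(lines, sep = "\n")
    invisible(lines)
}
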