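#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Pipeline thresholds
#'
#' Every numeric cut-off used by the pipeline lives in one object so that a
#' run can be reproduced from its configuration alone.  Defaults follow the
#' conventions of staged lncRNA surveys: a lncRNA is longer than 200 nt
#' (exclusive) with at least 2 exons; homology calls use a loose (1e-3) and a
#' strict (1e-10) E-value cut, both exclusive; conservation scores must
#' exceed 0.8; differential expression uses raw p < 0.05; module-stage
#' correlations are called at r > 0.6 and p < 0.05; co-expression targeting
#' requires |r| > 0.95; the fold-change screen is |FC| > 2 on the linear
#' scale; hubs have degree > 10; the cis window is 100 kb inclusive; a
#' feature counts as detected in a stage when its mean FPKM exceeds 0.1.
#'
#' @slot minLengthNt numeric, exclusive transcript-length cut (nt).
#' @slot minExons numeric, inclusive minimum exon count.
#' @slot evalueLoose,evalueStrict numeric, exclusive E-value cuts.
#' @slot phastconsMin numeric, exclusive conservation-score cut.
#' @slot deAlpha numeric, differential-expression alpha.
#' @slot moduleTraitRMin,moduleTraitAlpha numeric, module-stage calls.
#' @slot coexprAbsRMin numeric, exclusive |r| cut for co-expression targets.
#' @slot fcMin numeric, linear fold-change cut (|log2FC| >= log2(fcMin)).
#' @slot hubMinDegree numeric, exclusive hub degree cut.
#' @slot cisWindowBp numeric, inclusive cis window (bp).
#' @slot detectionFpkmMin numeric, stage-detection FPKM cut.
#' @exportClass PipelineConfig
setClass("PipelineConfig", representation(
    minLengthNt      = "numeric",
    minExons         = "numeric",
    evalueLoose      = "numeric",
    evalueStrict     = "numeric",
    phastconsMin     = "numeric",
    deAlpha          = "numeric",
    moduleTraitRMin  = "numeric",
    moduleTraitAlpha = "numeric",
    coexprAbsRMin    = "numeric",
    fcMin            = "numeric",
    hubMinDegree     = "numeric",
    cisWindowBp      = "numeric",
    detectionFpkmMin = "numeric"
), prototype(
    minLengthNt = 200, minExons = 2, evalueLoose = 1e-3,
    evalueStrict = 1e-10, phastconsMin = 0.8, deAlpha = 0.05,
    moduleTraitRMin = 0.6, moduleTraitAlpha = 0.05, coexprAbsRMin = 0.95,
    fcMin = 2, hubMinDegree = 10, cisWindowBp = 1e5, detectionFpkmMin = 0.1
))

setValidity("PipelineConfig", function(object) {
    msg <- character()
    num <- vapply(slotNames(object), function(s) slot(object, s), numeric(1))
    if (any(!is.finite(num)) || any(num <= 0))
        msg <- c(msg, "all thresholds must be finite and positive")
    for (a in c("deAlpha", "moduleTraitAlpha"))
        if (slot(object, a) >= 1)
            msg <- c(msg, sprintf("%s must lie in (0, 1)", a))
    if (object@evalueStrict > object@evalueLoose)
        msg <- c(msg, "evalueStrict must not exceed evalueLoose")
    if (length(msg)) msg else TRUE
})

#' @param ... named threshold overrides, see slot documentation.
#' @return A \code{PipelineConfig} object.
#' @examples
#' cfg <- pipelineConfig(deAlpha = 0.01)
#' cfg
#' @rdname PipelineConfig-class
#' @export
pipelineConfig <- function(...) {
    args <- list(...)
    bad <- setdiff(names(args), slotNames("PipelineConfig"))
    if (length(bad))
        stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
    do.call(new, c(list("PipelineConfig"), args))
}

setMethod("show", "PipelineConfig", function(object) {
    cat("PipelineConfig\n")
    for (s in slotNames(object))
        cat(sprintf("  %-18s %g\n", s, slot(object, s)))
})

## Canonical ordered developmental stages: five fetal days and two
## post-natal ages, three biological replicates each.
DEFAULT_STAGES <- c("F45", "F65", "F90", "F120", "F135", "B1", "B90")

#' Staged expression matrix
#'
#' A \linkS4class{SummarizedExperiment} carrying one \code{fpkm} assay and a
#' sample sheet (\code{stage}, \code{replicate}) in \code{colData}.  Stages
#' are an ordered factor; the default design has 7 stages x 3 replicates =
#' 21 samples.
#'
#' @exportClass StageExpression
setClass("StageExpression", contains = "SummarizedExperiment")

setValidity("StageExpression", function(object) {
    msg <- character()
    if (!"fpkm" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'fpkm' is required")
    else {
        v <- SummarizedExperiment::assay(object, "fpkm")
        if (any(!is.finite(v)) || any(v < 0))
            msg <- c(msg, "FPKM values must be finite and non-negative")
    }
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("stage", "replicate") %in% colnames(cd)))
        msg <- c(msg, "colData needs 'stage' and 'replicate'")
    else if (!is.factor(cd$stage))
        msg <- c(msg, "'stage' must be a factor with ordered levels")
    else if (anyNA(cd$stage))
        msg <- c(msg, "every sample must map to a stage")
    if (length(msg)) msg else TRUE
})

#' @param fpkm numeric matrix, features x samples, non-negative.
#' @param stage character or factor of per-sample stage labels.
#' @param replicate integer replicate index per sample; derived
#'   within stage when missing.
#' @param stageLevels ordered stage levels; defaults to the seven
#'   developmental stages F45 < F65 < F90 < F120 < F135 < B1 < B90.
#' @return A \code{StageExpression} object.
#' @examples
#' m <- matrix(rexp(5 * 21), 5, 21,
#'             dimnames = list(paste0("g", 1:5), paste0("s", 1:21)))
#' se <- StageExpression(m, rep(c("F45","F65","F90","F120","F135","B1","B90"),
#'                              each = 3))
#' stageOf(se)
#' @rdname StageExpression-class
#' @export
StageExpression <- function(fpkm, stage, replicate = NULL,
                            stageLevels = DEFAULT_STAGES) {
    fpkm <- as.matrix(fpkm)
    if (is.null(rownames(fpkm)))
        rownames(fpkm) <- paste0("feature_", seq_len(nrow(fpkm)))
    if (is.null(colnames(fpkm)))
        colnames(fpkm) <- paste0("sample_", seq_len(ncol(fpkm)))
    stage <- as.character(stage)
    if (length(stage) != ncol(fpkm))
        stop("one stage label per sample is required")
    if (!all(stage %in% stageLevels))
        stop("unknown stage label(s): ",
             paste(unique(setdiff(stage, stageLevels)), collapse = ", "))
    stage <- factor(stage, levels = stageLevels)
    if (is.null(replicate))
        replicate <- stats::ave(seq_along(stage), stage, FUN = seq_along)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(fpkm = fpkm),
        colData = S4Vectors::DataFrame(stage = stage,
                                       replicate = as.integer(replicate),
                                       row.names = colnames(fpkm)))
    new("StageExpression", se)
}

#' Planted co-expression module description
#'
#' Describes one module planted by the synthetic-data generator: a set of
#' features sharing a high/low step profile across stages.  The temporal
#' class constrains which stages may be high: \code{early} modules are high
#' within the first three stages, \code{late} within the last three, and
#' \code{stage_specific} in exactly one stage.
#'
#' @slot label module identifier.
#' @slot temporalClass one of \code{early}, \code{late},
#'   \code{stage_specific}.
#' @slot highStages stages in which members are high.
#' @slot size number of lncRNA members.
#' @slot nMrna number of mRNA members co-regulated with the module.
#' @slot delta log2-scale offset between high and low stages.
#' @exportClass PlantedModule
setClass("PlantedModule", representation(
    label = "character", temporalClass = "character",
    highStages = "character", size = "integer", nMrna = "integer",
    delta = "numeric"))

#' @param label,temporalClass,highStages,size,nMrna,delta see slots.
#' @rdname PlantedModule-class
#' @export
plantedModule <- function(label, temporalClass, highStages, size = 50L,
                          nMrna = size, delta = 4.0) {
    new("PlantedModule", label = label, temporalClass = temporalClass,
        highStages = highStages, size = as.integer(size),
        nMrna = as.integer(nMrna), delta = delta)
}

#' Synthetic study design
#'
#' Parameters of the synthetic fixture bundle.  The defaults emulate the
#' staged skeletal-muscle survey the pipeline is built for: 7 stages x 3
#' replicates (21 samples), a few hundred lncRNA candidates against a few
#' thousand coding genes, and planted early / late / stage-specific
#' co-expression modules whose members share a step profile of height
#' \code{delta} (log2 scale) plus Normal noise.
#'
#' @slot nMrna,nLncrna feature counts.
#' @slot stages ordered stage labels.
#' @slot replicatesPerStage replicates per stage (default 3).
#' @slot plantedModules list of \linkS4class{PlantedModule}.
#' @slot noiseSd log2-scale noise standard deviation (default 0.3).
#' @slot loadingRange per-feature loading interval (default [0.6, 1]).
#' @slot baselineRange per-feature baseline interval on the log2(FPKM+1)
#'   scale (default [2, 6]).
#' @slot lncClassProps proportions of lincRNA / antisense / intronic
#'   placements among lncRNA loci.
#' @slot contaminantFraction fraction of lncRNA candidates marked coding
#'   by at least one predictor in the verdict table.
#' @slot seed integer seed; all generator randomness derives from it.
#' @exportClass SimulationDesign
setClass("SimulationDesign", representation(
    nMrna = "integer", nLncrna = "integer", stages = "character",
    replicatesPerStage = "integer", plantedModules = "list",
    noiseSd = "numeric", loadingRange = "numeric", baselineRange = "numeric",
    lncClassProps = "numeric", contaminantFraction = "numeric",
    seed = "integer"))

setValidity("SimulationDesign", function(object) {
    msg <- character()
    if (object@nMrna < 1L || object@nLncrna < 1L)
        msg <- c(msg, "feature counts must be positive")
    if (object@noiseSd <= 0)
        msg <- c(msg, "noiseSd must be positive")
    if (length(object@loadingRange) != 2L ||
        diff(object@loadingRange) < 0)
        msg <- c(msg, "loadingRange must be an interval [lo, hi]")
    if (length(object@lncClassProps) != 3L ||
        abs(sum(object@lncClassProps) - 1) > 1e-8)
        msg <- c(msg, "lncClassProps must be 3 proportions summing to 1")
    if (object@contaminantFraction < 0 || object@contaminantFraction >= 1)
        msg <- c(msg, "contaminantFraction must lie in [0, 1)")
    ns <- length(object@stages)
    early <- object@stages[seq_len(min(3L, ns))]
    late  <- object@stages[seq.int(max(1L, ns - 2L), ns)]
    szLnc <- 0L; szM <- 0L
    for (pm in object@plantedModules) {
        if (!is(pm, "PlantedModule")) {
            msg <- c(msg, "plantedModules must contain PlantedModule objects")
            next
        }
        if (!all(pm@highStages %in% object@stages))
            msg <- c(msg, sprintf("module %s: unknown high stage", pm@label))
        ok <- switch(pm@temporalClass,
            early = all(pm@highStages %in% early),
            late  = all(pm@highStages %in% late),
            stage_specific = length(pm@highStages) == 1L,
            FALSE)
        if (!isTRUE(ok))
            msg <- c(msg, sprintf(
                "module %s: high stages inconsistent with class '%s'",
                pm@label, pm@temporalClass))
        szLnc <- szLnc + pm@size; szM <- szM + pm@nMrna
    }
    if (szLnc > object@nLncrna || szM > object@nMrna)
        msg <- c(msg, "planted module sizes exceed feature counts")
    if (length(msg)) msg else TRUE
})

#' @param nMrna,nLncrna,stages,replicatesPerStage,plantedModules,noiseSd,loadingRange,baselineRange,lncClassProps,contaminantFraction,seed
#'   see slot documentation.
#' @return A validated \code{SimulationDesign}.
#' @examples
#' d <- simulationDesign(nMrna = 200, nLncrna = 60,
#'                       plantedModules = list(
#'                         plantedModule("early", "early", c("F45", "F65"),
#'                                       size = 20, nMrna = 20)))
#' d
#' @rdname SimulationDesign-class
#' @export
simulationDesign <- function(nMrna = 2000L, nLncrna = 500L,
                             stages = DEFAULT_STAGES,
                             replicatesPerStage = 3L,
                             plantedModules = defaultPlantedModules(),
                             noiseSd = 0.3, loadingRange = c(0.6, 1.0),
                             baselineRange = c(2, 6),
                             lncClassProps = c(lincRNA = 0.5,
                                               antisense = 0.3,
                                               intronic = 0.2),
                             contaminantFraction = 0.1, seed = 1L) {
    new("SimulationDesign", nMrna = as.integer(nMrna),
        nLncrna = as.integer(nLncrna), stages = stages,
        replicatesPerStage = as.integer(replicatesPerStage),
        plantedModules = plantedModules, noiseSd = noiseSd,
        loadingRange = loadingRange, baselineRange = baselineRange,
        lncClassProps = lncClassProps,
        contaminantFraction = contaminantFraction, seed = as.integer(seed))
}

#' Default planted modules
#'
#' One module per temporal class.  Early and late modules are high in two
#' stages: with a step profile over n = 21 samples the correlation between
#' a module eigengene and a one-hot stage indicator is
#' sqrt(3(n - m) / (m(n - 3))) where m is the number of high samples, which
#' exceeds the 0.6 call threshold only for m <= 6, i.e. at most two high
#' stages.
#'
#' @return list of \linkS4class{PlantedModule}.
#' @export
defaultPlantedModules <- function() {
    list(plantedModule("earlyA", "early", c("F45", "F65"), size = 60L),
         plantedModule("lateA", "late", c("B1", "B90"), size = 60L),
         plantedModule("peakF90", "stage_specific", "F90", size = 40L))
}

setMethod("show", "SimulationDesign", function(object) {
    cat(sprintf("SimulationDesign: %d mRNA + %d lncRNA, %d stages x %d reps\n",
                object@nMrna, object@nLncrna, length(object@stages),
                object@replicatesPerStage))
    for (pm in object@plantedModules)
        cat(sprintf("  module %-10s %-15s high: %-12s size %d lnc / %d mRNA\n",
                    pm@label, pm@temporalClass,
                    paste(pm@highStages, collapse = ","), pm@size, pm@nMrna))
    cat(sprintf("  noiseSd %.2g, loadings [%.2g, %.2g], seed %d\n",
                object@noiseSd, object@loadingRange[1],
                object@loadingRange[2], object@seed))
})

#' Transcript-level annotation
#'
#' Exon-resolved transcript models plus gene spans, the substrate of the
#' structural filters, positional classification and cis-window search.
#'
#' @slot exons \code{GRangesList}, one element per transcript (names are
#'   transcript ids), exons sorted and non-overlapping.
#' @slot txMeta \code{DataFrame} with \code{transcript_id}, \code{gene_id},
#'   \code{biotype} and optional \code{sequence}.
#' @slot genes \code{GRanges} of gene spans, names are gene ids.
#' @exportClass TranscriptAnnotation
setClass("TranscriptAnnotation", representation(
    exons = "GRangesList", txMeta = "DataFrame", genes = "GRanges"))

setValidity("TranscriptAnnotation", function(object) {
    msg <- character()
    if (length(object@exons) != nrow(object@txMeta))
        msg <- c(msg, "one metadata row per transcript is required")
    if (!identical(names(object@exons), object@txMeta$transcript_id))
        msg <- c(msg, "exon list names must equal txMeta$transcript_id")
    if (anyDuplicated(object@txMeta$transcript_id))
        msg <- c(msg, "duplicate transcript_id")
    if (length(object@exons)) {
        n <- S4Vectors::elementNROWS(object@exons)
        if (any(n < 1L)) msg <- c(msg, "every transcript needs >= 1 exon")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "TranscriptAnnotation", function(object) {
    tab <- table(object@txMeta$biotype)
    cat(sprintf("TranscriptAnnotation: %d transcripts, %d genes\n",
                length(object@exons), length(object@genes)))
    cat("  biotypes:", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n")
})

#' Co-expression module set
#'
#' Result of signed weighted co-expression module detection: per-feature
#' labels (colour aliases, size-ordered, \code{grey} = unassigned), module
#' eigengenes, the variance they explain, module-stage correlation
#' statistics and the temporal class of each module.
#'
#' @slot labels named character, feature -> module colour.
#' @slot moduleOrder module colours in decreasing size order.
#' @slot eigengenes matrix, modules x samples, unit-norm rows.
#' @slot varianceExplained named numeric per module.
#' @slot traitStats data.frame: module, stage, r, t, df, p, significant.
#' @slot temporalClass named character per module.
#' @slot dendrogram the \code{hclust} tree modules were cut from.
#' @slot beta soft-threshold power used.
#' @slot cutHeight static cut height used.
#' @exportClass ModuleSet
setClass("ModuleSet", representation(
    labels = "character", moduleOrder = "character",
    eigengenes = "matrix", varianceExplained = "numeric",
    traitStats = "data.frame", temporalClass = "character",
    dendrogram = "ANY", beta = "numeric", cutHeight = "numeric"))

setMethod("show", "ModuleSet", function(object) {
    sizes <- table(factor(object@labels,
                          levels = c(object@moduleOrder, "grey")))
    cat(sprintf("ModuleSet: %d features, %d modules (beta = %g)\n",
                length(object@labels), length(object@moduleOrder),
                object@beta))
    for (m in object@moduleOrder)
        cat(sprintf("  %-12s %4d features  class: %s\n", m, sizes[[m]],
                    object@temporalClass[[m]]))
    cat(sprintf("  grey (unassigned): %d\n", sizes[["grey"]]))
})

#' Bipartite lncRNA-mRNA target network
#'
#' Evidence edges between differentially expressed lncRNAs and coding
#' genes.  An edge carries cis evidence (genomic distance within the
#' window), co-expression evidence (|Pearson r| above the cut), or both;
#' duplicate (lncRNA, gene) pairs are collapsed keeping both records.
#'
#' @slot edges data.frame: lncrna, gene, mode, distance_bp, r.
#' @slot lncNodes,mrnaNodes node id vectors.
#' @slot degree named integer, edges incident to each node.
#' @exportClass TargetNetwork
setClass("TargetNetwork", representation(
    edges = "data.frame", lncNodes = "character", mrnaNodes = "character",
    degree = "integer"))

setValidity("TargetNetwork", function(object) {
    msg <- character()
    e <- object@edges
    if (nrow(e)) {
        if (!all(e$lncrna %in% object@lncNodes))
            msg <- c(msg, "edge lncRNA endpoint missing from node set")
        if (!all(e$gene %in% object@mrnaNodes))
            msg <- c(msg, "edge gene endpoint missing from node set")
        if (any(e$lncrna %in% object@mrnaNodes & e$gene %in% object@lncNodes))
            msg <- c(msg, "edges must join a lncRNA to an mRNA")
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "TargetNetwork", function(object) {
    cat(sprintf("TargetNetwork: %d lncRNA x %d mRNA nodes, %d edges\n",
                length(object@lncNodes), length(object@mrnaNodes),
                nrow(object@edges)))
    if (nrow(object@edges))
        print(table(object@edges$mode))
})
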