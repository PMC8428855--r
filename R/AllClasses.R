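#' @import methods
NULL

# ---------------------------------------------------------------------------
# Synthetic-data configuration
# ---------------------------------------------------------------------------

#' Configuration for the synthetic reference generator
#'
#' Holds the study conditions under which a synthetic dissociated-cell
#' reference taxonomy is generated: the hierarchy size, the size and strength
#' of planted marker-gene blocks, per-cell sequencing noise and the number of
#' non-neuronal (glial) classes used as contamination sources.
#'
#' @slot seed integer, master seed; all generation is a pure function of it.
#' @slot nClasses integer, number of broad classes (root branches).
#' @slot typesPerClass integer, leaf transcriptomic types per class.
#' @slot nGenes integer, total gene count.
#' @slot markersPerClass integer, planted class-marker genes per class.
#' @slot markersPerType integer, planted type-marker genes per leaf type.
#' @slot markerEffect numeric, log2-expression units added to class-marker
#'   means in their own class.
#' @slot typeEffect numeric, log2-expression units added to type-marker means
#'   in their own leaf type.
#' @slot nRefCellsPerType integer, reference cells simulated per leaf type.
#' @slot noiseSd numeric, per-cell log2-expression noise standard deviation.
#' @slot gliaClasses integer, number of the classes that are non-neuronal.
#' @slot nbSize numeric, negative-binomial size (dispersion) of count draws.
#' @slot libSize numeric, expected library size (total counts) per cell.
#' @export
setClass("SynthConfig",
  representation(
    seed = "integer", nClasses = "integer", typesPerClass = "integer",
    nGenes = "integer", markersPerClass = "integer", markersPerType = "integer",
    markerEffect = "numeric", typeEffect = "numeric",
    nRefCellsPerType = "integer", noiseSd = "numeric",
    gliaClasses = "integer", nbSize = "numeric", libSize = "numeric"
  )
)

setValidity("SynthConfig", function(object) {
  msg <- character()
  cnt <- c(
    nClasses = object@nClasses, typesPerClass = object@typesPerClass,
    nGenes = object@nGenes, markersPerClass = object@markersPerClass,
    markersPerType = object@markersPerType,
    nRefCellsPerType = object@nRefCellsPerType
  )
  if (any(cnt < 1L)) {
    msg <- c(msg, paste("counts must be >= 1:",
                        paste(names(cnt)[cnt < 1L], collapse = ", ")))
  }
  if (object@markerEffect < 0) msg <- c(msg, "markerEffect must be >= 0")
  if (object@typeEffect < 0) msg <- c(msg, "typeEffect must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@gliaClasses < 0 || object@gliaClasses >= object@nClasses) {
    msg <- c(msg, "gliaClasses must be in [0, nClasses)")
  }
  needed <- object@nClasses * object@markersPerClass +
    object@nClasses * object@typesPerClass * object@markersPerType
  if (needed > object@nGenes) {
    msg <- c(msg, sprintf(
      "disjoint marker blocks need %d genes but nGenes = %d",
      needed, object@nGenes))
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Reference taxonomy
# ---------------------------------------------------------------------------

#' Hierarchical dissociated-cell reference taxonomy
#'
#' A root -> class -> leaf-type hierarchy together with a reference expression
#' matrix in log2(CPM+1) space, per-cell leaf-type labels, per-node branch
#' marker genes and per-type cluster mean profiles. This is the object every
#' transcriptomic QC and mapping operation works against.
#'
#' @slot exprs numeric matrix, genes x reference cells, log2(CPM+1).
#' @slot cellType character, leaf-type label per reference cell (column).
#' @slot classOf named character, leaf type -> class.
#' @slot children named list, internal node id -> character vector of child
#'   node ids; the root node is called \code{"root"}.
#' @slot branchMarkers named list, internal node id -> marker genes used to
#'   resolve among that node's children.
#' @slot typeMeans numeric matrix, genes x leaf types: per-type mean linear
#'   CPM profile, re-normalized to sum 1e6 and stored as log2(CPM+1).
#' @slot isGlia named logical over classes.
#' @slot plantedMarkers list with elements \code{class} and \code{type}
#'   recording the generator's planted marker blocks (empty for imported
#'   taxonomies).
#' @export
setClass("ReferenceTaxonomy",
  representation(
    exprs = "matrix", cellType = "character", classOf = "character",
    children = "list", branchMarkers = "list", typeMeans = "matrix",
    isGlia = "logical", plantedMarkers = "list"
  )
)

setValidity("ReferenceTaxonomy", function(object) {
  msg <- character()
  if (ncol(object@exprs) != length(object@cellType)) {
    msg <- c(msg, "cellType length must equal ncol(exprs)")
  }
  if (is.null(rownames(object@exprs)) || is.null(colnames(object@exprs))) {
    msg <- c(msg, "exprs needs gene rownames and cell colnames")
  }
  kids <- object@children
  if (!"root" %in% names(kids)) msg <- c(msg, "children must contain 'root'")
  allChildren <- unlist(kids, use.names = FALSE)
  if (anyDuplicated(allChildren)) {
    msg <- c(msg, "tree is not acyclic: a node has two parents")
  }
  internal <- names(kids)
  leaves <- setdiff(allChildren, internal)
  orphan <- setdiff(internal, c("root", allChildren))
  if (length(orphan)) {
    msg <- c(msg, paste("disconnected internal nodes:",
                        paste(orphan, collapse = ", ")))
  }
  if (!all(object@cellType %in% leaves)) {
    msg <- c(msg, "every cellType must be a leaf of the tree")
  }
  if (length(leaves)) {
    tab <- table(factor(object@cellType, levels = leaves))
    if (any(tab < 2L)) {
      msg <- c(msg, paste("every leaf needs >= 2 reference cells; short:",
                          paste(names(tab)[tab < 2L], collapse = ", ")))
    }
  }
  if (!setequal(names(object@branchMarkers), internal)) {
    msg <- c(msg, "branchMarkers must be keyed by the internal nodes")
  } else if (any(!vapply(object@branchMarkers, length, 1L))) {
    msg <- c(msg, "branch marker sets must be non-empty")
  }
  if (!setequal(colnames(object@typeMeans), leaves)) {
    msg <- c(msg, "typeMeans columns must be the leaf types")
  }
  if (!setequal(names(object@classOf), leaves)) {
    msg <- c(msg, "classOf must be keyed by the leaf types")
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Electrophysiology
# ---------------------------------------------------------------------------

#' A uniformly sampled current-clamp sweep
#'
#' Recorded membrane voltage and injected current on a shared uniform time
#' base, plus the stimulus epochs (kind, onset, offset, amplitude) that were
#' applied. Epoch kinds are \code{short_pulse}, \code{long_square} and
#' \code{ramp}; for a ramp the amplitude field is the slope in pA/s.
#'
#' @slot startTime numeric, seconds.
#' @slot dt numeric, sampling interval in seconds.
#' @slot voltage numeric, membrane potential in mV.
#' @slot stimulus numeric, injected current in pA, same length as voltage.
#' @slot epochs data.frame with columns kind, onset, offset, amplitude.
#' @export
setClass("VoltageSweep",
  representation(
    startTime = "numeric", dt = "numeric", voltage = "numeric",
    stimulus = "numeric", epochs = "data.frame"
  )
)

setValidity("VoltageSweep", function(object) {
  msg <- character()
  if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
  if (length(object@voltage) != length(object@stimulus)) {
    msg <- c(msg, "voltage and stimulus must have the same length")
  }
  ep <- object@epochs
  need <- c("kind", "onset", "offset", "amplitude")
  if (!all(need %in% names(ep))) {
    msg <- c(msg, "epochs needs columns kind, onset, offset, amplitude")
  } else if (nrow(ep)) {
    dur <- length(object@voltage) * object@dt
    if (any(ep$offset <= ep$onset)) msg <- c(msg, "epoch offset must exceed onset")
    if (any(ep$onset < object@startTime - 1e-12) ||
        any(ep$offset > object@startTime + dur + 1e-9)) {
      msg <- c(msg, "epochs must lie within the sweep")
    }
    if (!all(ep$kind %in% c("short_pulse", "long_square", "ramp"))) {
      msg <- c(msg, "epoch kind must be short_pulse, long_square or ramp")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Passive-membrane and stereotyped-spike model specification
#'
#' Parameters of the first-order (leaky) membrane model used by
#' [makeSweep()]: subthreshold voltage relaxes toward
#' \code{rmp + rInput * I(t)} with time constant \code{tau}; whenever the
#' trajectory crosses \code{spikeThreshold} a stereotyped action-potential
#' template is pasted into the trace.
#'
#' @slot rmp numeric, resting membrane potential, mV.
#' @slot rInput numeric, input resistance, MOhm.
#' @slot tau numeric, membrane time constant, ms.
#' @slot spikeThreshold numeric, spike threshold, mV (Inf = passive cell).
#' @slot apTemplate numeric, spike waveform in mV relative to the voltage at
#'   threshold crossing (starts at 0).
#' @slot apPeakDvdt numeric, the template's maximum dV/dt in mV/ms (reported
#'   for detector boundary tests).
#' @slot noiseRms numeric, additive white measurement noise RMS, mV.
#' @slot driftRate numeric, linear baseline drift, mV/s.
#' @slot samplingRate numeric, kHz.
#' @export
setClass("MembraneSpec",
  representation(
    rmp = "numeric", rInput = "numeric", tau = "numeric",
    spikeThreshold = "numeric", apTemplate = "numeric", apPeakDvdt = "numeric",
    noiseRms = "numeric", driftRate = "numeric", samplingRate = "numeric"
  )
)

setValidity("MembraneSpec", function(object) {
  msg <- character()
  if (object@tau <= 0) msg <- c(msg, "tau must be > 0")
  if (object@samplingRate <= 0) msg <- c(msg, "samplingRate must be > 0")
  if (object@rInput <= 0) msg <- c(msg, "rInput must be > 0")
  if (object@noiseRms < 0) msg <- c(msg, "noiseRms must be >= 0")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Sweep QC
# ---------------------------------------------------------------------------

#' Sweep quality-control configuration
#'
#' Numerical criteria of the online QC engine. Defaults are the acquisition
#' criteria used throughout: the resting membrane potential must stay within
#' 1 mV of target, short-window (1.5 ms) and long-window (500 ms) RMS noise
#' must stay below 0.07 mV and 0.5 mV, a ramp stimulus is terminated after 5
#' detected spikes, bias current must stay within +/-100 pA, bridge balance
#' and access resistance below 20 MOhm and 15% of the input resistance, and
#' the pre-break-in seal above 1 GOhm.
#'
#' @slot targetVm numeric, target membrane potential, mV.
#' @slot rmpTolerance numeric, mV (inclusive bound).
#' @slot baselineWindow numeric, ms of pre-stimulus data evaluated.
#' @slot rmsShortWindow numeric, ms; sub-window for high-frequency noise.
#' @slot rmsShortMax numeric, mV (strict bound).
#' @slot rmsLongWindow numeric, ms; full window for patch stability.
#' @slot rmsLongMax numeric, mV (strict bound).
#' @slot recoveryMin numeric, ms of enforced minimal recovery.
#' @slot recoveryEval numeric, ms per post-stimulus evaluation window.
#' @slot recoveryMax numeric, s after stimulus end before the sweep fails.
#' @slot rampSpikeLimit integer, spikes after which a ramp is terminated.
#' @slot leakLimit numeric, pA; |bias current| bound (inclusive).
#' @slot bridgeAbsMax numeric, MOhm (strict).
#' @slot bridgeFracMax numeric, fraction of R_input (strict).
#' @slot accessAbsMax numeric, MOhm (strict).
#' @slot accessFracMax numeric, fraction of R_input (strict).
#' @slot sealMin numeric, GOhm (strict lower bound).
#' @slot spikeDvdt numeric, mV/ms online spike-detection threshold.
#' @slot smoothSamples integer, causal boxcar width for online detection.
#' @slot maxBiasStep numeric, pA; autobias step clip.
#' @export
setClass("QCConfig",
  representation(
    targetVm = "numeric", rmpTolerance = "numeric", baselineWindow = "numeric",
    rmsShortWindow = "numeric", rmsShortMax = "numeric",
    rmsLongWindow = "numeric", rmsLongMax = "numeric",
    recoveryMin = "numeric", recoveryEval = "numeric", recoveryMax = "numeric",
    rampSpikeLimit = "integer", leakLimit = "numeric",
    bridgeAbsMax = "numeric", bridgeFracMax = "numeric",
    accessAbsMax = "numeric", accessFracMax = "numeric", sealMin = "numeric",
    spikeDvdt = "numeric", smoothSamples = "integer", maxBiasStep = "numeric"
  )
)

setValidity("QCConfig", function(object) {
  pos <- c(
    rmpTolerance = object@rmpTolerance, baselineWindow = object@baselineWindow,
    rmsShortWindow = object@rmsShortWindow, rmsShortMax = object@rmsShortMax,
    rmsLongWindow = object@rmsLongWindow, rmsLongMax = object@rmsLongMax,
    recoveryMin = object@recoveryMin, recoveryEval = object@recoveryEval,
    recoveryMax = object@recoveryMax,
    rampSpikeLimit = as.numeric(object@rampSpikeLimit),
    leakLimit = object@leakLimit, bridgeAbsMax = object@bridgeAbsMax,
    bridgeFracMax = object@bridgeFracMax, accessAbsMax = object@accessAbsMax,
    accessFracMax = object@accessFracMax, sealMin = object@sealMin,
    spikeDvdt = object@spikeDvdt,
    smoothSamples = as.numeric(object@smoothSamples),
    maxBiasStep = object@maxBiasStep
  )
  if (any(pos <= 0)) {
    paste("must be positive:", paste(names(pos)[pos <= 0], collapse = ", "))
  } else TRUE
})

#' Verdict of a quality-control evaluation
#'
#' @slot passed logical.
#' @slot reasons character, coded failure reasons; empty iff passed.
#' @slot measured named numeric, the metric values that were evaluated.
#' @export
setClass("QCVerdict",
  representation(passed = "logical", reasons = "character",
                 measured = "numeric")
)

setValidity("QCVerdict", function(object) {
  if (object@passed != (length(object@reasons) == 0L)) {
    "passed must be TRUE exactly when reasons is empty"
  } else TRUE
})

# ---------------------------------------------------------------------------
# AP features
# ---------------------------------------------------------------------------

#' Per-cell electrophysiology feature matrix
#'
#' Cells x features matrix with a category label per column. Categories follow
#' the standard six-block construction: (a) first-AP waveform, (b) its
#' derivative, (c) duration-normalized ISI shape, (d) binned instantaneous
#' firing-rate features at rheobase/+40/+80 pA, (e) binned subthreshold
#' responses, (f) the largest hyperpolarizing step normalized to its minimum
#' and baseline.
#'
#' @slot values numeric matrix, cells x features.
#' @slot category character, one of "a".."f" per column.
#' @slot dropped character, ids of cells dropped with no fillable sweeps.
#' @export
setClass("FeatureMatrix",
  representation(values = "matrix", category = "character",
                 dropped = "character")
)

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  if (ncol(object@values) != length(object@category)) {
    msg <- c(msg, "one category label per column required")
  }
  if (nrow(object@values) && any(!is.finite(object@values))) {
    msg <- c(msg, "feature values must be finite after interpolation")
  }
  if (length(msg)) msg else TRUE
})

#' Sparse PCA result
#'
#' @slot loadings list per category of loading matrices (features x kept
#'   components).
#' @slot scores numeric matrix, cells x kept components (z-scored), columns
#'   named category.component.
#' @slot adjEV list per category of adjusted explained-variance fractions for
#'   all computed components.
#' @slot kept list per category of logical retention masks.
#' @slot retention numeric, the adjusted-EV retention threshold used.
#' @export
setClass("SparsePCResult",
  representation(loadings = "list", scores = "matrix", adjEV = "list",
                 kept = "list", retention = "numeric")
)

# ---------------------------------------------------------------------------
# Transcriptomic QC
# ---------------------------------------------------------------------------

#' On/off marker gene sets per class
#'
#' @slot onMarkers named list, class -> character vector of on-marker genes.
#' @slot offClasses named list, class -> classes counted as "off" when
#'   computing the contamination score (default: all other classes).
#' @export
setClass("MarkerSets",
  representation(onMarkers = "list", offClasses = "list")
)

setValidity("MarkerSets", function(object) {
  msg <- character()
  if (!setequal(names(object@onMarkers), names(object@offClasses))) {
    msg <- c(msg, "onMarkers and offClasses must cover the same classes")
  }
  genes <- unlist(object@onMarkers, use.names = FALSE)
  if (anyDuplicated(genes)) {
    msg <- c(msg, "on-marker lists must be disjoint across classes")
  }
  if (length(msg)) msg else TRUE
})

#' Reference (FACS) summary statistics for marker scoring
#'
#' @slot classMedians named numeric: per class, the median over that class's
#'   reference cells of the mean on-marker log2(CPM+1) expression.
#' @slot typeProfiles numeric matrix, marker-union genes x leaf types: mean
#'   expression profile per type over all on+off markers.
#' @slot typeClass named character, leaf type -> class.
#' @export
setClass("FacsSummary",
  representation(classMedians = "numeric", typeProfiles = "matrix",
                 typeClass = "character")
)

# ---------------------------------------------------------------------------
# Taxonomy mapping
# ---------------------------------------------------------------------------

#' Result of bootstrapped taxonomy mapping for one cell
#'
#' @slot probabilities named numeric over leaf types, multiples of 1/nBoot,
#'   summing to 1.
#' @slot assignedType character, argmax leaf.
#' @slot nBoot integer, bootstrap iterations performed.
#' @slot kl numeric, KL divergence (nats) from the assigned type's reference
#'   mapping distribution (NA until classified).
#' @slot typeCorrelation numeric in [-1, 1] (NA until classified).
#' @slot consistency character: "highly", "moderately", "inconsistent" or NA.
#' @export
setClass("MappingResult",
  representation(probabilities = "numeric", assignedType = "character",
                 nBoot = "integer", kl = "numeric",
                 typeCorrelation = "numeric", consistency = "character")
)

setValidity("MappingResult", function(object) {
  msg <- character()
  p <- object@probabilities
  if (abs(sum(p) - 1) > 1e-8) msg <- c(msg, "probabilities must sum to 1")
  if (any(p < -1e-12)) msg <- c(msg, "probabilities must be >= 0")
  if (length(object@nBoot) && object@nBoot > 0L) {
    if (any(abs(p * object@nBoot - round(p * object@nBoot)) > 1e-6)) {
      msg <- c(msg, "probabilities must be multiples of 1/nBoot")
    }
  }
  if (length(p) && !is.null(names(p))) {
    if (!identical(object@assignedType, names(p)[which.max(p)])) {
      msg <- c(msg, "assignedType must be the argmax leaf")
    }
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Outcomes
# ---------------------------------------------------------------------------

#' Empirical ROC curve with AUC
#'
#' @slot thresholds numeric, decision thresholds (on the oriented score).
#' @slot fpr numeric, false-positive rates.
#' @slot tpr numeric, true-positive rates.
#' @slot auc numeric in [0, 1], trapezoidal area.
#' @slot direction character, "greater" if higher scores predict the positive
#'   class, else "less".
#' @export
setClass("ROCResult",
  representation(thresholds = "numeric", fpr = "numeric", tpr = "numeric",
                 auc = "numeric", direction = "character")
)

setValidity("ROCResult", function(object) {
  msg <- character()
  if (object@auc < 0 || object@auc > 1) msg <- c(msg, "auc must be in [0, 1]")
  if (is.unsorted(object@fpr) || is.unsorted(object@tpr)) {
    msg <- c(msg, "fpr and tpr must be monotone along the curve")
  }
  if (length(msg)) msg else TRUE
})
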