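#' Read an expression matrix (CSV or MTX triplet)
#'
#' CSV: genes x cells with gene names in the first column and cell names in
#' the header. MTX: a MatrixMarket file plus one gene name and one cell name
#' per line in the side files. Returns raw counts together with a
#' log2(CPM+1) view, where CPM = counts / column sum x 1e6.
#'
#' @param path matrix file.
#' @param format "csv" or "mtx".
#' @param genesFile,cellsFile name files (mtx only; defaults to
#'   \code{genes.txt} / \code{cells.txt} next to the matrix).
#' @return list with \code{counts} and \code{logCPM} (genes x cells).
#' @export
readExpression <- function(path, format = c("csv", "mtx"),
                           genesFile = file.path(dirname(path), "genes.txt"),
                           cellsFile = file.path(dirname(path), "cells.txt")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE)
    if (ncol(df) < 2L || !is.character(df[[1]]) ||
        anyDuplicated(df[[1]]) || any(!vapply(df[-1], is.numeric, TRUE))) {
      stop("malformed expression CSV (", path,
           "): expected unique gene names in column 1 and numeric cells")
    }
    counts <- as.matrix(df[, -1, drop = FALSE])
    rownames(counts) <- df[[1]]
  } else {
    counts <- as.matrix(Matrix::readMM(path))
    genes <- readLines(genesFile)
    cells <- readLines(cellsFile)
    if (nrow(counts) != length(genes) || ncol(counts) != length(cells)) {
      stop("dimension mismatch: matrix is ", nrow(counts), " x ",
           ncol(counts), " but names give ", length(genes), " x ",
           length(cells))
    }
    dimnames(counts) <- list(genes, cells)
  }
  list(counts = counts, logCPM = log2cpm(counts))
}

#' Write an expression matrix
#'
#' @param counts genes x cells matrix with dimnames.
#' @param path matrix file (csv) or .mtx file.
#' @param format "csv" or "mtx".
#' @export
writeExpression <- function(counts, path, format = c("csv", "mtx")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                "generalMatrix"), path)
    writeLines(rownames(counts), file.path(dirname(path), "genes.txt"))
    writeLines(colnames(counts), file.path(dirname(path), "cells.txt"))
  }
  invisible(path)
}

#' Write sweeps as long-format CSV
#'
#' Produces \code{<stem>.csv} (sweep_id, time_s, voltage_mV, stimulus_pA) and
#' \code{<stem>_epochs.csv} (sweep_id, kind, onset, offset, amplitude).
#'
#' @param sweeps list of [VoltageSweep-class] (named or auto-named).
#' @param stem output path without extension.
#' @export
writeSweeps <- function(sweeps, stem) {
  if (is.null(names(sweeps))) {
    names(sweeps) <- sprintf("sweep%03d", seq_along(sweeps))
  }
  long <- do.call(rbind, lapply(names(sweeps), function(id) {
    sw <- sweeps[[id]]
    data.frame(sweep_id = id, time_s = sweepTimes(sw),
               voltage_mV = sw@voltage, stimulus_pA = sw@stimulus,
               stringsAsFactors = FALSE)
  }))
  eps <- do.call(rbind, lapply(names(sweeps), function(id) {
    ep <- sweeps[[id]]@epochs
    if (!nrow(ep)) return(NULL)
    cbind(data.frame(sweep_id = id, stringsAsFactors = FALSE), ep)
  }))
  utils::write.csv(long, paste0(stem, ".csv"), row.names = FALSE)
  utils::write.csv(
    if (is.null(eps)) {
      data.frame(sweep_id = character(), kind = character(),
                 onset = numeric(), offset = numeric(), amplitude = numeric())
    } else eps,
    paste0(stem, "_epochs.csv"), row.names = FALSE)
  invisible(stem)
}

#' Read sweeps written by [writeSweeps()]
#'
#' @param stem path stem used at write time.
#' @return named list of [VoltageSweep-class].
#' @export
readSweeps <- function(stem) {
  long <- utils::read.csv(paste0(stem, ".csv"), stringsAsFactors = FALSE)
  eps <- utils::read.csv(paste0(stem, "_epochs.csv"),
                         stringsAsFactors = FALSE)
  need <- c("sweep_id", "time_s", "voltage_mV", "stimulus_pA")
  if (!all(need %in% names(long))) {
    stop("malformed sweep CSV: expected columns ",
         paste(need, collapse = ", "))
  }
  ids <- unique(long$sweep_id)
  out <- lapply(ids, function(id) {
    d <- long[long$sweep_id == id, ]
    ep <- eps[eps$sweep_id == id, c("kind", "onset", "offset", "amplitude")]
    rownames(ep) <- NULL
    new("VoltageSweep", startTime = d$time_s[1],
        dt = stats::median(diff(d$time_s)), voltage = d$voltage_mV,
        stimulus = d$stimulus_pA, epochs = ep)
  })
  stats::setNames(out, ids)
}

#' Write a reference taxonomy bundle
#'
#' A directory with \code{tree.json} (children, classOf, isGlia,
#' branchMarkers, plantedMarkers), \code{exprs.csv} (log2(CPM+1), full
#' precision), \code{cells.csv} (cell, type) and \code{type_means.csv}.
#'
#' @param tax A [ReferenceTaxonomy-class].
#' @param dir output directory (created).
#' @export
writeReferenceBundle <- function(tax, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(children = tax@children, classOf = as.list(tax@classOf),
         isGlia = as.list(tax@isGlia), branchMarkers = tax@branchMarkers,
         plantedMarkers = tax@plantedMarkers),
    file.path(dir, "tree.json"), auto_unbox = TRUE)
  writeMatrixCsv(tax@exprs, "gene", file.path(dir, "exprs.csv"))
  utils::write.csv(data.frame(cell = colnames(tax@exprs),
                              type = tax@cellType),
                   file.path(dir, "cells.csv"), row.names = FALSE)
  writeMatrixCsv(tax@typeMeans, "gene", file.path(dir, "type_means.csv"))
  invisible(dir)
}

writeMatrixCsv <- function(m, keyName, path) {
  df <- data.frame(key = rownames(m),
                   as.data.frame(format(m, digits = 17, trim = TRUE,
                                        scientific = TRUE)),
                   check.names = FALSE)
  names(df)[1] <- keyName
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

readMatrixCsv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read a reference taxonomy bundle
#'
#' @param dir directory written by [writeReferenceBundle()].
#' @return A [ReferenceTaxonomy-class].
#' @export
readReferenceBundle <- function(dir) {
  tree <- jsonlite::read_json(file.path(dir, "tree.json"),
                              simplifyVector = TRUE)
  exprs <- readMatrixCsv(file.path(dir, "exprs.csv"))
  cells <- utils::read.csv(file.path(dir, "cells.csv"),
                           stringsAsFactors = FALSE)
  if (!identical(cells$cell, colnames(exprs))) {
    stop("cells.csv does not match the expression matrix columns")
  }
  tm <- readMatrixCsv(file.path(dir, "type_means.csv"))
  asCharList <- function(x) lapply(x, as.character)
  new("ReferenceTaxonomy", exprs = exprs, cellType = cells$type,
      classOf = unlist(tree$classOf), children = asCharList(tree$children),
      branchMarkers = asCharList(tree$branchMarkers), typeMeans = tm,
      isGlia = unlist(tree$isGlia),
      plantedMarkers = lapply(tree$plantedMarkers, asCharList))
}

#' Pipeline run configuration
#'
#' Nested defaults mirroring each module's parameters; serializable to JSON
#' and back for run manifests.
#'
#' @param seed integer.
#' @param paths named list of input paths.
#' @param qc named list overriding [qcConfig()] defaults.
#' @param txqc named list: \code{nMarkers}, \code{cutoff}.
#' @param taxmap named list: \code{nBoot}, \code{cellFrac},
#'   \code{markerFrac} and the [consistencyThresholds()].
#' @param apfeat named list: [apParams()] and sPCA \code{retention},
#'   \code{penalty}.
#' @return named list.
#' @export
runConfig <- function(seed = 1L, paths = list(), qc = list(),
                      txqc = list(), taxmap = list(), apfeat = list()) {
  merge <- function(defaults, over) {
    defaults[names(over)] <- over
    defaults
  }
  qcDef <- qcConfig()
  qcList <- stats::setNames(lapply(slotNames(qcDef), function(s) {
    slot(qcDef, s)
  }), slotNames(qcDef))
  list(
    seed = as.integer(seed), paths = paths,
    qc = merge(qcList, qc),
    txqc = merge(list(nMarkers = 50L, cutoff = 0.4), txqc),
    taxmap = merge(c(list(nBoot = 100L, cellFrac = 0.7, markerFrac = 0.7),
                     consistencyThresholds()), taxmap),
    apfeat = merge(c(apParams(), list(retention = 0.01, penalty = 0)),
                   apfeat)
  )
}

#' Write / read a run configuration as JSON
#'
#' @param cfg from [runConfig()].
#' @param path JSON file.
#' @return the path ([writeRunConfig()]) or the configuration list
#'   ([readRunConfig()]).
#' @export
writeRunConfig <- function(cfg, path) {
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Write a joined per-cell report
#'
#' Joins any number of per-cell tables on \code{cellId} (full outer join) and
#' writes \code{report.csv} plus \code{manifest.json} (seed, configuration,
#' package version). Tables with duplicated cell ids are rejected with the
#' offending ids listed.
#'
#' @param tables named list of data.frames, each with a \code{cellId} column.
#' @param dir output directory (created).
#' @param config run configuration stored in the manifest.
#' @return the joined data.frame, invisibly.
#' @export
writeReport <- function(tables, dir, config = runConfig()) {
  tables <- Filter(Negate(is.null), tables)
  if (!length(tables)) stop("no module results to report")
  for (nm in names(tables)) {
    if (!"cellId" %in% names(tables[[nm]])) {
      stop("table '", nm, "' lacks a cellId column")
    }
    dup <- unique(tables[[nm]]$cellId[duplicated(tables[[nm]]$cellId)])
    if (length(dup)) {
      stop("conflicting (duplicated) cell ids in table '", nm, "': ",
           paste(utils::head(dup, 5), collapse = ", "))
    }
  }
  joined <- Reduce(function(a, b) merge(a, b, by = "cellId", all = TRUE),
                   tables)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(joined, file.path(dir, "report.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(seed = config$seed, config = config,
         package = as.character(utils::packageVersion("PatchSeqKit"))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(joined)
}
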