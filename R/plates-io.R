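#' @include AllClasses.R
NULL

#' Row-major 96-well plate labels
#'
#' Well index `w` maps to labels row-major: A1 is 1, A2 is 2, ..., H12 is
#' 96.
#'
#' @param n number of wells (at most 96).
#' @return character vector of labels.
#' @examples
#' plateWellLabels(5)
#' @export
plateWellLabels <- function(n = 96) {
    stopifnot(n >= 1, n <= 96)
    all <- as.vector(t(outer(LETTERS[1:8], 1:12, paste0)))
    all[seq_len(n)]
}

#' Construct a fluorescence plate
#'
#' @param fluorescence cycle x well numeric matrix (rows are cycles 1..n,
#'   columns are wells in row-major order).
#' @param concentration total probe concentration, mol/L.
#' @param probeState `"active"`, `"inactive"` or `"sample"`.
#' @param plateId identifier.
#' @param wellLabels well labels; default the row-major labels for
#'   `ncol(fluorescence)` wells.
#' @return a [ProbePlate] object.
#' @examples
#' ProbePlate(matrix(1, 3, 4), concentration = pmolPerL(0.125),
#'            probeState = "inactive", plateId = "ctrl1")
#' @export
ProbePlate <- function(fluorescence, concentration, probeState, plateId,
                       wellLabels = NULL) {
    fluorescence <- as.matrix(fluorescence)
    if (is.null(wellLabels)) {
        wellLabels <- colnames(fluorescence)
        if (is.null(wellLabels))
            wellLabels <- plateWellLabels(ncol(fluorescence))
    }
    colnames(fluorescence) <- wellLabels
    rownames(fluorescence) <- seq_len(nrow(fluorescence))
    se <- SummarizedExperiment(
        assays = list(fluorescence = fluorescence),
        rowData = DataFrame(cycle = seq_len(nrow(fluorescence))),
        colData = DataFrame(well = wellLabels, row.names = wellLabels))
    new("ProbePlate", se, plateId = as.character(plateId),
        probeState = as.character(probeState),
        concentration = as.numeric(concentration))
}

#' @describeIn ProbePlate probe state label.
#' @param object a `ProbePlate`.
#' @export
setMethod("probeState", "ProbePlate", function(object) object@probeState)

#' @describeIn ProbePlate total probe concentration (mol/L).
#' @export
setMethod("probeConcentration", "ProbePlate",
    function(object) object@concentration)

#' @describeIn ProbePlate plate identifier.
#' @export
setMethod("plateId", "ProbePlate", function(object) object@plateId)

setMethod("show", "ProbePlate", function(object) {
    cat("ProbePlate '", object@plateId, "': ", nrow(object), " cycles x ",
        ncol(object), " wells, probe ", object@probeState,
        ", C = ", format(object@concentration, digits = 4), " mol/L\n",
        sep = "")
})

#' Read and write plate CSV files
#'
#' Long-format plate files with required header
#' `plate_id, probe_state, concentration_mol_per_L, cycle, well,
#' fluorescence`.  Missing (cycle, well) combinations are tolerated and
#' stored as `NA` (masked, never imputed); malformed rows raise an error
#' naming the offending line.
#'
#' @param path CSV file path.
#' @return `readPlateCSV`: a list of [ProbePlate] objects, one per
#'   `plate_id`.
#' @export
readPlateCSV <- function(path) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("plate_id", "probe_state", "concentration_mol_per_L",
              "cycle", "well", "fluorescence")
    if (!all(need %in% names(df)))
        stop("plate CSV must have columns: ", paste(need, collapse = ", "))
    bad <- which(!is.finite(df$fluorescence) | !is.finite(df$cycle) |
                 df$cycle < 1 | df$cycle != round(df$cycle))
    if (length(bad))
        stop("malformed plate CSV row(s) at line(s): ",
             paste(utils::head(bad + 1L, 5), collapse = ", "),
             " (header is line 1)")
    lapply(split(df, df$plate_id), function(p) {
        cyc <- sort(unique(p$cycle))
        wells <- unique(p$well)
        # preserve row-major well order when labels are standard
        std <- plateWellLabels(96)
        wells <- c(std[std %in% wells], setdiff(wells, std))
        m <- matrix(NA_real_, length(cyc), length(wells),
                    dimnames = list(cyc, wells))
        m[cbind(match(p$cycle, cyc), match(p$well, wells))] <- p$fluorescence
        ProbePlate(m, concentration = p$concentration_mol_per_L[1],
                   probeState = p$probe_state[1], plateId = p$plate_id[1],
                   wellLabels = wells)
    })
}

#' @rdname readPlateCSV
#' @param plates a [ProbePlate] or list of them.
#' @return `writePlateCSV`: the path, invisibly.
#' @export
writePlateCSV <- function(plates, path) {
    if (is(plates, "ProbePlate")) plates <- list(plates)
    rows <- lapply(plates, function(p) {
        m <- assay(p, "fluorescence")
        df <- data.frame(
            plate_id = p@plateId, probe_state = p@probeState,
            concentration_mol_per_L = p@concentration,
            cycle = rep(seq_len(nrow(m)), times = ncol(m)),
            well = rep(colnames(m), each = nrow(m)),
            fluorescence = as.vector(m))
        df[is.finite(df$fluorescence), , drop = FALSE]
    })
    write.csv(do.call(rbind, rows), path, row.names = FALSE)
    invisible(path)
}
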