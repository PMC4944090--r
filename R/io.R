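# Plain-text readers and writers for every pipeline artifact.

#' Read and write trajectory CSV files
#'
#' The on-disk format is long: one row per frame with header
#' `animal_id,group,t_s,cx_mm,cy_mm`. `writeTrajectoryCSV()` writes either
#' one long-format file (default) or one file per animal under a directory.
#'
#' @param trajs a list of [WormTrajectory-class] objects.
#' @param path output CSV path (or directory when `perAnimal = TRUE`).
#' @param perAnimal write one `<animal_id>.csv` per animal instead of one
#'   long file.
#' @return `readTrajectoryCSV`: a list of [WormTrajectory-class] objects;
#'   `writeTrajectoryCSV`: the path(s) written, invisibly.
#' @examples
#' coh <- simulateCohort(list(list(group = "g", params = simParams(durationS = 5),
#'                                 nAnimals = 2)), seed = 1)
#' f <- tempfile(fileext = ".csv")
#' writeTrajectoryCSV(coh, f)
#' length(readTrajectoryCSV(f))
#' @export
writeTrajectoryCSV <- function(trajs, path, perAnimal = FALSE) {
  rows <- lapply(trajs, function(tr)
    data.frame(animal_id = tr@animalId, group = tr@group,
               t_s = tr@samples$t, cx_mm = tr@samples$x, cy_mm = tr@samples$y))
  if (perAnimal) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    paths <- vapply(rows, function(df) {
      p <- file.path(path, paste0(df$animal_id[1], ".csv"))
      write.csv(df, p, row.names = FALSE, quote = FALSE)
      p
    }, "")
    return(invisible(paths))
  }
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTrajectoryCSV
#' @export
readTrajectoryCSV <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "group", "t_s", "cx_mm", "cy_mm")
  stopIfNot(all(need %in% names(df)),
            sprintf("trajectory CSV must have columns %s", paste(need, collapse = ",")))
  lapply(split(df, df$animal_id), function(d)
    new("WormTrajectory", animalId = d$animal_id[1], group = d$group[1],
        samples = data.frame(t = d$t_s, x = d$cx_mm, y = d$cy_mm)))
}

#' Read and write step-table CSV files
#'
#' Long format, one row per step, header `animal_id,group,step_idx,t_start,
#' t_end,length_mm,angle_deg,speed_mm_s,length_norm,angle_norm,speed_norm`.
#'
#' @param tables a list of [StepTable-class] objects.
#' @param path CSV path.
#' @return `readStepTableCSV`: a list of [StepTable-class] objects;
#'   the writer returns `path` invisibly.
#' @export
writeStepTableCSV <- function(tables, path) {
  rows <- lapply(tables, function(tb) {
    s <- tb@steps
    if (!nrow(s)) return(NULL)
    data.frame(animal_id = tb@animalId, group = tb@group, step_idx = s$stepIdx,
               t_start = s$tStart, t_end = s$tEnd, length_mm = s$lengthMm,
               angle_deg = s$angleDeg, speed_mm_s = s$speedMmS,
               length_norm = s$lengthNorm, angle_norm = s$angleNorm,
               speed_norm = s$speedNorm)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeStepTableCSV
#' @param normalized whether the file holds normalized columns (recorded in
#'   the rebuilt objects).
#' @export
readStepTableCSV <- function(path, normalized = TRUE) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$animal_id), function(d)
    new("StepTable", animalId = d$animal_id[1], group = d$group[1],
        steps = data.frame(stepIdx = d$step_idx, tStart = d$t_start,
                           tEnd = d$t_end, lengthMm = d$length_mm,
                           angleDeg = d$angle_deg, speedMmS = d$speed_mm_s,
                           lengthNorm = d$length_norm, angleNorm = d$angle_norm,
                           speedNorm = d$speed_norm),
        normalized = normalized, degenerateFeatures = character()))
}

#' Read and write symbol strings
#'
#' Tab-separated text, one animal per line: `animal_id<TAB>group<TAB>2212...`.
#'
#' @param strings a list of [SymbolString-class] objects.
#' @param path file path.
#' @param k alphabet size recorded in the rebuilt objects (reader).
#' @return `readSymbolStrings`: a list of [SymbolString-class] objects; the
#'   writer returns `path` invisibly.
#' @export
writeSymbolStrings <- function(strings, path) {
  lines <- vapply(strings, function(s)
    paste(s@animalId, s@group, paste(s@symbols, collapse = ""), sep = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeSymbolStrings
#' @export
readSymbolStrings <- function(path, k = 2L) {
  lines <- readLines(path)
  lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    stopIfNot(length(f) == 3L, "each line must be animal<TAB>group<TAB>symbols")
    sym <- if (nchar(f[3])) as.integer(strsplit(f[3], "")[[1]]) else integer()
    new("SymbolString", animalId = f[1], group = f[2], symbols = sym,
        k = max(k, sym, 1L))
  })
}

#' Write an RLE matrix with its metadata sidecar
#'
#' Writes the count grid as CSV (header row = column values, first column =
#' symbol index) plus a JSON sidecar carrying kind, n_r, n_p and the bin
#' scheme.
#'
#' @param m a [RLEMatrix-class].
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.meta.json`.
#' @return the CSV path, invisibly.
#' @export
writeRLEMatrixCSV <- function(m, path) {
  df <- cbind(data.frame(symbol = seq_len(nrow(m@counts))),
              as.data.frame(m@counts))
  names(df)[-1] <- paste0("j_", format(m@colValues, trim = TRUE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(animal_id = m@animalId, group = m@group, kind = m@kind,
               n_r = m@nRuns, n_p = m@nSteps, col_values = m@colValues)
  if (!is.null(m@binScheme))
    meta$bins <- list(lower = m@binScheme@lower, upper = m@binScheme@upper)
  if (length(m@emptyBins)) meta$empty_bins = m@emptyBins
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Write a descriptor table
#'
#' @param table a `data.frame` from [descriptorTable()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
writeDescriptorCSV <- function(table, path) {
  write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeDescriptorCSV
#' @export
readDescriptorCSV <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
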