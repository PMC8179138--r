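# File I/O: perturbation-series TSV, multi-model PDB trajectories with an
# orientation sidecar, and van't Hoff tables.

#' Write perturbation series to TSV
#'
#' Columns: window_index, lambda, frame, delta_U_kcal_mol, with a mandatory
#' header line; the temperature is carried in a `# temperature_K=` comment.
#'
#' @param series list of [PerturbationSeries-class] (as returned by
#'   [sampleAlchemicalPath()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePerturbationTsv <- function(series, path) {
  temp <- unique(vapply(series, function(s) s@temperature, numeric(1)))
  .stopIfNot(length(temp) == 1, "all series must share one temperature")
  # %.17g keeps doubles bit-exact through the round trip
  rows <- do.call(rbind, lapply(series, function(s)
    data.frame(window_index = s@windowIndex,
               lambda = sprintf("%.17g", s@lambda),
               frame = seq_along(s@deltaU),
               delta_U_kcal_mol = sprintf("%.17g", s@deltaU))))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# temperature_K=%.10g", temp), con)
  write.table(rows, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read perturbation series from TSV
#'
#' Expects the format of [writePerturbationTsv()]: a header row naming
#' window_index, lambda, frame and delta_U_kcal_mol.  Malformed rows are
#' rejected with their line numbers; duplicate (window, frame) pairs are an
#' error.
#'
#' @param path input file.
#' @param temperature K; overrides the file's `# temperature_K=` comment.
#' @return list of [PerturbationSeries-class], ordered by window.
#' @export
readPerturbationTsv <- function(path, temperature = NULL) {
  lines <- readLines(path)
  isComment <- startsWith(lines, "#")
  if (is.null(temperature)) {
    tline <- grep("^# temperature_K=", lines, value = TRUE)
    temperature <- if (length(tline)) as.numeric(sub("^# temperature_K=", "", tline[1])) else 300
  }
  body <- lines[!isComment]
  .stopIfNot(length(body) >= 2, "file has no data rows")
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  need <- c("window_index", "lambda", "frame", "delta_U_kcal_mol")
  miss <- setdiff(need, header)
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  lineNo <- which(!isComment)[-1] # file line numbers of the data rows
  cells <- strsplit(body[-1], "\t", fixed = TRUE)
  bad <- which(lengths(cells) != length(header))
  if (length(bad))
    stop("malformed row(s) at line(s): ", paste(lineNo[bad], collapse = ", "))
  m <- do.call(rbind, cells)
  colnames(m) <- header
  num <- suppressWarnings(apply(m[, need, drop = FALSE], 2, as.numeric))
  if (nrow(m) == 1) num <- matrix(num, nrow = 1, dimnames = list(NULL, need))
  badNum <- which(!complete.cases(num))
  if (length(badNum))
    stop("non-numeric value(s) at line(s): ", paste(lineNo[badNum], collapse = ", "))
  key <- paste(num[, "window_index"], num[, "frame"])
  if (anyDuplicated(key))
    stop("duplicate (window, frame) pair(s) at line(s): ",
         paste(lineNo[duplicated(key)], collapse = ", "))
  df <- as.data.frame(num)
  out <- lapply(split(df, df$window_index), function(d) {
    d <- d[order(d$frame), ]
    new("PerturbationSeries", windowIndex = as.integer(d$window_index[1]),
        lambda = d$lambda[1], lambdaNext = NA_real_,
        deltaU = d$delta_U_kcal_mol, temperature = temperature)
  })
  out[order(vapply(out, function(s) s@windowIndex, integer(1)))]
}

#' Write a trajectory as multi-model PDB plus orientation sidecar
#'
#' One MODEL per frame; solute particles as carbon ATOM records (residue
#' LIG), waters as oxygen records (residue HOH).  Orientations go to a TSV
#' sidecar with columns frame, water_id, ux, uy, uz.  PDB coordinates are
#' written at the format's 0.001 Angstrom precision.
#'
#' @param traj a [Trajectory-class]; all frames must share the particle
#'   counts of the first frame (the PDB MODEL convention).
#' @param pdbPath,orientationPath output files.
#' @return `pdbPath`, invisibly.
#' @export
writeTrajectoryPdb <- function(traj, pdbPath, orientationPath) {
  f1 <- traj@frames[[1]]
  ns <- nrow(f1$solute); nw <- nrow(f1$water)
  ok <- vapply(traj@frames, function(f)
    nrow(f$solute) == ns && nrow(f$water) == nw, logical(1))
  .stopIfNot(all(ok), "all frames must have identical particle counts for PDB output")
  xyz <- do.call(rbind, lapply(traj@frames, function(f)
    as.numeric(t(rbind(f$solute, f$water)))))
  n <- ns + nw
  bio3d::write.pdb(file = pdbPath, xyz = xyz,
                   type = rep(c("ATOM", "HETATM"), c(ns, nw)),
                   resno = seq_len(n),
                   resid = rep(c("LIG", "HOH"), c(ns, nw)),
                   elety = rep(c("C", "O"), c(ns, nw)),
                   chain = rep("A", n))
  ori <- do.call(rbind, lapply(seq_along(traj@frames), function(i) {
    o <- traj@frames[[i]]$orient
    data.frame(frame = i, water_id = seq_len(nrow(o)),
               ux = o[, 1], uy = o[, 2], uz = o[, 3])
  }))
  write.table(ori, orientationPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(pdbPath)
}

#' Read a trajectory from multi-model PDB plus orientation sidecar
#'
#' Frames are aligned by MODEL index with the sidecar's `frame` column; every
#' water in every frame must have an orientation row.  Orientation vectors
#' with \eqn{| \lVert u \rVert - 1 | < 10^{-3}} are re-normalized; larger
#' deviations are an error.
#'
#' @param pdbPath multi-model PDB (waters = residue HOH).
#' @param orientationPath TSV with columns frame, water_id, ux, uy, uz.
#' @param regionCenter,regionRadius spherical region; the radius defaults to
#'   just enclosing all coordinates.
#' @param temperature K.
#' @return A [Trajectory-class].
#' @export
readTrajectoryPdb <- function(pdbPath, orientationPath,
                              regionCenter = c(0, 0, 0), regionRadius = NULL,
                              temperature = 300) {
  pdb <- bio3d::read.pdb(pdbPath, multi = TRUE)
  isWater <- pdb$atom$resid == "HOH"
  nf <- nrow(pdb$xyz)
  ori <- read.delim(orientationPath)
  need <- c("frame", "water_id", "ux", "uy", "uz")
  miss <- setdiff(need, names(ori))
  if (length(miss)) stop("orientation file missing column(s): ",
                         paste(miss, collapse = ", "))
  if (max(ori$frame) != nf)
    stop(sprintf("frame-count mismatch: PDB has %d models, orientation file %d frames",
                 nf, max(ori$frame)))
  nw <- sum(isWater)
  frames <- vector("list", nf)
  for (i in seq_len(nf)) {
    co <- matrix(pdb$xyz[i, ], ncol = 3, byrow = TRUE)
    wat <- co[isWater, , drop = FALSE]
    sol <- co[!isWater, , drop = FALSE]
    oi <- ori[ori$frame == i, ]
    oi <- oi[order(oi$water_id), ]
    missing <- setdiff(seq_len(nw), oi$water_id)
    if (length(missing))
      stop(sprintf("orientation row missing for frame %d, water_id %s", i,
                   paste(missing, collapse = ",")))
    u <- as.matrix(oi[, c("ux", "uy", "uz")])
    nrm <- sqrt(rowSums(u^2))
    if (any(abs(nrm - 1) >= 1e-3))
      stop(sprintf("orientation vector far from unit norm in frame %d", i))
    frames[[i]] <- list(solute = sol, water = wat, orient = u / nrm)
  }
  if (is.null(regionRadius)) {
    rmax <- max(vapply(frames, function(f) {
      w <- rbind(f$water, f$solute)
      if (nrow(w) == 0) 0 else max(sqrt(rowSums(sweep(w, 2, regionCenter)^2)))
    }, numeric(1)))
    regionRadius <- rmax + 1e-3
  }
  new("Trajectory", frames = frames, regionCenter = regionCenter,
      regionRadius = regionRadius, temperature = temperature)
}

#' Write / read a van't Hoff table as TSV
#'
#' @param table data.frame with columns temperature, replicate, dG.
#' @param path file path.
#' @return `path` (write) or the data.frame (read).
#' @export
writeVantHoffTsv <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeVantHoffTsv
#' @export
readVantHoffTsv <- function(path) {
  tab <- read.delim(path)
  .checkVHTable(tab)
  tab
}
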