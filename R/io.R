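# Readers and writers for the plain-text exchange formats: two-column
# experimental spectra (optionally JCAMP-DX), ensemble manifests with
# three-column stick files, and the corresponding writers used by the
# simulator and the CLI.

#' Read an experimental spectrum
#'
#' Accepts two-column delimited text (wavenumber, intensity; whitespace or
#' comma separated, `#` comments allowed) or JCAMP-DX in the simple
#' `XYDATA (X++(Y..Y))` and `XYPOINTS` dialects.  Points are sorted by
#' wavenumber and linearly interpolated onto the configured uniform grid;
#' grid points outside the measured range are set to 0 and flagged
#' unmeasured, which excludes them from similarity evaluation downstream.
#'
#' @param path file to read.
#' @param mode `"VA"` or `"VCD"`.
#' @param cfg a [broadening_config()] supplying the target grid.
#' @return a [continuous_spectrum()] on `cfg$grid`.
#' @export
read_experimental_spectrum <- function(path, mode = c("VCD", "VA"),
                                       cfg = broadening_config()) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stopf("spectrum file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  xy <- if (any(grepl("^##", lines))) parse_jcamp(lines) else parse_two_column(lines)
  if (nrow(xy) < 2L) stopf("need at least 2 spectral points in %s", path)
  o <- order(xy[, 1])
  x <- xy[o, 1]; y <- xy[o, 2]
  if (any(diff(x) <= 0)) stopf("duplicate wavenumbers in %s", path)
  v <- stats::approx(x, y, xout = cfg$grid, rule = 1)$y
  measured <- !is.na(v)
  v[!measured] <- 0
  continuous_spectrum(cfg$grid, v, mode = mode, measured = measured)
}

parse_two_column <- function(lines) {
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stopf("no data lines in spectrum file")
  parts <- strsplit(lines, "[,;[:space:]]+")
  bad <- vapply(parts, length, integer(1)) != 2L
  if (any(bad)) stopf("expected two columns, offending line: '%s'",
                      lines[which(bad)[1]])
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 2L, byrow = TRUE)
  if (any(!is.finite(m))) stopf("non-numeric value in spectrum file")
  m
}

# Minimal JCAMP-DX reader: XYDATA=(X++(Y..Y)) with XFACTOR/YFACTOR/DELTAX,
# and XYPOINTS=(XY..XY).  Compressed ASDF forms (SQZ/DIF/DUP) are not
# supported.
parse_jcamp <- function(lines) {
  get_field <- function(name) {
    hit <- grep(sprintf("^##%s=", name), lines, ignore.case = TRUE, value = TRUE)
    if (length(hit) == 0L) return(NA_character_)
    trimws(sub("^##[^=]*=", "", hit[1L]))
  }
  num_field <- function(name, default) {
    v <- suppressWarnings(as.numeric(get_field(name)))
    if (is.na(v)) default else v
  }
  xf <- num_field("XFACTOR", 1); yf <- num_field("YFACTOR", 1)
  i_xy <- grep("^##XYDATA=", lines, ignore.case = TRUE)
  i_pt <- grep("^##XYPOINTS=", lines, ignore.case = TRUE)
  i_end <- grep("^##END", lines, ignore.case = TRUE)
  stop_at <- if (length(i_end)) i_end[1L] else length(lines) + 1L
  if (length(i_xy)) {
    body <- lines[(i_xy[1L] + 1L):(stop_at - 1L)]
    body <- body[!grepl("^##", body)]
    rows <- lapply(body, function(ln) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(ln), "[,[:space:]]+")[[1]]))
      v[!is.na(v)]
    })
    rows <- rows[vapply(rows, length, integer(1)) >= 2L]
    if (length(rows) == 0L) stopf("empty JCAMP XYDATA block")
    npts <- sum(vapply(rows, length, integer(1))) - length(rows)
    dx <- num_field("DELTAX", NA_real_)
    if (is.na(dx)) {
      first <- num_field("FIRSTX", NA_real_); last <- num_field("LASTX", NA_real_)
      n <- num_field("NPOINTS", npts)
      if (is.na(first) || is.na(last) || n < 2) stopf("JCAMP file lacks DELTAX/FIRSTX/LASTX")
      dx <- (last - first) / (n - 1)
    }
    out <- do.call(rbind, lapply(rows, function(v) {
      x0 <- v[1L] * xf
      ys <- v[-1L] * yf
      cbind(x0 + dx * (seq_along(ys) - 1L), ys)
    }))
    return(out)
  }
  if (length(i_pt)) {
    body <- lines[(i_pt[1L] + 1L):(stop_at - 1L)]
    body <- body[!grepl("^##", body)]
    v <- suppressWarnings(as.numeric(unlist(strsplit(trimws(body), "[,;[:space:]]+"))))
    v <- v[!is.na(v)]
    if (length(v) < 4L || length(v) %% 2L != 0L) stopf("malformed JCAMP XYPOINTS block")
    m <- matrix(v, ncol = 2L, byrow = TRUE)
    m[, 1] <- m[, 1] * xf; m[, 2] <- m[, 2] * yf
    return(m)
  }
  stopf("JCAMP file has neither XYDATA nor XYPOINTS")
}

#' Write a spectrum as two-column text
#'
#' Only measured grid points are written, at 12 significant digits, so a
#' read/write round trip is lossless to text precision.
#'
#' @param spectrum a [continuous_spectrum()].
#' @param path output file.
#' @export
write_spectrum <- function(spectrum, path) {
  keep <- spectrum$measured
  lines <- sprintf("%.12g %.12g", spectrum$grid[keep], spectrum$values[keep])
  writeLines(c("# wavenumber_cm-1 intensity", lines), path)
  invisible(path)
}

#' Read a conformer ensemble from a manifest file
#'
#' The manifest is delimited text with header `id,energy_kcal,sticks_path`;
#' stick paths are resolved relative to the manifest's directory.  Each stick
#' file has three numeric columns: wavenumber (cm^-1), dipole strength,
#' rotational strength.  Energies are shifted so the minimum is 0.
#'
#' @param path manifest file.
#' @return a [vcd_ensemble()].
#' @export
read_conformer_ensemble <- function(path) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  man <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                         strip.white = TRUE)
  need <- c("id", "energy_kcal", "sticks_path")
  if (!all(need %in% names(man))) {
    stopf("manifest must have columns %s", paste(need, collapse = ", "))
  }
  base <- dirname(path)
  conformers <- lapply(seq_len(nrow(man)), function(i) {
    sp <- man$sticks_path[i]
    if (!file.exists(sp)) sp <- file.path(base, man$sticks_path[i])
    if (!file.exists(sp)) stopf("stick file missing for conformer %s: %s",
                                man$id[i], man$sticks_path[i])
    sticks <- read_sticks(sp)
    conformer_record(as.character(man$id[i]), man$energy_kcal[i], sticks)
  })
  vcd_ensemble(conformers)
}

read_sticks <- function(path) {
  lines <- sub("#.*$", "", readLines(path, warn = FALSE))
  lines <- trimws(lines); lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[,;[:space:]]+")
  bad <- vapply(parts, length, integer(1)) != 3L
  if (any(bad)) stopf("stick file %s: expected 3 columns, offending line '%s'",
                      path, lines[which(bad)[1]])
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 3L, byrow = TRUE)
  if (any(!is.finite(m))) stopf("non-numeric value in stick file %s", path)
  stick_spectrum(m[, 1], m[, 2], m[, 3])
}

#' Write an ensemble as a manifest plus per-conformer stick files
#'
#' Inverse of [read_conformer_ensemble()], used by the simulator and the CLI.
#'
#' @param ensemble a [vcd_ensemble()].
#' @param dir output directory (created if absent).
#' @return the manifest path, invisibly.
#' @export
write_ensemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(ensemble$n)
  for (i in seq_len(ensemble$n)) {
    cf <- ensemble$conformers[[i]]
    paths[i] <- sprintf("sticks_%s.dat", gsub("[^A-Za-z0-9_.-]", "_", cf$id))
    lines <- sprintf("%.12g %.12g %.12g", cf$sticks$frequencies,
                     cf$sticks$dipole_strengths, cf$sticks$rotational_strengths)
    writeLines(c("# wavenumber_cm-1 dipole_strength rotational_strength", lines),
               file.path(dir, paths[i]))
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(data.frame(id = ensemble$ids,
                              energy_kcal = ensemble$energies,
                              sticks_path = paths),
                   manifest, row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
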