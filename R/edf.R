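# Minimal EDF (European Data Format) I/O: 16-bit integer samples in 1 s data
# records, ASCII header. Only what the grid pipeline needs — no EDF+
# annotations, no per-channel sampling rates. Grid channels are labeled
# "R{r}C{c}", the bipolar channel "BIP". Metadata that EDF cannot carry
# (electrode spacing, annotation marks, ground truth) travels in a JSON
# sidecar, see write_annotations().

.edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  paste0(x, strrep(" ", width - nchar(x)))
}

#' Write a grid recording to an EDF file
#'
#' @param recording a [grid_recording()]; `fs_hz` must be an integer (one
#'   data record per second). A trailing partial second is truncated.
#' @param path output file path.
#' @param sidecar write the JSON annotation sidecar next to the EDF
#'   (default TRUE, at `paste0(path, ".json")`).
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path, sidecar = TRUE) {
  fs <- recording$fs_hz
  if (fs != round(fs)) stop_invalid("EDF export requires an integer fs_hz (got %g)", fs)
  d <- dim(recording$grid)
  nrec <- (d[3] %/% fs)
  if (nrec < 1) stop_invalid("recording shorter than one 1 s data record")
  if (nrec * fs < d[3])
    warning(sprintf("truncating %d trailing samples to whole seconds", d[3] - nrec * fs))
  nt <- nrec * fs
  labels <- as.vector(outer(seq_len(d[1]), seq_len(d[2]),
                            function(r, cc) sprintf("R%dC%d", r, cc)))
  sig <- cbind(t(matrix(recording$grid[, , seq_len(nt), drop = FALSE],
                        nrow = d[1] * d[2])),
               recording$bipolar[seq_len(nt)])
  labels <- c(labels, "BIP")
  ns <- ncol(sig)

  pmin_ <- apply(sig, 2, min); pmax_ <- apply(sig, 2, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768; dmax <- 32767
  dig <- round((t(sig) - pmin_) / (pmax_ - pmin_) * (dmax - dmin) + dmin)
  dig <- t(dig)
  storage.mode(dig) <- "integer"

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8),
    .edf_pad("X X X X", 80),
    .edf_pad("Startdate X X X X", 80),
    "01.01.00", "00.00.00",
    .edf_pad(256 * (ns + 1), 8),
    .edf_pad("", 44),
    .edf_pad(nrec, 8),
    .edf_pad(1, 8),
    .edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width)
    writeChar(paste(vapply(vals, .edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  field(labels, 16)
  field(rep("", ns), 80)                      # transducer
  field(rep("uV", ns), 8)
  field(sprintf("%.6g", pmin_), 8)
  field(sprintf("%.6g", pmax_), 8)
  field(rep(dmin, ns), 8)
  field(rep(dmax, ns), 8)
  field(rep("", ns), 80)                      # prefiltering
  field(rep(fs, ns), 8)
  field(rep("", ns), 32)
  # data: per record, each signal's fs samples contiguously
  arr <- array(dig, dim = c(fs, nrec, ns))
  writeBin(as.integer(aperm(arr, c(1, 3, 2))), con, size = 2, endian = "little")
  if (sidecar) write_annotations(recording, paste0(path, ".json"))
  invisible(path)
}

#' Read a grid recording from an EDF file
#'
#' Reconstructs the grid from the `R{r}C{c}` channel labels and the bipolar
#' channel from `BIP`. If a JSON sidecar written by [write_annotations()] is
#' found at `paste0(path, ".json")` (or passed explicitly), annotation marks
#' and the electrode spacing are restored from it.
#'
#' @param path EDF file path.
#' @param annotations optional sidecar path.
#' @param electrode_spacing_cm fallback spacing when no sidecar is present.
#' @return a [grid_recording()].
#' @export
read_edf <- function(path, annotations = NULL, electrode_spacing_cm = 0.5) {
  if (!file.exists(path)) stop_invalid("no such EDF file: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                       # header bytes
  rd(44)
  nrec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1)
    stop_invalid("mixed per-signal sampling rates are not supported")
  fs <- spr[1] / dur
  raw <- readBin(con, "integer", n = nrec * sum(spr), size = 2,
                 endian = "little")
  arr <- aperm(array(raw, dim = c(spr[1], ns, nrec)), c(1, 3, 2)) # spr,nrec,ns
  phys <- vapply(seq_len(ns), function(i)
    (as.vector(arr[, , i]) - dmin[i]) / (dmax[i] - dmin[i]) *
      (pmax_[i] - pmin_[i]) + pmin_[i], numeric(spr[1] * nrec))

  m <- regmatches(labels, regexec("^R([0-9]+)C([0-9]+)$", labels))
  is_grid <- lengths(m) == 3
  if (!any(is_grid)) stop_invalid("no R{r}C{c} grid channels found")
  rr <- as.integer(vapply(m[is_grid], `[`, "", 2))
  cc <- as.integer(vapply(m[is_grid], `[`, "", 3))
  nr <- max(rr); nc <- max(cc)
  nt <- spr[1] * nrec
  grid <- array(0, dim = c(nr, nc, nt))
  gi <- which(is_grid)
  for (k in seq_along(gi)) grid[rr[k], cc[k], ] <- phys[, gi[k]]
  bip <- if ("BIP" %in% labels) phys[, which(labels == "BIP")[1]] else numeric(nt)

  toco <- matrix(numeric(0), ncol = 2)
  perc <- numeric(0)
  spacing <- electrode_spacing_cm
  side <- annotations %||% paste0(path, ".json")
  if (file.exists(side)) {
    ann <- read_annotations(side)
    toco <- ann$toco_marks
    perc <- ann$perception_marks
    spacing <- ann$electrode_spacing_cm %||% spacing
  }
  grid_recording(grid, bip, fs, spacing, toco, perc)
}

#' Write the annotation sidecar for a recording
#'
#' JSON with `toco` (list of `[onset_s, duration_s]`), `perception` (list of
#' instants), `electrode_spacing_cm`, and — for synthetic recordings — the
#' generating scenario under `ground_truth`.
#' @param recording a [grid_recording()].
#' @param path output JSON path.
#' @export
write_annotations <- function(recording, path) {
  gt <- recording$ground_truth
  obj <- list(
    toco = unname(apply(recording$toco_marks, 1, function(r) as.numeric(r),
                        simplify = FALSE)),
    perception = as.numeric(recording$perception_marks),
    electrode_spacing_cm = recording$electrode_spacing_cm)
  if (!is.null(gt)) {
    obj$ground_truth <- list(
      true_cv_cm_s = gt$true_cv_cm_s, true_angle_rad = gt$true_angle_rad,
      snr_db = if (is.finite(gt$snr_db)) gt$snr_db else "Inf",
      rng_seed = gt$rng_seed,
      contraction_schedule = unname(apply(gt$contraction_schedule, 1,
                                          as.numeric, simplify = FALSE)))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an annotation sidecar
#' @param path JSON path written by [write_annotations()] (or hand-authored
#'   with fields `toco` and `perception`).
#' @return list with `toco_marks` (matrix), `perception_marks`,
#'   `electrode_spacing_cm`, `ground_truth` (may be NULL).
#' @export
read_annotations <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  toco <- obj$toco
  if (is.null(toco) || length(toco) == 0) toco <- matrix(numeric(0), ncol = 2)
  else if (is.list(toco)) toco <- do.call(rbind, toco)
  else toco <- matrix(toco, ncol = 2)
  list(toco_marks = matrix(as.numeric(toco), ncol = 2),
       perception_marks = as.numeric(obj$perception %||% numeric(0)),
       electrode_spacing_cm = obj$electrode_spacing_cm,
       ground_truth = obj$ground_truth)
}
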