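#' Write a trajectory to disk
#'
#' Two plain-text formats are supported. The compact dialect has one header
#' line (`<n_beads> <box_side>`) followed by per-frame blocks: a
#' `<frame_index> <time_ns>` line and then one `x y z` line per bead
#' (Angstrom, 0-based bead order as in the topology). The multi-model PDB
#' format writes one bead per ATOM record (serials 1-based, molecule label
#' in the chain ID: `R` receptor / `L` ligand, bead charge in the occupancy
#' column), one frame per MODEL, with the frame time on a preceding
#' `REMARK 250 TIME=` line.
#'
#' @param trajectory A `bd_trajectory` with recorded frames.
#' @param path Output path.
#' @param format `"dat"` (compact dialect) or `"pdb"`; `"auto"` picks by
#'   file extension (`.pdb` vs anything else).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path,
                             format = c("auto", "dat", "pdb")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "dat"
  }
  if (is.null(trajectory$frames)) stop("trajectory has no recorded frames")
  n <- nrow(trajectory$topology$beads)
  nf <- length(trajectory$times)
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "dat") {
    writeLines(sprintf("%d %.6f", n, trajectory$box_side), con)
    for (f in seq_len(nf)) {
      writeLines(sprintf("%d %.6f", f - 1L, trajectory$times[f]), con)
      xyz <- matrix(trajectory$frames[f, ], ncol = 3, byrow = TRUE)
      writeLines(sprintf("%.4f %.4f %.4f", xyz[, 1], xyz[, 2], xyz[, 3]), con)
    }
  } else {
    b <- trajectory$topology$beads
    chain <- ifelse(b$molecule == "receptor", "R", "L")
    writeLines(sprintf("REMARK 250 BOX= %.6f", trajectory$box_side), con)
    for (f in seq_len(nf)) {
      writeLines(sprintf("REMARK 250 TIME= %.6f", trajectory$times[f]), con)
      writeLines(sprintf("MODEL     %4d", f), con)
      xyz <- matrix(trajectory$frames[f, ], ncol = 3, byrow = TRUE)
      writeLines(sprintf(
        "ATOM  %5d  BB  BEA %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
        seq_len(n), chain, seq_len(n), xyz[, 1], xyz[, 2], xyz[, 3],
        b$charge, 0), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  }
  invisible(path)
}

#' Read a trajectory from disk
#'
#' Auto-detects the format written by [write_trajectory()] (compact dialect
#' vs multi-model PDB; PDB files are parsed with bio3d).
#'
#' @param path Input path.
#' @param topology The system `bead_topology` the file must match.
#' @return A `bd_trajectory` (frames, times, topology, box side; no scalar
#'   series).
#' @export
read_trajectory <- function(path, topology) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines1 <- readLines(path, n = 1)
  if (length(lines1) == 0) stop("empty trajectory file: ", path)
  is_pdb <- grepl("^(REMARK|MODEL|ATOM|HEADER)", lines1)
  n <- nrow(topology$beads)
  if (is_pdb) {
    txt <- readLines(path)
    times <- as.numeric(sub(".*TIME= *", "",
                            grep("REMARK 250 TIME=", txt, value = TRUE)))
    box_line <- grep("REMARK 250 BOX=", txt, value = TRUE)
    box <- if (length(box_line)) {
      as.numeric(sub(".*BOX= *", "", box_line[1]))
    } else topology$box_side
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    if (ncol(xyz) != 3 * n) {
      stop("format error: bead count mismatch (file has ", ncol(xyz) / 3,
           ", topology has ", n, ")")
    }
    nf <- nrow(xyz)
    if (length(times) != nf) times <- seq_len(nf) - 1
    frames <- matrix(unclass(xyz), nrow = nf)
  } else {
    tok <- scan(path, what = numeric(), quiet = TRUE)
    n_file <- tok[1]
    box <- tok[2]
    if (n_file != n) {
      stop("format error: bead count mismatch (file has ", n_file,
           ", topology has ", n, ")")
    }
    body <- tok[-(1:2)]
    per_frame <- 2 + 3 * n
    if (length(body) %% per_frame != 0) {
      stop("format error: truncated frame block")
    }
    nf <- length(body) / per_frame
    if (nf == 0) stop("empty trajectory file: ", path)
    blk <- matrix(body, nrow = per_frame)
    times <- blk[2, ]
    frames <- t(blk[-(1:2), , drop = FALSE])
  }
  if (nf == 0) stop("empty trajectory file: ", path)
  if (any(diff(times) <= 0) && nf > 1) {
    stop("data error: frame times must be strictly increasing")
  }
  if (!all(is.finite(frames))) stop("data error: non-finite coordinates")
  structure(list(times = times, frames = frames, contacts = NULL,
                 com_distance = NULL, energies = NULL, fpt = NA,
                 censored = NA, topology = topology, box_side = box),
            class = "bd_trajectory")
}

#' Re-centre one frame across periodic boundaries
#'
#' Translates the whole system so the receptor centre of mass sits at the
#' box centre, then shifts the ligand by the lattice vector that minimises
#' its centre-of-mass distance to the receptor (the minimum image).
#' Intra-molecular distances are untouched; the operation is idempotent.
#'
#' @param frame N x 3 coordinate matrix.
#' @param topology The system `bead_topology`.
#' @param box_side Cubic box side (defaults to `topology$box_side`).
#' @return Re-centred N x 3 coordinate matrix.
#' @export
autoimage_recenter <- function(frame, topology, box_side = NULL) {
  if (is.null(box_side)) box_side <- topology$box_side
  b <- topology$beads
  is_lig <- b$molecule == "ligand"
  m <- b$mass
  rec_com <- colSums(frame[!is_lig, , drop = FALSE] * m[!is_lig]) /
    sum(m[!is_lig])
  shift <- box_side / 2 - rec_com
  out <- sweep(frame, 2, shift, "+")
  if (any(is_lig)) {
    lig_com <- colSums(out[is_lig, , drop = FALSE] * m[is_lig]) /
      sum(m[is_lig])
    lat <- -box_side * round((lig_com - box_side / 2) / box_side)
    out[is_lig, ] <- sweep(out[is_lig, , drop = FALSE], 2, lat, "+")
  }
  out
}

#' Re-centre every frame of a trajectory
#'
#' @param trajectory A `bd_trajectory` with recorded frames.
#' @return The trajectory with all frames passed through
#'   [autoimage_recenter()].
#' @export
autoimage_trajectory <- function(trajectory) {
  if (is.null(trajectory$frames)) stop("trajectory has no recorded frames")
  nf <- length(trajectory$times)
  for (f in seq_len(nf)) {
    xyz <- matrix(trajectory$frames[f, ], ncol = 3, byrow = TRUE)
    xyz <- autoimage_recenter(xyz, trajectory$topology, trajectory$box_side)
    trajectory$frames[f, ] <- as.vector(t(xyz))
  }
  trajectory
}
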