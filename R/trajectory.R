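# Geometric analysis of CYP3A4-ligand trajectories: virtual Compound I
# oxygen construction, productive/selective frame classification, distance
# histograms and per-residue ligand contact statistics.

#' Build an in-memory trajectory object
#'
#' A minimal trajectory container: an atom table plus an
#' `n_frames x (3 * n_atoms)` coordinate matrix in Angstrom, mirroring the
#' layout used by [bio3d::read.dcd()].
#'
#' @param atoms Data frame with columns `name`, `resname`, `resid`,
#'   `chain`, `element`.
#' @param xyz Numeric matrix (`n_frames` rows, `3 * n_atoms` columns) of
#'   coordinates in Angstrom, atom-major (`x1, y1, z1, x2, ...`).
#' @return An object of class `cyp_traj`.
#' @export
cyp_trajectory <- function(atoms, xyz) {
  need <- c("name", "resname", "resid", "chain", "element")
  if (!is.data.frame(atoms) || !all(need %in% names(atoms)))
    stop_input(paste("atoms must be a data frame with columns:",
                     paste(need, collapse = ", ")))
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3L * nrow(atoms))
    stop_input("xyz must have 3 * n_atoms columns")
  structure(list(atoms = atoms, xyz = xyz), class = "cyp_traj")
}

#' @export
print.cyp_traj <- function(x, ...) {
  cat("Trajectory:", nrow(x$xyz), "frames,", nrow(x$atoms), "atoms\n")
  invisible(x)
}

n_frames <- function(traj) nrow(traj$xyz)

# coordinates of frame i as an n_atoms x 3 matrix
frame_coords <- function(traj, i) {
  matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE)
}

#' Read a trajectory from PDB topology plus coordinate file
#'
#' The topology is a PDB file; coordinates come either from the same file
#' (multi-MODEL PDB) or from a separate multi-MODEL PDB or binary DCD file.
#' All coordinates are kept in Angstrom.
#'
#' @param topology Path to a PDB file defining the atoms.
#' @param trajectory Optional path to the coordinate file (`.pdb`
#'   multi-model or `.dcd`); if `NULL` the topology's own models are used.
#' @return A [cyp_trajectory()] object.
#' @export
read_trajectory <- function(topology, trajectory = NULL) {
  if (!file.exists(topology)) stop_io(paste("topology not found:", topology))
  pdb <- tryCatch(bio3d::read.pdb(topology, multi = TRUE, verbose = FALSE),
                  error = function(e) stop_io(paste("cannot read topology:",
                                                    conditionMessage(e))))
  atoms <- data.frame(name = pdb$atom$elety,
                      resname = pdb$atom$resid,
                      resid = pdb$atom$resno,
                      chain = ifelse(is.na(pdb$atom$chain), "", pdb$atom$chain),
                      element = pdb$atom$elesy,
                      stringsAsFactors = FALSE)
  # fall back to the first character of the atom name when the element
  # column is absent from the PDB
  blank <- is.na(atoms$element) | atoms$element == ""
  atoms$element[blank] <- substr(gsub("[0-9']", "", atoms$name[blank]), 1, 1)

  if (is.null(trajectory)) {
    xyz <- pdb$xyz
  } else {
    if (!file.exists(trajectory))
      stop_io(paste("trajectory not found:", trajectory))
    ext <- tolower(tools::file_ext(trajectory))
    xyz <- switch(ext,
      dcd = tryCatch(bio3d::read.dcd(trajectory, verbose = FALSE),
                     error = function(e) stop_io(paste("cannot read DCD:",
                                                       conditionMessage(e)))),
      pdb = bio3d::read.pdb(trajectory, multi = TRUE, verbose = FALSE)$xyz,
      stop_io(paste("unsupported trajectory format:", ext)))
  }
  cyp_trajectory(atoms, unclass(xyz))
}

#' Select atoms with a small chain/resid/name grammar
#'
#' Selection strings are `and`-joined clauses of the form
#' `keyword value [value ...]` with keywords `name`, `resname`, `resid`,
#' `chain` and `elem`, e.g. `"resname MDZ and name C1"` or
#' `"resid 508 and name NA NB NC ND"`.  Integer vectors pass through
#' unchanged.
#'
#' @param traj A [cyp_trajectory()] object.
#' @param sel Selection string or integer vector of atom indices.
#' @return Integer vector of atom indices (1-based).
#' @export
select_atoms <- function(traj, sel) {
  if (is.numeric(sel)) {
    sel <- as.integer(sel)
    if (any(sel < 1) || any(sel > nrow(traj$atoms)))
      stop_selection("atom indices out of range")
    return(sel)
  }
  if (!is.character(sel) || length(sel) != 1L)
    stop_selection("selection must be a string or integer vector")
  clauses <- strsplit(sel, "\\s+and\\s+")[[1]]
  keep <- rep(TRUE, nrow(traj$atoms))
  for (cl in clauses) {
    tok <- strsplit(trimws(cl), "\\s+")[[1]]
    if (length(tok) < 2)
      stop_selection(paste("malformed selection clause:", sQuote(cl)))
    key <- tok[1]
    vals <- tok[-1]
    keep <- keep & switch(key,
      name    = traj$atoms$name %in% vals,
      resname = traj$atoms$resname %in% vals,
      resid   = traj$atoms$resid %in% as.integer(vals),
      chain   = traj$atoms$chain %in% vals,
      elem    = traj$atoms$element %in% vals,
      stop_selection(paste("unknown selection keyword:", sQuote(key))))
  }
  which(keep)
}

#' Heme geometry for the virtual-oxygen construction
#'
#' @param fe 3D position of the heme iron (Angstrom).
#' @param pyrrole_n 4 x 3 matrix of the four pyrrole nitrogen positions.
#' @param axial_s 3D position of the proximal cysteine thiolate sulfur.
#' @return A `heme_geometry` object.  The pyrrole nitrogens must be
#'   near-coplanar (out-of-plane deviation < 0.5 Angstrom) and the axial
#'   sulfur must sit more than 1 Angstrom off that plane.
#' @export
heme_geometry <- function(fe, pyrrole_n, axial_s) {
  fe <- as.numeric(fe); axial_s <- as.numeric(axial_s)
  if (length(fe) != 3 || length(axial_s) != 3 ||
      !is.matrix(pyrrole_n) || !all(dim(pyrrole_n) == c(4, 3)) ||
      any(!is.finite(c(fe, axial_s, pyrrole_n))))
    stop_input("heme geometry needs fe (3), pyrrole_n (4 x 3) and axial_s (3), all finite")
  pl <- fit_plane(pyrrole_n)
  dev <- abs((pyrrole_n - matrix(pl$centroid, 4, 3, byrow = TRUE)) %*% pl$normal)
  if (max(dev) >= 0.5)
    stop_geometry("pyrrole nitrogens deviate >= 0.5 Angstrom from a common plane")
  s_off <- sum((axial_s - pl$centroid) * pl$normal)
  if (abs(s_off) <= 1)
    stop_orientation("axial sulfur lies within 1 Angstrom of the pyrrole plane; cannot orient the distal side")
  structure(list(fe = fe, pyrrole_n = pyrrole_n, axial_s = axial_s),
            class = "heme_geometry")
}

# least-squares plane through a point cloud; normal from the smallest
# principal direction
fit_plane <- function(points) {
  centroid <- colMeans(points)
  centered <- sweep(points, 2, centroid)
  sv <- svd(centered)
  if (sv$d[2] < 1e-6 * max(sv$d[1], 1e-12))
    stop_geometry("degenerate (collinear) points: no unique plane")
  list(centroid = centroid, normal = sv$v[, 3], sv = sv$d)
}

#' Place the virtual Compound I ferryl oxygen
#'
#' The reactive (FeO) oxygen is represented by a virtual point placed
#' `fe_o_distance` above the heme iron along the distal normal of the
#' least-squares plane through the four pyrrole nitrogens, oriented away
#' from the proximal cysteine thiolate sulfur.  The default 1.65 Angstrom
#' is a typical ferryl Fe=O bond length.
#'
#' @param heme A [heme_geometry()] object, or a list with elements `fe`,
#'   `pyrrole_n` and `axial_s`.
#' @param fe_o_distance Fe to virtual-oxygen distance (Angstrom).
#' @return Numeric length-3 position of the virtual oxygen.
#' @examples
#' h <- heme_geometry(fe = c(0, 0, 0),
#'                    pyrrole_n = rbind(c(2, 0, 0), c(-2, 0, 0),
#'                                      c(0, 2, 0), c(0, -2, 0)),
#'                    axial_s = c(0, 0, -2.3))
#' build_virtual_oxygen(h)  # c(0, 0, 1.65)
#' @export
build_virtual_oxygen <- function(heme, fe_o_distance = 1.65) {
  if (!inherits(heme, "heme_geometry"))
    heme <- heme_geometry(heme$fe, heme$pyrrole_n, heme$axial_s)
  if (!is.numeric(fe_o_distance) || length(fe_o_distance) != 1L ||
      !is.finite(fe_o_distance) || fe_o_distance <= 0)
    stop_input("fe_o_distance must be a single number > 0")
  pl <- fit_plane(heme$pyrrole_n)
  n <- pl$normal
  if (sum((heme$axial_s - pl$centroid) * n) > 0) n <- -n
  as.numeric(heme$fe + fe_o_distance * n)
}

#' Distance thresholds for frame classification
#'
#' @param productive_cutoff Maximal C1 to virtual-oxygen distance for a
#'   frame to count as productive (Angstrom; default 4.5, inclusive).
#' @param selective_cutoff Minimal C4 to virtual-oxygen distance for a
#'   productive frame to count as selective (Angstrom; default 5.5,
#'   strict).
#' @param contact_cutoff Maximal heavy-atom pair distance defining a
#'   residue-ligand contact (Angstrom; default 4.0).
#' @return A `classification_thresholds` object.
#' @export
classification_thresholds <- function(productive_cutoff = 4.5,
                                      selective_cutoff = 5.5,
                                      contact_cutoff = 4.0) {
  v <- c(productive_cutoff, selective_cutoff, contact_cutoff)
  if (any(!is.finite(v)) || any(v <= 0))
    stop_input("all thresholds must be finite and > 0")
  if (selective_cutoff < productive_cutoff)
    stop_input("selective_cutoff must be >= productive_cutoff")
  structure(list(productive_cutoff = productive_cutoff,
                 selective_cutoff = selective_cutoff,
                 contact_cutoff = contact_cutoff),
            class = "classification_thresholds")
}

#' Classify a single frame as productive / selective
#'
#' A frame is *productive* when the main site of metabolism C1 lies within
#' `productive_cutoff` of the virtual ferryl oxygen (inclusive boundary,
#' matching "within"); a productive frame is *selective* when the minor
#' site C4 lies strictly more than `selective_cutoff` away (matching "more
#' than"), i.e. only C1 is exposed to hydrogen abstraction.  Selectivity is
#' undefined (`NA`) for non-productive frames.
#'
#' @param c1,c4 3D positions of the substrate C1 and C4 carbons (Angstrom).
#' @param o_virtual 3D position of the virtual oxygen, from
#'   [build_virtual_oxygen()].
#' @param thresholds A [classification_thresholds()] object.
#' @return List with `d_c1_o`, `d_c4_o`, `productive`, `selective`.
#' @export
classify_frame <- function(c1, c4, o_virtual,
                           thresholds = classification_thresholds()) {
  if (length(c1) != 3 || length(c4) != 3 || length(o_virtual) != 3 ||
      any(!is.finite(c(c1, c4, o_virtual))))
    stop_input("c1, c4 and o_virtual must be finite 3D points")
  d1 <- sqrt(sum((c1 - o_virtual)^2))
  d4 <- sqrt(sum((c4 - o_virtual)^2))
  productive <- d1 <= thresholds$productive_cutoff
  selective <- if (productive) d4 > thresholds$selective_cutoff else NA
  list(d_c1_o = d1, d_c4_o = d4, productive = productive,
       selective = selective)
}

resolve_selection <- function(traj, sel, label, n_expected) {
  idx <- tryCatch(select_atoms(traj, sel), error = function(e)
    stop_selection(sprintf("selection %s (%s) failed: %s", sQuote(label),
                           if (is.character(sel)) sel else "indices",
                           conditionMessage(e))))
  if (length(idx) != n_expected)
    stop_selection(sprintf("selection %s resolved to %d atoms, expected %d",
                           sQuote(label), length(idx), n_expected))
  idx
}

#' Scan a trajectory for productive and selective frames
#'
#' For every frame (at the given stride) the virtual Compound I oxygen is
#' rebuilt from that frame's heme coordinates and the C1/C4 distances are
#' classified with [classify_frame()].  Frame indices in the output are
#' 0-based over the trajectory as read; the stride is applied after
#' reading, before classification.
#'
#' @param traj A [cyp_trajectory()] object or a path handled by
#'   [read_trajectory()].
#' @param selections Named list of atom selections (strings or index
#'   vectors) with entries `c1`, `c4`, `fe`, `axial_s` (one atom each) and
#'   `pyrrole_n` (four atoms).
#' @param thresholds A [classification_thresholds()] object.
#' @param stride Keep every `stride`-th frame (default 1 = all frames).
#' @param fe_o_distance Fe to virtual-oxygen distance (Angstrom).
#' @return A `traj_scan` object: `$frames` data frame
#'   (`frame, d_c1_o, d_c4_o, productive, selective`) and `$summary` list
#'   (`n_total`, `n_productive`, `productive_fraction`, `n_selective`,
#'   `n_nonselective`).
#' @export
scan_trajectory <- function(traj, selections,
                            thresholds = classification_thresholds(),
                            stride = 1, fe_o_distance = 1.65) {
  if (is.character(traj)) traj <- read_trajectory(traj)
  if (!inherits(traj, "cyp_traj")) stop_input("traj must be a cyp_traj object")
  if (!is.numeric(stride) || length(stride) != 1L || stride < 1 ||
      stride != round(stride))
    stop_input("stride must be a positive integer")
  need <- c("c1", "c4", "fe", "axial_s", "pyrrole_n")
  if (!is.list(selections) || !all(need %in% names(selections)))
    stop_selection(paste("selections must name:", paste(need, collapse = ", ")))
  i_c1 <- resolve_selection(traj, selections$c1, "c1", 1)
  i_c4 <- resolve_selection(traj, selections$c4, "c4", 1)
  i_fe <- resolve_selection(traj, selections$fe, "fe", 1)
  i_s  <- resolve_selection(traj, selections$axial_s, "axial_s", 1)
  i_n  <- resolve_selection(traj, selections$pyrrole_n, "pyrrole_n", 4)

  idx <- seq.int(1L, n_frames(traj), by = as.integer(stride))
  m <- length(idx)
  d1 <- d4 <- numeric(m)
  productive <- logical(m)
  selective <- rep(NA, m)
  for (k in seq_len(m)) {
    co <- frame_coords(traj, idx[k])
    o <- build_virtual_oxygen(list(fe = co[i_fe, ],
                                   pyrrole_n = co[i_n, , drop = FALSE],
                                   axial_s = co[i_s, ]),
                              fe_o_distance = fe_o_distance)
    cl <- classify_frame(co[i_c1, ], co[i_c4, ], o, thresholds)
    d1[k] <- cl$d_c1_o
    d4[k] <- cl$d_c4_o
    productive[k] <- cl$productive
    selective[k] <- cl$selective
  }
  frames <- data.frame(frame = as.integer(idx - 1L), d_c1_o = d1, d_c4_o = d4,
                       productive = productive, selective = selective)
  summary <- list(n_total = m,
                  n_productive = sum(productive),
                  productive_fraction = if (m > 0) sum(productive) / m else NA_real_,
                  n_selective = sum(selective %in% TRUE),
                  n_nonselective = sum(selective %in% FALSE))
  structure(list(frames = frames, summary = summary,
                 thresholds = thresholds, stride = stride),
            class = "traj_scan")
}

#' @export
print.traj_scan <- function(x, ...) {
  s <- x$summary
  cat("Trajectory scan:", s$n_total, "frames (stride", x$stride, ")\n")
  cat(sprintf("  productive: %d (%.1f%%); selective: %d; non-selective: %d\n",
              s$n_productive, 100 * s$productive_fraction,
              s$n_selective, s$n_nonselective))
  invisible(x)
}

#' Histogram of C1 or C4 virtual-oxygen distances
#'
#' @param scan A `traj_scan` object from [scan_trajectory()], or its
#'   `$frames` data frame.
#' @param which Which distance to histogram: `"c1"` or `"c4"`.
#' @param bin_edges Strictly increasing vector of bin edges (Angstrom).
#' @param productive_only Restrict to frames classified productive.
#' @return Data frame `(bin_lo, bin_hi, count)`; counts sum to the number
#'   of selected frames falling inside the binned range.
#' @export
distance_histogram <- function(scan, which = c("c1", "c4"), bin_edges,
                               productive_only = FALSE) {
  which <- match.arg(which)
  frames <- if (inherits(scan, "traj_scan")) scan$frames else scan
  if (!is.data.frame(frames) || !all(c("d_c1_o", "d_c4_o", "productive")
                                     %in% names(frames)))
    stop_input("scan must be a traj_scan or its frames data frame")
  if (length(bin_edges) < 2 || any(diff(bin_edges) <= 0))
    stop_input("bin_edges must be strictly increasing with >= 2 values")
  if (productive_only) frames <- frames[frames$productive, , drop = FALSE]
  vals <- if (which == "c1") frames$d_c1_o else frames$d_c4_o
  out <- data.frame(bin_lo = bin_edges[-length(bin_edges)],
                    bin_hi = bin_edges[-1])
  if (length(vals) == 0) {
    warning("no frames selected: returning an empty histogram")
    out$count <- 0L
    return(out)
  }
  if (any(vals < bin_edges[1] | vals > bin_edges[length(bin_edges)]))
    warning("some distances fall outside the binned range and are not counted")
  bins <- cut(vals, breaks = bin_edges, include.lowest = TRUE, right = TRUE)
  out$count <- as.integer(table(bins))
  out
}

#' Per-residue ligand contact counts over productive frames
#'
#' A residue is in contact with the ligand in a frame iff the minimum
#' distance over all heavy-atom pairs (hydrogens excluded) is at most
#' `contact_cutoff`.  Counts are accumulated over masked frames only
#' (typically the productive frames from [scan_trajectory()]).
#'
#' @param traj A [cyp_trajectory()] object.
#' @param ligand_sel Atom selection for the ligand (string or indices).
#' @param residue_ids Integer vector of residue numbers to analyse.
#' @param mask Logical vector, one entry per trajectory frame; only `TRUE`
#'   frames are counted.
#' @param contact_cutoff Heavy-atom distance cutoff (Angstrom).
#' @param condition Label for the condition (used in reports and when
#'   comparing tables).
#' @return A `contact_table` object with per-residue counts and the number
#'   of frames analysed.
#' @export
contact_counts <- function(traj, ligand_sel, residue_ids, mask,
                           contact_cutoff = 4.0, condition = "condition") {
  if (!inherits(traj, "cyp_traj")) stop_input("traj must be a cyp_traj object")
  if (length(residue_ids) == 0) stop_input("residue_ids must be non-empty")
  if (length(mask) != n_frames(traj))
    stop_input("mask length must equal the number of trajectory frames")
  if (!is.numeric(contact_cutoff) || contact_cutoff < 0)
    stop_input("contact_cutoff must be >= 0")
  lig <- select_atoms(traj, ligand_sel)
  lig <- lig[traj$atoms$element[lig] != "H"]
  if (length(lig) == 0) stop_selection("ligand selection has no heavy atoms")

  keep <- which(as.logical(mask))
  counts <- integer(length(residue_ids))
  names(counts) <- as.character(residue_ids)
  for (r in seq_along(residue_ids)) {
    rid <- residue_ids[r]
    ratoms <- which(traj$atoms$resid == rid & traj$atoms$element != "H")
    ratoms <- setdiff(ratoms, lig)
    if (length(ratoms) == 0)
      stop_input(paste("unknown residue id (no heavy atoms):", rid))
    if (length(keep) == 0) next
    # per-frame minimum over all (residue atom, ligand atom) pairs,
    # vectorised over frames
    mind2 <- rep(Inf, length(keep))
    for (ra in ratoms) {
      rx <- traj$xyz[keep, 3 * ra - 2]; ry <- traj$xyz[keep, 3 * ra - 1]
      rz <- traj$xyz[keep, 3 * ra]
      for (la in lig) {
        d2 <- (rx - traj$xyz[keep, 3 * la - 2])^2 +
          (ry - traj$xyz[keep, 3 * la - 1])^2 +
          (rz - traj$xyz[keep, 3 * la])^2
        mind2 <- pmin(mind2, d2)
      }
    }
    counts[r] <- sum(mind2 <= contact_cutoff^2)
  }
  structure(list(condition = condition,
                 n_frames = length(keep),
                 counts = counts,
                 residue_ids = as.integer(residue_ids),
                 contact_cutoff = contact_cutoff),
            class = "contact_table")
}

#' @export
print.contact_table <- function(x, ...) {
  cat("Contact table (", x$condition, "): ", x$n_frames,
      " frames, cutoff ", x$contact_cutoff, " Angstrom\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Between-condition differential of contact frequencies
#'
#' Relative change of each residue's contact frequency from condition `a`
#' to condition `b`: `(freq_b - freq_a) / freq_a`.  Residues crossing
#' `major_threshold` are flagged as major losses/gains (the >= 50% change
#' criterion by default); residues with zero baseline frequency are
#' reported in a `"new-contact"` category instead of dividing by zero, and
#' residues absent from contact in both conditions are kept with category
#' `"no-contact"`.
#'
#' @param table_a,table_b `contact_table` objects built with identical
#'   residue lists and contact cutoff.
#' @param major_threshold Relative-change magnitude flagged as major
#'   (default 0.5).
#' @return A `contact_differential` data frame with columns `residue`,
#'   `freq_a`, `freq_b`, `rel_change`, `category`, `flag_major_loss`,
#'   `flag_major_gain`.
#' @export
contact_differential <- function(table_a, table_b, major_threshold = 0.5) {
  if (!inherits(table_a, "contact_table") || !inherits(table_b, "contact_table"))
    stop_input("table_a and table_b must be contact_table objects")
  if (!identical(sort(table_a$residue_ids), sort(table_b$residue_ids)))
    stop_comparability("contact tables cover different residue lists")
  if (!isTRUE(all.equal(table_a$contact_cutoff, table_b$contact_cutoff)))
    stop_comparability("contact tables were computed with different cutoffs")
  if (table_a$n_frames == 0 || table_b$n_frames == 0)
    stop_input("contact tables with zero analysed frames cannot be compared")

  ids <- table_a$residue_ids
  fa <- table_a$counts[as.character(ids)] / table_a$n_frames
  fb <- table_b$counts[as.character(ids)] / table_b$n_frames
  rel <- rep(NA_real_, length(ids))
  category <- rep("change", length(ids))
  nz <- fa > 0
  rel[nz] <- (fb[nz] - fa[nz]) / fa[nz]
  category[!nz & fb > 0] <- "new-contact"
  category[!nz & fb == 0] <- "no-contact"
  rel[!nz & fb == 0] <- 0
  out <- data.frame(residue = ids,
                    freq_a = unname(fa), freq_b = unname(fb),
                    rel_change = rel,
                    category = category,
                    flag_major_loss = !is.na(rel) & rel <= -major_threshold,
                    flag_major_gain = (!is.na(rel) & rel >= major_threshold) |
                      category == "new-contact")
  attr(out, "major_threshold") <- major_threshold
  attr(out, "conditions") <- c(a = table_a$condition, b = table_b$condition)
  class(out) <- c("contact_differential", "data.frame")
  out
}
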