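#' Read a protein backbone from a PDB file as a 3D curve
#'
#' Extracts the backbone atoms N, CA, C (or CA only) of one chain and one
#' model, in residue order, and returns them as a parameterized curve with
#' parameters t_i = i/n. Alternate locations other than ' '/'A' are dropped
#' (the reader's default); residues with missing backbone atoms contribute
#' only the atoms they have, with a warning.
#'
#' @param path path to a PDB file.
#' @param chain chain identifier; `NULL` takes the first chain in the file.
#' @param model model index for multi-model (NMR) files; default 1 = first.
#' @param residue_range optional inclusive residue-number interval,
#'   e.g. `c(12, 37)`.
#' @param atoms `"backbone"` for N, CA, C (the default) or `"ca"` for the
#'   CA trace only.
#' @return a [backbone_curve()] labelled `<file>_<chain>_m<model>`.
#' @export
read_backbone <- function(path, chain = NULL, model = 1L,
                          residue_range = NULL,
                          atoms = c("backbone", "ca")) {
  atoms <- match.arg(atoms)
  if (!file.exists(path)) stop("PDB file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  atom <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(atom) == 0L) stop("no ATOM records in ", path)

  n_models <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  model <- as.integer(model)
  if (model < 1L || model > n_models)
    stop(sprintf("model %d not present (file has %d model(s))", model, n_models))

  chains <- unique(atom$chain)
  if (is.null(chain)) chain <- chains[1L]
  if (!chain %in% chains)
    stop(sprintf("chain '%s' not found (available: %s)",
                 chain, paste(chains, collapse = ", ")))

  wanted <- if (atoms == "backbone") c("N", "CA", "C") else "CA"
  # CA-trace files (models, coarse structures) carry no N/C at all: fall
  # back to the CA trace instead of warning once per residue
  if (atoms == "backbone" &&
      !any(atom$chain == chain & atom$elety %in% c("N", "C")))
    wanted <- "CA"
  sel <- atom$chain == chain & atom$elety %in% wanted
  if (!is.null(residue_range)) {
    if (length(residue_range) != 2L || residue_range[1] > residue_range[2])
      stop("'residue_range' must be an increasing pair c(first, last)")
    sel <- sel & atom$resno >= residue_range[1] & atom$resno <= residue_range[2]
  }
  atom <- atom[sel, , drop = FALSE]
  if (nrow(atom) == 0L) stop("no usable backbone atoms after selection")

  # residue order as deposited; within a residue enforce N, CA, C order
  res_ids <- paste(atom$resno, atom$insert %||% "", sep = "_")
  res_order <- unique(res_ids)
  rank_atom <- match(atom$elety, wanted)
  ord <- order(match(res_ids, res_order), rank_atom)
  atom <- atom[ord, , drop = FALSE]

  n_complete <- length(res_order) * length(wanted)
  if (nrow(atom) < n_complete)
    warning(sprintf("%d residue(s) missing backbone atoms in %s chain %s; using atoms present",
                    n_complete - nrow(atom), basename(path), chain))

  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[model, ] else pdb$xyz
  idx <- atom$eleno
  # map eleno -> xyz triplet via the full (first-model) atom table row index
  row_of <- match(idx, pdb$atom$eleno)
  pts <- cbind(xyz[3 * (row_of - 1) + 1],
               xyz[3 * (row_of - 1) + 2],
               xyz[3 * (row_of - 1) + 3])
  if (!all(is.finite(pts))) stop("non-finite coordinates in ", path)

  n <- nrow(pts)
  label <- sprintf("%s_%s_m%d", sub("\\.(pdb|ent)$", "", basename(path)), chain, model)
  curve <- backbone_curve(pts, (1:n) / n, label)
  collapse_repeated_points(curve)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write curves as a multi-model PDB of CA pseudo-atoms
#'
#' Each curve becomes one MODEL/ENDMDL block of CA records so that geodesic
#' paths and sampled shapes render directly in molecular viewers. Coordinates
#' are written with the standard fixed-column precision (0.001).
#'
#' @param curves a [backbone_curve()] or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_curve_pdb <- function(curves, path) {
  if (inherits(curves, "backbone_curve")) curves <- list(curves)
  stopifnot(length(curves) >= 1L,
            all(vapply(curves, inherits, logical(1), "backbone_curve")))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in seq_along(curves)) {
    pts <- curves[[k]]$points
    if (max(abs(pts)) >= 10000) stop("coordinates too large for PDB columns")
    writeLines(sprintf("MODEL     %4d", k), con)
    lines <- sprintf(
      "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(nrow(pts)), seq_len(nrow(pts)), pts[, 1], pts[, 2], pts[, 3])
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
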