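#' Load a protein structure from PDB or mmCIF
#'
#' Keeps the first model only, resolves alternate locations to the highest
#' occupancy, and drops waters.
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @return An object of class `structure_model` holding an atom table
#'   (`chain`, `resno`, `resid`, `atom_name`, `element`, `x`, `y`, `z`,
#'   `occupancy`).
#' @export
load_structure <- function(path) {
  if (!file.exists(path) || file.size(path) == 0L) {
    stop("cannot read structure file '", path, "': missing or empty")
  }
  ext <- tolower(tools::file_ext(path))
  pdb <- tryCatch(
    if (ext == "cif") bio3d::read.cif(path) else
      suppressWarnings(bio3d::read.pdb(path, multi = FALSE,
                                       rm.alt = FALSE)),
    error = function(e) stop("unparseable structure file '", path, "': ",
                             conditionMessage(e)))
  at <- pdb$atom
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]
  if (is.null(at$o)) at$o <- 1
  at$o[is.na(at$o)] <- 1
  ## highest-occupancy altloc per (chain, residue, atom name)
  key <- paste(at$chain, at$resno, at$insert %||% "", at$elety, sep = "|")
  at <- at[order(key, -at$o), , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert %||% "",
                             at$elety, sep = "|")), , drop = FALSE]
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
    elem <- toupper(substr(gsub("[0-9]", "", at$elety), 1L, 1L))
  }
  atoms <- data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                      atom_name = at$elety, element = toupper(trimws(elem)),
                      x = at$x, y = at$y, z = at$z, occupancy = at$o,
                      stringsAsFactors = FALSE, row.names = NULL)
  atoms <- atoms[order(atoms$chain, atoms$resno), , drop = FALSE]
  structure(list(id = basename(path), atoms = atoms),
            class = "structure_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model '%s': %d atoms, %d chain(s), %d residues\n",
              x$id, nrow(x$atoms), length(unique(x$atoms$chain)),
              nrow(unique(x$atoms[, c("chain", "resno")]))))
  invisible(x)
}

#' Select atoms from a structure
#'
#' @param model A `structure_model` (or a bare atom table).
#' @param chain Optional chain id; default: first chain.
#' @param resno Optional residue number range (inclusive), e.g. `26:57`.
#' @param atom_name Atom name filter (default `"CA"`); `NULL` for all.
#' @return Atom table subset, ordered by residue number.
#' @export
select_atoms <- function(model, chain = NULL, resno = NULL,
                         atom_name = "CA") {
  at <- if (inherits(model, "structure_model")) model$atoms else model
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain == chain, , drop = FALSE]
  if (!is.null(resno)) at <- at[at$resno %in% resno, , drop = FALSE]
  if (!is.null(atom_name)) {
    at <- at[at$atom_name %in% atom_name, , drop = FALSE]
  }
  at[order(at$resno), , drop = FALSE]
}

## Parse a CLI-style selection "chain:first-last".
parse_selection <- function(sel) {
  m <- regmatches(sel, regexec("^([^:]+):(\\d+)-(\\d+)$", sel))[[1]]
  if (length(m) != 4L) stop("selection must look like 'A:26-57', got '",
                            sel, "'")
  list(chain = m[2], resno = as.integer(m[3]):as.integer(m[4]))
}

atom_coords <- function(at) as.matrix(at[, c("x", "y", "z")])

## Least-squares optimal rotation (Kabsch): returns the 3x3 proper
## rotation R minimizing ||Pc %*% R - Qc|| for row-vector point sets.
kabsch_rotation <- function(Pc, Qc) {
  H <- t(Pc) %*% Qc
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Superpose one structure selection onto another
#'
#' Computes the least-squares optimal rigid-body transform (Kabsch
#' algorithm) between paired atom lists — by default the C-alpha atoms of
#' the two residue ranges, matched by order — and the RMSD of the mobile
#' selection after transformation. A proper rotation (det = +1) is
#' enforced.
#'
#' @param mobile,target `structure_model`s (or atom tables).
#' @param mobile_sel,target_sel Selections as `list(chain =, resno =)` or
#'   a string `"chain:first-last"`; `NULL` selects everything.
#' @param atom_name Atom name used for pairing (default `"CA"`).
#' @return A `superposition` object: `rotation` (3x3, det +1),
#'   `translation` (length-3, Angstrom), `rmsd`, `n_atoms`, `selection`.
#'   Row-vector convention: transformed = coords %*% rotation + translation.
#' @export
superpose <- function(mobile, target, mobile_sel = NULL, target_sel = NULL,
                      atom_name = "CA") {
  get_sel <- function(model, sel) {
    if (is.character(sel)) sel <- parse_selection(sel)
    select_atoms(model, chain = sel$chain %||% NULL,
                 resno = sel$resno %||% NULL, atom_name = atom_name)
  }
  ma <- get_sel(mobile, mobile_sel %||% list())
  ta <- get_sel(target, target_sel %||% list())
  if (nrow(ma) != nrow(ta)) {
    stop("selections pair ", nrow(ma), " mobile with ", nrow(ta),
         " target atoms; they must be equal")
  }
  if (nrow(ma) < 3L) stop("need at least 3 paired atoms, got ", nrow(ma))
  P <- atom_coords(ma); Q <- atom_coords(ta)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp); Qc <- sweep(Q, 2L, cq)
  sv <- svd(Pc)$d
  if (sv[2] < 1e-8 * max(sv[1], 1)) {
    stop("degenerate (collinear) selection; rotation is not determined")
  }
  R <- kabsch_rotation(Pc, Qc)
  moved <- Pc %*% R
  rmsd <- sqrt(mean(rowSums((moved - Qc)^2)))
  structure(list(rotation = R, translation = as.numeric(cq - cp %*% R),
                 rmsd = rmsd, n_atoms = nrow(ma),
                 selection = list(mobile = mobile_sel, target = target_sel,
                                  atom_name = atom_name)),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: %d paired atoms, rmsd %.3f Angstrom\n",
              x$n_atoms, x$rmsd))
  invisible(x)
}

#' Apply a rigid transform to coordinates or a structure
#'
#' @param x A `structure_model`, atom table, or Nx3 coordinate matrix.
#' @param transform A `superposition` (or list with `rotation`,
#'   `translation`).
#' @return Object of the same shape with transformed coordinates.
#' @export
apply_transform <- function(x, transform) {
  tx <- function(m) sweep(m %*% transform$rotation, 2L,
                          transform$translation, "+")
  if (is.matrix(x)) return(tx(x))
  at <- if (inherits(x, "structure_model")) x$atoms else x
  at[, c("x", "y", "z")] <- tx(atom_coords(at))
  if (inherits(x, "structure_model")) { x$atoms <- at; x } else at
}

#' Default van der Waals radii (Angstrom)
#' @export
vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

#' Enumerate steric clashes between two atom groups
#'
#' Reports every inter-group atom pair closer than the sum of the two van
#' der Waals radii minus the tolerance, sorted by overlap depth.
#' Hydrogens are excluded by default.
#'
#' @param group_a,group_b Atom tables (see [select_atoms()]).
#' @param radii Named vector of van der Waals radii per element.
#' @param tolerance Tolerance in Angstrom subtracted from the radius sum.
#' @param include_hydrogens Keep H atoms (default `FALSE`).
#' @return A `clash_report` data frame `(atom_a, atom_b, distance, cutoff,
#'   overlap)` with attributes `tolerance` and `radii`.
#' @export
detect_clashes <- function(group_a, group_b, radii = vdw_radii,
                           tolerance = 0.4, include_hydrogens = FALSE) {
  prep <- function(at) {
    if (inherits(at, "structure_model")) at <- at$atoms
    if (!include_hydrogens) at <- at[at$element != "H", , drop = FALSE]
    at
  }
  a <- prep(group_a); b <- prep(group_b)
  empty <- structure(
    data.frame(atom_a = character(), atom_b = character(),
               distance = numeric(), cutoff = numeric(),
               overlap = numeric(), stringsAsFactors = FALSE),
    class = c("clash_report", "data.frame"),
    tolerance = tolerance, radii = radii)
  if (!nrow(a) || !nrow(b)) return(empty)
  for (at in list(a, b)) {
    unk <- setdiff(unique(at$element), names(radii))
    if (length(unk)) {
      bad <- at[at$element %in% unk, ][1L, ]
      stop("no van der Waals radius for element '", bad$element,
           "' (atom ", bad$atom_name, " of ", bad$resid, bad$resno, ")")
    }
  }
  pa <- atom_coords(a); pb <- atom_coords(b)
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * pa %*% t(pb)
  dist <- sqrt(pmax(d2, 0))
  cutoff <- outer(radii[a$element], radii[b$element], "+") - tolerance
  hit <- which(dist < cutoff, arr.ind = TRUE)
  lab <- function(at, i) sprintf("%s/%s%d/%s", at$chain[i], at$resid[i],
                                 at$resno[i], at$atom_name[i])
  out <- data.frame(atom_a = lab(a, hit[, 1]), atom_b = lab(b, hit[, 2]),
                    distance = dist[hit], cutoff = cutoff[hit],
                    overlap = cutoff[hit] - dist[hit],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$overlap), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("clash_report", "data.frame"),
            tolerance = tolerance, radii = radii)
}
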