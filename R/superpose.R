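# Kabsch least-squares rigid superposition (proper rotations only).
# Returns list(R, t, rmsd): y ~ x %*% R + t maps x onto y.
kabsch <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(nrow(x) == nrow(y), ncol(x) == 3)
  if (nrow(x) < 3) stop("need at least 3 points for superposition")
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  s <- svd(crossprod(xc, yc))
  d <- sign(det(s$u %*% t(s$v)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  t <- cy - as.vector(cx %*% R)
  fitted <- sweep(xc %*% R, 2, cy, "+")
  list(R = R, t = t, rmsd = sqrt(mean(rowSums((fitted - y)^2))))
}

#' Protomer model: C-alpha coordinates by residue number
#'
#' @param xyz m x 3 matrix of C-alpha coordinates, Angstrom.
#' @param resno integer residue numbers (unique).
#' @param chain chain identifier.
#' @param source optional source file name.
#' @return a `protomer_model` object.
#' @export
protomer_model <- function(xyz, resno, chain = "A", source = NA_character_) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, nrow(xyz) == length(resno))
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  resno <- as.integer(resno)
  if (anyDuplicated(resno)) stop("residue numbers must be unique")
  structure(list(xyz = xyz, resno = resno, chain = chain, source = source),
            class = "protomer_model")
}

#' @export
print.protomer_model <- function(x, ...) {
  cat(sprintf("Protomer model: %d C-alpha atoms, chain %s, residues %d-%d\n",
              nrow(x$xyz), x$chain, min(x$resno), max(x$resno)))
  invisible(x)
}

#' Read a protomer model (C-alpha trace) from a PDB file
#'
#' @param file PDB file path.
#' @param chain chain to extract (default: first chain in the file).
#' @return a [protomer_model()].
#' @export
read_protomer <- function(file, chain = NULL) {
  pdb <- bio3d::read.pdb(file)
  ca <- bio3d::atom.select(pdb, "calpha")
  at <- pdb$atom[ca$atom, ]
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain == chain, ]
  protomer_model(cbind(at$x, at$y, at$z), at$resno, chain = chain,
                 source = file)
}

#' Superpose a protomer model onto a reference
#'
#' Least-squares rigid superposition (Kabsch, proper rotation enforced)
#' over the C-alpha atoms of residues shared between model and reference.
#'
#' @param model,reference [protomer_model()] objects.
#' @param subset optional residue numbers restricting the fit set (the
#'   displacements are still reported for all shared residues).
#' @return the aligned model, with attributes `rotation`, `translation`
#'   and `rmsd` (Angstrom).
#' @export
superpose <- function(model, reference, subset = NULL) {
  stopifnot(inherits(model, "protomer_model"), inherits(reference, "protomer_model"))
  shared <- intersect(model$resno, reference$resno)
  if (!is.null(subset)) shared <- intersect(shared, subset)
  if (length(shared) < 3) stop("fewer than 3 shared residues")
  mi <- match(shared, model$resno)
  ri <- match(shared, reference$resno)
  fit <- kabsch(model$xyz[mi, , drop = FALSE], reference$xyz[ri, , drop = FALSE])
  out <- model
  out$xyz <- sweep(model$xyz %*% fit$R, 2, fit$t, "+")
  attr(out, "rotation") <- fit$R
  attr(out, "translation") <- fit$t
  attr(out, "rmsd") <- fit$rmsd
  out
}

#' The actin subdomain residue scheme
#'
#' Residue ranges (inclusive) defining the seven subdomain segments used
#' for displacement averaging: 7-35, 35-72, 72-147, 340-377, 147-183,
#' 272-340, 183-272. Overlapping boundary residues are kept as stated, so
#' a boundary residue contributes to two segment means.
#'
#' @return data frame with columns `name`, `start`, `end`.
#' @export
actin_subdomain_scheme <- function() {
  data.frame(
    name = c("7-35", "35-72", "72-147", "340-377", "147-183", "272-340",
             "183-272"),
    start = c(7L, 35L, 72L, 340L, 147L, 272L, 183L),
    end = c(35L, 72L, 147L, 377L, 183L, 340L, 272L),
    stringsAsFactors = FALSE)
}

#' Averaged per-subdomain C-alpha displacement vectors
#'
#' After rigid superposition of a deformed protomer onto the reference,
#' computes the displacement vector (model minus reference) of every
#' shared C-alpha and averages it within each subdomain residue range.
#'
#' @param aligned a [superpose()]d model.
#' @param reference the reference [protomer_model()].
#' @param scheme residue ranges ([actin_subdomain_scheme()] by default).
#' @return data frame: `subdomain`, `dx`, `dy`, `dz`, `magnitude`
#'   (Angstrom), `n_residues`. Ranges without shared residues get NA
#'   vectors and a zero count.
#' @export
subdomain_vectors <- function(aligned, reference, scheme = actin_subdomain_scheme()) {
  shared <- intersect(aligned$resno, reference$resno)
  mi <- match(shared, aligned$resno)
  ri <- match(shared, reference$resno)
  disp <- aligned$xyz[mi, , drop = FALSE] - reference$xyz[ri, , drop = FALSE]
  out <- lapply(seq_len(nrow(scheme)), function(q) {
    in_range <- shared >= scheme$start[q] & shared <= scheme$end[q]
    if (!any(in_range)) {
      warning("no shared residues in subdomain range ", scheme$name[q])
      return(data.frame(subdomain = scheme$name[q], dx = NA_real_,
                        dy = NA_real_, dz = NA_real_, magnitude = NA_real_,
                        n_residues = 0L))
    }
    v <- colMeans(disp[in_range, , drop = FALSE])
    data.frame(subdomain = scheme$name[q], dx = v[1], dy = v[2], dz = v[3],
               magnitude = sqrt(sum(v^2)), n_residues = sum(in_range))
  })
  do.call(rbind, out)
}
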