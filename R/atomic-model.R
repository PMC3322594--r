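#' Atomic model
#'
#' An ordered table of atom records with the fields needed for docking and
#' rasterization: atom name, residue, chain, coordinates (Angstrom),
#' occupancy and temperature factor. Stored as a data frame so standard
#' subsetting applies; coordinate round-trips through PDB files preserve
#' positions to the fixed-column precision (3 decimals) and occupancy to
#' 2 decimals.
#'
#' @param x,y,z coordinates in Angstrom.
#' @param elety atom name (PDB `elety`), recycled.
#' @param resid residue name, recycled.
#' @param chain chain identifier, recycled.
#' @param resno residue number; defaults to a sequence.
#' @param eleno atom serial number; defaults to a sequence.
#' @param o occupancy, recycled.
#' @param b temperature factor, recycled.
#' @return Object of class `atomic_model` (a data frame).
#' @export
atomic_model <- function(x, y, z, elety = "CA", resid = "ALA", chain = "A",
                         resno = NULL, eleno = NULL, o = 1, b = 0) {
  n <- length(x)
  if (length(y) != n || length(z) != n) stop("x, y, z lengths differ")
  if (n == 0) stop("empty model: no atoms")
  if (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(z)))
    stop("non-finite coordinates")
  m <- data.frame(
    eleno = if (is.null(eleno)) seq_len(n) else eleno,
    elety = rep_len(elety, n),
    resid = rep_len(resid, n),
    chain = rep_len(chain, n),
    resno = if (is.null(resno)) seq_len(n) else rep_len(resno, n),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    o = rep_len(as.numeric(o), n), b = rep_len(as.numeric(b), n),
    stringsAsFactors = FALSE)
  class(m) <- c("atomic_model", "data.frame")
  m
}

#' @export
print.atomic_model <- function(x, ...) {
  cat(sprintf("atomic_model: %d atoms, %d chain(s)\n",
              nrow(x), length(unique(x$chain))))
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("  ...\n")
  invisible(x)
}

#' Coordinates of an atomic model as a matrix
#'
#' @param model an `atomic_model` (or bead model).
#' @return n x 3 numeric matrix.
#' @export
coords <- function(model) {
  cbind(x = model$x, y = model$y, z = model$z)
}

#' Geometric centroid of a model
#' @param model an `atomic_model`.
#' @return Length-3 numeric vector.
#' @export
centroid <- function(model) colMeans(coords(model))

#' Read an atomic model from a PDB file
#'
#' Parses ATOM and HETATM records (fixed-column convention, via bio3d);
#' other record types are ignored.
#'
#' @param path PDB file.
#' @return An [atomic_model].
#' @export
read_pdb <- function(path) {
  p <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                error = function(e) stop("cannot parse PDB file '", path,
                                         "': ", conditionMessage(e)))
  a <- p$atom
  if (is.null(a) || nrow(a) == 0) stop("no ATOM/HETATM records in '", path, "'")
  chain <- ifelse(is.na(a$chain), "A", a$chain)
  m <- atomic_model(a$x, a$y, a$z, elety = a$elety, resid = a$resid,
                    chain = chain, resno = a$resno, eleno = a$eleno,
                    o = ifelse(is.na(a$o), 1, a$o),
                    b = ifelse(is.na(a$b), 0, a$b))
  m
}

#' Write an atomic model to a PDB file
#'
#' Fixed-column PDB output (via bio3d): coordinates at 3 decimals,
#' occupancy and B factor at 2 decimals in their standard columns.
#'
#' @param model an [atomic_model] or bead model.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(model, path) {
  if (inherits(model, "bead_model")) model <- as_atomic_model(model)
  stopifnot(inherits(model, "atomic_model"))
  xyz <- as.vector(t(coords(model)))
  bio3d::write.pdb(file = path, xyz = xyz, type = rep("ATOM", nrow(model)),
                   eleno = model$eleno, elety = model$elety,
                   resid = model$resid, chain = model$chain,
                   resno = model$resno, o = model$o, b = model$b)
  invisible(path)
}

#' Combine several models into one
#'
#' Concatenates atom records, reassigning serial numbers and (optionally)
#' chain identifiers per input model -- used to assemble symmetry mates into
#' a single structure.
#'
#' @param models list of [atomic_model]s.
#' @param chains optional vector of chain ids, one per model.
#' @return An [atomic_model].
#' @export
combine_models <- function(models, chains = NULL) {
  stopifnot(length(models) >= 1)
  if (!is.null(chains)) {
    stopifnot(length(chains) == length(models))
    models <- lapply(seq_along(models), function(i) {
      m <- models[[i]]; m$chain <- chains[i]; m
    })
  }
  out <- do.call(rbind, lapply(models, as.data.frame))
  out$eleno <- seq_len(nrow(out))
  class(out) <- c("atomic_model", "data.frame")
  out
}
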