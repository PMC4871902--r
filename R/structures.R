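#' Subunit coordinate models
#'
#' A `subunit_model` is the rigid unit of refinement: one chain of residues
#' with exactly one C-alpha position each, ordered by strictly increasing
#' residue number, with the first observed residue flagged as the protein
#' N-terminus. Backbone heavy atoms (N, CA, C, O) are carried along when the
#' source structure provides them, for backbone-level RMSD; all refinement
#' energetics are C-alpha based.
#'
#' @param chain_id chain identifier (single character, typically).
#' @param resno integer vector of residue numbers, strictly increasing.
#' @param resid character vector of 3-letter residue names.
#' @param xyz n x 3 matrix of C-alpha coordinates in Angstrom.
#' @param backbone optional data frame of backbone atoms with columns
#'   `resno`, `elety`, `x`, `y`, `z`.
#' @return an object of class `subunit_model`.
#' @export
subunit_model <- function(chain_id, resno, resid, xyz, backbone = NULL) {
  xyz <- as.matrix(xyz)
  stopifnot(length(resno) == length(resid), nrow(xyz) == length(resno),
            ncol(xyz) == 3)
  if (any(diff(resno) <= 0)) stop("residue numbers must be strictly increasing")
  structure(list(
    chain_id = chain_id,
    resno = as.integer(resno),
    resid = as.character(resid),
    xyz = unname(xyz),
    is_n_terminus = seq_along(resno) == 1L,
    backbone = backbone
  ), class = "subunit_model")
}

#' @export
print.subunit_model <- function(x, ...) {
  cat(sprintf("<subunit_model> chain %s: %d residues (%d-%d)%s\n",
              x$chain_id, length(x$resno), min(x$resno), max(x$resno),
              if (is.null(x$backbone)) "" else ", with backbone atoms"))
  invisible(x)
}

#' @method as_tibble subunit_model
#' @export
as_tibble.subunit_model <- function(x, ...) {
  su <- unclass(x)
  tibble::tibble(chain = su$chain_id, resno = su$resno, resid = su$resid,
                 x = su$xyz[, 1], y = su$xyz[, 2], z = su$xyz[, 3],
                 is_n_terminus = su$is_n_terminus)
}

#' C-alpha coordinates of a subunit
#' @param model a `subunit_model`.
#' @return n x 3 matrix.
#' @export
ca_xyz <- function(model) model$xyz

#' Read one chain of a PDB file as a subunit model
#'
#' Parses the file with [bio3d::read.pdb()], keeps ATOM records of the
#' requested chain (altloc A where alternates exist, waters and heteroatoms
#' ignored), and builds the C-alpha model. Residues lacking a C-alpha are
#' skipped with a warning; files using insertion codes are rejected.
#'
#' @param path PDB file.
#' @param chain chain identifier to extract.
#' @return a [subunit_model()].
#' @export
read_subunit <- function(path, chain) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT")), , drop = FALSE]
  chains <- sort(unique(at$chain))
  if (!chain %in% chains) {
    stop(sprintf("chain '%s' not found; available chains: %s",
                 chain, paste(chains, collapse = ", ")))
  }
  at <- at[at$chain == chain, , drop = FALSE]
  if (any(!is.na(at$insert) & at$insert != "")) {
    stop("insertion codes are not supported")
  }
  at <- at[is.na(at$alt) | at$alt %in% c("", "A"), , drop = FALSE]

  ca <- at[at$elety == "CA", , drop = FALSE]
  ca <- ca[order(ca$resno), , drop = FALSE]
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  if (nrow(ca) < 3) stop("need at least 3 residues with a C-alpha atom")

  all_res <- sort(unique(at$resno))
  missing_ca <- setdiff(all_res, ca$resno)
  if (length(missing_ca) > 0) {
    warning(sprintf("chain %s: skipped %d residue(s) without C-alpha: %s",
                    chain, length(missing_ca),
                    paste(missing_ca, collapse = ", ")))
  }
  bb <- at[at$elety %in% c("N", "CA", "C", "O") & at$resno %in% ca$resno, ,
           drop = FALSE]
  backbone <- data.frame(resno = bb$resno, elety = bb$elety,
                         x = bb$x, y = bb$y, z = bb$z)
  backbone <- backbone[order(backbone$resno, match(backbone$elety,
                                                   c("N", "CA", "C", "O"))), ]
  subunit_model(chain, ca$resno, ca$resid,
                cbind(ca$x, ca$y, ca$z), backbone = backbone)
}

#' Apply a rigid transform
#'
#' Moves a subunit (or every subunit of a complex) as a rigid body:
#' `x -> R x + t`. Internal geometry is preserved exactly.
#'
#' @param model a `subunit_model` or `complex_model`.
#' @param rt a [rigid_transform()].
#' @return the transformed object, same class as the input.
#' @export
apply_transform <- function(model, rt) UseMethod("apply_transform")

#' @export
apply_transform.subunit_model <- function(model, rt) {
  model$xyz <- transform_xyz(model$xyz, rt)
  if (!is.null(model$backbone)) {
    b <- transform_xyz(as.matrix(model$backbone[, c("x", "y", "z")]), rt)
    model$backbone$x <- b[, 1]; model$backbone$y <- b[, 2]; model$backbone$z <- b[, 3]
  }
  model
}

#' @export
apply_transform.complex_model <- function(model, rt) {
  model$fixed <- apply_transform(model$fixed, rt)
  model$mobile <- lapply(model$mobile, apply_transform, rt = rt)
  model
}

#' Two-subunit complex model
#'
#' Holds one fixed subunit and N rigid conformers of the mobile subunit
#' (N = 1 for a single-structure representation, N > 1 for an ensemble).
#'
#' @param fixed,mobile `subunit_model`; `mobile` may be a list of conformers.
#' @param provenance optional list (run id, seed, final energies).
#' @return an object of class `complex_model`.
#' @export
complex_model <- function(fixed, mobile, provenance = list()) {
  if (inherits(mobile, "subunit_model")) mobile <- list(mobile)
  stopifnot(inherits(fixed, "subunit_model"),
            all(vapply(mobile, inherits, TRUE, "subunit_model")))
  structure(list(fixed = fixed, mobile = mobile, provenance = provenance),
            class = "complex_model")
}

#' @export
print.complex_model <- function(x, ...) {
  cat(sprintf("<complex_model> fixed chain %s (%d res), %d mobile conformer(s) of chain %s (%d res)\n",
              x$fixed$chain_id, length(x$fixed$resno), length(x$mobile),
              x$mobile[[1]]$chain_id, length(x$mobile[[1]]$resno)))
  invisible(x)
}

kabsch <- function(P, Q) {
  # optimal proper rotation R and translation t minimizing |R P + t - Q|
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- crossprod(P - rep(cp, each = nrow(P)), Q - rep(cq, each = nrow(Q)))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cq - as.numeric(R %*% cp)
  list(R = R, t = t)
}

#' Least-squares superposition of two subunits
#'
#' Kabsch superposition over the C-alpha atoms of the residues common to both
#' models (or a supplied residue selection), returning the optimal rigid
#' transform mapping `a` onto `b` and the post-fit RMSD.
#'
#' @param a,b `subunit_model` objects.
#' @param selection optional integer vector of residue numbers to fit on.
#' @return list with elements `transform` ([rigid_transform()]) and `rmsd` (Angstrom).
#' @export
superpose <- function(a, b, selection = NULL) {
  common <- intersect(a$resno, b$resno)
  if (!is.null(selection)) common <- intersect(common, selection)
  if (length(common) < 3) stop("need at least 3 common residues to superpose")
  P <- a$xyz[match(common, a$resno), , drop = FALSE]
  Q <- b$xyz[match(common, b$resno), , drop = FALSE]
  k <- kabsch(P, Q)
  rt <- rigid_transform(mat_to_quat(k$R), k$t)
  diffs <- transform_xyz(P, rt) - Q
  list(transform = rt, rmsd = sqrt(mean(rowSums(diffs^2))))
}

backbone_coords <- function(su) {
  if (!is.null(su$backbone) && nrow(su$backbone) > 0) {
    list(key = paste(su$backbone$resno, su$backbone$elety),
         xyz = as.matrix(su$backbone[, c("x", "y", "z")]))
  } else {
    list(key = paste(su$resno, "CA"), xyz = su$xyz)
  }
}

paired_coords <- function(a, b, label) {
  ca <- backbone_coords(a); cb <- backbone_coords(b)
  common <- intersect(ca$key, cb$key)
  if (length(common) == 0) {
    stop(sprintf("no common atoms in %s; residue numbering mismatch (a: %s... b: %s...)",
                 label, ca$key[1], cb$key[1]))
  }
  if (length(common) < length(union(ca$key, cb$key))) {
    message(sprintf("%s: RMSD computed over %d common atoms", label, length(common)))
  }
  list(P = ca$xyz[match(common, ca$key), , drop = FALSE],
       Q = cb$xyz[match(common, cb$key), , drop = FALSE])
}

#' Backbone RMSD between two complex models
#'
#' Superposes `model` onto `reference` using the fixed subunit's C-alpha
#' atoms, then reports the backbone heavy-atom RMSD over the whole complex
#' (fixed plus mobile conformers, paired by index). Falls back to C-alpha-only
#' when backbone atoms are absent.
#'
#' @param model,reference `complex_model` objects with matching chains/residues.
#' @return RMSD in Angstrom.
#' @export
complex_rmsd <- function(model, reference) {
  stopifnot(length(model$mobile) == length(reference$mobile))
  fit <- superpose(model$fixed, reference$fixed)
  model <- apply_transform(model, fit$transform)
  if (is.null(model$fixed$backbone) || is.null(reference$fixed$backbone)) {
    message("backbone atoms unavailable; complex RMSD downgraded to C-alpha only")
  }
  pieces <- c(list(paired_coords(model$fixed, reference$fixed, "fixed subunit")),
              lapply(seq_along(model$mobile), function(i) {
                paired_coords(model$mobile[[i]], reference$mobile[[i]],
                              sprintf("mobile conformer %d", i))
              }))
  sq <- unlist(lapply(pieces, function(p) rowSums((p$P - p$Q)^2)))
  sqrt(mean(sq))
}

format_atom <- function(serial, elety, resid, chain, resno, xyz) {
  name <- if (nchar(elety) < 4) sprintf(" %-3s", elety) else elety
  sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
          serial %% 100000, name, resid, chain, resno,
          xyz[1], xyz[2], xyz[3], 1, 0)
}

subunit_atom_lines <- function(su, serial0) {
  lines <- character(0)
  serial <- serial0
  if (!is.null(su$backbone) && nrow(su$backbone) > 0) {
    for (i in seq_len(nrow(su$backbone))) {
      ri <- su$backbone$resno[i]
      lines <- c(lines, format_atom(serial, su$backbone$elety[i],
                                    su$resid[match(ri, su$resno)], su$chain_id,
                                    ri, c(su$backbone$x[i], su$backbone$y[i],
                                          su$backbone$z[i])))
      serial <- serial + 1
    }
  } else {
    for (i in seq_along(su$resno)) {
      lines <- c(lines, format_atom(serial, "CA", su$resid[i], su$chain_id,
                                    su$resno[i], su$xyz[i, ]))
      serial <- serial + 1
    }
  }
  list(lines = lines, serial = serial)
}

#' Write complex models as a multi-model PDB file
#'
#' Emits one MODEL/ENDMDL block per complex, with stable chain identifiers;
#' mobile conformers beyond the first get successive chain letters.
#' Coordinates round-trip through [read_subunit()] at PDB precision (0.001 A).
#'
#' @param models a `complex_model` or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_models <- function(models, path) {
  if (inherits(models, "complex_model")) models <- list(models)
  stopifnot(length(models) >= 1)
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(models)) {
    cm <- models[[m]]
    writeLines(sprintf("MODEL     %4d", m), con)
    serial <- 1
    res <- subunit_atom_lines(cm$fixed, serial)
    writeLines(res$lines, con); serial <- res$serial
    writeLines("TER", con)
    used <- cm$fixed$chain_id
    for (i in seq_along(cm$mobile)) {
      su <- cm$mobile[[i]]
      if (length(cm$mobile) > 1 || su$chain_id %in% used) {
        su$chain_id <- setdiff(LETTERS, used)[1]
      }
      used <- c(used, su$chain_id)
      res <- subunit_atom_lines(su, serial)
      writeLines(res$lines, con); serial <- res$serial
      writeLines("TER", con)
    }
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read all models of a multi-model PDB written by [write_models()]
#'
#' @param path multi-model PDB file.
#' @param fixed_chain chain id of the fixed subunit (default: first chain).
#' @return list of `complex_model` objects.
#' @export
read_models <- function(path, fixed_chain = NULL) {
  lines <- readLines(path)
  starts <- grep("^MODEL", lines)
  ends <- grep("^ENDMDL", lines)
  if (length(starts) == 0) { starts <- 1; ends <- length(lines) }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  lapply(seq_along(starts), function(m) {
    writeLines(lines[starts[m]:ends[m]], tmp)
    atom_lines <- grep("^ATOM", lines[starts[m]:ends[m]], value = TRUE)
    chains <- unique(substr(atom_lines, 22, 22))
    fc <- if (is.null(fixed_chain)) chains[1] else fixed_chain
    fixed <- read_subunit(tmp, fc)
    mobile <- lapply(setdiff(chains, fc), function(ch) read_subunit(tmp, ch))
    complex_model(fixed, mobile)
  })
}
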