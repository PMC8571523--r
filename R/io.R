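#' Write a feature trajectory as a delimited table with metadata sidecar
#'
#' The matrix goes to a tab-separated file with a header row of feature
#' labels; frame spacing and provenance go to a YAML sidecar
#' (`<file>.meta.yml`).
#'
#' @param ft a [feature_trajectory()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_features <- function(ft, file) {
  stopifnot(inherits(ft, "feature_trajectory"))
  utils::write.table(ft$mat, file, sep = "\t", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  yaml::write_yaml(c(list(dt_ns = ft$dt_ns), ft$meta),
                   paste0(file, ".meta.yml"))
  invisible(file)
}

#' Read a feature trajectory written by [write_features()]
#'
#' @param file path to the delimited table.
#' @return A [feature_trajectory()].
#' @export
read_features <- function(file) {
  mat <- as.matrix(utils::read.table(file, header = TRUE, sep = "\t",
                                     check.names = FALSE))
  meta <- yaml::read_yaml(paste0(file, ".meta.yml"))
  dt <- meta$dt_ns
  meta$dt_ns <- NULL
  feature_trajectory(mat, dt_ns = dt, labels = colnames(mat), meta = meta)
}

#' Write a discrete (microstate) trajectory with sidecar metadata
#'
#' @param labels integer state labels.
#' @param file output path.
#' @param dt_ns frame spacing (ns).
#' @param meta optional named list (e.g. seed, generator spec).
#' @return `file`, invisibly.
#' @export
write_discrete_trajectory <- function(labels, file, dt_ns = 1, meta = list()) {
  utils::write.table(data.frame(frame = seq_along(labels) - 1L,
                                state = as.integer(labels)),
                     file, sep = "\t", row.names = FALSE, quote = FALSE)
  yaml::write_yaml(c(list(dt_ns = dt_ns), meta), paste0(file, ".meta.yml"))
  invisible(file)
}

#' Read a discrete trajectory written by [write_discrete_trajectory()]
#'
#' @param file path.
#' @return Integer vector of state labels with attributes `dt_ns`, `meta`.
#' @export
read_discrete_trajectory <- function(file) {
  tab <- utils::read.table(file, header = TRUE, sep = "\t")
  meta <- yaml::read_yaml(paste0(file, ".meta.yml"))
  out <- as.integer(tab$state)
  attr(out, "dt_ns") <- meta$dt_ns
  meta$dt_ns <- NULL
  attr(out, "meta") <- meta
  out
}

#' Write a pseudo-structure (residues + ligand) as PDB records
#'
#' Serializes toy pseudo-residue coordinates and an optional ligand
#' position as PDB ATOM/HETATM records (coordinates converted nm to
#' Angstrom) so the standard structure-reader path can be exercised on
#' synthetic data. Requires the `bio3d` package.
#'
#' @param residues list of residue coordinate matrices (nm); 1- or 2-D
#'   coordinates are zero-padded to 3-D.
#' @param file output PDB path.
#' @param ligand optional ligand coordinates (atoms x d, nm), written as a
#'   residue named `LIG`.
#' @return `file`, invisibly.
#' @export
write_pseudo_pdb <- function(residues, file, ligand = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("write_pseudo_pdb requires the bio3d package")
  pad3 <- function(x) {
    if (!is.matrix(x)) x <- matrix(x, nrow = 1)
    cbind(x, matrix(0, nrow(x), 3 - ncol(x)))
  }
  coords <- do.call(rbind, lapply(residues, pad3))
  resno <- rep(seq_along(residues),
               vapply(residues, function(r) nrow(pad3(r)), integer(1)))
  resid <- rep("GLY", nrow(coords))
  if (!is.null(ligand)) {
    lig <- pad3(ligand)
    coords <- rbind(coords, lig)
    resno <- c(resno, rep(max(resno) + 1L, nrow(lig)))
    resid <- c(resid, rep("LIG", nrow(lig)))
  }
  xyz <- as.numeric(t(coords * 10))  # nm -> Angstrom
  bio3d::write.pdb(file = file, xyz = xyz, resno = resno, resid = resid,
                   elety = rep("CA", length(resno)),
                   chain = rep("A", length(resno)))
  invisible(file)
}

#' Read a reference structure and define the binding pocket
#'
#' Reads a PDB file (via `bio3d`), splits it into ligand and protein
#' residues, and defines the binding pocket as the protein atoms within
#' `pocket_cutoff` of any ligand atom in the reference pose. Coordinates
#' are returned in nm.
#'
#' @param file PDB path.
#' @param ligand_resid residue name identifying the ligand (default "LIG").
#' @param pocket_cutoff pocket definition cutoff in nm (default 0.5).
#' @return List with `ligand` (atoms x 3, nm), `residues` (list of per-
#'   residue coordinate matrices, nm), `pocket` (pocket atom coordinates),
#'   `pocket_residues` (indices of pocket residues).
#' @export
read_reference_pdb <- function(file, ligand_resid = "LIG",
                               pocket_cutoff = 0.5) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("read_reference_pdb requires the bio3d package")
  pdb <- bio3d::read.pdb(file)
  at <- pdb$atom
  is_lig <- at$resid == ligand_resid
  if (!any(is_lig)) stop(sprintf("no residue named '%s' in %s",
                                 ligand_resid, file))
  xyz <- cbind(at$x, at$y, at$z) / 10  # Angstrom -> nm
  lig <- xyz[is_lig, , drop = FALSE]
  prot <- at[!is_lig, ]
  pxyz <- xyz[!is_lig, , drop = FALSE]
  residues <- lapply(split(seq_len(nrow(prot)), prot$resno),
                     function(i) pxyz[i, , drop = FALSE])
  mind <- vapply(residues, function(rc) .min_dist(lig, rc), numeric(1))
  pocket_idx <- which(mind < pocket_cutoff)
  pocket <- do.call(rbind, residues[pocket_idx])
  list(ligand = lig, residues = residues, pocket = pocket,
       pocket_residues = pocket_idx)
}

#' Write a metadynamics hill ledger in a HILLS-style layout
#'
#' Space-delimited columns `time center* sigma* height biasf` preceded by
#' a `#! FIELDS` header line, re-readable by PLUMED-aware tooling.
#'
#' @param hills hills data.frame from [run_wtmetad()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_hills <- function(hills, file) {
  ncv <- if (all(is.na(hills$center2))) 1L else 2L
  fields <- c("time", paste0("cv", seq_len(ncv)),
              paste0("sigma_cv", seq_len(ncv)), "height", "biasf")
  # PLUMED column convention: centers then sigmas
  ord <- if (ncv == 1) c("time", "center1", "width1", "height", "bias_factor")
  else c("time", "center1", "center2", "width1", "width2", "height",
         "bias_factor")
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(fields, collapse = " ")), con)
  utils::write.table(hills[, ord], con, sep = " ", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a hill ledger written by [write_hills()]
#'
#' @param file path.
#' @return data.frame with the column layout of [run_wtmetad()] hills.
#' @export
read_hills <- function(file) {
  header <- readLines(file, n = 1)
  fields <- strsplit(sub("^#! FIELDS ", "", header), " ")[[1]]
  tab <- utils::read.table(file, skip = 1)
  ncv <- sum(grepl("^cv", fields))
  if (ncv == 1) {
    names(tab) <- c("time", "center1", "width1", "height", "bias_factor")
    tab$center2 <- NA_real_
    tab$width2 <- NA_real_
    tab <- tab[, c("time", "center1", "center2", "width1", "width2",
                   "height", "bias_factor")]
  } else {
    names(tab) <- c("time", "center1", "center2", "width1", "width2",
                    "height", "bias_factor")
  }
  tab
}
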