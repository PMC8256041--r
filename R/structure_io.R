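#' Read a protein structure in PDB format
#'
#' Parses a PDB file (single- or multi-MODEL) into a topology tibble plus the
#' first coordinate frame. Partial charges default to 0 and donor/acceptor
#' flags are unset until annotated with [read_charge_table()] /
#' [apply_charge_table()] or [infer_donors_acceptors()].
#'
#' @param path Path to a PDB file.
#' @return A list with elements
#'   \describe{
#'     \item{topology}{Tibble with one row per atom: `atom_id` (1-based file
#'       order), `serial` (PDB serial), `name`, `element`, `chain_id`,
#'       `residue_number`, `insert` (insertion code, `""` if none),
#'       `residue_name`, `partial_charge`, `is_donor_hydrogen`, `is_acceptor`.}
#'     \item{frame}{Numeric matrix `n_atoms x 3` of first-model coordinates in
#'       Angstrom.}
#'     \item{n_models}{Number of MODEL blocks found.}
#'   }
#' @seealso [read_trajectory()] to load all models as a time series.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("PDB file not found: ", path))
  }
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
    error = function(e) abort(paste0("Failed to parse PDB '", path, "': ", conditionMessage(e)))
  )
  atom <- pdb$atom
  if (is.null(atom) || nrow(atom) == 0) {
    abort(paste0("PDB file contains zero atoms: ", path))
  }
  topo <- tibble::tibble(
    atom_id = seq_len(nrow(atom)),
    serial = atom$eleno,
    name = atom$elety,
    element = guess_elements(atom$elesy, atom$elety),
    chain_id = ifelse(is.na(atom$chain), "", atom$chain),
    residue_number = atom$resno,
    insert = ifelse(is.na(atom$insert), "", atom$insert),
    residue_name = atom$resid,
    partial_charge = 0,
    is_donor_hydrogen = FALSE,
    is_acceptor = FALSE
  )
  bad <- which(!is.finite(topo$residue_number))
  if (length(bad) > 0) {
    abort(paste0("Malformed PDB coordinate line(s) for atom serial(s): ",
                 paste(topo$serial[bad], collapse = ", ")))
  }
  xyz <- pdb$xyz
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  frame0 <- matrix(xyz[1, ], ncol = 3, byrow = TRUE)
  if (any(!is.finite(frame0))) {
    abort(paste0("Non-finite coordinates in first model of ", path))
  }
  list(topology = topo, frame = frame0, n_models = nrow(xyz))
}

# Element symbols from the PDB element column, falling back to the atom name
# (leading digits stripped, first character; two-letter metals not needed for
# protein work are handled by the explicit column when present).
guess_elements <- function(elesy, elety) {
  out <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  miss <- out == ""
  if (any(miss)) {
    nm <- gsub("^[0-9']+", "", trimws(elety[miss]))
    out[miss] <- toupper(substr(nm, 1, 1))
  }
  # normalise e.g. "Cl" style capitalisation for single letters kept as-is
  out
}

#' Read a coordinate trajectory
#'
#' Loads a multi-MODEL PDB or a binary DCD file against a known topology and
#' returns an `md_trajectory`: the topology plus a frames-by-3N coordinate
#' matrix with frame times.
#'
#' Frame times are assigned `0, dt, 2*dt, ...` (ns) from `frame_interval`
#' unless `times` is supplied explicitly.
#'
#' @param topology Topology tibble from [read_structure()].
#' @param path Path to a multi-model PDB (`.pdb`) or DCD (`.dcd`) file.
#' @param frame_interval Time between saved frames in ns (default 0.02, i.e.
#'   one frame every 20 ps).
#' @param times Optional explicit frame times (ns), overriding
#'   `frame_interval`.
#' @return An object of class `md_trajectory`: list with `topology`, `xyz`
#'   (matrix `n_frames x 3*n_atoms`, Angstrom), `times` (ns).
#' @export
read_trajectory <- function(topology, path, frame_interval = 0.02, times = NULL) {
  if (!file.exists(path)) abort(paste0("Trajectory file not found: ", path))
  if (grepl("\\.dcd$", path, ignore.case = TRUE)) {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  } else {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  }
  n_atoms <- nrow(topology)
  found <- ncol(xyz) / 3
  if (found != n_atoms) {
    abort(sprintf("Trajectory atom count mismatch: topology has %d atoms, file has %g",
                  n_atoms, found))
  }
  if (is.null(times)) times <- (seq_len(nrow(xyz)) - 1) * frame_interval
  new_trajectory(topology, xyz, times)
}

#' Construct a trajectory object from in-memory parts
#'
#' @param topology Topology tibble.
#' @param xyz Coordinate matrix, `n_frames x 3*n_atoms` (Angstrom), atom-major
#'   triples `(x1, y1, z1, x2, ...)`.
#' @param times Frame times in ns, strictly increasing.
#' @return An `md_trajectory` object.
#' @export
new_trajectory <- function(topology, xyz, times) {
  if (is.vector(xyz)) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3 * nrow(topology)) {
    abort(sprintf("Coordinate count (%d) does not match topology atom count (%d)",
                  ncol(xyz) / 3, nrow(topology)))
  }
  if (length(times) != nrow(xyz)) {
    abort("One time per frame required")
  }
  if (any(!is.finite(times)) || any(times < 0)) abort("Frame times must be finite and non-negative")
  if (nrow(xyz) > 1 && any(diff(times) <= 0)) abort("Frame times must be strictly increasing")
  structure(list(topology = topology, xyz = unname(xyz), times = as.numeric(times)),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("<md_trajectory> %d atoms, %d frames, t = [%g, %g] ns\n",
              nrow(x$topology), nrow(x$xyz), min(x$times), max(x$times)))
  invisible(x)
}

#' Extract one frame's coordinates as an n_atoms x 3 matrix
#'
#' @param trajectory An `md_trajectory`.
#' @param i Frame index (1-based).
#' @return Numeric matrix `n_atoms x 3` (Angstrom).
#' @export
frame_coords <- function(trajectory, i) {
  matrix(trajectory$xyz[i, ], ncol = 3, byrow = TRUE)
}

#' Write a trajectory as a multi-MODEL PDB file
#'
#' Coordinates are written with the standard fixed-width PDB format (%8.3f),
#' so a read/write round trip preserves them to 0.001 Angstrom.
#'
#' @param trajectory An `md_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_pdb <- function(trajectory, path) {
  topo <- trajectory$topology
  con <- file(path, "w")
  on.exit(close(con))
  name4 <- ifelse(nchar(topo$name) < 4, sprintf(" %-3s", topo$name), substr(topo$name, 1, 4))
  for (f in seq_len(nrow(trajectory$xyz))) {
    co <- frame_coords(trajectory, f)
    writeLines(sprintf("MODEL     %4d", f), con)
    lines <- sprintf("ATOM  %5d %4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00          %2s",
                     topo$serial %||% topo$atom_id, name4, topo$residue_name,
                     substr(paste0(topo$chain_id, " "), 1, 1),
                     topo$residue_number, substr(paste0(topo$insert, " "), 1, 1),
                     co[, 1], co[, 2], co[, 3], topo$element)
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a partial-charge / donor-acceptor annotation table
#'
#' The TSV must carry either an `atom_id` key column or the triple
#' `chain`, `resnum`, `atom_name`, plus any of `partial_charge`,
#' `is_donor_h`, `is_acceptor`.
#'
#' @param path Path to a tab-separated annotation table.
#' @return A tibble of annotations suitable for [apply_charge_table()].
#' @export
read_charge_table <- function(path) {
  if (!file.exists(path)) abort(paste0("Charge table not found: ", path))
  tab <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  has_id <- "atom_id" %in% names(tab)
  has_key <- all(c("chain", "resnum", "atom_name") %in% names(tab))
  if (!has_id && !has_key) {
    abort("Charge table needs an 'atom_id' column or 'chain'/'resnum'/'atom_name' key columns")
  }
  tibble::as_tibble(tab)
}

#' Apply a charge/flag annotation table to a topology
#'
#' Annotates `partial_charge`, `is_donor_hydrogen` and `is_acceptor` on the
#' matching atoms. Rows whose key matches no atom produce a warning naming
#' them; duplicate keys are an error; topology atoms left unannotated are
#' reported via a warning (their charge stays 0).
#'
#' @param topology Topology tibble.
#' @param charges Annotation tibble from [read_charge_table()] (or built in
#'   code). An empty (zero-row) table leaves all charges at 0 with a warning.
#' @return The annotated topology tibble.
#' @export
apply_charge_table <- function(topology, charges) {
  if (nrow(charges) == 0) {
    warn("Empty charge table: all partial charges remain 0")
    return(topology)
  }
  if ("atom_id" %in% names(charges)) {
    key <- as.integer(charges$atom_id)
    idx <- match(key, topology$atom_id)
  } else {
    tk <- paste(topology$chain_id, topology$residue_number, topology$name, sep = "\r")
    ck <- paste(charges$chain, charges$resnum, charges$atom_name, sep = "\r")
    key <- ck
    idx <- match(ck, tk)
  }
  if (anyDuplicated(key)) {
    abort(paste0("Duplicate keys in charge table: ",
                 paste(unique(key[duplicated(key)]), collapse = ", ")))
  }
  unmatched <- which(is.na(idx))
  if (length(unmatched) > 0) {
    warn(paste0(length(unmatched), " charge-table row(s) match no atom: rows ",
                paste(head(unmatched, 10), collapse = ", ")))
    charges <- charges[-unmatched, , drop = FALSE]
    idx <- idx[-unmatched]
  }
  if ("partial_charge" %in% names(charges)) {
    q <- as.numeric(charges$partial_charge)
    if (any(abs(q) >= 5, na.rm = TRUE)) abort("Implausible |partial charge| >= 5 e in table")
    topology$partial_charge[idx] <- q
  }
  if ("is_donor_h" %in% names(charges)) {
    topology$is_donor_hydrogen[idx] <- as.logical(charges$is_donor_h)
  }
  if ("is_acceptor" %in% names(charges)) {
    topology$is_acceptor[idx] <- as.logical(charges$is_acceptor)
  }
  bad_h <- topology$is_donor_hydrogen & topology$element != "H"
  if (any(bad_h)) {
    abort(paste0("Donor-hydrogen flag on non-hydrogen atom_id(s): ",
                 paste(topology$atom_id[bad_h], collapse = ", ")))
  }
  n_un <- sum(topology$partial_charge == 0 & !topology$is_donor_hydrogen & !topology$is_acceptor)
  if (n_un > 0) {
    inform(paste0(n_un, " atom(s) remain unannotated (charge 0, no flags)"))
  }
  topology
}

#' Infer donor hydrogens and acceptors geometrically
#'
#' When no annotation table carries donor/acceptor flags, hydrogens within
#' `bond_cutoff` of an N, O or S atom in the reference frame are marked donor
#' hydrogens, and all N, O, S atoms are marked acceptors. This mirrors what a
#' CHARMM-style topology would encode but derives it from geometry alone.
#'
#' @param topology Topology tibble.
#' @param frame Reference coordinates (`n_atoms x 3`), typically frame 0.
#' @param bond_cutoff Covalent-bond distance cutoff in Angstrom (default 1.2).
#' @return Topology with `is_donor_hydrogen` / `is_acceptor` filled in.
#' @export
infer_donors_acceptors <- function(topology, frame, bond_cutoff = 1.2) {
  elems <- topology$element
  topology$is_acceptor <- elems %in% c("N", "O", "S")
  h_idx <- which(elems == "H")
  don_idx <- which(topology$is_acceptor)
  topology$is_donor_hydrogen <- FALSE
  if (length(h_idx) > 0 && length(don_idx) > 0) {
    d2 <- cross_dist2(frame[h_idx, , drop = FALSE], frame[don_idx, , drop = FALSE])
    topology$is_donor_hydrogen[h_idx] <- apply(d2, 1, min) < bond_cutoff^2
  }
  topology
}

#' Resolve a named domain selection to an atom index set
#'
#' A domain spec names a chain and an inclusive residue range (or explicit
#' residue list), e.g. the variable domain of a TCR gamma chain as residues
#' 1-119 of chain G.
#'
#' @param spec A list (or [domain_spec()]) with `name`, `chain_id`, and either
#'   `residue_range = c(start, end)` or `residues = c(...)`.
#' @param topology Topology tibble.
#' @return Integer vector of `atom_id`s in topology order.
#' @export
resolve_domain <- function(spec, topology) {
  if (!spec$chain_id %in% topology$chain_id) {
    abort(paste0("Domain '", spec$name, "': chain '", spec$chain_id,
                 "' not present in topology"))
  }
  in_chain <- topology$chain_id == spec$chain_id
  if (!is.null(spec$residues)) {
    sel <- in_chain & topology$residue_number %in% spec$residues
  } else {
    rr <- spec$residue_range
    if (is.null(rr) || length(rr) != 2 || rr[1] > rr[2]) {
      abort(paste0("Domain '", spec$name, "': invalid residue range"))
    }
    sel <- in_chain & topology$residue_number >= rr[1] & topology$residue_number <= rr[2]
  }
  ids <- topology$atom_id[sel]
  if (length(ids) == 0) {
    abort(paste0("Domain '", spec$name, "' resolves to zero atoms"))
  }
  ids
}

#' Build a domain specification
#'
#' @param name Human-readable domain name (e.g. `"Vgamma"`, `"Cbeta"`).
#' @param chain_id Chain identifier.
#' @param residue_range Inclusive `c(start, end)` residue numbers, or `NULL`.
#' @param residues Explicit residue numbers, overriding `residue_range`.
#' @return A list of class `domain_spec`.
#' @export
domain_spec <- function(name, chain_id, residue_range = NULL, residues = NULL) {
  if (is.null(residue_range) && is.null(residues)) {
    abort("domain_spec needs residue_range or residues")
  }
  structure(list(name = name, chain_id = chain_id,
                 residue_range = residue_range, residues = residues),
            class = "domain_spec")
}

# squared Euclidean cross-distance matrix between two coordinate sets
cross_dist2 <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}
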