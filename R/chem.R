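# Chemistry perception. All SMILES parsing, validity checking and
# canonicalization is delegated to OpenBabel through ChemmineOB; the
# Bemis-Murcko pruning operates on the V2000 MOL-block graph.

.strip_can <- function(x) sub("[ \t].*$", "", trimws(x))

.convert <- function(from, to, source) {
  out <- tryCatch(ChemmineOB::convertFormat(from, to, source),
                  error = function(e) "")
  if (length(out) == 0L) "" else out
}

#' Canonical SMILES
#'
#' OpenBabel canonical form of each input SMILES; `NA` for strings that do
#' not parse.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of the same length.
#' @export
canonical_smiles <- function(smiles) {
  if (length(smiles) == 0L) return(character(0))
  out <- .convert("SMI", "CAN", paste(smiles, collapse = "\n"))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == length(smiles)) {
    return(vapply(lines, .strip_can, "", USE.NAMES = FALSE))
  }
  # at least one input failed to parse: resolve one by one
  vapply(smiles, function(s) {
    o <- .convert("SMI", "CAN", s)
    o <- .strip_can(o)
    if (nzchar(o)) o else NA_character_
  }, "", USE.NAMES = FALSE)
}

#' Test whether SMILES strings are parseable molecules
#'
#' @param smiles Character vector.
#' @return Logical vector.
#' @export
is_valid_smiles <- function(smiles) {
  !is.na(canonical_smiles(smiles))
}

# Parse one V2000 MOL block into atoms (element, charge) and bonds
# (from, to, order). Bond fields read by fixed width; atom symbol by split.
.parse_molblock <- function(block) {
  lines <- strsplit(block, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  natoms <- as.integer(substr(counts, 1, 3))
  nbonds <- as.integer(substr(counts, 4, 6))
  elem <- character(natoms)
  coords <- matrix(0, natoms, 3)
  for (a in seq_len(natoms)) {
    f <- strsplit(trimws(lines[4 + a]), "[ \t]+")[[1]]
    coords[a, ] <- as.numeric(f[1:3])
    elem[a] <- f[4]
  }
  bonds <- matrix(0L, nbonds, 3)
  for (b in seq_len(nbonds)) {
    ln <- lines[4 + natoms + b]
    bonds[b, ] <- c(as.integer(substr(ln, 1, 3)),
                    as.integer(substr(ln, 4, 6)),
                    as.integer(substr(ln, 7, 9)))
  }
  charge <- integer(natoms)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "[ \t]+")[[1]])
    k <- f[1]
    for (j in seq_len(k)) charge[f[2 * j]] <- f[2 * j + 1]
  }
  list(natoms = natoms, elem = elem, coords = coords,
       bonds = bonds, charge = charge)
}

# Bonds that lie on a cycle: removing the bond leaves its endpoints connected.
.ring_bonds <- function(mol) {
  nb <- nrow(mol$bonds)
  if (nb == 0L) return(logical(0))
  adj <- vector("list", mol$natoms)
  for (b in seq_len(nb)) {
    i <- mol$bonds[b, 1]; j <- mol$bonds[b, 2]
    adj[[i]] <- c(adj[[i]], b)
    adj[[j]] <- c(adj[[j]], b)
  }
  vapply(seq_len(nb), function(b) {
    src <- mol$bonds[b, 1]; dst <- mol$bonds[b, 2]
    seen <- logical(mol$natoms)
    seen[src] <- TRUE
    queue <- src
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (bb in adj[[v]]) {
        if (bb == b) next
        w <- mol$bonds[bb, 1] + mol$bonds[bb, 2] - v
        if (!seen[w]) {
          if (w == dst) return(TRUE)
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    FALSE
  }, logical(1))
}

# Indices of atoms kept by Murcko pruning: ring atoms plus linkers, plus
# terminal atoms attached to the scaffold by a bond of order >= 2.
.murcko_atoms <- function(mol) {
  ring <- .ring_bonds(mol)
  if (!any(ring)) return(integer(0))
  ring_atom <- logical(mol$natoms)
  ring_atom[unique(as.vector(mol$bonds[ring, 1:2]))] <- TRUE
  keep <- rep(TRUE, mol$natoms)
  repeat {
    deg <- integer(mol$natoms)
    for (b in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds[b, 1]; j <- mol$bonds[b, 2]
      if (keep[i] && keep[j]) {
        deg[i] <- deg[i] + 1L
        deg[j] <- deg[j] + 1L
      }
    }
    drop <- keep & !ring_atom & deg <= 1L
    if (!any(drop)) break
    keep[drop] <- FALSE
  }
  # re-attach multiply bonded terminal atoms (exocyclic =O and kin)
  for (b in seq_len(nrow(mol$bonds))) {
    if (mol$bonds[b, 3] >= 2L) {
      i <- mol$bonds[b, 1]; j <- mol$bonds[b, 2]
      if (keep[i] && !keep[j]) keep[j] <- TRUE
      else if (keep[j] && !keep[i]) keep[i] <- TRUE
    }
  }
  which(keep)
}

# Write a V2000 MOL block for the induced subgraph on `atoms`.
.write_molblock <- function(mol, atoms) {
  idx <- match(seq_len(mol$natoms), atoms) # old -> new, NA if dropped
  bsel <- which(!is.na(idx[mol$bonds[, 1]]) & !is.na(idx[mol$bonds[, 2]]))
  header <- c("", "  scaffold", "",
              sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                      length(atoms), length(bsel)))
  atom_lines <- vapply(atoms, function(a) {
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            mol$coords[a, 1], mol$coords[a, 2], mol$coords[a, 3], mol$elem[a])
  }, "")
  bond_lines <- vapply(bsel, function(b) {
    sprintf("%3d%3d%3d  0  0  0  0",
            idx[mol$bonds[b, 1]], idx[mol$bonds[b, 2]], mol$bonds[b, 3])
  }, "")
  chg <- which(mol$charge[atoms] != 0L)
  chg_lines <- if (length(chg)) {
    sprintf("M  CHG%3d%s", length(chg),
            paste(sprintf("%4d%4d", chg, mol$charge[atoms][chg]), collapse = ""))
  } else {
    character(0)
  }
  paste(c(header, atom_lines, bond_lines, chg_lines, "M  END", "$$$$", ""),
        collapse = "\n")
}

#' Bemis-Murcko scaffold of a molecule
#'
#' The scaffold is the molecule's ring systems together with the linker
#' atoms connecting them; side chains are removed, except that terminal
#' atoms double- or triple-bonded to a scaffold atom are retained (so a
#' ring carbonyl keeps its oxygen).  Acyclic molecules have the empty
#' scaffold `""`.  Scaffold strings are OpenBabel-canonical, so two
#' molecules share a scaffold if and only if their returned strings are
#' equal.  Stereochemistry is not retained in the scaffold string.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical scaffold SMILES (`""` for acyclic
#'   molecules).
#' @examples
#' \donttest{
#' murcko_scaffold(c("CCO", "c1ccccc1CC", "c1ccccc1C"))
#' }
#' @export
murcko_scaffold <- function(smiles) {
  if (length(smiles) == 0L) return(character(0))
  sdf <- .convert("SMI", "SDF", paste(smiles, collapse = "\n"))
  blocks <- strsplit(sdf, "\\$\\$\\$\\$\n?")[[1]]
  blocks <- blocks[vapply(blocks, function(b) grepl("V2000", b), logical(1))]
  if (length(blocks) != length(smiles)) {
    if (length(smiles) == 1L) stop(sprintf(
      "murcko_scaffold: unparsable SMILES '%s'", smiles))
    return(vapply(smiles, function(s) murcko_scaffold(s), "",
                  USE.NAMES = FALSE))
  }
  scaf_blocks <- character(length(smiles))
  for (k in seq_along(blocks)) {
    mol <- .parse_molblock(blocks[[k]])
    atoms <- .murcko_atoms(mol)
    scaf_blocks[k] <- if (length(atoms)) .write_molblock(mol, atoms) else ""
  }
  out <- rep("", length(smiles))
  cyclic <- which(nzchar(scaf_blocks))
  if (length(cyclic)) {
    can <- .convert("SDF", "CAN", paste(scaf_blocks[cyclic], collapse = ""))
    lines <- strsplit(can, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(trimws(lines))]
    lines <- vapply(lines, .strip_can, "", USE.NAMES = FALSE)
    if (length(lines) != length(cyclic)) {
      stop("murcko_scaffold: scaffold canonicalization failed")
    }
    out[cyclic] <- lines[seq_along(cyclic)]
  }
  out
}
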