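#' @title Minimal V2000 molblock handling
#' @description A small parser/writer for the V2000 connection-table format,
#' used for graph computations the fingerprint backend does not expose:
#' Bemis-Murcko framework pruning, ring/charge/atom counts, and the
#' coordinates feeding the WHIM descriptors.
#' @name molblock-tools
#' @keywords internal
NULL

#' Parse a V2000 molblock
#'
#' @param block molblock text (single string or vector of lines).
#' @return list with `atoms` (data.frame: elem, x, y, z, charge) and
#'   `bonds` (data.frame: i, j, order), or `NULL` when malformed.
#' @export
parse_molblock <- function(block) {
  lines <- if (length(block) == 1L) strsplit(block, "\n", fixed = TRUE)[[1]] else block
  if (length(lines) < 4L) return(NULL)
  counts <- lines[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb) || length(lines) < 4L + na + nb) return(NULL)
  at <- lines[4L + seq_len(na)]
  atoms <- data.frame(
    elem = trimws(substr(at, 32, 34)),
    x = as.numeric(substr(at, 1, 10)),
    y = as.numeric(substr(at, 11, 20)),
    z = as.numeric(substr(at, 21, 30)),
    charge = 0L,
    stringsAsFactors = FALSE
  )
  bonds <- if (nb > 0L) {
    bl <- lines[4L + na + seq_len(nb)]
    data.frame(
      i = as.integer(substr(bl, 1, 3)),
      j = as.integer(substr(bl, 4, 6)),
      order = as.integer(substr(bl, 7, 9))
    )
  } else {
    data.frame(i = integer(0), j = integer(0), order = integer(0))
  }
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
    k <- f[1]
    if (length(f) >= 1 + 2 * k) {
      for (q in seq_len(k)) {
        atoms$charge[f[2 * q]] <- f[2 * q + 1]
      }
    }
  }
  list(atoms = atoms, bonds = bonds)
}

#' Write a V2000 molblock
#'
#' @param mol list as returned by [parse_molblock()].
#' @param title molblock title line.
#' @return single-string molblock.
#' @export
write_molblock <- function(mol, title = "") {
  a <- mol$atoms
  b <- mol$bonds
  hdr <- c(title, " cliffbench", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(a), nrow(b)))
  al <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                a$x, a$y, a$z, a$elem)
  bl <- if (nrow(b)) sprintf("%3d%3d%3d  0  0  0  0", b$i, b$j, b$order) else character(0)
  chg <- which(a$charge != 0L)
  cl <- if (length(chg)) {
    sprintf("M  CHG%3d%s", length(chg),
            paste(sprintf("%4d%4d", chg, a$charge[chg]), collapse = ""))
  } else character(0)
  paste(c(hdr, al, bl, cl, "M  END"), collapse = "\n")
}

# Degree vector of the bond graph.
.mol_degree <- function(n, bonds) {
  d <- integer(n)
  if (nrow(bonds)) {
    t1 <- tabulate(bonds$i, n)
    t2 <- tabulate(bonds$j, n)
    d <- t1 + t2
  }
  d
}

#' Bemis-Murcko framework of a molecule
#'
#' Removes side chains by iteratively pruning terminal atoms, keeping ring
#' systems and the linkers between them, plus atoms attached to the retained
#' skeleton by a double or triple bond (e.g. carbonyl oxygens on a linker).
#' Atom types are retained (non-generic framework).
#'
#' @param mol parsed molblock (list with `atoms`, `bonds`).
#' @return framework as a parsed-molblock list, or `NULL` for acyclic
#'   molecules (empty framework).
#' @export
murcko_framework <- function(mol) {
  n <- nrow(mol$atoms)
  if (!n) return(NULL)
  keep <- rep(TRUE, n)
  bonds <- mol$bonds
  repeat {
    idx <- which(keep)
    sub <- bonds[keep[bonds$i] & keep[bonds$j], , drop = FALSE]
    deg <- .mol_degree(n, sub)
    leaves <- which(keep & deg <= 1L)
    if (!length(leaves)) break
    keep[leaves] <- FALSE
    if (!any(keep)) break
  }
  if (!any(keep)) return(NULL)
  # re-attach multiply-bonded decorations of the skeleton (one shell)
  sk <- keep
  multi <- bonds$order >= 2L
  add <- unique(c(bonds$j[multi & sk[bonds$i] & !sk[bonds$j]],
                  bonds$i[multi & sk[bonds$j] & !sk[bonds$i]]))
  keep[add] <- TRUE
  idx <- which(keep)
  remap <- integer(n)
  remap[idx] <- seq_along(idx)
  b <- bonds[keep[bonds$i] & keep[bonds$j], , drop = FALSE]
  list(atoms = mol$atoms[idx, , drop = FALSE],
       bonds = data.frame(i = remap[b$i], j = remap[b$j], order = b$order))
}

# Number of smallest rings (cyclomatic number) of a parsed molblock,
# assuming a single connected component.
.mol_n_rings <- function(mol) {
  max(0L, nrow(mol$bonds) - nrow(mol$atoms) + 1L)
}
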