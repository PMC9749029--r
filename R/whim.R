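#' @title WHIM descriptors
#' @description Weighted holistic invariant molecular (WHIM) descriptors:
#' principal-axis statistics of the weighted, centred atomic coordinates of a
#' 3D conformer. Seven atomic weighting schemes are used (unit, atomic mass,
#' van der Waals volume, Sanderson electronegativity, atomic polarizability,
#' first ionization energy, Kier-Hall intrinsic state), each producing 11
#' directional descriptors (eigenvalues L1-L3, proportions P1-P2, symmetries
#' G1-G3, inverse kurtoses E1-E3), followed by the global blocks T, A
#' (per scheme), G (unit and mass), K, D and V (per scheme): 114 values.
#' @name whim-descriptors
#' @keywords internal
NULL

# Atomic property tables, relative to carbon. Mass: IUPAC relative atomic
# masses. vdW volume: (r/r_C)^3 from Bondi radii. Electronegativity:
# Sanderson scale. Polarizability: dipole polarizabilities (A^3).
# Ionization energy: first IE (eV). Unlisted elements fall back to carbon.
.whim_props <- local({
  elems <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Br", "I")
  mass <- c(1.008, 10.811, 12.011, 14.007, 15.999, 18.998, 28.086, 30.974,
            32.066, 35.453, 79.904, 126.904)
  rvdw <- c(1.20, 1.92, 1.70, 1.55, 1.52, 1.47, 2.10, 1.80, 1.80, 1.75,
            1.85, 1.98)
  sanderson <- c(2.592, 2.275, 2.746, 3.194, 3.654, 4.000, 2.138, 2.515,
                 2.957, 3.475, 3.219, 2.778)
  alpha <- c(0.667, 3.030, 1.760, 1.100, 0.802, 0.557, 5.380, 3.630, 2.900,
             2.180, 3.050, 4.700)
  ie <- c(13.598, 8.298, 11.260, 14.534, 13.618, 17.423, 8.152, 10.487,
          10.360, 12.968, 11.814, 10.451)
  ic <- match("C", elems)
  data.frame(elem = elems,
             m = mass / mass[ic],
             v = (rvdw / rvdw[ic])^3,
             e = sanderson / sanderson[ic],
             p = alpha / alpha[ic],
             i = ie / ie[ic],
             stringsAsFactors = FALSE)
})

# Principal quantum numbers for the Kier-Hall intrinsic state.
.whim_pqn <- c(H = 1, B = 2, C = 2, N = 2, O = 2, F = 2,
               Si = 3, P = 3, S = 3, Cl = 3, Br = 4, I = 5)
.whim_zval <- c(H = 1, B = 3, C = 4, N = 5, O = 6, F = 7,
                Si = 4, P = 5, S = 6, Cl = 7, Br = 7, I = 7)

# Kier-Hall intrinsic (electrotopological) state I = ((2/N)^2 dv + 1)/d,
# computed on the hydrogen-suppressed graph; hydrogens get I = 0.
.istate_weights <- function(elem, bonds) {
  n <- length(elem)
  heavy <- elem != "H"
  nH <- integer(n)
  degH <- integer(n)
  if (nrow(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      i <- bonds$i[r]; j <- bonds$j[r]
      if (heavy[i] && heavy[j]) {
        degH[i] <- degH[i] + 1L
        degH[j] <- degH[j] + 1L
      } else if (heavy[i] && !heavy[j]) {
        nH[i] <- nH[i] + 1L
      } else if (!heavy[i] && heavy[j]) {
        nH[j] <- nH[j] + 1L
      }
    }
  }
  w <- numeric(n)
  for (k in which(heavy)) {
    el <- elem[k]
    pqn <- if (el %in% names(.whim_pqn)) .whim_pqn[[el]] else 2
    zv <- if (el %in% names(.whim_zval)) .whim_zval[[el]] else 4
    dv <- zv - nH[k]
    d <- max(degH[k], 1L)
    w[k] <- ((2 / pqn)^2 * dv + 1) / d
  }
  w
}

.whim_weights <- function(elem, bonds) {
  idx <- match(elem, .whim_props$elem)
  idx[is.na(idx)] <- match("C", .whim_props$elem)
  list(
    u = rep(1, length(elem)),
    m = .whim_props$m[idx],
    v = .whim_props$v[idx],
    e = .whim_props$e[idx],
    p = .whim_props$p[idx],
    i = .whim_props$i[idx],
    s = .istate_weights(elem, bonds)
  )
}

# Directional WHIM statistics for one weighting scheme.
# Symmetry gamma: atoms with a mirror partner (score -t within tol) or on the
# axis plane form one symmetry class, every other atom its own class;
# gamma = 1 / (1 + Shannon information of the class partition).
.whim_scheme <- function(coords, w, tol = 5e-3) {
  n <- nrow(coords)
  sw <- sum(w)
  if (sw <= 0) w <- rep(1, n)
  mu <- colSums(coords * w) / sum(w)
  xc <- sweep(coords, 2, mu)
  cov <- crossprod(xc * w, xc) / sum(w)
  eg <- eigen(cov, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  scores <- xc %*% eg$vectors
  tot <- sum(lam)
  theta <- if (tot > 0) lam / tot else rep(1 / 3, 3)
  gam <- eta <- numeric(3)
  for (k in 1:3) {
    t <- scores[, k]
    if (lam[k] <= 1e-12) {
      gam[k] <- 1
      eta[k] <- 0
      next
    }
    eta[k] <- lam[k]^2 * n / sum(t^4)
    central <- abs(t) < tol
    paired <- vapply(seq_len(n), function(a) {
      central[a] || any(abs(t + t[a]) < tol & seq_len(n) != a)
    }, logical(1))
    ns <- sum(paired)
    info <- 0
    if (ns > 0) info <- info - (ns / n) * log2(ns / n)
    if (ns < n) info <- info - (n - ns) * (1 / n) * log2(1 / n)
    gam[k] <- 1 / (1 + info)
  }
  list(lam = lam, theta = theta, gam = gam, eta = eta,
       T = tot,
       A = lam[1] * lam[2] + lam[1] * lam[3] + lam[2] * lam[3],
       V = tot + lam[1] * lam[2] + lam[1] * lam[3] + lam[2] * lam[3] +
         lam[1] * lam[2] * lam[3],
       K = sum(abs(theta - 1 / 3)) / (4 / 3),
       D = sum(eta) / 3,
       G = prod(gam)^(1 / 3))
}

#' WHIM descriptors from a conformer
#'
#' @param mol parsed molblock with 3D coordinates (explicit hydrogens
#'   included), as produced by [rdkit_conformers()] + [parse_molblock()].
#' @return named numeric vector of length 114.
#' @export
whim_from_mol <- function(mol) {
  coords <- as.matrix(mol$atoms[, c("x", "y", "z")])
  ws <- .whim_weights(mol$atoms$elem, mol$bonds)
  schemes <- lapply(ws, function(w) .whim_scheme(coords, w))
  dir_names <- c("L1", "L2", "L3", "P1", "P2", "G1", "G2", "G3",
                 "E1", "E2", "E3")
  out <- numeric(0)
  nm <- character(0)
  for (s in names(schemes)) {
    b <- schemes[[s]]
    out <- c(out, b$lam, b$theta[1:2], b$gam, b$eta)
    nm <- c(nm, paste0(dir_names, s))
  }
  for (g in c("T", "A")) {
    out <- c(out, vapply(schemes, `[[`, numeric(1), g))
    nm <- c(nm, paste0(g, names(schemes)))
  }
  out <- c(out, schemes$u$G, schemes$m$G)
  nm <- c(nm, "Gu", "Gm")
  for (g in c("K", "D", "V")) {
    out <- c(out, vapply(schemes, `[[`, numeric(1), g))
    nm <- c(nm, paste0(g, names(schemes)))
  }
  names(out) <- nm
  out
}
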