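#' @title Molecular descriptor families
#' @description Four descriptor families used by the benchmark: hashed
#' extended-connectivity fingerprints (ECFP, radius 2, 1024 bits), MACCS
#' keys (166 bits), WHIM descriptors (114, from a seeded 3D conformer), and
#' 11 physicochemical drug-likeness properties.
#' @name descriptors
NULL

DESCRIPTOR_KINDS <- c("ECFP", "MACCS", "WHIM", "PHYSCHEM")

descriptor_dim <- function(kind) {
  switch(kind, ECFP = 1024L, MACCS = 166L, WHIM = 114L, PHYSCHEM = 11L,
         stop("unknown descriptor kind: ", kind))
}

descriptor_is_binary <- function(kind) kind %in% c("ECFP", "MACCS")

#' Extended-connectivity fingerprints
#'
#' @param smiles character vector of (canonical) SMILES.
#' @param radius circular-environment radius in bonds.
#' @param nbits fold length of the hashed fingerprint.
#' @return integer 0/1 matrix (molecules x bits). Rows of `NA` indicate
#'   parse failures.
#' @export
compute_ecfp <- function(smiles, radius = 2L, nbits = 1024L) {
  if (radius != 2L) {
    stop("only radius 2 (ECFP4) is supported by the fingerprint backend",
         call. = FALSE)
  }
  m <- ob_fingerprint(smiles, "ECFP4", nbits = nbits)
  colnames(m) <- paste0("ecfp", seq_len(ncol(m)))
  m
}

#' MACCS keys
#'
#' @param smiles character vector of SMILES.
#' @return integer 0/1 matrix with 166 columns.
#' @export
compute_maccs <- function(smiles) {
  m <- ob_fingerprint(smiles, "MACCS")
  colnames(m) <- paste0("maccs", seq_len(ncol(m)))
  m
}

#' WHIM descriptors
#'
#' One conformer per molecule is embedded with seeded knowledge-based
#' distance geometry and MMFF94-optimized ([rdkit_conformers()]); the 114
#' WHIM statistics are then computed from its coordinates
#' ([whim_from_mol()]). The same SMILES and seed always give the same
#' vector. Molecules that fail 3D embedding yield `NA` rows and a warning;
#' callers are expected to drop them from WHIM-based experiments only.
#'
#' @param smiles character vector of SMILES.
#' @param seed embedding seed, recorded in the result's attributes.
#' @return numeric matrix (molecules x 114) with attribute `seed`.
#' @export
compute_whim <- function(smiles, seed = 42L) {
  blocks <- rdkit_conformers(smiles, seed = seed)
  out <- matrix(NA_real_, length(smiles), 114L)
  for (k in seq_along(blocks)) {
    if (is.na(blocks[k])) next
    mol <- parse_molblock(blocks[k])
    if (is.null(mol)) next
    v <- whim_from_mol(mol)
    out[k, ] <- v
    if (k == 1L || is.null(colnames(out))) colnames(out) <- names(v)
  }
  failed <- apply(out, 1, anyNA)
  if (any(failed & !is.na(smiles))) {
    warning(sum(failed & !is.na(smiles)),
            " molecule(s) failed 3D embedding (EMBED_FAIL)")
  }
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Physicochemical drug-likeness descriptors
#'
#' The 11 properties, in order: molecular weight, predicted octanol-water
#' partition coefficient (logP), molar refractivity, topological polar
#' surface area, formal charge, hydrogen-bond donors, hydrogen-bond
#' acceptors, rotatable bonds, atoms (hydrogens included), rings, and heavy
#' atoms.
#'
#' @param smiles character vector of SMILES.
#' @return numeric matrix (molecules x 11).
#' @export
compute_physchem <- function(smiles) {
  props <- ob_properties(smiles)
  blocks <- ob_molblock(smiles, add_h = TRUE)
  n <- length(smiles)
  extra <- matrix(NA_real_, n, 4,
                  dimnames = list(NULL, c("charge", "atoms", "rings", "heavy")))
  for (k in seq_len(n)) {
    if (is.na(blocks[k])) next
    mol <- parse_molblock(blocks[k])
    if (is.null(mol)) next
    extra[k, "charge"] <- sum(mol$atoms$charge)
    extra[k, "atoms"] <- nrow(mol$atoms)
    extra[k, "rings"] <- .mol_n_rings(mol)
    extra[k, "heavy"] <- sum(mol$atoms$elem != "H")
  }
  out <- cbind(
    MW = props[, "MW"], logP = props[, "logP"], MR = props[, "MR"],
    TPSA = props[, "TPSA"], charge = extra[, "charge"],
    HBD = props[, "HBD"], HBA = props[, "HBA"], rotors = props[, "rotors"],
    atoms = extra[, "atoms"], rings = extra[, "rings"],
    heavy_atoms = extra[, "heavy"]
  )
  out
}

#' Compute a descriptor matrix of a given kind
#'
#' @param smiles character vector of SMILES.
#' @param kind one of `"ECFP"`, `"MACCS"`, `"WHIM"`, `"PHYSCHEM"`.
#' @param seed conformer seed (WHIM only).
#' @return object of class `descriptor_matrix`: the numeric matrix with
#'   attributes `kind` and `standardized`.
#' @export
descriptor_matrix <- function(smiles, kind = DESCRIPTOR_KINDS, seed = 42L) {
  kind <- match.arg(kind)
  m <- switch(kind,
              ECFP = compute_ecfp(smiles),
              MACCS = compute_maccs(smiles),
              WHIM = compute_whim(smiles, seed = seed),
              PHYSCHEM = compute_physchem(smiles))
  structure(m, kind = kind, standardized = FALSE, class = "descriptor_matrix")
}

#' Gaussian standardization with training statistics
#'
#' Standardizes real-valued descriptor matrices to zero mean and unit
#' variance using the training data mean and standard deviation, applying
#' the same transform to the test matrix. Zero-variance features map to 0 in
#' both. Binary kinds (ECFP, MACCS) are refused.
#'
#' @param train,test numeric matrices (test may be NULL).
#' @param kind descriptor kind of the matrices (binary kinds error).
#' @return list with `train` and `test` standardized matrices.
#' @export
standardize_descriptors <- function(train, test = NULL, kind = "PHYSCHEM") {
  if (descriptor_is_binary(kind)) {
    stop("KIND_ERROR: binary descriptor kinds are not standardized",
         call. = FALSE)
  }
  stopifnot(nrow(train) >= 1)
  mu <- colMeans(train)
  sigma <- apply(train, 2, stats::sd)
  if (nrow(train) == 1L) sigma[] <- 0
  zero <- !is.finite(sigma) | sigma == 0
  scale_one <- function(m) {
    z <- sweep(sweep(m, 2, mu), 2, ifelse(zero, 1, sigma), "/")
    z[, zero] <- 0
    z
  }
  list(train = scale_one(train),
       test = if (!is.null(test)) scale_one(test) else NULL)
}
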