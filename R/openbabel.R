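#' @title Open Babel backend
#' @description Thin, batch-oriented wrappers around the `obabel` executable.
#' All chemistry I/O in cliffbench (canonicalization, neutralization,
#' fingerprints, 3D embedding, additive property predictions) funnels through
#' these helpers so that a single external dependency carries the standard
#' format handling.
#' @name openbabel-backend
#' @keywords internal
NULL

.ob_cache <- new.env(parent = emptyenv())

ob_path <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p)) {
    stop("Open Babel ('obabel') was not found on the PATH; ",
         "cliffbench requires it for all structure handling.", call. = FALSE)
  }
  p
}

#' Run obabel on a batch of inputs
#'
#' @param input character vector written as the input file (one record per
#'   element, e.g. "SMILES title" lines).
#' @param args character vector of obabel arguments (input/output format
#'   flags etc.). The input and output files are appended automatically.
#' @param iext input file extension (determines the format obabel assumes).
#' @return character vector of output lines.
#' @keywords internal
ob_run <- function(input, args, iext = "smi") {
  fin <- tempfile(fileext = paste0(".", iext))
  fout <- tempfile(fileext = ".txt")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(input, fin)
  status <- suppressWarnings(
    system2(ob_path(), c(shQuote(fin), args, "-O", shQuote(fout)),
            stdout = FALSE, stderr = FALSE)
  )
  if (!file.exists(fout)) return(character(0))
  readLines(fout, warn = FALSE)
}

# Parse "SMILES\ttitle" output lines into a vector indexed by integer title.
.ob_titled <- function(lines, n) {
  out <- rep(NA_character_, n)
  if (!length(lines)) return(out)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (p in parts) {
    if (length(p) >= 2) {
      i <- suppressWarnings(as.integer(trimws(p[2])))
      if (!is.na(i)) out[i] <- trimws(p[1])
    }
  }
  out
}

#' Canonicalize (and optionally neutralize) SMILES strings
#'
#' Charged atoms that can be neutralized by adding or removing protons are
#' neutralized (+1/-1 centres); permanently charged centres such as quaternary
#' ammonium are left untouched. Strings obabel cannot parse yield `NA`.
#'
#' @param smiles character vector of SMILES strings.
#' @param neutralize neutralize +1/-1 charges before canonicalization.
#' @return character vector of canonical SMILES, `NA` where parsing failed.
#' @export
ob_canonical <- function(smiles, neutralize = TRUE) {
  n <- length(smiles)
  if (!n) return(character(0))
  ok <- !is.na(smiles) & nzchar(trimws(smiles))
  out <- rep(NA_character_, n)
  if (!any(ok)) return(out)
  idx <- which(ok)
  lines <- paste(trimws(smiles[idx]), idx)
  args <- c("-ocan")
  if (neutralize) args <- c(args, "--neutralize")
  res <- .ob_titled(ob_run(lines, args), n)
  res
}

.hex_to_bits <- function(h) {
  nib <- strtoi(strsplit(gsub("[^0-9a-fA-F]", "", h), "", fixed = FALSE)[[1]], 16L)
  as.integer(unlist(lapply(nib, function(x) as.integer(intToBits(x))[4:1])))
}

# Parse obabel's -ofpt hex dump into a bit matrix (rows in input order).
.parse_fpt <- function(lines, n, nbits) {
  mat <- matrix(NA_integer_, nrow = n, ncol = nbits)
  if (!length(lines)) return(mat)
  hdr <- grepl("^>", lines)
  grp <- cumsum(hdr)
  titles <- sub("^>\\s*([^ ]+).*$", "\\1", lines[hdr])
  for (g in seq_along(titles)) {
    i <- suppressWarnings(as.integer(titles[g]))
    if (is.na(i)) next
    body <- lines[!hdr & grp == g]
    body <- body[grepl("^[0-9a-fA-F ]+$", body)]  # drop commentary lines
    if (!length(body)) next
    bits <- .hex_to_bits(paste(body, collapse = ""))
    if (length(bits) >= nbits) mat[i, ] <- bits[seq_len(nbits)]
  }
  mat
}

#' Compute hashed fingerprints for a batch of molecules
#'
#' @param smiles character vector of SMILES (or molblock text via `sdf`).
#' @param type one of "ECFP4" (extended-connectivity, radius 2) or "MACCS".
#' @param nbits fold length for hashed types; fixed at 166 keys for MACCS.
#' @param sdf optional character vector of V2000 molblocks (each ending in
#'   `$$$$`) used instead of `smiles`; titles must be integer indices.
#' @return integer 0/1 matrix, one row per input, `NA` rows where parsing
#'   failed.
#' @export
ob_fingerprint <- function(smiles = NULL, type = c("ECFP4", "MACCS"),
                           nbits = 1024L, sdf = NULL) {
  type <- match.arg(type)
  raw_bits <- if (type == "MACCS") 256L else as.integer(nbits)
  if (is.null(sdf)) {
    n <- length(smiles)
    if (!n) return(matrix(integer(0), 0, if (type == "MACCS") 166L else nbits))
    ok <- !is.na(smiles) & nzchar(smiles)
    lines <- paste(smiles[ok], which(ok))
    args <- c("-ofpt", paste0("-xf", type), "-xh")
    if (type != "MACCS") args <- c(args, "-xN", as.character(raw_bits))
    out <- ob_run(lines, args)
  } else {
    n <- length(sdf)
    args <- c("-ofpt", paste0("-xf", type), "-xh")
    if (type != "MACCS") args <- c(args, "-xN", as.character(raw_bits))
    out <- ob_run(unlist(strsplit(paste(sdf, collapse = "\n"), "\n")),
                  args, iext = "sdf")
  }
  mat <- .parse_fpt(out, n, raw_bits)
  if (type == "MACCS") mat <- mat[, seq_len(166L), drop = FALSE]
  mat
}

#' Topology-only molblocks for a batch of SMILES
#'
#' Converts SMILES to V2000 molblocks without generating coordinates,
#' optionally with explicit hydrogens. Used for graph-based computations
#' (framework pruning, ring and atom counts).
#'
#' @param smiles character vector of SMILES.
#' @param add_h add explicit hydrogens.
#' @return character vector of molblocks, `NA` where parsing failed.
#' @export
ob_molblock <- function(smiles, add_h = FALSE) {
  n <- length(smiles)
  if (!n) return(character(0))
  ok <- !is.na(smiles) & nzchar(smiles)
  out <- rep(NA_character_, n)
  if (!any(ok)) return(out)
  lines <- paste(smiles[ok], which(ok))
  args <- c("-osdf")
  if (add_h) args <- c(args, "-h")
  res <- ob_run(lines, args)
  if (!length(res)) return(out)
  ends <- which(res == "$$$$")
  start <- 1L
  for (e in ends) {
    block <- res[start:(e - 1L)]
    i <- suppressWarnings(as.integer(trimws(block[1])))
    if (!is.na(i)) out[i] <- paste(block, collapse = "\n")
    start <- e + 1L
  }
  out
}

#' Additive property predictions from Open Babel
#'
#' Returns the obabel-predicted molecular weight, logP, molar refractivity,
#' topological polar surface area, hydrogen-bond donor and acceptor counts
#' and rotatable-bond count for each input.
#'
#' @param smiles character vector of SMILES.
#' @return numeric matrix with columns MW, logP, MR, TPSA, HBD, HBA, rotors.
#' @export
ob_properties <- function(smiles) {
  cols <- c("MW", "logP", "MR", "TPSA", "HBD", "HBA", "rotors")
  n <- length(smiles)
  mat <- matrix(NA_real_, n, length(cols), dimnames = list(NULL, cols))
  if (!n) return(mat)
  ok <- !is.na(smiles) & nzchar(smiles)
  if (!any(ok)) return(mat)
  lines <- paste(smiles[ok], which(ok))
  res <- ob_run(lines, c("-osmi", "--append", "MW logP MR TPSA HBD HBA1 rotors"))
  if (!length(res)) return(mat)
  for (ln in res) {
    f <- strsplit(ln, "[ \t]+")[[1]]
    # SMILES, title, then the 7 appended values
    if (length(f) < 9) next
    i <- suppressWarnings(as.integer(f[2]))
    if (is.na(i)) next
    vals <- suppressWarnings(as.numeric(f[3:9]))
    mat[i, ] <- vals
  }
  mat
}
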