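#' Seeded 3D conformer generation
#'
#' Embeds one minimum-energy conformer per molecule with experimental-torsion
#' knowledge distance geometry (ETKDG) followed by MMFF94 force-field
#' optimization, via the RDKit toolkit driven through a batched `python`
#' subprocess. The embedding is fully reproducible: the same SMILES and seed
#' always give the same coordinates.
#'
#' @param smiles character vector of SMILES strings.
#' @param seed integer random seed for the distance-geometry embedding.
#' @return character vector of V2000 molblocks (explicit hydrogens,
#'   optimized 3D coordinates); `NA` for molecules that fail to parse or
#'   embed.
#' @export
rdkit_conformers <- function(smiles, seed = 42L) {
  n <- length(smiles)
  if (!n) return(character(0))
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) {
    stop("No 'python' executable with RDKit found on the PATH; ",
         "3D descriptors require it.", call. = FALSE)
  }
  fin <- tempfile(fileext = ".smi")
  fout <- tempfile(fileext = ".sdf")
  fscript <- tempfile(fileext = ".py")
  on.exit(unlink(c(fin, fout, fscript)), add = TRUE)
  ok <- !is.na(smiles) & nzchar(smiles)
  writeLines(paste(smiles[which(ok)], which(ok)), fin)
  writeLines(c(
    "import sys",
    "from rdkit import Chem",
    "from rdkit.Chem import AllChem",
    "from rdkit import RDLogger",
    "RDLogger.DisableLog('rdApp.*')",
    sprintf("seed = %d", as.integer(seed)),
    sprintf("out = open(%s, 'w')", deparse(fout)),
    sprintf("fh = open(%s)", deparse(fin)),
    "for line in fh:",
    "    parts = line.split()",
    "    if len(parts) < 2: continue",
    "    smi, title = parts[0], parts[1]",
    "    m = Chem.MolFromSmiles(smi)",
    "    if m is None: continue",
    "    m = Chem.AddHs(m)",
    "    p = AllChem.ETKDGv3()",
    "    p.randomSeed = seed",
    "    if AllChem.EmbedMolecule(m, p) != 0: continue",
    "    try:",
    "        AllChem.MMFFOptimizeMolecule(m)",
    "    except Exception:",
    "        pass",
    "    m.SetProp('_Name', title)",
    "    out.write(Chem.MolToMolBlock(m))",
    "    out.write('$$$$\\n')",
    "out.close()"
  ), fscript)
  status <- suppressWarnings(system2(py, shQuote(fscript),
                                     stdout = FALSE, stderr = FALSE))
  out <- rep(NA_character_, n)
  if (status != 0 || !file.exists(fout)) {
    warning("conformer generation subprocess failed for all molecules")
    return(out)
  }
  res <- readLines(fout, warn = FALSE)
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
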