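#' @title Synthetic congeneric-series datasets
#' @description Seeded generator of raw bioactivity tables with known ground
#' truth, emulating the statistical structure of curated target datasets:
#' congeneric scaffold families built by enumerative decoration of template
#' SMILES, planted activity cliffs (large within-family potency gaps),
#' replicate annotations, Dixon-detectable outliers, over-dispersed
#' replicate sets, invalid-flag rows, and stereo-duplicate records. Every
#' injected artifact is recorded so curation and cliff detection can be
#' checked exactly.
#' @name fixtures
NULL

# Decoration templates. Substituents replace "%s" slots; they are acyclic
# side chains, so all members of a family share one Bemis-Murcko framework
# (scaffold similarity 1.0 within a family) while frameworks differ across
# families. Chosen to be structurally heterogeneous enough that
# cross-family similarities stay clearly below the 0.9 cliff threshold.
.fixture_templates <- list(
  benzamide = function(a, b) sprintf("O=C(NCc1ccc(%s)cc1)c1ccc(%s)cc1", a, b),
  ether_pyridine = function(a, b) sprintf("%sc1ccnc(OCCN(C)Cc2ccc(%s)cc2)c1", a, b),
  quinoline = function(a, b) sprintf("%sc1ccc2nc(N%s)ccc2c1", a, b),
  piperidine = function(a, b) sprintf("O=S(=O)(N1CCC(%s)CC1)c1cc(%s)sc1", a, b),
  indole = function(a, b) sprintf("%sc1ccc2[nH]c(C(=O)N(C)C%s)cc2c1", a, b)
)

.fixture_subs <- c("F", "Cl", "Br", "I", "C", "CC", "C(C)C", "CCC", "OC",
                   "OCC", "N", "O", "C(F)(F)F", "CN", "CO", "CCN")

#' Fixture specification
#'
#' @param n_scaffolds number of scaffold families (max 5 templates).
#' @param analogs_per_scaffold decorated analogs per family.
#' @param cliff_pair_fraction fraction of molecules participating in a
#'   planted cliff pair (each pair consumes two molecules of one family).
#' @param replicate_rate fraction of molecules annotated in triplicate.
#' @param outlier_rate fraction of molecules whose replicate set contains
#'   one Dixon-detectable outlier (forces the molecule into triplicate).
#' @param invalid_rate fraction of additional rows carrying a data-validity
#'   flag.
#' @param stereo_dup_rate fraction of molecules duplicated as an
#'   enantiomeric SMILES pair (both members removed by curation).
#' @param sd_reject_rate fraction of additional molecules whose replicates
#'   disperse beyond the 1-log SD cutoff.
#' @param activity_base_p centre of the p-activity distribution.
#' @param cliff_gap_log planted potency gap in log10 units (>= 1 guarantees
#'   the ten-fold criterion).
#' @param noise_sd_log standard deviation of the per-molecule activity
#'   noise (log10 units).
#' @param seed integer seed.
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_scaffolds = 5L, analogs_per_scaffold = 20L,
                         cliff_pair_fraction = 0.2, replicate_rate = 0.2,
                         outlier_rate = 0.05, invalid_rate = 0.05,
                         stereo_dup_rate = 0.05, sd_reject_rate = 0.0,
                         activity_base_p = 7.0, cliff_gap_log = 2.0,
                         noise_sd_log = 0.2, seed = 1L) {
  rates <- c(cliff_pair_fraction, replicate_rate, outlier_rate,
             invalid_rate, stereo_dup_rate, sd_reject_rate)
  if (any(rates < 0 | rates > 1)) stop("SPEC_INVALID: rates must be in [0,1]")
  if (cliff_gap_log < 1) stop("SPEC_INVALID: cliff_gap_log must be >= 1 ",
                              "to guarantee the ten-fold criterion")
  if (n_scaffolds < 1 || n_scaffolds > length(.fixture_templates)) {
    stop("SPEC_INVALID: n_scaffolds must be in 1..",
         length(.fixture_templates))
  }
  structure(as.list(environment())[names(formals(fixture_spec))],
            class = "fixture_spec")
}

# Enumerate analogs of one family: deterministic sweep over substituent
# combinations. Combos whose decorated molecules collapse to an already
# seen canonical structure - or to an already seen folded ECFP, which the
# curation stage would treat as a stereo-inconsistent duplicate - are
# skipped, so clean family members are guaranteed to survive curation.
.family_smiles <- function(template, n) {
  subs <- .fixture_subs
  combos <- expand.grid(a = subs, b = subs, stringsAsFactors = FALSE)
  stopifnot(n <= nrow(combos) - 20L)
  smi <- vapply(seq_len(nrow(combos)),
                function(i) template(combos$a[i], combos$b[i]), character(1))
  can <- ob_canonical(smi)
  keep <- !is.na(can) & !duplicated(can)
  smi <- smi[keep]
  fp <- compute_ecfp(ob_canonical(smi))
  fpkey <- apply(fp, 1, paste, collapse = "")
  smi <- smi[!duplicated(fpkey)]
  stopifnot(n <= length(smi))
  smi[seq_len(n)]
}

#' Generate a congeneric-series raw table with ground truth
#'
#' @param spec a [fixture_spec()].
#' @return list of class `fixture_dataset`: `raw` (data.frame: smiles,
#'   activity_nM, validity_flag), `truth` (list: per-molecule table with
#'   family, role and true activity; expected cliff pairs as canonical
#'   SMILES pairs; injected artifact records).
#' @export
generate_congeneric_dataset <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    fams <- names(.fixture_templates)[seq_len(spec$n_scaffolds)]
    mol <- do.call(rbind, lapply(seq_along(fams), function(fi) {
      smi <- .family_smiles(.fixture_templates[[fams[fi]]],
                            spec$analogs_per_scaffold)
      data.frame(smiles = smi, family = fams[fi],
                 stringsAsFactors = FALSE)
    }))
    n <- nrow(mol)
    mol$p_true <- spec$activity_base_p +
      0.3 * (match(mol$family, fams) - (length(fams) + 1) / 2) +
      stats::rnorm(n, 0, spec$noise_sd_log)

    # plant cliff pairs: disjoint within-family pairs get a gap of
    # cliff_gap_log between their members
    n_pairs <- floor(spec$cliff_pair_fraction * n / 2)
    planted <- matrix(integer(0), 0, 2)
    if (n_pairs > 0) {
      avail <- split(seq_len(n), mol$family)
      pool <- unlist(lapply(avail, function(ix) {
        ix <- ix[sample.int(length(ix))]
        if (length(ix) >= 2) ix[seq_len(2 * floor(length(ix) / 2))]
        else integer(0)
      }), use.names = FALSE)
      n_pairs <- min(n_pairs, floor(length(pool) / 2))
      if (n_pairs > 0) {
        sel <- pool[seq_len(2 * n_pairs)]
        planted <- matrix(sel, ncol = 2, byrow = TRUE)
        hi <- planted[, 1]
        lo <- planted[, 2]
        mol$p_true[lo] <- mol$p_true[hi] - spec$cliff_gap_log
      }
    }
    mol$activity_nM <- nM_from_p(mol$p_true)

    # roles
    mol$role <- "clean"
    rep_extra <- integer(0)
    n_out <- floor(spec$outlier_rate * n)
    n_rep <- max(floor(spec$replicate_rate * n), n_out)
    rep_idx <- sample.int(n, n_rep)
    out_idx <- rep_idx[seq_len(n_out)]
    mol$role[rep_idx] <- "replicate"
    mol$role[out_idx] <- "outlier"

    rows <- data.frame(smiles = mol$smiles,
                       activity_nM = mol$activity_nM,
                       validity_flag = "", stringsAsFactors = FALSE)
    add <- function(rows, smiles, act, flag = "") {
      rbind(rows, data.frame(smiles = smiles, activity_nM = act,
                             validity_flag = flag, stringsAsFactors = FALSE))
    }
    # triplicate annotations; outlier molecules get one wild value that
    # Dixon's Q flags (n = 3, two identical values, Q = 1 > 0.970)
    for (i in rep_idx) {
      rows <- add(rows, mol$smiles[i], mol$activity_nM[i])
      third <- if (i %in% out_idx) mol$activity_nM[i] * 10^3 else
        mol$activity_nM[i]
      rows <- add(rows, mol$smiles[i], third)
    }

    # over-dispersed molecules: two replicates 4 logs apart -> REJECT_SD
    n_sd <- floor(spec$sd_reject_rate * n)
    sd_smiles <- character(0)
    if (n_sd > 0) {
      base <- .family_smiles(.fixture_templates[[fams[1]]],
                             spec$analogs_per_scaffold + n_sd)
      sd_smiles <- utils::tail(base, n_sd)
      for (s in sd_smiles) {
        act <- nM_from_p(spec$activity_base_p)
        rows <- add(rows, s, act * 1e-2)
        rows <- add(rows, s, act * 1e2)
      }
    }

    # invalid-flag rows: extra decorated molecules, flagged
    n_inv <- floor(spec$invalid_rate * n)
    inv_smiles <- character(0)
    if (n_inv > 0) {
      base <- .family_smiles(.fixture_templates[[fams[length(fams)]]],
                             spec$analogs_per_scaffold + n_sd + n_inv)
      inv_smiles <- utils::tail(base, n_inv)
      for (s in inv_smiles) {
        rows <- add(rows, s, nM_from_p(spec$activity_base_p),
                    flag = "Potential author error")
      }
    }

    # stereo duplicates: an enantiomeric pair of SMILES with a chiral side
    # chain; canonical forms differ, achiral ECFPs coincide -> both removed
    n_st <- floor(spec$stereo_dup_rate * n)
    st_smiles <- character(0)
    if (n_st > 0) {
      for (q in seq_len(n_st)) {
        sub <- .fixture_subs[1 + (q - 1) %% length(.fixture_subs)]
        tpl <- .fixture_templates[[fams[1 + q %% length(fams)]]]
        pair <- c(tpl(sprintf("C(O)(%s)[C@H](N)C", sub), "F"),
                  tpl(sprintf("C(O)(%s)[C@@H](N)C", sub), "F"))
        act <- nM_from_p(spec$activity_base_p)
        rows <- add(rows, pair[1], act)
        rows <- add(rows, pair[2], act)
        st_smiles <- c(st_smiles, pair)
      }
    }

    # exact expected cliff-pair set: same family and >= 10-fold gap
    # (index pairs into the clean molecule table)
    expected <- list()
    for (fi in fams) {
      ix <- which(mol$family == fi)
      if (length(ix) < 2) next
      cmb <- utils::combn(ix, 2)
      gap <- abs(mol$p_true[cmb[1, ]] - mol$p_true[cmb[2, ]])
      keep <- gap >= log10(10) - 1e-12
      if (any(keep)) {
        expected[[fi]] <- cbind(cmb[1, keep], cmb[2, keep])
      }
    }
    expected <- if (length(expected)) do.call(rbind, expected) else
      matrix(integer(0), 0, 2)

    truth <- list(
      molecules = mol,
      planted_pairs = planted,
      expected_cliff_pairs = expected,
      expected_cliff_smiles = cbind(mol$smiles[expected[, 1]],
                                    mol$smiles[expected[, 2]]),
      invalid_smiles = inv_smiles,
      sd_reject_smiles = sd_smiles,
      stereo_dup_smiles = st_smiles,
      outlier_smiles = mol$smiles[out_idx]
    )
    structure(list(raw = rows, truth = truth, spec = spec),
              class = "fixture_dataset")
  })
}

#' Synthetic response surface over descriptor matrices
#'
#' Draws sparse linear weights plus a single multiplicative interaction
#' over the descriptor columns, producing synthetic p-activities used for
#' model-recovery tests; returns the generating weights so the irreducible
#' error is known.
#'
#' @param x_train,x_test numeric descriptor matrices.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param n_active number of active (non-zero-weight) columns; 0 gives a
#'   pure-noise response.
#' @param interaction_strength coefficient of the single multiplicative
#'   interaction; 0 gives a purely linear response.
#' @param seed integer seed.
#' @return list: `y_train`, `y_test`, `weights`, `interaction` (column
#'   pair or NULL), `noise_sd`.
#' @export
generate_response_surface <- function(x_train, x_test = NULL, noise_sd = 0.3,
                                      n_active = NULL,
                                      interaction_strength = 0.5,
                                      seed = 1L) {
  p <- ncol(x_train)
  if (is.null(n_active)) n_active <- min(p, 10L)
  with_seed(seed, {
    w <- numeric(p)
    active <- if (n_active > 0) sample.int(p, n_active) else integer(0)
    if (n_active > 0) w[active] <- stats::rnorm(n_active) / sqrt(n_active)
    ia <- if (interaction_strength != 0 && length(active) >= 2L) {
      sort(sample(active, 2L))
    } else NULL
    f <- function(x) {
      out <- as.numeric(x %*% w)
      if (!is.null(ia)) {
        out <- out + interaction_strength * x[, ia[1]] * x[, ia[2]]
      }
      out
    }
    y_train <- f(x_train) + stats::rnorm(nrow(x_train), 0, noise_sd)
    y_test <- if (!is.null(x_test)) {
      f(x_test) + stats::rnorm(nrow(x_test), 0, noise_sd)
    } else NULL
  })
  list(y_train = y_train, y_test = y_test, weights = w, interaction = ia,
       noise_sd = noise_sd)
}
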