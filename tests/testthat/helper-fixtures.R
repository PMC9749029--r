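# Shared fixtures, generated once per test run and memoised: several tests
# reuse the same curated dataset, and fingerprinting it repeatedly would
# dominate the suite's runtime.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# A small mixed fixture with every artifact type planted.
dirty_fixture <- function() {
  cached("dirty", {
    spec <- fixture_spec(n_scaffolds = 3, analogs_per_scaffold = 12,
                         cliff_pair_fraction = 0.2, replicate_rate = 0.2,
                         outlier_rate = 0.08, invalid_rate = 0.05,
                         stereo_dup_rate = 0.05, sd_reject_rate = 0.05,
                         noise_sd_log = 0.2, seed = 7)
    fx <- generate_congeneric_dataset(spec)
    fx$curated <- curate_dataset(fx$raw)
    fx$clean_canonical <- ob_canonical(fx$truth$molecules$smiles)
    fx
  })
}

# Clean noise-free fixture: detection ground truth is exact.
clean_fixture <- function() {
  cached("clean", {
    spec <- fixture_spec(n_scaffolds = 4, analogs_per_scaffold = 10,
                         cliff_pair_fraction = 0.3, replicate_rate = 0,
                         outlier_rate = 0, invalid_rate = 0,
                         stereo_dup_rate = 0, noise_sd_log = 0, seed = 11)
    fx <- generate_congeneric_dataset(spec)
    fx$curated <- curate_dataset(fx$raw)
    fx
  })
}

# Engineered cliff-rich fixture with a spectral split, for model tests.
cliff_model_fixture <- function() {
  cached("cliffmodel", {
    spec <- fixture_spec(n_scaffolds = 4, analogs_per_scaffold = 24,
                         cliff_pair_fraction = 0.5, replicate_rate = 0,
                         outlier_rate = 0, invalid_rate = 0,
                         stereo_dup_rate = 0, noise_sd_log = 0.1, seed = 9)
    fx <- generate_congeneric_dataset(spec)
    cur <- curate_dataset(fx$raw)
    pairs <- find_cliff_pairs(cur$data)
    ann <- annotate_cliffs(cur$data, pairs)
    cfg <- split_config(n_clusters = 4, seed = 5)
    asg <- split_dataset(cur$data, ann$is_cliff, cfg)
    list(fx = fx, data = cur$data, pairs = pairs, ann = ann, asg = asg,
         fp = compute_ecfp(cur$data$smiles))
  })
}

canonical_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
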