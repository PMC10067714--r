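# Shared fixtures: built in code, no files on disk.

ref_model <- function() gu_model(A = 2000, B = 60, C = 0.8)

# A constant-count series without randomness.
flat_series <- function(count, n_bins, bin_width = 1,
                        run_kind = "background", t_origin = NULL) {
  photon_series(rep(count, n_bins), bin_width = bin_width,
                run_kind = run_kind, t_origin = t_origin)
}

# Noise-free DL series: rounded exact expected counts.
noise_free_dl <- function(model = ref_model(), offset = 5, duration = 300) {
  mu <- expected_dl_bin_counts(model, offset, duration, 1)
  photon_series(round(mu), run_kind = "dl")
}

# Random valid Gu model spanning roughly a decade per parameter.
random_model <- function() {
  gu_model(A = exp(runif(1, log(500), log(5000))),
           B = exp(runif(1, log(20), log(200))),
           C = exp(runif(1, log(0.3), log(3))))
}

# Minimal protocol-conforming sample record with flat runs.
tiny_record <- function(sample_id = "s1", thickness = 0.3,
                        spe_bins = 600, dl_bins = 300, n_dl = 3) {
  sample_record(
    sample_id, species = "motherwort", group = "CG", stage = 1,
    fresh_mass = 1, thickness = thickness,
    spe_run = flat_series(12, spe_bins, run_kind = "spe"),
    dl_runs = lapply(seq_len(n_dl), function(i)
      flat_series(12, dl_bins, run_kind = "dl")),
    background_pre = flat_series(5, 600),
    background_post = flat_series(5, 600)
  )
}
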