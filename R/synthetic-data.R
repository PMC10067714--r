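#' Simulate a constant-rate photon run
#'
#' Independent Poisson(rate x bin_width) counts per bin: the model for
#' instrument background and for steady-state spontaneous emission.
#'
#' @param rate Mean rate in counts/s (>= 0).
#' @param duration Run duration in seconds.
#' @param bin_width Bin width in seconds.
#' @param seed Optional integer seed for reproducibility.
#' @param run_kind `"background"` (default) or `"spe"`.
#' @return A [photon_series()].
#' @export
simulate_constant_run <- function(rate, duration = 600, bin_width = 1,
                                  seed = NULL, run_kind = c("background", "spe")) {
  run_kind <- match.arg(run_kind)
  if (!is_scalar_number(rate) || rate < 0) stop_validation("rate must be >= 0")
  check_scalar_positive(duration, "duration")
  nb <- floor(duration / bin_width)
  if (!is.null(seed)) set.seed(seed)
  photon_series(rpois(nb, rate * bin_width), bin_width = bin_width, run_kind = run_kind)
}

#' Exact per-bin expected counts of a DL run
#'
#' The expected count of bin \[t1, t2\] is the integral of the rate:
#' A * B * (coth(t1/B + C) - coth(t2/B + C)) + floor_rate * (t2 - t1),
#' using the closed-form antiderivative of csch^2 rather than a midpoint
#' approximation, so the simulator introduces no discretization bias into
#' parameter-recovery studies.
#'
#' @param model A [gu_model()].
#' @param floor_rate Steady floor in counts/s (background + spontaneous
#'   emission).
#' @inheritParams simulate_constant_run
#' @param t_origin Seconds between end of excitation and the first bin.
#' @return Numeric vector of expected counts per bin.
#' @export
expected_dl_bin_counts <- function(model, floor_rate, duration = 300,
                                   bin_width = 1, t_origin = 0) {
  stopifnot(inherits(model, "gu_model"))
  nb <- floor(duration / bin_width)
  t1 <- t_origin + (seq_len(nb) - 1) * bin_width
  t2 <- t1 + bin_width
  coth <- function(x) 1 / tanh(x)
  model$A * model$B * (coth(t1 / model$B + model$C) - coth(t2 / model$B + model$C)) +
    floor_rate * bin_width
}

#' Simulate a delayed-luminescence photon run
#'
#' Per-bin counts are Poisson with mean equal to the exact integral of the
#' decaying rate gu_intensity(t) + floor_rate over the bin
#' (see [expected_dl_bin_counts()]). Time zero is the end of excitation.
#'
#' @inheritParams expected_dl_bin_counts
#' @param seed Optional integer seed.
#' @return A DL [photon_series()].
#' @export
simulate_dl_run <- function(model, floor_rate, duration = 300, bin_width = 1,
                            seed = NULL, t_origin = 0) {
  if (!is_scalar_number(floor_rate) || floor_rate < 0) {
    stop_validation("floor_rate must be >= 0")
  }
  mu <- expected_dl_bin_counts(model, floor_rate, duration, bin_width, t_origin)
  if (!is.null(seed)) set.seed(seed)
  photon_series(rpois(length(mu), mu), bin_width = bin_width, run_kind = "dl",
                t_origin = t_origin)
}

#' Specify a synthetic study cohort
#'
#' Defines the ground-truth structure a simulated cohort is drawn from:
#' groups with multiplicative effects on the DL amplitude A (hence on I0)
#' and on B (hence on T), a growth-stage decay on A and the SPE rate,
#' per-sample lognormal heterogeneity, and a target Pearson correlation
#' between true I0 and active-ingredient content. Content follows
#' content = k * I0^gamma * eps with lognormal eps whose spread is
#' calibrated so the cohort-level log-scale correlation matches
#' `rho_content` in expectation. The per-sample B multiplier is coupled as
#' multiplier^(-b_coupling), so samples with stronger emission decay faster
#' — yielding the negative T-vs-content association seen in stressed versus
#' healthy plants.
#'
#' Defaults emulate the reference protocol: 600-s background and SPE runs,
#' three 300-s DL runs, 1-s bins; base Gu parameters A = 2000 counts/s,
#' B = 60 s, C = 0.8; sample SPE rate 50 counts/s over a 5 counts/s
#' instrument background.
#'
#' @param groups Tibble with columns `label`, `a_mult`, `b_mult`.
#' @param n_stages Number of growth stages.
#' @param stage_decay Multiplier on A and SPE rate per stage step.
#' @param n_per_cell Samples per (group, stage) cell.
#' @param base_model Ground-truth [gu_model()] for the reference cell.
#' @param spe_rate Sample spontaneous-emission rate, counts/s.
#' @param background_rate Instrument dark rate, counts/s.
#' @param noise_sd SD of the per-sample lognormal multiplier (log scale).
#' @param rho_content Target Pearson correlation between log I0 and log
#'   content, in (0, 1).
#' @param gamma Exponent of the content model.
#' @param content_scale Scale k of the content model (mg/g); default set so
#'   the reference cell's content is 10 mg/g.
#' @param b_coupling Exponent coupling the per-sample multiplier to B.
#' @param content_name Name of the content column.
#' @param spe_duration,dl_duration,background_duration Run lengths, seconds.
#' @param bin_width Bin width, seconds.
#' @param n_dl_repeats DL repeats per sample.
#' @param mass_range,thickness_range Uniform ranges for fresh mass (g) and
#'   leaf thickness (mm); `thickness_range = NULL` omits thickness
#'   (mass-only normalization, as for flowers).
#' @param species Species label.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(groups = tibble(label = c("healthy", "poor"),
                                          a_mult = c(1, 0.5),
                                          b_mult = c(1, 1.4)),
                          n_stages = 1, stage_decay = 0.8, n_per_cell = 10,
                          base_model = gu_model(2000, 60, 0.8),
                          spe_rate = 50, background_rate = 5,
                          noise_sd = 0.25, rho_content = 0.9, gamma = 1,
                          content_scale = NULL, b_coupling = 0.5,
                          content_name = "content_mg_g",
                          spe_duration = 600, dl_duration = 300,
                          background_duration = 600, bin_width = 1,
                          n_dl_repeats = 3,
                          mass_range = c(0.5, 2), thickness_range = c(0.2, 0.5),
                          species = "motherwort") {
  stopifnot(inherits(base_model, "gu_model"))
  groups <- as_tibble(groups)
  if (!all(c("label", "a_mult", "b_mult") %in% names(groups))) {
    stop_validation("groups needs columns label, a_mult, b_mult")
  }
  if (any(groups$a_mult <= 0) || any(groups$b_mult <= 0)) {
    stop_validation("group multipliers must be > 0")
  }
  if (n_per_cell < 1) stop_validation("n_per_cell must be >= 1")
  if (spe_rate < 0 || background_rate < 0) stop_validation("rates must be >= 0")
  if (!is_scalar_number(rho_content) || rho_content <= 0 || rho_content >= 1) {
    stop_validation("rho_content must be in (0, 1)")
  }
  if (noise_sd < 0) stop_validation("noise_sd must be >= 0")
  # Calibrate the content-noise SD so that on the log scale
  # cor(log I0, log content) = rho in expectation: log I0 spreads by the
  # cell effects plus the per-sample multiplier, log content adds eps.
  cell_log <- as.vector(outer(log(groups$a_mult),
                              log(stage_decay) * (seq_len(n_stages) - 1), `+`))
  var_I0 <- stats::var(rep(cell_log, each = n_per_cell)) *
    (n_per_cell * length(cell_log) - 1) / (n_per_cell * length(cell_log))
  if (!is.finite(var_I0)) var_I0 <- 0
  sigma_I0 <- sqrt(var_I0 + noise_sd^2)
  if (sigma_I0 == 0) {
    stop_validation("target correlation infeasible: no variation in true I0 (all effects 1 and noise_sd 0)")
  }
  eps_sd <- gamma * sigma_I0 * sqrt(1 / rho_content^2 - 1)
  if (is.null(content_scale)) {
    content_scale <- 10 / initial_intensity(base_model$A, base_model$C)^gamma
  }
  structure(
    list(groups = groups, n_stages = n_stages, stage_decay = stage_decay,
         n_per_cell = n_per_cell, base_model = base_model,
         spe_rate = spe_rate, background_rate = background_rate,
         noise_sd = noise_sd, rho_content = rho_content, gamma = gamma,
         content_scale = content_scale, eps_sd = eps_sd,
         b_coupling = b_coupling, content_name = content_name,
         spe_duration = spe_duration, dl_duration = dl_duration,
         background_duration = background_duration, bin_width = bin_width,
         n_dl_repeats = n_dl_repeats, mass_range = mass_range,
         thickness_range = thickness_range, species = species),
    class = "cohort_design"
  )
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf("<cohort_design: %d groups x %d stages x %d samples; base I0 = %.4g counts/s; rho(I0, content) target %.2f>\n",
              nrow(x$groups), x$n_stages, x$n_per_cell,
              initial_intensity(x$base_model$A, x$base_model$C), x$rho_content))
  invisible(x)
}

# One master seed; per-(sample, run) seeds by a fixed counter scheme, so
# adding samples never reshuffles earlier streams. Kept < 2^31.
derive_seed <- function(master, sample_index, run_index) {
  as.integer((master * 100003 + sample_index * 131 + run_index) %% 2147483647)
}

#' Simulate a complete study cohort
#'
#' Draws one full measurement session from a [cohort_design()]: for each
#' (group, stage, replicate) sample, a per-sample lognormal multiplier
#' scales the DL amplitude and the SPE rate; B is scaled by the group effect
#' and the coupling; two 10-min background runs, one SPE run and
#' `n_dl_repeats` DL runs are generated as Poisson photon streams; fresh
#' mass (and thickness, when configured) are drawn uniformly; contents
#' follow the calibrated content model; absorbance triplets are generated so
#' pigment contents track the same group/stage effects.
#'
#' With `dir` set, the counts files, a YAML manifest, `content.csv`,
#' `absorbance.csv` and `ground_truth.csv` are written there — exactly the
#' formats [read_manifest()], [cohort_table()] and [pigment_panel()]
#' consume.
#'
#' @param design A [cohort_design()].
#' @param seed Master integer seed; fully determines the cohort.
#' @param dir Optional output directory.
#' @return A list: `session` ([measurement_session()]), `content_table`,
#'   `absorbance_table`, `ground_truth` (tibbles), `design`, `seed`, and
#'   `paths` when files were written.
#' @export
simulate_cohort <- function(design, seed = 1, dir = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  d <- design
  cells <- tidyr::expand_grid(group_idx = seq_len(nrow(d$groups)),
                              stage = seq_len(d$n_stages),
                              rep = seq_len(d$n_per_cell))
  samples <- vector("list", nrow(cells))
  truth <- vector("list", nrow(cells))
  contents <- vector("list", nrow(cells))
  absorb <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    g <- d$groups[cells$group_idx[i], ]
    stage <- cells$stage[i]
    sid <- sprintf("%s_s%d_%02d", g$label, stage, cells$rep[i])

    set.seed(derive_seed(seed, i, 0L))
    u <- rnorm(1, 0, d$noise_sd)            # per-sample log multiplier
    mass <- runif(1, d$mass_range[1], d$mass_range[2])
    thick <- if (is.null(d$thickness_range)) NULL else
      runif(1, d$thickness_range[1], d$thickness_range[2])
    eps <- rnorm(1, 0, d$eps_sd)
    abs_noise <- rnorm(1, 0, 0.1)

    # intrinsic (per-unit-size) multiplier: group effect x stage decay x
    # per-sample lognormal heterogeneity
    mult <- exp(u) * g$a_mult * d$stage_decay^(stage - 1)
    # emission scales with the amount of tissue measured; the size factor is
    # relative to the mid-range sample so that mass/thickness normalization
    # recovers the intrinsic signal
    size <- mass / mean(d$mass_range)
    if (!is.null(thick)) size <- size * thick / mean(d$thickness_range)
    A_i <- d$base_model$A * mult * size
    B_i <- d$base_model$B * g$b_mult * exp(u)^(-d$b_coupling)
    C_i <- d$base_model$C
    spe_rate_i <- d$spe_rate * mult * size
    model_i <- gu_model(A_i, B_i, C_i, m = d$base_model$m)
    I0_i <- initial_intensity(A_i, C_i)
    I0_intrinsic_i <- initial_intensity(d$base_model$A * mult, C_i)
    T_i <- coherence_time(B_i, C_i, d$base_model$m)
    # content is intensive (per unit dry mass): tied to the intrinsic I0
    content_i <- d$content_scale * I0_intrinsic_i^d$gamma * exp(eps)

    bg_pre <- simulate_constant_run(d$background_rate, d$background_duration,
                                    d$bin_width, seed = derive_seed(seed, i, 1L))
    spe <- simulate_constant_run(d$background_rate + spe_rate_i, d$spe_duration,
                                 d$bin_width, seed = derive_seed(seed, i, 2L),
                                 run_kind = "spe")
    floor_i <- d$background_rate + spe_rate_i
    dls <- lapply(seq_len(d$n_dl_repeats), function(j) {
      simulate_dl_run(model_i, floor_i, d$dl_duration, d$bin_width,
                      seed = derive_seed(seed, i, 2L + j))
    })
    bg_post <- simulate_constant_run(d$background_rate, d$background_duration,
                                     d$bin_width,
                                     seed = derive_seed(seed, i, 3L + d$n_dl_repeats))
    samples[[i]] <- sample_record(sid, d$species, g$label, stage, mass,
                                  thickness = thick, spe_run = spe, dl_runs = dls,
                                  background_pre = bg_pre, background_post = bg_post)
    truth[[i]] <- tibble(sample_id = sid, group = g$label, stage = stage,
                         A = A_i, B = B_i, C = C_i, I0 = I0_i,
                         I0_intrinsic = I0_intrinsic_i, T = T_i,
                         spe_rate = spe_rate_i, content = content_i,
                         fresh_mass = mass,
                         thickness = if (is.null(thick)) NA_real_ else thick)
    contents[[i]] <- tibble(sample_id = sid, !!d$content_name := content_i)
    abs_scale <- sqrt(mult) * exp(abs_noise)
    absorb[[i]] <- tibble(sample_id = sid,
                          a474 = 0.30 * abs_scale, a642 = 0.25 * abs_scale,
                          a665 = 0.55 * abs_scale,
                          volume_l = 0.015, mass_g = 0.1)
  }
  session <- measurement_session(samples, session_id = sprintf("synthetic_seed%d", seed))
  out <- list(session = session,
              content_table = dplyr::bind_rows(contents),
              absorbance_table = dplyr::bind_rows(absorb),
              ground_truth = dplyr::bind_rows(truth),
              design = design, seed = seed)
  if (!is.null(dir)) out$paths <- write_cohort_files(out, dir)
  out
}

# Writes counts files, manifest and CSV tables for a simulated cohort.
write_cohort_files <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man_samples <- lapply(cohort$session$samples, function(s) {
    fp <- function(suffix) sprintf("%s_%s.tsv", s$sample_id, suffix)
    write_photon_series(s$background_pre, file.path(dir, fp("bg_pre")))
    write_photon_series(s$background_post, file.path(dir, fp("bg_post")))
    write_photon_series(s$spe_run, file.path(dir, fp("spe")))
    dl_names <- sprintf("%s_dl%d.tsv", s$sample_id, seq_along(s$dl_runs))
    for (k in seq_along(s$dl_runs)) {
      write_photon_series(s$dl_runs[[k]], file.path(dir, dl_names[k]))
    }
    entry <- list(sample_id = s$sample_id, species = s$species, group = s$group,
                  stage = s$stage, fresh_mass_g = s$fresh_mass,
                  spe = fp("spe"), dl = as.list(dl_names),
                  background_pre = fp("bg_pre"), background_post = fp("bg_post"))
    if (!is.null(s$thickness)) entry$thickness_mm <- s$thickness
    entry
  })
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(session_id = cohort$session$session_id,
                        bin_width = attr(cohort$session$samples[[1]]$spe_run, "bin_width"),
                        samples = man_samples),
                   manifest, precision = 15)
  paths <- c(manifest = manifest,
             content = file.path(dir, "content.csv"),
             absorbance = file.path(dir, "absorbance.csv"),
             ground_truth = file.path(dir, "ground_truth.csv"))
  write.csv(as.data.frame(cohort$content_table), paths["content"], row.names = FALSE)
  write.csv(as.data.frame(cohort$absorbance_table), paths["absorbance"], row.names = FALSE)
  write.csv(as.data.frame(cohort$ground_truth), paths["ground_truth"], row.names = FALSE)
  paths
}

#' Read a content table from CSV
#'
#' @param path CSV with a `sample_id` column plus one column per analyte.
#' @return A tibble.
#' @export
read_content_table <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("content table not found: %s", path))
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
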