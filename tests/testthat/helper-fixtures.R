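# Shared fixtures. Heavy rendered cohorts are cached in an environment so
# that the acceptance tests (which reuse the same calibrated cohorts for
# several checks) only pay the rendering cost once per run.

.fixture_cache <- new.env(parent = emptyenv())

# Hand-built cohort_sim with prescribed per-platelet counts and diameters:
# lets render/detect tests use exactly known geometry.
make_sim <- function(diameters_by_platelet, patient_id = 1L) {
  counts <- lengths(diameters_by_platelet)
  platelets <- data.frame(
    patient_id = patient_id,
    platelet_id = seq_along(counts),
    n_granules = as.integer(counts)
  )
  plt_of_granule <- rep(seq_along(counts), counts)
  diam <- unlist(diameters_by_platelet, use.names = FALSE)
  if (is.null(diam)) diam <- numeric(0)
  granules <- data.frame(
    patient_id = rep(patient_id, length(plt_of_granule)),
    platelet_id = plt_of_granule,
    granule_id = sequence(counts),
    diameter_nm = diam
  )
  spec <- cohort_spec("fixture", n_patients = 1,
                      platelets_per_patient = max(length(counts), 1),
                      count_shape = 1, count_scale = 1,
                      diameter_median_nm = 140, diameter_sdlog = 0)
  structure(list(granules = granules, platelets = platelets,
                 patients = data.frame(patient_id = patient_id, rate = NA),
                 moments = cohort_moments(spec), spec = spec, seed = NA),
            class = "cohort_sim")
}

# Full render+detect+profile run for one calibrated group, cached.
# Base seeds are fixed per group (chosen once): simulate = base,
# layout = base + 1, measure = base + 2, sizing = base + 3.
rendered_cohort_run <- function(group, n_patients, base_seed) {
  key <- paste(group, n_patients, base_seed, sep = "_")
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  spec <- calibrated_cohort_spec(group, n_patients = n_patients)
  sim <- simulate_cohort(spec, seed = base_seed)
  truth <- layout_wholemount(sim, seed = base_seed + 1)
  meas <- measure_wholemount_cohort(truth, seed = base_seed + 2)
  # low-count groups legitimately have patients with < 12 platelets
  # carrying >= 4 granules; the selection warning is expected there
  profiles <- suppressWarnings(profile_cohort(meas, seed = base_seed + 3))
  enum <- enumerate_platelets(meas$records)
  run <- list(spec = spec, sim = sim, meas = meas,
              profiles = profiles, enum = enum)
  .fixture_cache[[key]] <- run
  run
}

control_run <- function() rendered_cohort_run("control", 49, 101L)
dspd_run <- function() rendered_cohort_run("dspd", 100, 102L)
mgspd_run <- function() rendered_cohort_run("mgspd", 50, 103L)

# Reference ranges from the published control row (means and SEs).
paper_control_reference <- function() {
  reference_from_summary(
    means = c(dg_per_platelet = 4.64, mean_diameter_nm = 143.14,
              tdgv_nm3 = 10.79e6),
    ses = c(dg_per_platelet = 0.11, mean_diameter_nm = 1.56,
            tdgv_nm3 = 0.42e6),
    n = 49
  )
}

# Exact two-sided Mann-Whitney p-value by enumeration of all rank
# assignments (independent oracle for small samples, no ties assumed).
mw_exact_enumeration <- function(x, y) {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  u_of <- function(ix) {
    r <- rank(pooled)
    sum(r[ix]) - m * (m + 1) / 2
  }
  u_obs <- u_of(seq_len(m))
  combos <- utils::combn(m + n, m)
  r_all <- rank(pooled)
  us <- apply(combos, 2, function(ix) sum(r_all[ix]) - m * (m + 1) / 2)
  centre <- m * n / 2
  p <- mean(abs(us - centre) >= abs(u_obs - centre) - 1e-12)
  list(statistic = u_obs, p_value = min(1, p))
}
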