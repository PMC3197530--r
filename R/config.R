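#' Treatment arms
#'
#' The six experimental arms: untreated control, agonist anti-CD137 mAb
#' alone, naive or activated OT-1 transfer alone, and the two combinations.
#' @export
ARMS <- c("CONTROL", "ANTI_CD137", "OT1_NAIVE", "OT1_NAIVE_PLUS_CD137",
          "OT1_ACTIVE", "OT1_ACTIVE_PLUS_CD137")

config_defaults <- function() list(
  # scenario
  arm = "CONTROL",
  treatment_day = 3,
  cd137_on_endothelium = TRUE,      # FALSE = endothelial CD137 knockout
  duration_days = 33,
  timestep_hours = 8,
  lattice_L = 200,
  tissue_mm = 60,
  seed = 1L,
  # repertoire
  nbit_str = 12L,
  min_match = 9L,
  affinity_level = 5e-2,
  hyper_mut = 1e-4,
  thym_eff = 0.999,
  match_mode = "complement",
  self_peptide_count = 6L,
  select_tc = TRUE,
  ova_peptide = NA,                 # NA: alternating-bit pattern for nbit_str
  # populations (per uL) and half-lives (days)
  density_B = 260, density_TH = 200, density_TC = 434, density_cDC = 351,
  density_M = 351, density_EP = 351, density_NK = 351, density_P = 0,
  half_life_cell = 3.3, half_life_IC = 4.0, half_life_IL2 = 1.6,
  half_life_CA = 1.6, half_life_IgG = 23.0, half_life_TUMOR = 3650,
  half_life_anti_CD137 = 23.0,
  density_scale = NA,               # NA: auto, ~2e4 leukocytes at L = 200
  homeostasis_rate = 1.0,
  nk_present = TRUE,                # NK agents exist, decay and move; no rule
  half_life_antigen = 4.0,
  # doses (physiological, scaled onto the lattice by dose_to_density)
  dose_ot1 = 2e6,
  dose_mab_ug = 100,
  dose_to_density = 5e-4,
  mab_quanta_per_ug = 900,
  mab_recirculate = 0.5,            # per-step fraction re-entering circulation
  entry_mode = "vessels",           # "vessels" or "walls"
  # tumor
  injected_tumor_cells = 5e5,
  engraftment_death_fraction = 0.6,
  gompertz_a = NA, gompertz_b = NA, # NA: shipped calibrated defaults
  cell_diameter_um = 20,
  tumor_capacity_full = 8,          # per-site capacity at L = 946
  sacrifice_area_mm2 = 450,
  antigen_shed_prob = 5e-5,
  # interaction probabilities (per 8-hour step)
  prob_M_Ag = 1e-2, prob_M_IC = 1e-1, prob_cDC_Ag = 2e-2, prob_B_Ag = 1e-2,
  plasma_rel_quanta = 1L,
  B_dup = 16L, TH_dup = 16L, TC_dup = 16L,
  max_lfact = 5,
  IL2_eff = 1.0,
  il2_half_sat = 2,
  il2_kill_floor = 0.5,
  il2_secrete_quanta = 2L,
  # calibrated free parameters (see scripts/calibrate_arms.R)
  base_kill_prob = 0.006,
  kill_contacts = 150L,
  restim_prob = 0.5,
  cd137_kill_mult = 60,
  cd137_dup_mult = 2,
  cd137_chemo_mult = 12,
  cd137_survival_mult = 2,          # 4-1BB anti-apoptotic signaling
  infiltration_prob_wt = 0.8,
  infiltration_prob_ko = 0.01,
  # movement / chemotaxis / diffusion
  moves_per_step = 8L,
  base_sensitivity = 1,
  ca_diffusion_fraction = 0.5,
  mol_diffusion_fraction = 0.5,
  ca_diffusion_rounds = 6L,
  il2_diffusion_rounds = 2L,
  antigen_diffusion_rounds = 2L,
  mab_diffusion_rounds = 3L,
  ca_ep_rate = 0.02, ca_m_rate = 1L, ca_ot1_rate = 3L
)

#' Build and validate a simulation configuration
#'
#' Every Table-style model constant is an overridable key; unknown keys are
#' rejected and out-of-range values raise a validation error naming the
#' key.  Derived quantities (timesteps, agent scale, per-site tumor
#' capacity, scaled doses) are resolved here.
#'
#' @param ... named overrides of the default keys (see
#'   `b16ovasim:::config_defaults()` for the full registry).
#' @param file optional path to a flat `key: value` text file (a
#'   YAML-compatible subset); file values are applied before `...`
#'   overrides.
#' @return A list of class `sim_config` including derived fields
#'   `n_steps`, `steps_per_day`, `density_scale`, `tumor_capacity`,
#'   `ot1_dose_agents`, `mab_dose_quanta`, `x0`, plus parameter objects
#'   `affinity`, `population`, `growth`.
#' @examples
#' cfg <- sim_config(arm = "OT1_ACTIVE_PLUS_CD137", lattice_L = 100)
#' cfg$ot1_dose_agents
#' @export
sim_config <- function(..., file = NULL) {
  cfg <- config_defaults()
  overrides <- list(...)
  if (!is.null(file)) overrides <- c(read_flat_config(file), overrides)
  # explicit arguments beat file values beat defaults
  overrides <- overrides[!duplicated(names(overrides), fromLast = TRUE)]
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (k in names(overrides)) cfg[[k]] <- overrides[[k]]
  validate_config(cfg)
  finalize_config(cfg)
}

read_flat_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl(":", ln, fixed = TRUE)) stop("malformed config line: ", ln)
    key <- trimws(sub(":.*$", "", ln))
    val <- trimws(sub("^[^:]*:", "", ln))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
      else if (val %in% c("true", "TRUE", "yes")) TRUE
      else if (val %in% c("false", "FALSE", "no")) FALSE
      else val
  }
  out
}

validate_config <- function(cfg) {
  chk <- function(cond, key, msg) {
    if (!cond) stop(sprintf("config key '%s': %s", key, msg))
  }
  chk(cfg$arm %in% ARMS, "arm",
      paste("must be one of", paste(ARMS, collapse = ", ")))
  chk(cfg$treatment_day %in% c(3, 8), "treatment_day", "must be 3 or 8")
  chk(cfg$lattice_L >= 16, "lattice_L", "must be >= 16")
  chk(cfg$duration_days > 0, "duration_days", "must be positive")
  chk(cfg$timestep_hours > 0 && 24 %% cfg$timestep_hours == 0,
      "timestep_hours", "must divide 24")
  chk(cfg$nbit_str >= 1 && cfg$nbit_str <= 30, "nbit_str",
      "must be in [1, 30] (default 12)")
  chk(cfg$min_match >= 1 && cfg$min_match <= cfg$nbit_str, "min_match",
      "must satisfy 0 < min_match <= nbit_str (default 9)")
  chk(cfg$affinity_level > 0 && cfg$affinity_level <= 1, "affinity_level",
      "must be in (0, 1] (default 5e-2)")
  chk(cfg$thym_eff >= 0 && cfg$thym_eff <= 1, "thym_eff",
      "must be in [0, 1] (default 0.999)")
  chk(cfg$hyper_mut >= 0 && cfg$hyper_mut <= 1, "hyper_mut",
      "must be in [0, 1] (default 1e-4)")
  chk(is.na(cfg$ova_peptide) ||
        (cfg$ova_peptide >= 0 && cfg$ova_peptide < 2^cfg$nbit_str),
      "ova_peptide", "must lie in the repertoire")
  chk(cfg$entry_mode %in% c("vessels", "walls"), "entry_mode",
      "must be 'vessels' or 'walls'")
  for (k in grep("^(prob_|infiltration_)", names(cfg), value = TRUE))
    chk(cfg[[k]] >= 0 && cfg[[k]] <= 1, k, "must be a probability")
  for (k in grep("^(density_|half_life_)", names(cfg), value = TRUE))
    chk(is.na(cfg[[k]]) || cfg[[k]] >= 0, k, "must be non-negative")
  for (k in c("cd137_kill_mult", "cd137_dup_mult", "cd137_chemo_mult",
              "cd137_survival_mult"))
    chk(cfg[[k]] >= 1, k, "must be >= 1")
  chk(cfg$engraftment_death_fraction >= 0 && cfg$engraftment_death_fraction <= 1,
      "engraftment_death_fraction", "must be in [0, 1]")
  chk(cfg$base_kill_prob >= 0 && cfg$base_kill_prob <= 1, "base_kill_prob",
      "must be a probability")
  chk(cfg$IL2_eff >= 0 && cfg$IL2_eff <= 1, "IL2_eff", "must be in [0, 1]")
  invisible(cfg)
}

finalize_config <- function(cfg) {
  if (!isTRUE(cfg$nk_present)) cfg$density_NK <- 0
  if (is.na(cfg$ova_peptide))  # 1010...10: the canonical OVA epitope code
    cfg$ova_peptide <- sum(2^seq(1, cfg$nbit_str - 1, by = 2))
  cfg$ova_peptide <- as.integer(cfg$ova_peptide)
  L <- as.integer(cfg$lattice_L)
  cfg$lattice_L <- L
  cfg$steps_per_day <- as.integer(24 / cfg$timestep_hours)
  cfg$n_steps <- as.integer(cfg$duration_days * cfg$steps_per_day)
  if (is.na(cfg$density_scale))
    cfg$density_scale <- 8.7 * (L / 200)^2
  cfg$tumor_capacity <- max(1L, as.integer(round(
    cfg$tumor_capacity_full * (946 / L)^2)))
  cfg$ot1_dose_agents <- as.integer(round(
    cfg$dose_ot1 * cfg$density_scale * cfg$dose_to_density))
  cfg$mab_dose_quanta <- as.integer(round(
    cfg$dose_mab_ug * cfg$mab_quanta_per_ug * cfg$density_scale / 8.7))
  cfg$x0 <- seed_initial_tumor(cfg$injected_tumor_cells,
                               cfg$engraftment_death_fraction)
  if (is.na(cfg$gompertz_a) || is.na(cfg$gompertz_b)) {
    gp <- gompertz_default_params()
    cfg$gompertz_a <- gp$a; cfg$gompertz_b <- gp$b
  }
  cfg$affinity <- affinity_params(cfg$nbit_str, cfg$min_match,
                                  cfg$affinity_level, cfg$hyper_mut,
                                  cfg$thym_eff, cfg$match_mode)
  cfg$population <- population_params(
    density = c(B = cfg$density_B, TH = cfg$density_TH, TC = cfg$density_TC,
                cDC = cfg$density_cDC, M = cfg$density_M, EP = cfg$density_EP,
                NK = cfg$density_NK, P = cfg$density_P),
    half_life_days = c(cell = cfg$half_life_cell, IC = cfg$half_life_IC,
                       IL2 = cfg$half_life_IL2, CA = cfg$half_life_CA,
                       IgG = cfg$half_life_IgG, TUMOR = cfg$half_life_TUMOR,
                       anti_CD137 = cfg$half_life_anti_CD137),
    density_scale = cfg$density_scale)
  cfg$growth <- gompertz_params(cfg$gompertz_a, cfg$gompertz_b)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> arm %s, treatment day %d%s\n", x$arm,
              x$treatment_day,
              if (x$cd137_on_endothelium) "" else " [endothelial CD137 KO]"))
  cat(sprintf("  lattice %d x %d (%.0f mm tissue), %d steps of %g h over %g days\n",
              x$lattice_L, x$lattice_L, x$tissue_mm, x$n_steps,
              x$timestep_hours, x$duration_days))
  cat(sprintf("  x0 = %d tumor cells, OT-1 dose %d agents, mAb %d quanta\n",
              x$x0, x$ot1_dose_agents, x$mab_dose_quanta))
  invisible(x)
}

arm_payload <- function(arm) {
  switch(arm,
    CONTROL = list(ot1 = FALSE, activated = FALSE, mab = FALSE),
    ANTI_CD137 = list(ot1 = FALSE, activated = FALSE, mab = TRUE),
    OT1_NAIVE = list(ot1 = TRUE, activated = FALSE, mab = FALSE),
    OT1_NAIVE_PLUS_CD137 = list(ot1 = TRUE, activated = FALSE, mab = TRUE),
    OT1_ACTIVE = list(ot1 = TRUE, activated = TRUE, mab = FALSE),
    OT1_ACTIVE_PLUS_CD137 = list(ot1 = TRUE, activated = TRUE, mab = TRUE),
    stop("unknown arm: ", arm))
}
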