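# small but complete replicates: L = 48, short horizons
small_cfg <- function(...) sim_config(lattice_L = 48, ...)

test_that("replicates are bit-identical under the same (config, seed)", {
  cfg <- small_cfg(duration_days = 4)
  r1 <- run_replicate(cfg, seed = 101)
  r2 <- run_replicate(cfg, seed = 101)
  expect_identical(r1$timeseries, r2$timeseries)
  expect_identical(r1$outcome, r2$outcome)
  r3 <- run_replicate(cfg, seed = 102)
  expect_false(identical(r1$timeseries, r3$timeseries))
})

test_that("configuration validation catches bad keys and ranges", {
  expect_error(sim_config(nonsense_key = 1), "unknown configuration key")
  expect_error(sim_config(treatment_day = 5), "treatment_day")
  expect_error(sim_config(min_match = 13), "min_match")
  expect_error(sim_config(arm = "PLACEBO"), "arm")
  expect_error(sim_config(prob_M_Ag = 1.5), "probability")
  # defaults carry the canonical tuning values
  cfg <- sim_config()
  expect_identical(cfg$min_match, 9L)
  expect_identical(cfg$nbit_str, 12L)
  expect_equal(cfg$affinity_level, 5e-2)
  expect_equal(cfg$thym_eff, 0.999)
  expect_identical(cfg$timestep_hours, 8)
  expect_identical(cfg$B_dup, 16L)
  expect_equal(cfg$IL2_eff, 1)
  expect_identical(cfg$x0, 2e5)
  expect_identical(cfg$n_steps, 99L)
  # derived repertoire bound follows nbit_str overrides
  expect_identical(2^sim_config(nbit_str = 10)$nbit_str, 1024)
})

test_that("flat config files round-trip through sim_config", {
  path <- tempfile(fileext = ".yml")
  writeLines(c("# scenario", "arm: OT1_ACTIVE", "treatment_day: 8",
               "lattice_L: 64", "cd137_on_endothelium: false"), path)
  cfg <- sim_config(file = path)
  expect_identical(cfg$arm, "OT1_ACTIVE")
  expect_identical(cfg$treatment_day, 8)
  expect_identical(cfg$lattice_L, 64L)
  expect_false(cfg$cd137_on_endothelium)
  # explicit overrides beat file values
  cfg2 <- sim_config(file = path, treatment_day = 3)
  expect_identical(cfg2$treatment_day, 3)
})

test_that("census accounting balances every step", {
  cfg <- small_cfg(duration_days = 6)
  r <- run_replicate(cfg, seed = 7)
  ts <- r$timeseries
  types <- paste0("n_", names(CELL_TYPES)[1:8])
  tot <- rowSums(ts[, types])
  for (i in seq_len(nrow(ts) - 1L)) {
    expect_identical(tot[i + 1L],
                     tot[i] + ts$births[i + 1L] + ts$divisions[i + 1L] -
                       ts$deaths[i + 1L],
                     label = sprintf("census balance at step %d", i))
  }
})

test_that("an untreated tumor grows monotonically to sacrifice", {
  cfg <- small_cfg(arm = "CONTROL", duration_days = 33)
  r <- run_replicate(cfg, seed = 11)
  ts <- r$timeseries
  expect_true(all(diff(ts$tumor_cells) >= 0))
  expect_false(r$outcome == "REJECTED")
  # area is the fixed monotone transform of the cell count
  expect_equal(ts$tumor_area_mm2,
               area_from_cells(ts$tumor_cells, cfg$cell_diameter_um))
  # horizon: at most 99 steps + the initial row
  expect_lte(nrow(ts), 100L)
})

test_that("tumor newborn placement conserves the Euler counts", {
  cfg <- small_cfg(arm = "CONTROL", duration_days = 8)
  r <- run_replicate(cfg, seed = 13)
  ts <- r$timeseries
  # growth equals placed newborns minus kills, up to the tiny natural
  # death of tumor cells (10-year half-life, ~6e-5 per step)
  natural_death_bound <- 3 * 6.4e-5 * max(ts$tumor_cells) * nrow(ts)
  expect_lt(abs((ts$tumor_cells[nrow(ts)] - ts$tumor_cells[1]) -
                  (sum(ts$newborn_tumor) - sum(ts$kills))),
            natural_death_bound)
})

test_that("treatment payloads follow the arm definitions and schedule", {
  # control: nothing placed
  cfg <- small_cfg(arm = "CONTROL", duration_days = 4)
  r <- run_replicate(cfg, seed = 3)
  expect_identical(max(r$timeseries$mab_total), 0)
  expect_identical(max(r$timeseries$ot1), 0)
  # naive cohort + antibody on day 3 (step 9)
  cfg2 <- small_cfg(arm = "OT1_NAIVE_PLUS_CD137", duration_days = 4)
  r2 <- run_replicate(cfg2, seed = 3)
  ts2 <- r2$timeseries
  expect_identical(ts2$ot1[ts2$step == 8], 0)
  expect_identical(ts2$ot1[ts2$step == 9], as.numeric(cfg2$ot1_dose_agents))
  expect_gt(ts2$mab_total[ts2$step == 9], 0)
  # day-8 arms schedule at step 24
  cfg3 <- small_cfg(arm = "OT1_ACTIVE", treatment_day = 8,
                    duration_days = 9)
  r3 <- run_replicate(cfg3, seed = 3)
  ts3 <- r3$timeseries
  expect_identical(ts3$ot1[ts3$step == 23], 0)
  expect_identical(ts3$ot1[ts3$step == 24], as.numeric(cfg3$ot1_dose_agents))
  expect_identical(max(ts3$mab_total), 0)
})

test_that("naive cohorts enter naive; activated cohorts enter active", {
  cfg <- small_cfg(arm = "OT1_NAIVE", duration_days = 4)
  r <- run_replicate(cfg, seed = 5)
  ts <- r$timeseries
  at <- ts[ts$step == 9, ]
  # the cohort arrives naive (only stray endogenous priming can be active)
  expect_lt(at$tc_active, as.numeric(cfg$ot1_dose_agents) / 2)
  cfg2 <- small_cfg(arm = "OT1_ACTIVE", duration_days = 4)
  r2 <- run_replicate(cfg2, seed = 5)
  at2 <- r2$timeseries[r2$timeseries$step == 9, ]
  expect_gte(at2$tc_active, as.numeric(cfg2$ot1_dose_agents))
})

test_that("intratumoral TC counting is positionally exact", {
  st <- blank_state(L = 16)
  expect_identical(intratumoral_tc_count(st), 0L)
  st$tumor[st$center] <- 5L
  put_agent(st, "TC", "ACTIVE", st$center)
  put_agent(st, "TC", "ACTIVE", neighbors(st$center, st$lattice)[1])
  put_agent(st, "M", "ACTIVE", st$center)
  expect_identical(intratumoral_tc_count(st), 1L)
  st$tumor[neighbors(st$center, st$lattice)[1]] <- 1L
  expect_identical(intratumoral_tc_count(st), 2L)
})

test_that("run_experiment aggregates replicates reproducibly", {
  cfg <- small_cfg(duration_days = 3)
  ex <- run_experiment(cfg, n_reps = 3, base_seed = 41)
  expect_length(ex$results, 3)
  expect_identical(ex$results[[2]]$seed, 42L)
  # replicate 2 in isolation gives the identical run
  solo <- run_replicate(cfg, seed = 42)
  expect_identical(solo$timeseries, ex$results[[2]]$timeseries)
  # summary means lie within the per-day envelope
  expect_true(all(ex$summary$mean_area_mm2 >= ex$summary$min_area_mm2 - 1e-9))
  expect_true(all(ex$summary$mean_area_mm2 <= ex$summary$max_area_mm2 + 1e-9))
  # n_reps = 1: the summary is the single replicate
  ex1 <- run_experiment(cfg, n_reps = 1, base_seed = 41)
  ts1 <- ex1$results[[1]]$timeseries
  expect_equal(ex1$summary$mean_area_mm2[seq_len(nrow(ts1))],
               ts1$tumor_area_mm2)
})

test_that("agents never leave the lattice or sit on invalid sites", {
  cfg <- small_cfg(duration_days = 5)
  set.seed(19)
  st <- sim_state_init(cfg)
  for (s in 1:15) {
    st$step <- s
    b16ovasim:::phase_tumor_growth(st)
    b16ovasim:::phase_molecules(st)
    b16ovasim:::phase_agent_decay(st)
    b16ovasim:::phase_interactions(st)
    rule_duplicate(st)
    b16ovasim:::phase_movement(st)
    b16ovasim:::phase_homeostasis(st)
    expect_true(all(st$agents$site >= 1L &
                      st$agents$site <= st$lattice$n_sites))
    # EP agents are immobile vessel walls
  }
  ep0 <- st$agents$site[st$agents$type == CELL_TYPES[["EP"]]]
  b16ovasim:::phase_movement(st)
  expect_identical(st$agents$site[st$agents$type == CELL_TYPES[["EP"]]], ep0)
})

test_that("snapshots capture the lattice at requested days", {
  cfg <- small_cfg(duration_days = 3)
  r <- run_replicate(cfg, seed = 23, snapshot_days = c(1, 2))
  expect_named(r$snapshots, c("day_1", "day_2"))
  snap <- r$snapshots$day_1
  expect_identical(dim(snap$tumor), c(48L, 48L))
  expect_identical(sum(snap$tumor),
                   as.integer(r$timeseries$tumor_cells[
                     r$timeseries$step == 3]))
})
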