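#' Simulation engine
#'
#' One replicate advances a fixed 9-phase sequence per 8-hour timestep:
#' (1) Gompertz forward-Euler tumor seeding and newborn placement,
#' (2) molecule decay and diffusion, (3) stochastic agent death by
#' half-life, (4) site-local interactions, (5) duplication,
#' (6) movement with chemotaxis bias and the endothelial CD137
#' infiltration gate, (7) bone-marrow homeostasis, (8) scheduled treatment
#' events, (9) observables.  The run stops at the sacrifice threshold
#' (tumor area >= 450 mm^2), at rejection (zero tumor cells) or at the
#' day-33 horizon, and is fully reproducible from `(config, seed)`.
#'
#' @name engine
NULL

#' Initialize a simulation state
#'
#' Builds the lattice, the self-peptide panel, the resting leukocyte
#' populations and the engrafted tumor seed (a compact disk at the lattice
#' center, filled innermost-ring-first at the per-site capacity).
#'
#' @param cfg a [sim_config()].
#' @return An environment of class `sim_state` holding the agent table,
#'   the per-site tumor counts and molecule fields, and bookkeeping.
#' @export
sim_state_init <- function(cfg) {
  st <- new.env(parent = emptyenv())
  st$cfg <- cfg
  st$lattice <- hex_lattice(cfg$lattice_L, cfg$tissue_mm)
  st$self_peptides <- sample_repertoire(cfg$self_peptide_count, cfg$nbit_str)
  st$agents <- initialize_populations(cfg$population, st$lattice,
                                      cfg$affinity, st$self_peptides,
                                      cfg$select_tc)
  n <- st$lattice$n_sites
  st$tumor <- integer(n)
  st$il2 <- integer(n); st$ca <- integer(n)
  st$mab <- integer(n); st$antigen <- integer(n)
  st$igg <- list(site = integer(0), receptor = integer(0), qty = integer(0))
  st$ic <- list(site = integer(0), receptor = integer(0), qty = integer(0))
  st$center <- site_index(st$lattice$L %/% 2L, st$lattice$L %/% 2L,
                          st$lattice$L)
  seed_sites <- placement_tumor_seed(st$lattice, cfg$x0, cfg$tumor_capacity)
  fills <- rep(cfg$tumor_capacity, length(seed_sites))
  extra <- sum(fills) - cfg$x0
  if (extra > 0) fills[length(fills)] <- fills[length(fills)] - extra
  st$tumor[seed_sites] <- as.integer(fills)
  st$x_t <- sum(st$tumor)
  st$growth_residual <- 0
  st$step <- 0L
  st$kills_step <- 0L
  st$treated <- FALSE
  class(st) <- c("sim_state", "environment")
  st
}

# ---- phases ---------------------------------------------------------------

phase_tumor_growth <- function(st) {
  en <- euler_newborns(st$x_t, st$cfg$growth, dt = 1,
                       residual = st$growth_residual)
  st$growth_residual <- en$residual
  if (en$w > 0L) place_tumor_newborns(st, en$w)
  invisible(en$w)
}

# place w newborn tumor cells adjacent to existing tumor, innermost first
place_tumor_newborns <- function(st, w) {
  cap <- st$cfg$tumor_capacity
  guard <- 0L
  while (w > 0L && guard < 100L) {
    guard <- guard + 1L
    ts <- which(st$tumor > 0L)
    if (!length(ts)) { # tumor was eliminated this very step; no regrowth
      break
    }
    open <- ts[st$tumor[ts] < cap]
    if (length(open)) {
      open <- open[order(site_distance(open, st$center, st$lattice))]
      fr <- cap - st$tumor[open]
      cum <- cumsum(fr)
      k <- match(TRUE, cum >= w)
      if (is.na(k)) {
        st$tumor[open] <- cap
        st$x_t <- st$x_t + sum(fr)
        w <- w - sum(fr)
      } else {
        if (k > 1L) st$tumor[open[seq_len(k - 1L)]] <- cap
        prev <- if (k > 1L) cum[k - 1L] else 0L
        st$tumor[open[k]] <- st$tumor[open[k]] + (w - prev)
        st$x_t <- st$x_t + w
        w <- 0L
      }
    } else {
      nb <- unique(as.vector(st$lattice$nbr[ts, ]))
      nb <- nb[!is.na(nb)]
      nb <- nb[st$tumor[nb] == 0L]
      if (!length(nb)) break  # lattice full
      nb <- nb[order(site_distance(nb, st$center, st$lattice))]
      take <- min(length(nb), ceiling(w / cap))
      sel <- nb[seq_len(take)]
      fills <- rep(cap, take)
      fills[take] <- w - cap * (take - 1L)
      st$tumor[sel] <- as.integer(fills)
      st$x_t <- st$x_t + sum(fills)
      w <- 0L
    }
  }
  invisible(NULL)
}

phase_molecules <- function(st) {
  thin <- function(field, half_life_days) {
    p_surv <- 2^(-1 / (half_life_days * st$cfg$steps_per_day))
    occ <- which(field > 0L)
    if (length(occ)) field[occ] <- stats::rbinom(length(occ), field[occ],
                                                 p_surv)
    field
  }
  hl <- st$cfg$population$half_life_days
  st$il2 <- thin(st$il2, hl[["IL2"]])
  st$ca <- thin(st$ca, hl[["CA"]])
  st$mab <- thin(st$mab, hl[["anti_CD137"]])
  st$antigen <- thin(st$antigen, st$cfg$half_life_antigen)
  thin_sparse <- function(pool, h) {
    if (!length(pool$site)) return(pool)
    q <- stats::rbinom(length(pool$qty), pool$qty,
                       2^(-1 / (h * st$cfg$steps_per_day)))
    keep <- q > 0L
    list(site = pool$site[keep], receptor = pool$receptor[keep],
         qty = q[keep])
  }
  st$igg <- thin_sparse(st$igg, hl[["IgG"]])
  st$ic <- thin_sparse(st$ic, hl[["IC"]])
  # molecules diffuse much faster than cells: several neighbor-exchange
  # rounds per 8-hour step, scaled by molecular size
  rounds_of <- function(field, fraction, rounds) {
    for (i in seq_len(rounds))
      field <- diffuse_field(field, st$lattice, fraction)
    field
  }
  st$ca <- rounds_of(st$ca, st$cfg$ca_diffusion_fraction,
                     st$cfg$ca_diffusion_rounds)
  st$il2 <- rounds_of(st$il2, st$cfg$mol_diffusion_fraction,
                      st$cfg$il2_diffusion_rounds)
  st$mab <- rounds_of(st$mab, st$cfg$mol_diffusion_fraction,
                      st$cfg$mab_diffusion_rounds)
  # systemic antibody recirculates: a fraction re-enters the blood each
  # step and is re-deposited at vessel (EP) sites across the tissue
  if (st$cfg$mab_recirculate > 0 && sum(st$mab) > 0L) {
    occ <- which(st$mab > 0L)
    back <- stats::rbinom(length(occ), st$mab[occ], st$cfg$mab_recirculate)
    st$mab[occ] <- st$mab[occ] - back
    pool <- sum(back)
    if (pool > 0L) {
      ep <- st$agents$site[st$agents$type == CELL_TYPES[["EP"]]]
      if (!length(ep)) ep <- placement_iv(st$lattice, 64L)
      st$mab <- add_at(st$mab, ep[sample.int(length(ep), pool,
                                             replace = TRUE)],
                       rep(1L, pool))
    }
  }
  st$antigen <- rounds_of(st$antigen, st$cfg$mol_diffusion_fraction,
                          st$cfg$antigen_diffusion_rounds)
  # tumor cell natural death: 10-year half-life, effectively none
  p_tum <- decay_probability(hl[["TUMOR"]] * st$cfg$steps_per_day, 1)
  occ <- which(st$tumor > 0L)
  if (length(occ)) {
    d <- stats::rbinom(length(occ), st$tumor[occ], p_tum)
    st$tumor[occ] <- st$tumor[occ] - d
    st$x_t <- st$x_t - sum(d)
  }
  invisible(NULL)
}

phase_agent_decay <- function(st) {
  n <- agents_n(st$agents)
  if (n == 0L) return(invisible(integer(8L)))
  p <- rep(decay_probability(st$cfg$half_life_cell * st$cfg$steps_per_day, 1),
           n)
  # 4-1BB signaling is anti-apoptotic: boosted TCs live longer
  if (any(st$agents$boosted))
    p[st$agents$boosted] <- decay_probability(
      st$cfg$half_life_cell * st$cfg$steps_per_day *
        st$cfg$cd137_survival_mult, 1)
  die <- stats::runif(n) < p
  deaths <- integer(8L)
  tab <- tabulate(st$agents$type[die], nbins = 8L)
  deaths[] <- tab
  st$agents <- agents_subset(st$agents, !die)
  invisible(deaths)
}

phase_interactions <- function(st) {
  rule_antigen_shed(st)
  rule_capture(st)
  rule_th_help(st, "B")
  rule_th_help(st, "M")
  rule_tc_prime(st)
  rule_cd137_boost(st)
  st$kills_step <- rule_tc_kill(st)
  rule_humoral(st)
  rule_ca_release(st)
  invisible(NULL)
}

phase_movement <- function(st) {
  a <- st$agents
  n <- agents_n(a)
  if (n == 0L) return(invisible(NULL))
  mobile <- a$type != CELL_TYPES[["EP"]]
  idx <- which(mobile)
  if (!length(idx)) return(invisible(NULL))
  sens <- numeric(length(idx))
  ty <- a$type[idx]
  chem <- ty %in% c(CELL_TYPES[["TC"]], CELL_TYPES[["M"]], CELL_TYPES[["cDC"]])
  sens[chem] <- st$cfg$base_sensitivity
  boosted <- a$boosted[idx]
  sens[boosted] <- sens[boosted] * st$cfg$cd137_chemo_mult
  is_tc <- ty == CELL_TYPES[["TC"]]
  gate_p <- infiltration_gate_prob(st$cfg, sum(st$mab) > 0L)
  sites <- a$site[idx]
  for (h in seq_len(st$cfg$moves_per_step)) {
    dest <- hop_sites(sites, st$lattice, st$ca, sens)
    entering <- is_tc & st$tumor[dest] > 0L & st$tumor[sites] == 0L
    if (any(entering)) {
      veto <- entering & (stats::runif(length(dest)) >= gate_p)
      dest[veto] <- sites[veto]
    }
    sites <- dest
  }
  st$agents$site[idx] <- sites
  invisible(NULL)
}

phase_homeostasis <- function(st) {
  census <- census_by_type(st$agents)
  births <- apply_homeostasis(census, st$cfg$population,
                              st$cfg$homeostasis_rate)
  total <- sum(births)
  if (total == 0L) return(invisible(births))
  a <- new_agents(total)
  pos <- 1L
  for (ty in names(births)) {
    nb <- births[[ty]]
    if (nb == 0L) next
    i <- pos:(pos + nb - 1L)
    a$type[i] <- CELL_TYPES[[ty]]
    a$state[i] <- CELL_STATES[["NAIVE"]]
    a$site[i] <- sample.int(st$lattice$n_sites, nb, replace = TRUE)
    selected <- ty == "TH" || (ty == "TC" && st$cfg$select_tc)
    a$receptor[i] <- draw_selected_receptors(
      nb, st$cfg$affinity, if (selected) st$self_peptides)
    pos <- pos + nb
  }
  st$agents <- agents_bind(st$agents, a)
  invisible(births)
}

#' Apply scheduled treatment payloads
#'
#' At the treatment step the arm-appropriate payloads enter the tissue:
#' scaled anti-CD137 quanta and/or the OT-1 cohort (activated or naive per
#' arm).  Entry sites are endothelial (vessel) sites under the default
#' `entry_mode = "vessels"`, or the rigid top/bottom wall rows under
#' `"walls"`.  Control arms place nothing active (rat IgG is inert).
#'
#' @param st a simulation state environment.
#' @return Invisibly, a named list of payload sizes.
#' @export
apply_treatment <- function(st) {
  pay <- arm_payload(st$cfg$arm)
  placed <- list(mab = 0L, ot1 = 0L)
  entry <- function(n, avoid_tumor = FALSE) {
    if (st$cfg$entry_mode == "walls") return(placement_iv(st$lattice, n))
    ep <- st$agents$site[st$agents$type == CELL_TYPES[["EP"]]]
    # i.v. cells extravasate in normal tissue; entry into tumor-occupied
    # sites always goes through the endothelial CD137 infiltration gate
    if (avoid_tumor) ep <- ep[st$tumor[ep] == 0L]
    if (!length(ep)) return(placement_iv(st$lattice, n))
    ep[sample.int(length(ep), n, replace = TRUE)]
  }
  if (pay$mab && st$cfg$mab_dose_quanta > 0L) {
    s <- entry(st$cfg$mab_dose_quanta)
    st$mab <- add_at(st$mab, s, rep(1L, length(s)))
    placed$mab <- st$cfg$mab_dose_quanta
  }
  if (pay$ot1 && st$cfg$ot1_dose_agents > 0L) {
    cohort <- make_ot1_cohort(st$cfg$ot1_dose_agents, pay$activated,
                              st$cfg$ova_peptide, st$cfg$nbit_str)
    cohort$site <- entry(st$cfg$ot1_dose_agents, avoid_tumor = TRUE)
    st$agents <- agents_bind(st$agents, cohort)
    placed$ot1 <- st$cfg$ot1_dose_agents
  }
  st$treated <- TRUE
  invisible(placed)
}

#' Count of intratumoral cytotoxic T cells
#'
#' @param st a simulation state environment.
#' @return Number of TC agents on sites occupied by at least one tumor
#'   cell.
#' @export
intratumoral_tc_count <- function(st) {
  a <- st$agents
  sum(a$type == CELL_TYPES[["TC"]] & st$tumor[a$site] > 0L)
}

observe_row <- function(st, births, deaths, divisions, w) {
  a <- st$agents
  census <- census_by_type(a)
  tc <- a$type == CELL_TYPES[["TC"]]
  c(step = st$step, day = st$step / st$cfg$steps_per_day,
    tumor_cells = st$x_t,
    tumor_area_mm2 = area_from_cells(st$x_t, st$cfg$cell_diameter_um),
    stats::setNames(as.numeric(census), paste0("n_", names(census))),
    tc_active = sum(tc & a$state == CELL_STATES[["ACTIVE"]]),
    tc_boosted = sum(tc & a$boosted),
    ot1 = sum(a$is_ot1),
    intratumoral_tc = intratumoral_tc_count(st),
    il2_total = sum(st$il2), ca_total = sum(st$ca),
    mab_total = sum(st$mab), antigen_total = sum(st$antigen),
    igg_total = sum(st$igg$qty), ic_total = sum(st$ic$qty),
    kills = st$kills_step, newborn_tumor = w,
    births = sum(births), deaths = sum(deaths), divisions = divisions)
}

#' Run one seeded replicate
#'
#' @param config a [sim_config()].
#' @param seed integer RNG seed; the pair `(config, seed)` fully
#'   determines the output.
#' @param snapshot_days optional numeric vector of days at which to store
#'   plain grid snapshots of tumor counts and TC occupancy.
#' @return An object of class `sim_result`: `timeseries` (one row per
#'   completed step plus the initial row), `outcome` (`"REJECTED"`,
#'   `"SACRIFICED"` or `"SURVIVED_TO_END"`), `outcome_day`,
#'   `near_rejection_day` (first day tumor area drops below 1% of its
#'   peak; `NA` if never), `audit` (per-step, per-type census accounting),
#'   `snapshots`, `seed` and the `config` echo.
#' @examples
#' \donttest{
#' cfg <- sim_config(arm = "CONTROL", lattice_L = 60, duration_days = 5)
#' r <- run_replicate(cfg, seed = 1)
#' r
#' }
#' @export
run_replicate <- function(config, seed, snapshot_days = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  st <- sim_state_init(config)
  treat_step <- as.integer(config$treatment_day * config$steps_per_day)
  rows <- vector("list", config$n_steps + 1L)
  audit <- vector("list", config$n_steps)
  snaps <- list()
  rows[[1L]] <- observe_row(st, integer(8L), integer(8L), 0L, 0L)
  outcome <- "SURVIVED_TO_END"
  outcome_day <- config$duration_days
  for (s in seq_len(config$n_steps)) {
    st$step <- s
    st$kills_step <- 0L
    w <- phase_tumor_growth(st)
    phase_molecules(st)
    deaths <- phase_agent_decay(st)
    phase_interactions(st)
    pre_n <- agents_n(st$agents)
    divisions <- rule_duplicate(st)
    phase_movement(st)
    births <- phase_homeostasis(st)
    if (s == treat_step) {
      placed <- apply_treatment(st)
      births["TC"] <- births[["TC"]] + placed$ot1
    }
    rows[[s + 1L]] <- observe_row(st, births, deaths, divisions, w)
    audit[[s]] <- c(step = s, births = sum(births), deaths = sum(deaths),
                    divisions = divisions)
    day <- s / config$steps_per_day
    if (!is.null(snapshot_days) && any(abs(day - snapshot_days) < 1e-9)) {
      a <- st$agents
      tc_grid <- integer(st$lattice$n_sites)
      tc_sites <- a$site[a$type == CELL_TYPES[["TC"]]]
      if (length(tc_sites)) tc_grid <- add_at(tc_grid, tc_sites,
                                              rep(1L, length(tc_sites)))
      snaps[[sprintf("day_%g", day)]] <- list(
        day = day,
        tumor = matrix(st$tumor, config$lattice_L, byrow = TRUE),
        tc = matrix(tc_grid, config$lattice_L, byrow = TRUE))
    }
    if (st$x_t <= 0) { outcome <- "REJECTED"; outcome_day <- day; break }
    if (area_from_cells(st$x_t, config$cell_diameter_um) >=
          config$sacrifice_area_mm2) {
      outcome <- "SACRIFICED"; outcome_day <- day; break
    }
  }
  ts <- as.data.frame(do.call(rbind, rows[!vapply(rows, is.null, TRUE)]))
  res <- structure(list(
    timeseries = ts, outcome = outcome, outcome_day = outcome_day,
    near_rejection_day = near_rejection_day(ts),
    audit = as.data.frame(do.call(rbind,
                                  audit[!vapply(audit, is.null, TRUE)])),
    snapshots = snaps, seed = as.integer(seed), config = config),
    class = "sim_result")
  res
}

# first day tumor area falls below 1% of its peak (after the peak)
near_rejection_day <- function(ts) {
  peak_i <- which.max(ts$tumor_area_mm2)
  thr <- 0.01 * ts$tumor_area_mm2[peak_i]
  after <- ts[seq_len(nrow(ts)) > peak_i, ]
  hit <- which(after$tumor_area_mm2 < thr)
  if (!length(hit)) return(NA_real_)
  after$day[hit[1L]]
}

#' @export
print.sim_result <- function(x, ...) {
  last <- x$timeseries[nrow(x$timeseries), ]
  cat(sprintf("<sim_result> arm %s (seed %d): %s at day %g\n",
              x$config$arm, x$seed, x$outcome, x$outcome_day))
  cat(sprintf("  final tumor: %g cells (%.1f mm^2); near-rejection day: %s\n",
              last$tumor_cells, last$tumor_area_mm2,
              ifelse(is.na(x$near_rejection_day), "none",
                     format(x$near_rejection_day))))
  invisible(x)
}

#' @export
plot.sim_result <- function(x, ...) {
  plot(x$timeseries$day, x$timeseries$tumor_area_mm2, type = "l",
       xlab = "day post-injection", ylab = expression(tumor ~ area ~ (mm^2)),
       main = x$config$arm, ...)
  abline(v = x$config$treatment_day, lty = 3)
  invisible(x)
}

#' @export
as.data.frame.sim_result <- function(x, ...) x$timeseries

#' Run a seeded replicate set for one arm
#'
#' Replicate `k` uses seed `base_seed + k - 1`, so any replicate is
#' reproducible in isolation.
#'
#' @param config a [sim_config()].
#' @param n_reps number of replicates (>= 1).
#' @param base_seed base RNG seed.
#' @return An object of class `sim_experiment`: the replicate list, a
#'   per-day summary (mean and sd tumor area; rejected replicates carry
#'   area 0 forward, sacrificed ones their final area), the outcome tally
#'   and the rejection-day distribution.
#' @export
run_experiment <- function(config, n_reps, base_seed = 1L) {
  stopifnot(n_reps >= 1)
  results <- lapply(seq_len(n_reps), function(k)
    run_replicate(config, seed = base_seed + k - 1L))
  steps <- 0:config$n_steps
  days <- steps / config$steps_per_day
  area <- vapply(results, function(r) {
    a <- r$timeseries$tumor_area_mm2[match(steps, r$timeseries$step)]
    last <- max(which(!is.na(a)))
    if (last < length(a))
      a[(last + 1L):length(a)] <- if (r$outcome == "REJECTED") 0 else a[last]
    a
  }, numeric(length(days)))
  summary_df <- data.frame(
    day = days,
    mean_area_mm2 = rowMeans(area),
    sd_area_mm2 = apply(area, 1, stats::sd),
    min_area_mm2 = apply(area, 1, min),
    max_area_mm2 = apply(area, 1, max))
  structure(list(
    results = results, summary = summary_df,
    outcomes = table(factor(vapply(results, `[[`, "", "outcome"),
                            levels = c("REJECTED", "SACRIFICED",
                                       "SURVIVED_TO_END"))),
    near_rejection_days = vapply(results, `[[`, 0, "near_rejection_day"),
    config = config, base_seed = base_seed), class = "sim_experiment")
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf("<sim_experiment> arm %s, %d replicates (seeds %d..%d)\n",
              x$config$arm, length(x$results), x$base_seed,
              x$base_seed + length(x$results) - 1L))
  print(x$outcomes)
  nr <- x$near_rejection_days
  if (any(!is.na(nr)))
    cat(sprintf("  median near-rejection day: %g\n",
                stats::median(nr, na.rm = TRUE)))
  invisible(x)
}

#' Mean tumor area at a given day across an experiment's replicates
#'
#' @param x a `sim_experiment`.
#' @param day the day to read off.
#' @return Mean area in mm^2.
#' @export
mean_area_at <- function(x, day) {
  i <- which.min(abs(x$summary$day - day))
  x$summary$mean_area_mm2[i]
}
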