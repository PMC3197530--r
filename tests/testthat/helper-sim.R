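# shared fixtures: tiny configurations and hand-built simulation states

tiny_config <- function(...) {
  sim_config(lattice_L = 24, duration_days = 2, ...)
}

# a bare state on a small lattice with no agents and no tumor, for
# rule-level unit tests; populate fields/agents by hand afterwards
blank_state <- function(L = 16, ...) {
  cfg <- sim_config(lattice_L = L, injected_tumor_cells = 0,
                    density_B = 0, density_TH = 0, density_TC = 0,
                    density_cDC = 0, density_M = 0, density_EP = 0,
                    density_NK = 0, density_P = 0, ...)
  st <- sim_state_init(cfg)
  st$tumor[] <- 0L
  st$x_t <- 0
  st
}

# append one hand-built agent to a state; returns its row index
put_agent <- function(st, type, state, site, receptor = 0L,
                      is_ot1 = FALSE, boosted = FALSE,
                      pres_pep = NA_integer_, dup_timer = 0L) {
  a <- b16ovasim:::new_agents(1L)
  a$type[1] <- CELL_TYPES[[type]]
  a$state[1] <- CELL_STATES[[state]]
  a$site[1] <- site
  a$receptor[1] <- as.integer(receptor)
  a$is_ot1[1] <- is_ot1
  a$boosted[1] <- boosted
  a$pres_pep[1] <- pres_pep
  a$dup_timer[1] <- as.integer(dup_timer)
  st$agents <- b16ovasim:::agents_bind(st$agents, a)
  b16ovasim:::agents_n(st$agents)
}

# append n identical agents in one shot (for bulk rate tests)
put_agents <- function(st, n, type, state, site, receptor = 0L,
                       is_ot1 = FALSE, boosted = FALSE,
                       pres_pep = NA_integer_, dup_timer = 0L) {
  a <- b16ovasim:::new_agents(n)
  a$type[] <- CELL_TYPES[[type]]
  a$state[] <- CELL_STATES[[state]]
  a$site[] <- site
  a$receptor[] <- as.integer(receptor)
  a$is_ot1[] <- is_ot1
  a$boosted[] <- boosted
  a$pres_pep[] <- pres_pep
  a$dup_timer[] <- as.integer(dup_timer)
  st$agents <- b16ovasim:::agents_bind(st$agents, a)
  invisible(st)
}

# the anti-OVA receptor for a given config
ova_tcr <- function(cfg) receptor_complement(cfg$ova_peptide, cfg$nbit_str)
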