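#' Site-local interaction rules
#'
#' All interactions take place within a lattice site in a single timestep:
#' every rule reads and writes only entities co-located at the step's
#' start.  Rules operate vectorized over the whole simulation state (an
#' environment created by [sim_state_init()]); candidates competing for a
#' limited per-site resource (antigen quanta, antibody quanta, tumor cells)
#' are admitted in uniformly random order up to the site's availability.
#'
#' The six canonical rules are: B-TH cognate help (TH proliferates and
#' secretes IL-2, B proliferates and differentiates toward plasma),
#' macrophage-TH help (TH side only), cDC antigen capture with
#' cross-presentation on MHC-I and II, TC priming by presenting cDCs,
#' TC killing of B16-OVA tumor cells (IL-2 dependent, anti-CD137
#' amplified), and anti-CD137 boosting of activated TCs (cytotoxicity,
#' duplication rate and chemotaxis sensitivity).  Supporting molecular
#' events: macrophage capture of antigen and immune complexes, B-cell
#' antigen capture, immune-complex formation, plasma IgG release,
#' chemoattractant release, tumor antigen shedding, and the endothelial
#' CD137 infiltration gate consulted by movement.
#'
#' @name interactions
NULL

# admit candidates (agent indices) up to per-site availability, in random
# order; returns accepted indices
cap_accept <- function(idx, sites, avail) {
  if (length(idx) == 0L) return(integer(0))
  ord <- sample(seq_along(idx))
  idx <- idx[ord]; sites <- sites[ord]
  k <- stats::ave(rep(1L, length(idx)), sites, FUN = cumsum)
  idx[k <= avail[sites]]
}

# saturating IL-2 availability factor at given sites
il2_factor <- function(st, sites) {
  q <- st$il2[sites]
  st$cfg$IL2_eff * q / (q + st$cfg$il2_half_sat)
}

#' Tumor antigen shedding
#'
#' Each tumor cell sheds one OVA-tagged antigen quantum per step with a
#' small probability, feeding the presentation chain.
#' @param st a simulation state environment.
#' @return Invisibly, the number of shed quanta.
#' @export
rule_antigen_shed <- function(st) {
  occ <- which(st$tumor > 0L)
  if (!length(occ)) return(invisible(0L))
  shed <- stats::rbinom(length(occ), st$tumor[occ], st$cfg$antigen_shed_prob)
  st$antigen[occ] <- st$antigen[occ] + shed
  invisible(sum(shed))
}

#' Antigen capture and presentation by cDCs, macrophages and B cells
#'
#' A cDC co-located with antigen internalizes one quantum with probability
#' `prob_cDC_Ag` and cross-presents the processed peptide on MHC-I and II;
#' macrophages do the same at `prob_M_Ag` (and immune complexes at
#' `prob_M_IC`), presenting on MHC-II only; B cells bind antigen through
#' their receptor (`prob_B_Ag` times the bind probability of the match)
#' and present on MHC-II.
#'
#' @param st a simulation state environment.
#' @return Invisibly, a named count of capture events.
#' @export
rule_capture <- function(st) {
  a <- st$agents
  live <- a$state != CELL_STATES[["DEAD"]]
  has_ag <- st$antigen[a$site] > 0L
  counts <- c(dc = 0L, m_ag = 0L, m_ic = 0L, b = 0L)

  capture_into <- function(cand, prob, new_state) {
    fire <- cand[stats::runif(length(cand)) < prob]
    acc <- cap_accept(fire, a$site[fire], st$antigen)
    if (length(acc)) {
      st$antigen <- add_at(st$antigen, a$site[acc], rep(-1L, length(acc)))
      st$agents$state[acc] <- new_state
      st$agents$pres_pep[acc] <- st$cfg$ova_peptide
    }
    length(acc)
  }

  dc <- which(a$type == CELL_TYPES[["cDC"]] & live & has_ag)
  counts["dc"] <- capture_into(dc, st$cfg$prob_cDC_Ag,
                               CELL_STATES[["PRESENTING_MHC1_AND_2"]])

  a <- st$agents; has_ag <- st$antigen[a$site] > 0L
  m <- which(a$type == CELL_TYPES[["M"]] & live & has_ag)
  counts["m_ag"] <- capture_into(m, st$cfg$prob_M_Ag,
                                 CELL_STATES[["PRESENTING_MHC2"]])

  # macrophage phagocytosis of immune complexes
  if (length(st$ic$site)) {
    ic_at <- integer(st$lattice$n_sites)
    ic_at <- add_at(ic_at, st$ic$site, st$ic$qty)
    a <- st$agents
    m2 <- which(a$type == CELL_TYPES[["M"]] & a$state != CELL_STATES[["DEAD"]] &
                  ic_at[a$site] > 0L)
    fire <- m2[stats::runif(length(m2)) < st$cfg$prob_M_IC]
    acc <- cap_accept(fire, a$site[fire], ic_at)
    if (length(acc)) {
      st$agents$state[acc] <- CELL_STATES[["PRESENTING_MHC2"]]
      st$agents$pres_pep[acc] <- st$cfg$ova_peptide
      consume_sparse(st, "ic", a$site[acc])
      counts["m_ic"] <- length(acc)
    }
  }

  a <- st$agents; has_ag <- st$antigen[a$site] > 0L
  b <- which(a$type == CELL_TYPES[["B"]] & a$state == CELL_STATES[["NAIVE"]] &
               has_ag)
  if (length(b)) {
    m_match <- match_bits(a$receptor[b], st$cfg$ova_peptide,
                          st$cfg$nbit_str, st$cfg$match_mode)
    p <- st$cfg$prob_B_Ag * bind_probability(m_match, st$cfg$affinity)
    counts["b"] <- capture_into(b[stats::runif(length(b)) < p], 1,
                                CELL_STATES[["PRESENTING_MHC2"]])
  }
  invisible(counts)
}

# remove one quantum per listed site from a sparse molecule pool
consume_sparse <- function(st, pool, sites) {
  p <- st[[pool]]
  for (s in sites) {
    j <- which(p$site == s & p$qty > 0L)[1L]
    if (!is.na(j)) p$qty[j] <- p$qty[j] - 1L
  }
  keep <- p$qty > 0L
  st[[pool]] <- list(site = p$site[keep], receptor = p$receptor[keep],
                     qty = p$qty[keep])
  invisible(NULL)
}

#' Cognate help: presenting B cells / macrophages with helper T cells
#'
#' Each helper T cell co-located with a presenting B cell (or macrophage)
#' engages one random presenter; with the bind probability of the
#' receptor-peptide match the TH enters the duplicating state and secretes
#' IL-2 at the site, and (for the B-cell rule only) the presenting B cell
#' enters the duplicating state, its daughters differentiating into
#' plasma cells.
#'
#' @param st a simulation state environment.
#' @param presenter `"B"` or `"M"`.
#' @return Invisibly, the number of help events.
#' @export
rule_th_help <- function(st, presenter = c("B", "M")) {
  presenter <- match.arg(presenter)
  a <- st$agents
  ptype <- CELL_TYPES[[presenter]]
  pres <- which(a$type == ptype & a$state == CELL_STATES[["PRESENTING_MHC2"]])
  if (!length(pres)) return(invisible(0L))
  th <- which(a$type == CELL_TYPES[["TH"]] &
                a$state %in% c(CELL_STATES[["NAIVE"]], CELL_STATES[["ACTIVE"]]))
  th <- th[a$site[th] %in% a$site[pres]]
  if (!length(th)) return(invisible(0L))
  # one random presenter per site
  ord <- sample(seq_along(pres))
  site_pres <- pres[ord][!duplicated(a$site[pres][ord])]
  pick <- site_pres[match(a$site[th], a$site[site_pres])]
  pep <- a$pres_pep[pick]
  p <- bind_probability(match_bits(a$receptor[th], pep, st$cfg$nbit_str,
                                   st$cfg$match_mode), st$cfg$affinity)
  fire <- stats::runif(length(th)) < p
  if (!any(fire)) return(invisible(0L))
  thf <- th[fire]
  st$agents$state[thf] <- CELL_STATES[["DUPLICATING"]]
  st$agents$dup_timer[thf] <- st$cfg$TH_dup
  st$il2 <- add_at(st$il2, a$site[thf],
                   rep(st$cfg$il2_secrete_quanta, length(thf)))
  if (presenter == "B") {
    bf <- unique(pick[fire])
    st$agents$state[bf] <- CELL_STATES[["DUPLICATING"]]
    st$agents$dup_timer[bf] <- st$cfg$B_dup
  }
  invisible(length(thf))
}

#' Priming of naive cytotoxic T cells by presenting cDCs
#'
#' A naive TC co-located with a cDC presenting on MHC-I becomes activated
#' (primed) with the bind probability of its receptor against the
#' presented peptide.
#'
#' @param st a simulation state environment.
#' @return Invisibly, the number of priming events.
#' @export
rule_tc_prime <- function(st) {
  a <- st$agents
  dc <- which(a$type == CELL_TYPES[["cDC"]] &
                a$state == CELL_STATES[["PRESENTING_MHC1_AND_2"]])
  if (!length(dc)) return(invisible(0L))
  tc <- which(a$type == CELL_TYPES[["TC"]] & a$state == CELL_STATES[["NAIVE"]])
  tc <- tc[a$site[tc] %in% a$site[dc]]
  if (!length(tc)) return(invisible(0L))
  ord <- sample(seq_along(dc))
  site_dc <- dc[ord][!duplicated(a$site[dc][ord])]
  pick <- site_dc[match(a$site[tc], a$site[site_dc])]
  p <- bind_probability(match_bits(a$receptor[tc], a$pres_pep[pick],
                                   st$cfg$nbit_str, st$cfg$match_mode),
                        st$cfg$affinity)
  fire <- stats::runif(length(tc)) < p
  st$agents$state[tc[fire]] <- CELL_STATES[["ACTIVE"]]
  invisible(sum(fire))
}

#' Anti-CD137 boosting of activated cytotoxic T cells
#'
#' An activated TC co-located with an anti-CD137 quantum consumes one
#' quantum and becomes boosted for the rest of its life: its kill
#' probability, duplication rate and chemotaxis sensitivity are multiplied
#' by the configured factors.
#'
#' @param st a simulation state environment.
#' @return Invisibly, the number of boost events (quanta consumed).
#' @export
rule_cd137_boost <- function(st) {
  a <- st$agents
  tc <- which(a$type == CELL_TYPES[["TC"]] & !a$boosted &
                a$state %in% c(CELL_STATES[["ACTIVE"]],
                               CELL_STATES[["DUPLICATING"]]) &
                st$mab[a$site] > 0L)
  acc <- cap_accept(tc, a$site[tc], st$mab)
  if (length(acc)) {
    st$mab <- add_at(st$mab, a$site[acc], rep(-1L, length(acc)))
    st$agents$boosted[acc] <- TRUE
  }
  invisible(length(acc))
}

#' Cytotoxic killing of tumor cells
#'
#' Each effector TC (active or duplicating) on a tumor-occupied site
#' contacts up to `kill_contacts` tumor cells; each contact kills with
#' probability `bind * base_kill_prob * cd137_kill_mult^boosted * f(IL-2)`
#' where `bind` is the receptor/MHC-I-peptide bind probability and
#' `f(IL-2) = floor + (1 - floor) * IL2_eff * q / (q + k_half)` is the
#' saturating IL-2 availability factor.  Killed cells are removed from the
#' site (never below zero), release antigen debris, and successful killers
#' secrete IL-2 and may re-enter the duplicating state (restimulation).
#'
#' @param st a simulation state environment.
#' @return Invisibly, the number of tumor cells killed this call.
#' @export
rule_tc_kill <- function(st) {
  a <- st$agents
  eff <- which(a$type == CELL_TYPES[["TC"]] &
                 a$state %in% c(CELL_STATES[["ACTIVE"]],
                                CELL_STATES[["DUPLICATING"]]) &
                 st$tumor[a$site] > 0L)
  if (!length(eff)) return(invisible(0L))
  sites <- a$site[eff]
  bind <- bind_probability(match_bits(a$receptor[eff], st$cfg$ova_peptide,
                                      st$cfg$nbit_str, st$cfg$match_mode),
                           st$cfg$affinity)
  f_il2 <- st$cfg$il2_kill_floor +
    (1 - st$cfg$il2_kill_floor) * il2_factor(st, sites)
  p <- pmin(1, bind * st$cfg$base_kill_prob *
              ifelse(a$boosted[eff], st$cfg$cd137_kill_mult, 1) * f_il2)
  contacts <- pmin(st$tumor[sites], st$cfg$kill_contacts)
  kills <- stats::rbinom(length(eff), contacts, p)
  if (sum(kills) == 0L) return(invisible(0L))
  # cap per-site totals at the available tumor cells
  tot <- rowsum(kills, sites)
  at <- as.integer(rownames(tot))
  granted <- pmin(as.integer(tot[, 1L]), st$tumor[at])
  st$tumor[at] <- st$tumor[at] - granted
  st$x_t <- st$x_t - sum(granted)
  st$antigen[at] <- st$antigen[at] + granted
  # killers: IL-2 autocrine secretion and restimulation into duplication
  killer <- eff[kills > 0L]
  st$il2 <- add_at(st$il2, a$site[killer],
                   rep(st$cfg$il2_secrete_quanta, length(killer)))
  restim <- killer[a$state[killer] == CELL_STATES[["ACTIVE"]] &
                     stats::runif(length(killer)) <
                     pmin(1, st$cfg$restim_prob *
                            ifelse(a$boosted[killer], st$cfg$cd137_dup_mult, 1))]
  if (length(restim)) {
    st$agents$state[restim] <- CELL_STATES[["DUPLICATING"]]
    st$agents$dup_timer[restim] <- as.integer(round(
      st$cfg$TC_dup / ifelse(st$agents$boosted[restim],
                             st$cfg$cd137_dup_mult, 1)))
  }
  invisible(sum(granted))
}

#' Immune-complex formation and plasma IgG release
#'
#' Plasma cells release `plasma_rel_quanta` IgG quanta per step tagged with
#' their (hypermutated) receptor; IgG and antigen quanta co-located on a
#' site combine into immune complexes with the bind probability of the
#' IgG receptor against the antigen epitope (one IgG + one antigen ->
#' one IC; mass balance exact).
#'
#' @param st a simulation state environment.
#' @return Invisibly, the number of ICs formed.
#' @export
rule_humoral <- function(st) {
  a <- st$agents
  p_cells <- which(a$type == CELL_TYPES[["P"]] &
                     a$state == CELL_STATES[["PLASMA_SECRETING"]])
  if (length(p_cells)) {
    st$igg <- sparse_add(st$igg, a$site[p_cells], a$receptor[p_cells],
                         rep(st$cfg$plasma_rel_quanta, length(p_cells)))
  }
  if (!length(st$igg$site)) return(invisible(0L))
  has <- st$antigen[st$igg$site] > 0L
  if (!any(has)) return(invisible(0L))
  formed <- 0L
  idx <- which(has)[sample.int(sum(has))]
  for (j in idx) {
    s <- st$igg$site[j]
    avail <- min(st$igg$qty[j], st$antigen[s])
    if (avail <= 0L) next
    pb <- bind_probability(match_bits(st$igg$receptor[j], st$cfg$ova_peptide,
                                      st$cfg$nbit_str, st$cfg$match_mode),
                           st$cfg$affinity)
    k <- stats::rbinom(1L, avail, pb)
    if (k > 0L) {
      st$igg$qty[j] <- st$igg$qty[j] - k
      st$antigen[s] <- st$antigen[s] - k
      st$ic <- sparse_add(st$ic, s, st$igg$receptor[j], k)
      formed <- formed + k
    }
  }
  keep <- st$igg$qty > 0L
  st$igg <- list(site = st$igg$site[keep], receptor = st$igg$receptor[keep],
                 qty = st$igg$qty[keep])
  invisible(formed)
}

# add quanta to a sparse (site, receptor, qty) pool, merging duplicates
sparse_add <- function(pool, site, receptor, qty) {
  site <- c(pool$site, as.integer(site))
  receptor <- c(pool$receptor, as.integer(receptor))
  qty <- c(pool$qty, as.integer(qty))
  key <- paste(site, receptor)
  first <- !duplicated(key)
  tot <- rowsum(qty, key)
  ord <- key[first]
  list(site = site[first], receptor = receptor[first],
       qty = as.integer(tot[match(ord, rownames(tot)), 1L]))
}

#' Chemoattractant release
#'
#' Endothelial cells, presenting (activated) macrophages and activated
#' OT-1 cells release chemoattractant quanta at their sites.
#'
#' @param st a simulation state environment.
#' @return Invisibly `NULL`.
#' @export
rule_ca_release <- function(st) {
  a <- st$agents
  ep <- which(a$type == CELL_TYPES[["EP"]])
  if (length(ep)) {
    emit <- ep[stats::runif(length(ep)) < st$cfg$ca_ep_rate]
    if (length(emit)) st$ca <- add_at(st$ca, a$site[emit],
                                      rep(1L, length(emit)))
  }
  act_m <- which(a$type == CELL_TYPES[["M"]] &
                   a$state == CELL_STATES[["PRESENTING_MHC2"]])
  if (length(act_m))
    st$ca <- add_at(st$ca, a$site[act_m], rep(st$cfg$ca_m_rate, length(act_m)))
  # activated OT-1 cells release chemoattractant where they engage the
  # tumor (on or adjacent to tumor-occupied sites), recruiting peers
  ot1 <- which(a$is_ot1 & a$state %in% c(CELL_STATES[["ACTIVE"]],
                                         CELL_STATES[["DUPLICATING"]]))
  if (length(ot1)) {
    near <- logical(st$lattice$n_sites)
    t_occ <- which(st$tumor > 0L)
    if (length(t_occ)) {
      near[t_occ] <- TRUE
      nb <- as.vector(st$lattice$nbr[t_occ, ])
      near[nb[!is.na(nb)]] <- TRUE
    }
    ot1 <- ot1[near[a$site[ot1]]]
    if (length(ot1))
      st$ca <- add_at(st$ca, a$site[ot1],
                      rep(st$cfg$ca_ot1_rate, length(ot1)))
  }
  invisible(NULL)
}

#' Duplication of cells in the duplicating state
#'
#' Per step each duplicating cell creates one daughter at its site with
#' probability `min(1, max_lfact / n_same_type_here) * IL2factor`
#' (lymphocyte growth requires local IL-2 at efficiency `IL2_eff`); its
#' timer then decrements and the cell reverts to the active state at zero.
#' Daughters inherit the receptor; B-lineage daughters differentiate into
#' plasma cells with hypermutated receptors; OT-1 daughters keep the OT-1
#' flag (but must capture their own anti-CD137 quantum to be boosted).
#'
#' @param st a simulation state environment.
#' @return Invisibly, the number of daughters created.
#' @export
rule_duplicate <- function(st) {
  a <- st$agents
  dup <- which(a$state == CELL_STATES[["DUPLICATING"]] & a$dup_timer > 0L)
  born <- 0L
  if (length(dup)) {
    # local same-type crowding at the duplicating cells' sites
    key_all <- a$type * (st$lattice$n_sites + 1L) + a$site
    tab <- rowsum(rep(1L, length(key_all)), key_all)
    local_n <- as.integer(tab[match(as.character(key_all[dup]),
                                    rownames(tab)), 1L])
    p <- pmin(1, st$cfg$max_lfact / local_n) * il2_factor(st, a$site[dup])
    make <- dup[stats::runif(length(dup)) < p]
    if (length(make)) {
      d <- agents_subset(a, make)
      d$dup_timer[] <- 0L
      d$boosted[] <- FALSE
      d$pres_pep[] <- NA_integer_
      is_b <- d$type == CELL_TYPES[["B"]]
      if (any(is_b)) {
        d$type[is_b] <- CELL_TYPES[["P"]]
        d$state[is_b] <- CELL_STATES[["PLASMA_SECRETING"]]
        d$receptor[is_b] <- hypermutate(d$receptor[is_b], st$cfg$hyper_mut,
                                        st$cfg$nbit_str)
      }
      d$state[!is_b] <- CELL_STATES[["ACTIVE"]]
      st$agents <- agents_bind(st$agents, d)
      born <- length(make)
    }
    st$agents$dup_timer[dup] <- st$agents$dup_timer[dup] - 1L
    done <- dup[st$agents$dup_timer[dup] <= 0L]
    st$agents$state[done] <- CELL_STATES[["ACTIVE"]]
  }
  invisible(born)
}

#' Endothelial CD137 infiltration gate
#'
#' Probability that a cytotoxic T cell attempting to move into a
#' tumor-occupied site is admitted.  High (`infiltration_prob_wt`) only
#' when CD137 is expressed on the endothelium (wild type) and agonist
#' anti-CD137 antibody is present systemically; the endothelial-knockout
#' scenario forces the low branch (`infiltration_prob_ko`) regardless of
#' antibody.
#'
#' @param cfg a [sim_config()].
#' @param mab_present is anti-CD137 present systemically?
#' @return The admission probability.
#' @export
infiltration_gate_prob <- function(cfg, mab_present) {
  if (cfg$cd137_on_endothelium && mab_present) cfg$infiltration_prob_wt
  else cfg$infiltration_prob_ko
}
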