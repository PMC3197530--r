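#' Cell types and states
#'
#' Cellular agents carry one of the closed set of types
#' (B, TH, TC, cDC, M, EP, NK, P) and a biological state.  Plasmacytoid
#' dendritic cells are deliberately absent (they do not present antigen);
#' only conventional DCs are represented.  Tumor (B16-OVA) cells never move
#' and share a single MHC-I peptide, so the engine stores them as per-site
#' integer counts rather than individual agent rows; `CELL_TYPES` still
#' lists `TUMOR` for census and I/O purposes.
#'
#' @name cell_types
NULL

#' @rdname cell_types
#' @export
CELL_TYPES <- c(B = 1L, TH = 2L, TC = 3L, cDC = 4L, M = 5L, EP = 6L,
                NK = 7L, P = 8L, TUMOR = 9L)

#' @rdname cell_types
#' @export
CELL_STATES <- c(NAIVE = 1L, ACTIVE = 2L, PRESENTING_MHC2 = 3L,
                 PRESENTING_MHC1_AND_2 = 4L, DUPLICATING = 5L,
                 PLASMA_SECRETING = 6L, DEAD = 7L)

#' Population parameters: initial densities and half-lives
#'
#' Initial leukocyte densities (per microliter) and entity half-lives.
#' Densities are converted to agent counts by `density_scale`; the tissue
#' section has no literal volume, so the scale is the single knob mapping
#' physiological densities onto the lattice.
#'
#' @param density per-type initial density (per uL): B 260, TH 200, TC 434,
#'   cDC 351, M 351, EP 351, NK 351, P 0.
#' @param half_life_days per-entity half-life in days: all cells 3.3,
#'   IC 4.0, IL-2 1.6, chemoattractant 1.6, IgG 23, anti-CD137 23, tumor
#'   10 years (effectively immortal).
#' @param density_scale agents per (cell / uL) of density.
#' @return A list of class `population_params`.
#' @export
population_params <- function(
    density = c(B = 260, TH = 200, TC = 434, cDC = 351, M = 351,
                EP = 351, NK = 351, P = 0),
    half_life_days = c(cell = 3.3, IC = 4.0, IL2 = 1.6, CA = 1.6,
                       IgG = 23.0, TUMOR = 3650, anti_CD137 = 23.0),
    density_scale = 8.7) {
  if (any(density < 0)) stop("densities must be non-negative")
  if (any(half_life_days <= 0)) stop("half-lives must be positive")
  if (density_scale <= 0) stop("density_scale must be positive")
  structure(list(density = density, half_life_days = half_life_days,
                 density_scale = density_scale),
            class = "population_params")
}

#' Per-step death probability from a half-life
#'
#' Exponential survival: an agent (or molecular quantum) with half-life `h`
#' dies within a window `dt` with probability `1 - 2^(-dt / h)`; `h` and
#' `dt` must share units.
#'
#' @param half_life half-life (> 0).
#' @param dt window length in the same units (> 0).
#' @return Death probability in `(0, 1)`.
#' @examples
#' decay_probability(9.9, 1)  # 3.3-day half-life per 8-hour step
#' @export
decay_probability <- function(half_life, dt) {
  if (any(half_life <= 0) || any(dt <= 0))
    stop("half_life and dt must be positive")
  1 - 2^(-dt / half_life)
}

# ---- agent table ----------------------------------------------------------
# Agents live in a list of parallel vectors; rows are cells.  This is the
# performance-critical container: all per-step rules are vectorized over it.

new_agents <- function(n = 0L) {
  list(type = integer(n), state = integer(n), receptor = integer(n),
       site = integer(n), dup_timer = integer(n),
       is_ot1 = logical(n), boosted = logical(n),
       pres_pep = rep(NA_integer_, n))
}

agents_bind <- function(a, b) {
  if (agents_n(b) == 0L) return(a)
  if (agents_n(a) == 0L) return(b)
  mapply(c, a, b, SIMPLIFY = FALSE)
}

agents_subset <- function(a, keep) lapply(a, `[`, keep)

agents_n <- function(a) length(a$type)

#' Census of an agent table by type
#'
#' @param agents an internal agent table (see [initialize_populations()]).
#' @return Named integer vector over the eight leukocyte types.
#' @export
census_by_type <- function(agents) {
  out <- integer(8L)
  names(out) <- names(CELL_TYPES)[1:8]
  tab <- tabulate(agents$type, nbins = 8L)
  out[] <- tab
  out
}

#' Initialize resting leukocyte populations on the lattice
#'
#' For each type, `round(density * density_scale)` agents are created in the
#' naive state and placed uniformly at random (endothelial agents mark
#' immobile vessel sites).  Receptors are drawn uniformly from the
#' repertoire; TH and TC receptors pass thymic selection against the
#' simulation's self-peptide panel before release.
#'
#' @param params a [population_params()].
#' @param lattice a [hex_lattice()].
#' @param affinity an [affinity_params()].
#' @param self_peptides integer vector of self peptides (for thymic
#'   selection of TH/TC); `NULL` disables selection.
#' @param select_tc also apply thymic selection to TC thymocytes (default
#'   TRUE).
#' @return An agent table (list of parallel vectors).
#' @export
initialize_populations <- function(params, lattice,
                                   affinity = affinity_params(),
                                   self_peptides = NULL,
                                   select_tc = TRUE) {
  counts <- round(params$density * params$density_scale)
  total <- sum(counts)
  a <- new_agents(total)
  pos <- 1L
  for (ty in names(counts)) {
    n <- as.integer(counts[[ty]])
    if (n == 0L) next
    i <- pos:(pos + n - 1L)
    a$type[i] <- CELL_TYPES[[ty]]
    a$state[i] <- CELL_STATES[["NAIVE"]]
    a$site[i] <- sample.int(lattice$n_sites, n, replace = TRUE)
    selected <- !is.null(self_peptides) &&
      (ty == "TH" || (ty == "TC" && select_tc))
    a$receptor[i] <- draw_selected_receptors(n, affinity,
                                             if (selected) self_peptides)
    pos <- pos + n
  }
  a
}

# draw n receptors, passing thymic selection when self_peptides is given
draw_selected_receptors <- function(n, affinity, self_peptides = NULL) {
  if (n == 0L) return(integer(0))
  if (is.null(self_peptides)) return(sample_repertoire(n, affinity$nbit_str))
  out <- integer(0)
  while (length(out) < n) {
    batch <- max(n - length(out), 16L)
    # oversample: survival rate is 1 - p_auto * thym_eff
    cand <- sample_repertoire(ceiling(batch * 2.2), affinity$nbit_str)
    out <- c(out, thymic_select(cand, self_peptides, affinity))
  }
  out[seq_len(n)]
}

#' Bone-marrow homeostasis births
#'
#' Types below their initial target census are refilled toward the target:
#' expected births per step are `refill_rate * deficit` (rounded
#' stochastically).  Tumor and plasma cells are never replenished.
#'
#' @param census named census over types (see [census_by_type()]).
#' @param params a [population_params()].
#' @param refill_rate fraction of the deficit refilled per step (default 1:
#'   full refill in expectation).
#' @return Named integer vector of births per type (P forced to 0).
#' @export
apply_homeostasis <- function(census, params, refill_rate = 1) {
  target <- round(params$density * params$density_scale)
  deficit <- pmax(target[names(census)] - census, 0)
  births <- floor(deficit * refill_rate)
  frac <- deficit * refill_rate - births
  births <- births + (stats::runif(length(frac)) < frac)
  births["P"] <- 0L
  stats::setNames(as.integer(births), names(census))
}

#' Construct an adoptively transferred OT-1 cohort
#'
#' All cohort members are CD8 (TC) agents bearing the exact anti-OVA
#' receptor (the bit complement of the OVA peptide, a perfect match), with
#' the OT-1 flag set; pre-activated cohorts start in the active state,
#' naive cohorts in the naive state.
#'
#' @param n cohort size (post dose-scaling).
#' @param activated logical: antigen-activated before transfer?
#' @param ova_peptide the OVA MHC-I peptide bit-string.
#' @param nbit_str bits per receptor.
#' @return An agent table of `n` TC agents (sites unset, 0).
#' @export
make_ot1_cohort <- function(n, activated, ova_peptide, nbit_str = 12L) {
  n <- as.integer(n)
  if (n < 0L) stop("n must be non-negative")
  a <- new_agents(n)
  if (n == 0L) return(a)
  a$type[] <- CELL_TYPES[["TC"]]
  a$state[] <- if (activated) CELL_STATES[["ACTIVE"]] else CELL_STATES[["NAIVE"]]
  a$receptor[] <- receptor_complement(ova_peptide, nbit_str)
  a$is_ot1[] <- TRUE
  a
}
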