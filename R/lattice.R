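#' Hexagonal tissue lattice
#'
#' The tissue is an `L x L` hexagonal lattice (six neighbors per interior
#' site) with periodic boundary conditions left/right and rigid walls at the
#' top and bottom rows.  The full-scale reference is `L = 946` representing
#' 60 mm x 60 mm of tissue; smaller lattices represent the same physical
#' tissue at coarser resolution, so the per-site area scales as
#' `(60 / L)^2` mm^2.  Sites are indexed 1..L^2 in row-major order with
#' 0-based row `r` and column `c` (`site = r * L + c + 1`), using the
#' odd-row offset hex convention.
#'
#' @param L side length in sites (>= 4).
#' @param tissue_mm physical side length represented, in mm (default 60).
#' @return A list of class `hex_lattice` with elements `L`, `n_sites`,
#'   `nbr` (an `L^2 x 6` integer matrix of neighbor site indices, `NA`
#'   where a rigid wall truncates the neighborhood), `site_mm` (site pitch
#'   in mm) and `site_area_mm2`.
#' @examples
#' lat <- hex_lattice(8)
#' sum(!is.na(lat$nbr[1, ]))  # a top-row site has 4 neighbors
#' @export
hex_lattice <- function(L, tissue_mm = 60) {
  L <- as.integer(L)
  if (is.na(L) || L < 4L) stop("L must be an integer >= 4")
  n <- L * L
  r <- rep(0:(L - 1L), each = L)
  c <- rep(0:(L - 1L), times = L)
  wrap <- function(cc) cc %% L
  idx <- function(rr, cc) {
    out <- rr * L + wrap(cc) + 1L
    out[rr < 0L | rr >= L] <- NA_integer_
    out
  }
  odd <- r %% 2L == 1L
  # odd-r offset convention: row parity shifts the diagonal neighbors
  dc_up_a <- ifelse(odd, 0L, -1L); dc_up_b <- ifelse(odd, 1L, 0L)
  nbr <- cbind(
    idx(r, c - 1L), idx(r, c + 1L),
    idx(r - 1L, c + dc_up_a), idx(r - 1L, c + dc_up_b),
    idx(r + 1L, c + dc_up_a), idx(r + 1L, c + dc_up_b)
  )
  storage.mode(nbr) <- "integer"
  structure(list(L = L, n_sites = n, nbr = nbr,
                 tissue_mm = tissue_mm,
                 site_mm = tissue_mm / L,
                 site_area_mm2 = (tissue_mm / L)^2),
            class = "hex_lattice")
}

#' @export
print.hex_lattice <- function(x, ...) {
  cat(sprintf("<hex_lattice> %d x %d sites (%.3g mm/site, %.4g mm^2/site)\n",
              x$L, x$L, x$site_mm, x$site_area_mm2))
  cat("periodic left/right, rigid walls top/bottom\n")
  invisible(x)
}

site_row <- function(site, L) (site - 1L) %/% L
site_col <- function(site, L) (site - 1L) %% L

site_index <- function(row, col, L) as.integer(row) * L + as.integer(col) + 1L

#' Neighbors of a lattice site
#'
#' @param site site index (1-based) in the lattice.
#' @param lattice a [hex_lattice()].
#' @return Integer vector of neighbor site indices, in deterministic order;
#'   interior sites have 6, wall-row sites 4.
#' @export
neighbors <- function(site, lattice) {
  site <- as.integer(site)
  if (is.na(site) || site < 1L || site > lattice$n_sites)
    stop("site out of lattice bounds")
  v <- lattice$nbr[site, ]
  v[!is.na(v)]
}

#' Axial distance between sites in lattice units
#'
#' Euclidean distance between hex site centers (odd-row offset geometry),
#' ignoring the horizontal wrap; adequate for centroid/ring bookkeeping
#' around the central tumor.
#' @param site site index vector.
#' @param ref reference site index.
#' @param lattice a [hex_lattice()].
#' @return Numeric distances in site units.
#' @keywords internal
site_distance <- function(site, ref, lattice) {
  L <- lattice$L
  x <- site_col(site, L) + 0.5 * (site_row(site, L) %% 2L)
  y <- site_row(site, L) * sqrt(3) / 2
  xr <- site_col(ref, L) + 0.5 * (site_row(ref, L) %% 2L)
  yr <- site_row(ref, L) * sqrt(3) / 2
  sqrt((x - xr)^2 + (y - yr)^2)
}

#' Chemotaxis parameters
#'
#' Movement destinations are drawn over the current site plus its hex
#' neighborhood with weight `1 + sensitivity * CA(site)`; chemotaxis-blind
#' types use uniform weights.  Anti-CD137-boosted cytotoxic T cells multiply
#' their sensitivity by `cd137_sensitivity_boost`.
#'
#' @param base_sensitivity weight multiplier per unit chemoattractant.
#' @param cd137_sensitivity_boost extra multiplier for boosted TCs (>= 1).
#' @param ca_diffusion_fraction per-step fraction of site chemoattractant
#'   spread to neighbors.
#' @return A list of class `chemotaxis_params`.
#' @export
chemotaxis_params <- function(base_sensitivity = 1,
                              cd137_sensitivity_boost = 3,
                              ca_diffusion_fraction = 0.5) {
  if (base_sensitivity < 0 || cd137_sensitivity_boost < 0 ||
      ca_diffusion_fraction < 0 || ca_diffusion_fraction > 1)
    stop("chemotaxis parameters out of range")
  structure(list(base_sensitivity = base_sensitivity,
                 cd137_sensitivity_boost = cd137_sensitivity_boost,
                 ca_diffusion_fraction = ca_diffusion_fraction),
            class = "chemotaxis_params")
}

#' Destination probabilities for one movement hop
#'
#' @param site current site index.
#' @param lattice a [hex_lattice()].
#' @param ca per-site chemoattractant field (numeric vector, length
#'   `n_sites`).
#' @param sensitivity this agent's chemotaxis sensitivity (0 = blind).
#' @return A list with `sites` (candidate destinations, current site first)
#'   and `prob` (normalized probabilities).
#' @export
move_probabilities <- function(site, lattice, ca = NULL, sensitivity = 0) {
  cand <- c(site, neighbors(site, lattice))
  w <- rep(1, length(cand))
  if (!is.null(ca) && sensitivity > 0) w <- 1 + sensitivity * ca[cand]
  list(sites = cand, prob = w / sum(w))
}

#' Draw one movement destination
#'
#' Uses the weights of [move_probabilities()]; with a zero field or a blind
#' agent the draw is uniform over the current site and its neighbors.
#'
#' @inheritParams move_probabilities
#' @return The chosen destination site index.
#' @export
choose_move <- function(site, lattice, ca = NULL, sensitivity = 0) {
  mp <- move_probabilities(site, lattice, ca, sensitivity)
  mp$sites[sample.int(length(mp$sites), 1L, prob = mp$prob)]
}

# Vectorized movement hop for many agents at once.  Returns new site vector.
# sens: per-agent sensitivity (0 = uniform).  Gate handling is done by the
# caller (engine) which may veto individual moves.
hop_sites <- function(sites, lattice, ca = NULL, sens = NULL) {
  n <- length(sites)
  if (n == 0L) return(sites)
  cand <- cbind(sites, lattice$nbr[sites, , drop = FALSE])
  w <- matrix(1, n, 7L)
  if (!is.null(ca) && !is.null(sens) && any(sens > 0)) {
    cav <- matrix(ca[cand], n, 7L)
    w <- 1 + sens * cav
  }
  w[is.na(cand)] <- 0
  cs <- w
  for (j in 2:7) cs[, j] <- cs[, j - 1L] + w[, j]
  u <- stats::runif(n) * cs[, 7L]
  pick <- 1L + rowSums(cs[, 1:6, drop = FALSE] < u)
  cand[cbind(seq_len(n), pick)]
}

#' Conservative integer diffusion of a molecular field
#'
#' Each site exports a binomial fraction of its quanta, split multinomially
#' among its hex neighbors; the global sum is conserved exactly.
#'
#' @param field integer per-site quanta (length `n_sites`).
#' @param lattice a [hex_lattice()].
#' @param fraction expected exported fraction per step, in `[0, 1]`.
#' @return The diffused integer field.
#' @export
diffuse_field <- function(field, lattice, fraction) {
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  if (fraction == 0) return(field)
  occ <- which(field > 0L)
  if (length(occ) == 0L) return(field)
  out <- stats::rbinom(length(occ), field[occ], fraction)
  field[occ] <- field[occ] - out
  moving <- occ[out > 0L]
  out <- out[out > 0L]
  if (length(moving) == 0L) return(field)
  # multinomial split over valid neighbors, vectorized across sites via
  # sequential conditional binomials
  nb <- lattice$nbr[moving, , drop = FALSE]
  valid <- !is.na(nb)
  deg <- rowSums(valid)
  rem <- out
  left <- deg
  for (j in 1:6) {
    has <- valid[, j] & rem > 0L
    if (any(has)) {
      take <- integer(length(rem))
      take[has] <- stats::rbinom(sum(has), rem[has], 1 / left[has])
      sel <- has & take > 0L
      if (any(sel)) field <- add_at(field, nb[sel, j], take[sel])
      rem <- rem - take
    }
    left <- left - as.integer(valid[, j])
  }
  field
}

# accumulate integer `amount` onto `field` at (possibly duplicated) indices
add_at <- function(field, index, amount) {
  if (!length(index)) return(field)
  amount <- as.integer(amount)
  if (all(amount >= 0L))
    return(field + tabulate(rep.int(index, amount), nbins = length(field)))
  pos <- amount > 0L
  if (any(pos))
    field <- field + tabulate(rep.int(index[pos], amount[pos]),
                              nbins = length(field))
  neg <- amount < 0L
  field - tabulate(rep.int(index[neg], -amount[neg]), nbins = length(field))
}

#' Tumor seed placement: center site plus surrounding rings
#'
#' Returns a connected hex patch around the lattice center, large enough to
#' host `n_cells` tumor cells at `capacity` cells per site; the center site
#' comes first, then rings in order of distance.
#'
#' @param lattice a [hex_lattice()].
#' @param n_cells number of cells to host (default 1: just the center).
#' @param capacity per-site tumor cell capacity.
#' @return Integer vector of site indices (center first).
#' @export
placement_tumor_seed <- function(lattice, n_cells = 1, capacity = 1) {
  L <- lattice$L
  center <- site_index(L %/% 2L, L %/% 2L, L)
  need <- max(1L, ceiling(n_cells / capacity))
  sites <- center
  frontier <- center
  seen <- logical(lattice$n_sites)
  seen[center] <- TRUE
  while (length(sites) < need) {
    nxt <- unique(as.vector(lattice$nbr[frontier, ]))
    nxt <- nxt[!is.na(nxt) & !seen[nxt]]
    if (length(nxt) == 0L) break
    nxt <- nxt[order(site_distance(nxt, center, lattice))]
    seen[nxt] <- TRUE
    sites <- c(sites, nxt)
    frontier <- nxt
  }
  sites[seq_len(min(length(sites), max(need, 1L)))]
}

#' Wall-row placement for i.v. / i.p. payloads
#'
#' Draws `n` sites uniformly from the rigid top and bottom wall rows, the
#' boundary standing in for vasculature entry.
#'
#' @param lattice a [hex_lattice()].
#' @param n number of sites to draw (with replacement).
#' @return Integer vector of `n` site indices, all in row 0 or row `L - 1`.
#' @export
placement_iv <- function(lattice, n) {
  if (n < 0) stop("n must be non-negative")
  if (n == 0) return(integer(0))
  L <- lattice$L
  wall_sites <- c(seq_len(L), (L - 1L) * L + seq_len(L))
  wall_sites[sample.int(2L * L, n, replace = TRUE)]
}
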