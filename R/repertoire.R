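#' Bit-string receptor arithmetic
#'
#' Specific recognition (cell receptors, antibody paratopes, antigen epitopes
#' and processed peptides) is encoded as unsigned integers interpreted as
#' strings of `nbit_str` binary digits.  With the default `nbit_str = 12`
#' the potential repertoire holds `2^12 = 4096` distinct receptors.
#' "Match" between two strings is, by default, bitwise complementarity
#' (the Celada-Seiden convention): the number of positions at which the two
#' strings differ, i.e. the popcount of their XOR.  An equality convention
#' (popcount of NOT XOR) is available behind `match_mode = "identity"`.
#'
#' @name repertoire
NULL

#' Affinity parameters for bit-string recognition
#'
#' @param nbit_str number of bits per receptor (repertoire size `2^nbit_str`).
#' @param min_match minimal number of matching bits for a non-zero binding
#'   probability.
#' @param affinity_level binding probability at exactly `min_match` matching
#'   bits.
#' @param hyper_mut per-bit mutation probability per 8-hour timestep,
#'   applied to antibody-lineage daughter receptors.
#' @param thym_eff thymic selection efficiency: probability that a
#'   self-reactive thymocyte is deleted.
#' @param match_mode `"complement"` (default) counts complementary bit
#'   positions; `"identity"` counts equal positions.
#' @return A list of class `affinity_params`.
#' @examples
#' ap <- affinity_params()
#' bind_probability(9L, ap)   # 0.05 at the minimal match
#' @export
affinity_params <- function(nbit_str = 12L, min_match = 9L,
                            affinity_level = 5e-2, hyper_mut = 1e-4,
                            thym_eff = 0.999, match_mode = "complement") {
  nbit_str <- as.integer(nbit_str)
  min_match <- as.integer(min_match)
  if (nbit_str < 1L || nbit_str > 30L)
    stop("nbit_str must be in [1, 30]")
  if (min_match < 1L || min_match > nbit_str)
    stop("min_match must satisfy 0 < min_match <= nbit_str")
  if (affinity_level <= 0 || affinity_level > 1)
    stop("affinity_level must be in (0, 1]")
  if (hyper_mut < 0 || hyper_mut > 1)
    stop("hyper_mut must be in [0, 1]")
  if (thym_eff < 0 || thym_eff > 1)
    stop("thym_eff must be in [0, 1]")
  match_mode <- match.arg(match_mode, c("complement", "identity"))
  structure(list(nbit_str = nbit_str, min_match = min_match,
                 affinity_level = affinity_level, hyper_mut = hyper_mut,
                 thym_eff = thym_eff, match_mode = match_mode),
            class = "affinity_params")
}

check_receptor <- function(r, nbit_str) {
  if (any(is.na(r)) || any(r < 0) || any(r >= 2^nbit_str))
    stop("invalid receptor: values must lie in [0, 2^nbit_str)")
  invisible(r)
}

# popcount for integers < 2^30, vectorized
popcount <- function(x) {
  x <- as.integer(x)
  n <- integer(length(x))
  while (any(x > 0L)) {
    n <- n + (x %% 2L)
    x <- x %/% 2L
  }
  n
}

#' Complement of a receptor bit-string
#'
#' @param r receptor value(s) in `[0, 2^nbit_str)`.
#' @param nbit_str bits per receptor.
#' @return The bitwise complement within the `nbit_str`-bit word.
#' @export
receptor_complement <- function(r, nbit_str = 12L) {
  check_receptor(r, nbit_str)
  as.integer(2^nbit_str - 1) - as.integer(r)
}

#' Number of matching bits between two receptors
#'
#' Under the default complementarity convention this is the number of bit
#' positions at which `r1` and `r2` differ; under `"identity"` the number at
#' which they agree.  Symmetric in its arguments, bounded by `nbit_str`.
#'
#' @param r1,r2 receptor values (vectorized, recycled).
#' @param nbit_str bits per receptor.
#' @param match_mode `"complement"` or `"identity"`.
#' @return Integer match count(s) in `[0, nbit_str]`.
#' @examples
#' match_bits(0L, 4095L)  # 12: exact complement
#' match_bits(5L, 5L)     # 0: no position complements itself
#' @export
match_bits <- function(r1, r2, nbit_str = 12L, match_mode = "complement") {
  check_receptor(r1, nbit_str)
  check_receptor(r2, nbit_str)
  d <- popcount(bitwXor(as.integer(r1), as.integer(r2)))
  if (match_mode == "identity") as.integer(nbit_str) - d else d
}

#' Binding probability from a match count
#'
#' Zero below `min_match`, `affinity_level` at `min_match`, and geometric
#' interpolation up to 1 at a perfect match:
#' `p(m) = affinity_level^((nbit_str - m) / (nbit_str - min_match))`.
#' When `min_match == nbit_str` only the perfect match binds, with
#' probability `affinity_level`.
#'
#' @param match integer match count(s) in `[0, nbit_str]`.
#' @param params an [affinity_params()] object.
#' @return Binding probability/ies in `[0, 1]`, monotone non-decreasing in
#'   `match`.
#' @export
bind_probability <- function(match, params = affinity_params()) {
  match <- as.integer(match)
  if (any(is.na(match)) || any(match < 0L) || any(match > params$nbit_str))
    stop("match must lie in [0, nbit_str]")
  p <- numeric(length(match))
  ok <- match >= params$min_match
  if (params$min_match == params$nbit_str) {
    p[ok] <- params$affinity_level
  } else {
    expo <- (params$nbit_str - match[ok]) / (params$nbit_str - params$min_match)
    p[ok] <- params$affinity_level^expo
  }
  p
}

#' Per-bit hypermutation of receptors
#'
#' Each bit flips independently with probability `hyper_mut`; the expected
#' number of flipped bits per invocation is `nbit_str * hyper_mut`.  Applied
#' to antibody-producing lineages (B/plasma daughter receptors).
#'
#' @param r receptor value(s).
#' @param hyper_mut per-bit flip probability.
#' @param nbit_str bits per receptor.
#' @return Mutated receptor value(s).
#' @export
hypermutate <- function(r, hyper_mut = 1e-4, nbit_str = 12L) {
  check_receptor(r, nbit_str)
  r <- as.integer(r)
  if (hyper_mut <= 0) return(r)
  n <- length(r)
  flips <- matrix(stats::runif(n * nbit_str) < hyper_mut, nrow = n)
  mask <- as.integer(flips %*% 2^(0:(nbit_str - 1L)))
  bitwXor(r, mask)
}

#' Uniform draw from the potential repertoire
#'
#' @param n number of receptors to draw.
#' @param nbit_str bits per receptor; draws are uniform with replacement
#'   over `[0, 2^nbit_str)`.
#' @return Integer vector of `n` receptor values.
#' @export
sample_repertoire <- function(n, nbit_str = 12L) {
  if (n < 0) stop("n must be non-negative")
  if (n == 0) return(integer(0))
  sample.int(2^nbit_str, n, replace = TRUE) - 1L
}

#' Thymic negative selection of thymocytes
#'
#' A thymocyte whose best match against any self peptide reaches
#' `min_match` is self-reactive and is deleted with probability `thym_eff`;
#' survivors are returned in their original order.  With the default
#' `thym_eff = 99.9%` and the default self-peptide panel the released
#' self-reactive fraction stays below 0.1%.
#'
#' @param thymocytes integer vector of receptor values (may be empty).
#' @param self_peptides non-empty integer vector of self-peptide receptors.
#' @param params an [affinity_params()] object.
#' @return The surviving receptors (a subset of `thymocytes`, order
#'   preserved).
#' @export
thymic_select <- function(thymocytes, self_peptides,
                          params = affinity_params()) {
  if (length(self_peptides) == 0) stop("self-peptide set must be non-empty")
  if (length(thymocytes) == 0) return(integer(0))
  reactive <- is_self_reactive(thymocytes, self_peptides, params)
  del <- reactive & (stats::runif(length(thymocytes)) < params$thym_eff)
  thymocytes[!del]
}

#' Self-reactivity indicator
#'
#' @param receptors integer vector of receptor values.
#' @param self_peptides integer vector of self peptides.
#' @param params an [affinity_params()] object.
#' @return Logical vector: does the best self-match reach `min_match`?
#' @export
is_self_reactive <- function(receptors, self_peptides,
                             params = affinity_params()) {
  check_receptor(receptors, params$nbit_str)
  check_receptor(self_peptides, params$nbit_str)
  out <- rep(FALSE, length(receptors))
  for (sp in self_peptides) {
    out <- out | (match_bits(receptors, sp, params$nbit_str,
                             params$match_mode) >= params$min_match)
  }
  out
}
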