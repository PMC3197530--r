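test_that("cDC antigen capture fires at prob_cDC_Ag and cross-presents", {
  set.seed(21)
  st <- blank_state()
  site <- st$center
  n <- 4000L
  put_agents(st, n, "cDC", "NAIVE", site)
  st$antigen[site] <- n
  rule_capture(st)
  fired <- sum(st$agents$state == CELL_STATES[["PRESENTING_MHC1_AND_2"]])
  expect_lt(abs(fired / n - 0.02), 3 * sqrt(0.02 * 0.98 / n))
  expect_identical(st$antigen[site], n - fired)       # one quantum per event
  expect_true(all(st$agents$pres_pep[
    st$agents$state == CELL_STATES[["PRESENTING_MHC1_AND_2"]]] ==
      st$cfg$ova_peptide))
  # no antigen at the site: no event
  st2 <- blank_state()
  put_agent(st2, "cDC", "NAIVE", st2$center)
  rule_capture(st2)
  expect_identical(st2$agents$state[1], CELL_STATES[["NAIVE"]])
})

test_that("macrophage capture fires at its own rates, presenting MHC-II only", {
  set.seed(22)
  st <- blank_state()
  site <- st$center
  n <- 4000L
  put_agents(st, n, "M", "NAIVE", site)
  st$antigen[site] <- n
  rule_capture(st)
  fired <- sum(st$agents$state == CELL_STATES[["PRESENTING_MHC2"]])
  expect_lt(abs(fired / n - 0.01), 3 * sqrt(0.01 * 0.99 / n))
  expect_identical(sum(st$agents$state ==
                         CELL_STATES[["PRESENTING_MHC1_AND_2"]]), 0L)
  # immune complexes are taken up ten times faster
  st2 <- blank_state()
  put_agents(st2, n, "M", "NAIVE", st2$center)
  st2$ic <- list(site = st2$center, receptor = 0L, qty = n)
  rule_capture(st2)
  fired_ic <- sum(st2$agents$state == CELL_STATES[["PRESENTING_MHC2"]])
  expect_lt(abs(fired_ic / n - 0.1), 3 * sqrt(0.1 * 0.9 / n))
})

test_that("cognate B-TH help needs the match, secretes IL-2, makes plasma", {
  cfg_pep <- sim_config()$ova_peptide
  run_help <- function(th_receptor) {
    st <- blank_state()
    site <- st$center
    put_agent(st, "B", "PRESENTING_MHC2", site, pres_pep = cfg_pep)
    ith <- put_agent(st, "TH", "NAIVE", site, receptor = th_receptor)
    rule_th_help(st, "B")
    st
  }
  set.seed(25)
  # perfect match: fires with probability 1
  st <- run_help(receptor_complement(cfg_pep))
  expect_identical(st$agents$state[2], CELL_STATES[["DUPLICATING"]])
  expect_identical(st$agents$dup_timer[2], 16L)
  expect_identical(st$agents$state[1], CELL_STATES[["DUPLICATING"]])
  expect_gt(st$il2[st$center], 0L)                 # IL-2 strictly increases
  # a plasma cell appears within B_dup + 1 steps of duplication
  st$il2[st$center] <- 100L
  for (i in 1:17) rule_duplicate(st)
  expect_gt(sum(st$agents$type == CELL_TYPES[["P"]]), 0L)
  # match below min_match never fires
  st2 <- run_help(cfg_pep %% 8L)  # low-complementarity receptor
  m <- match_bits(cfg_pep %% 8L, cfg_pep)
  if (m < 9L) expect_identical(st2$agents$state[2], CELL_STATES[["NAIVE"]])
})

test_that("macrophage-TH help stimulates the TH side only", {
  set.seed(26)
  pep <- sim_config()$ova_peptide
  st <- blank_state()
  put_agent(st, "M", "PRESENTING_MHC2", st$center, pres_pep = pep)
  put_agent(st, "TH", "NAIVE", st$center,
            receptor = receptor_complement(pep))
  rule_th_help(st, "M")
  expect_identical(st$agents$state[2], CELL_STATES[["DUPLICATING"]])
  expect_identical(st$agents$state[1], CELL_STATES[["PRESENTING_MHC2"]])
  expect_gt(st$il2[st$center], 0L)
  expect_identical(sum(st$agents$type == CELL_TYPES[["P"]]), 0L)
})

test_that("TC priming requires a presenting cDC, naivety and the match", {
  pep <- sim_config()$ova_peptide
  set.seed(27)
  st <- blank_state()
  put_agent(st, "cDC", "PRESENTING_MHC1_AND_2", st$center, pres_pep = pep)
  itc <- put_agent(st, "TC", "NAIVE", st$center,
                   receptor = receptor_complement(pep), is_ot1 = TRUE)
  rule_tc_prime(st)
  expect_identical(st$agents$state[itc], CELL_STATES[["ACTIVE"]])
  # an already-active TC is not re-primed (state unchanged by this rule)
  st2 <- blank_state()
  put_agent(st2, "cDC", "PRESENTING_MHC1_AND_2", st2$center, pres_pep = pep)
  put_agent(st2, "TC", "ACTIVE", st2$center,
            receptor = receptor_complement(pep))
  rule_tc_prime(st2)
  expect_identical(st2$agents$state[2], CELL_STATES[["ACTIVE"]])
  # weak match stays naive
  st3 <- blank_state()
  put_agent(st3, "cDC", "PRESENTING_MHC1_AND_2", st3$center, pres_pep = 0L)
  put_agent(st3, "TC", "NAIVE", st3$center, receptor = 255L)  # match 8
  rule_tc_prime(st3)
  expect_identical(st3$agents$state[2], CELL_STATES[["NAIVE"]])
})

test_that("anti-CD137 boosting consumes one quantum and needs activation", {
  set.seed(28)
  st <- blank_state()
  itc <- put_agent(st, "TC", "ACTIVE", st$center)
  inv <- put_agent(st, "TC", "NAIVE", st$center)
  st$mab[st$center] <- 3L
  rule_cd137_boost(st)
  expect_true(st$agents$boosted[itc])
  expect_false(st$agents$boosted[inv])              # naive cells unaffected
  expect_identical(st$mab[st$center], 2L)           # exactly one consumed
  # consumption is capped by available quanta
  st2 <- blank_state()
  for (i in 1:5) put_agent(st2, "TC", "ACTIVE", st2$center)
  st2$mab[st2$center] <- 2L
  rule_cd137_boost(st2)
  expect_identical(sum(st2$agents$boosted), 2L)
  expect_identical(st2$mab[st2$center], 0L)
})

test_that("tumor killing: activation, match and boost set the rate", {
  pep <- sim_config()$ova_peptide
  kill_run <- function(state, boosted, receptor, n = 2000L, il2 = 1000L) {
    set.seed(29)
    st <- blank_state()
    st$tumor[st$center] <- 200000L
    st$x_t <- 200000
    st$il2[st$center] <- il2
    put_agents(st, n, "TC", state, st$center, receptor = receptor,
               boosted = boosted)
    k <- rule_tc_kill(st)
    expect_identical(200000L - st$tumor[st$center], k)  # bookkeeping
    k / n
  }
  anti <- receptor_complement(pep)
  k_boost <- kill_run("ACTIVE", TRUE, anti)
  k_plain <- kill_run("ACTIVE", FALSE, anti)
  expect_gt(k_boost, k_plain)         # boost strictly increases killing
  expect_gt(k_plain, 0)
  # naive cells never kill; weak matches never kill
  expect_identical(kill_run("NAIVE", TRUE, anti), 0)
  weak <- 255L  # match 8 vs default peptide
  if (match_bits(weak, pep) < 9L)
    expect_identical(kill_run("ACTIVE", TRUE, weak), 0)
})

test_that("kills are capped by the tumor cells present at the site", {
  set.seed(30)
  st <- blank_state()
  st$tumor[st$center] <- 10L
  st$x_t <- 10
  st$il2[st$center] <- 1000L
  anti <- receptor_complement(st$cfg$ova_peptide)
  put_agents(st, 500L, "TC", "ACTIVE", st$center, receptor = anti,
             boosted = TRUE)
  k <- rule_tc_kill(st)
  expect_identical(k, 10L)
  expect_identical(st$tumor[st$center], 0L)
  expect_gte(st$antigen[st$center], 10L)   # debris released as antigen
})

test_that("immune-complex formation conserves quanta exactly", {
  set.seed(33)
  st <- blank_state()
  s <- st$center
  anti <- receptor_complement(st$cfg$ova_peptide)
  st$igg <- list(site = s, receptor = anti, qty = 500L)
  st$antigen[s] <- 300L
  before <- 500L + 300L
  formed <- rule_humoral(st)
  expect_identical(formed, 300L)    # perfect match binds with probability 1
  igg_left <- if (length(st$igg$qty)) sum(st$igg$qty) else 0L
  expect_identical(igg_left, 200L)
  expect_identical(st$antigen[s], 0L)
  expect_identical(sum(st$ic$qty), 300L)
  expect_identical(igg_left + st$antigen[s] + 2L * sum(st$ic$qty),
                   before)          # each IC holds one IgG + one antigen
})

test_that("plasma cells release IgG quanta each step", {
  st <- blank_state()
  put_agent(st, "P", "PLASMA_SECRETING", st$center, receptor = 123L)
  rule_humoral(st)
  rule_humoral(st)
  expect_identical(sum(st$igg$qty), 2L * st$cfg$plasma_rel_quanta)
  expect_identical(st$igg$receptor[1], 123L)
})

test_that("duplication rate follows crowding and IL-2 availability", {
  # saturating IL-2 and a lone duplicating cell: division certain
  st <- blank_state()
  put_agent(st, "TC", "DUPLICATING", st$center, dup_timer = 16L)
  st$il2[st$center] <- 100000L
  set.seed(35)
  born <- rule_duplicate(st)
  expect_identical(born, 1L)
  expect_identical(st$agents$dup_timer[1], 15L)
  d <- b16ovasim:::agents_n(st$agents)
  expect_identical(st$agents$state[d], CELL_STATES[["ACTIVE"]])
  expect_false(st$agents$boosted[d])   # daughters must earn their own boost
  # no IL-2, no lymphocyte division
  st2 <- blank_state()
  put_agent(st2, "TC", "DUPLICATING", st2$center, dup_timer = 16L)
  expect_identical(rule_duplicate(st2), 0L)
  # timer expiry reverts to ACTIVE after dup steps
  st3 <- blank_state()
  put_agent(st3, "TH", "DUPLICATING", st3$center, dup_timer = 16L)
  for (i in 1:16) rule_duplicate(st3)
  expect_identical(st3$agents$state[1], CELL_STATES[["ACTIVE"]])
})

test_that("crowding throttles division at max_lfact over the local count", {
  set.seed(36)
  n <- 1000L
  st <- blank_state()
  put_agents(st, n, "TC", "DUPLICATING", st$center, dup_timer = 4L)
  st$il2[st$center] <- 1e6L
  born <- rule_duplicate(st)
  p_expect <- min(1, st$cfg$max_lfact / n)  # ~0.005
  expect_lt(abs(born / n - p_expect), 3 * sqrt(p_expect / n) + 0.002)
})

test_that("the infiltration gate opens only for wild type plus antibody", {
  cfg_wt <- sim_config()
  cfg_ko <- sim_config(cd137_on_endothelium = FALSE)
  expect_identical(infiltration_gate_prob(cfg_wt, TRUE),
                   cfg_wt$infiltration_prob_wt)
  expect_identical(infiltration_gate_prob(cfg_wt, FALSE),
                   cfg_wt$infiltration_prob_ko)
  expect_identical(infiltration_gate_prob(cfg_ko, TRUE),
                   cfg_ko$infiltration_prob_ko)
  expect_gt(cfg_wt$infiltration_prob_wt, cfg_wt$infiltration_prob_ko)
})

test_that("interaction rules are strictly site-local", {
  # actors on different sites never interact: same setup as the firing
  # tests but with the partners one site apart
  pep <- sim_config()$ova_peptide
  st <- blank_state()
  other <- neighbors(st$center, st$lattice)[1]
  put_agent(st, "B", "PRESENTING_MHC2", st$center, pres_pep = pep)
  put_agent(st, "TH", "NAIVE", other, receptor = receptor_complement(pep))
  put_agent(st, "cDC", "PRESENTING_MHC1_AND_2", st$center, pres_pep = pep)
  put_agent(st, "TC", "NAIVE", other, receptor = receptor_complement(pep))
  itc <- put_agent(st, "TC", "ACTIVE", other,
                   receptor = receptor_complement(pep), boosted = TRUE)
  st$tumor[st$center] <- 100L; st$x_t <- 100
  st$il2[st$center] <- 100L
  st$mab[st$center] <- 5L
  set.seed(37)
  rule_th_help(st, "B")
  rule_tc_prime(st)
  rule_cd137_boost(st)
  k <- rule_tc_kill(st)
  expect_identical(st$agents$state[2], CELL_STATES[["NAIVE"]])   # TH
  expect_identical(st$agents$state[4], CELL_STATES[["NAIVE"]])   # TC
  expect_false(st$agents$boosted[4])
  expect_identical(k, 0L)                                        # no kills
  expect_identical(st$tumor[st$center], 100L)
  expect_identical(st$mab[st$center], 5L)
})
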