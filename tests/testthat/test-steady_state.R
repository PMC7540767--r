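test_that("viability matches direct substitution", {
  pr <- base_params()
  expect_equal(viability(0.5, 1e-2, B = 5e7, P = 1e7, params = pr), 0.149,
               tolerance = 1e-12)
  # empty ecosystem: f reduces to gamma - alpha
  expect_equal(viability(0.7, 0.3, 0, 0, pr), 0.6, tolerance = 1e-12)
  # perfect defence: independent of phage pressure
  expect_equal(viability(0.5, 0, 4e7, 1e9, pr),
               viability(0.5, 0, 4e7, 0, pr), tolerance = 1e-12)
})

test_that("single perfectly defended strain settles at delta/(eta(beta-1))", {
  pr <- base_params()
  ss <- solve_steady_state(strain_params(0.5, 0), pr)
  expect_equal(ss$B, single_strain_density(pr), tolerance = 1e-9)
  expect_equal(ss$b, ss$B)
  # the same closed form holds for any omega < 1 when a single pair
  # coexists (the cross-infection terms cancel)
  ss2 <- solve_steady_state(strain_params(0.8, 0.3), pr)
  expect_equal(ss2$B, single_strain_density(pr), tolerance = 1e-9)
})

test_that("empty and degenerate strain sets are handled", {
  pr <- base_params()
  ss <- solve_steady_state(strain_params(), pr)
  expect_equal(ss$B, 0)
  expect_equal(ss$P, 0)
  expect_length(ss$survivors, 0)
  # a strain slower than the dilution rate cannot persist
  dead <- solve_steady_state(strain_params(0.05, 0.01), pr)
  expect_equal(dead$B, 0)
  expect_error(solve_steady_state(strain_params(0.5, 1), pr), "omega")
})

test_that("returned steady states are fixed points of the dynamics", {
  pr <- base_params()
  set.seed(21)
  for (rep in 1:10) {
    s <- sample_uncorrelated(sample(2:8, 1))
    ss <- prune_to_feasible(s, pr)
    if (!length(ss$survivors)) next
    st <- ecosystem_state(ss$strains, ss$b, ss$p)
    r <- ode_rhs(st, pr)
    scale <- pmax(abs(c(st$b, st$p)), 1)
    expect_lt(max(abs(c(r$db, r$dp)) / scale), 1e-6)
    # self-consistency up to the root-finding tolerance on B
    expect_equal(sum(ss$b), ss$B, tolerance = 1e-9)
    expect_equal(sum(ss$p), ss$P, tolerance = 1e-9)
    # every survivor is strictly viable at the ambient densities
    f <- viability(ss$strains$gamma, ss$strains$omega, ss$B, ss$P, pr)
    expect_true(all(f > 0))
  }
})

test_that("pruning removes exactly the non-viable strains", {
  pr <- base_params()
  s <- demo_strains()
  ss <- prune_to_feasible(s, pr)
  expect_length(attr(ss, "removed"), 0)  # all three are jointly viable
  expect_setequal(attr(ss, "kept"), 1:3)
  # an added strain slower than dilution is always culled
  s2 <- rbind(s, strain_params(0.05, 0.001))
  ss2 <- prune_to_feasible(s2, pr)
  expect_true(4 %in% attr(ss2, "removed"))
  expect_setequal(attr(ss2, "kept"), 1:3)
  expect_equal(ss2$B, ss$B, tolerance = 1e-9)
  # empty survivor set is representable
  ss3 <- prune_to_feasible(strain_params(0.01, 0.5), pr)
  expect_length(ss3$survivors, 0)
})

test_that("phage-free fallback reduces to competitive exclusion", {
  # a large phage decay rate prevents phage persistence entirely
  pr <- eco_params(delta = 1e4)
  # single strain: no coexistence root exists below the logistic cap,
  # so the phage-free branch is returned directly
  one <- solve_steady_state(strain_params(0.9, 0.01), pr)
  expect_true(one$phage_free)
  expect_equal(one$P, 0)
  expect_equal(one$B, pr$C * (1 - pr$alpha / 0.9), tolerance = 1e-12)
  # several strains: pruning removes all but the fastest grower, which
  # settles at its logistic capacity (competitive exclusion)
  s <- strain_params(c(0.9, 0.5), c(0.01, 0.001))
  ss <- prune_to_feasible(s, pr)
  expect_true(ss$phage_free)
  expect_equal(ss$P, 0)
  expect_equal(ss$B, pr$C * (1 - pr$alpha / 0.9), tolerance = 1e-12)
  expect_equal(attr(ss, "kept"), 1L)
})

test_that("iterative assembly follows the acceptance rule from round one", {
  pr <- base_params()
  # first draw grows faster than dilution: accepted, D = 1
  ok <- iterative_evolution(function(n) strain_params(rep(0.6, n),
                                                      rep(0.01, n)),
                            n_rounds = 1, pr)
  expect_equal(ok$D, 1L)
  expect_equal(ok$B[1], single_strain_density(pr), tolerance = 1e-9)
  # first draw slower than dilution: rejected, D stays 0
  no <- iterative_evolution(function(n) strain_params(rep(0.05, n),
                                                      rep(0.01, n)),
                            n_rounds = 3, pr)
  expect_equal(no$D, rep(0L, 3))
  expect_false(any(no$accepted))
})

test_that("assembly record is reproducible and monotone in total density", {
  pr <- base_params()
  sam <- make_sampler("correlated_product")
  r1 <- iterative_evolution(sam, 400, pr, seed = 33)
  r2 <- iterative_evolution(sam, 400, pr, seed = 33)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_equal(r1$time, r1$round * pr$T)
  # the viability frontier only constricts: B never decreases except
  # when an acceptance displaces residents (removal events)
  dB <- diff(r1$B)
  no_removal <- r1$n_removed[-1] == 0
  expect_true(all(dB[no_removal] >= -1e-6 * pmax(r1$B[-nrow(r1)], 1)[no_removal]))
  # diversity only changes on accepted rounds
  dD <- diff(r1$D)
  expect_true(all(dD[!r1$accepted[-1]] == 0))
})

test_that("survivor biomass increases with the gamma'/omega ratio", {
  pr <- base_params()
  sam <- make_sampler("correlated_product")
  rec <- iterative_evolution(sam, 1500, pr, seed = 2)
  fin <- attr(rec, "final")
  expect_gt(nrow(fin), 10)
  gp <- fin$gamma * (1 - rec$B[nrow(rec)] / pr$C) - pr$alpha
  rho <- cor(fin$b, gp / fin$omega, method = "spearman")
  expect_gt(rho, 0.95)
})
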