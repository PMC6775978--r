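sp <- species_table()
rx <- shipped_reactions()
jdfr <- fluid_profile("jdfr")

test_that("standard Gibbs energy is the signed formation sum at 298.15 K", {
  f <- toy_species_file(dGf = c(A = 0, B = -10), dHf = c(A = 5, B = 5))
  toy_sp <- species_table(f)
  expect_equal(standard_gibbs(toy_reaction(), toy_sp, 298.15), -10)
})

test_that("temperature correction follows Gibbs-Helmholtz with constant dH", {
  # equal formation enthalpies => dH0_r = 0 => dG0 scales as T/Tref
  f <- toy_species_file(dGf = c(A = 0, B = -10), dHf = c(A = 42, B = 42))
  toy_sp <- species_table(f)
  expect_equal(standard_gibbs(toy_reaction(), toy_sp, 337.15),
               (337.15 / 298.15) * -10, tolerance = 1e-9)
})

test_that("standard_gibbs matches the brute-force oracle on shipped reactions", {
  for (r in rx) {
    for (T_K in c(298.15, 337.15)) {
      expect_equal(standard_gibbs(r, sp, T_K),
                   oracle_standard_gibbs(r, sp, T_K), tolerance = 1e-9)
    }
  }
})

test_that("missing formation properties name the offending species", {
  f <- toy_species_file(dGf = c(A = 0, B = NA), dHf = c(A = 0, B = 0))
  toy_sp <- species_table(f)
  expect_error(standard_gibbs(toy_reaction(), toy_sp, 298.15), "B")
})

test_that("activity coefficients follow the Davies closed form", {
  expect_identical(activity_coefficient(0, 0.7, model = "davies"), 1)
  expect_identical(activity_coefficient(-2, 0, model = "davies"), 1)
  expect_identical(activity_coefficient(-2, 0.7, model = "ideal"), 1)
  I <- 0.1
  expected <- 10^(-0.509 * 1 * (sqrt(I) / (1 + sqrt(I)) - 0.3 * I))
  expect_equal(activity_coefficient(-1, I, model = "davies"), expected,
               tolerance = 1e-12)
  expect_error(activity_coefficient(1, -0.1), ">= 0")
})

test_that("reaction quotient reduces to 0 at unit activities and sums logs", {
  cond1 <- unit_conditions(rownames(sp))
  expect_equal(reaction_quotient(rx$co_sulfate, cond1, sp), 0,
               tolerance = 1e-12)
  f <- toy_species_file()
  toy_sp <- species_table(f)
  cond <- fluid_conditions(298.15, c(A = 1, B = exp(1)), pH = 7)
  expect_equal(reaction_quotient(toy_reaction(), cond, toy_sp), 1,
               tolerance = 1e-12)
})

test_that("reaction quotient matches the brute-force oracle (both models)", {
  for (model in c("ideal", "davies")) {
    cond <- fluid_profile("jdfr", activity_model = model)
    for (r in rx) {
      expect_equal(reaction_quotient(r, cond, sp),
                   oracle_lnq(r, sp, cond), tolerance = 1e-9)
    }
  }
})

test_that("missing concentrations are reported by species name", {
  cond <- fluid_conditions(337.15, c(`SO4-2` = 0.018), pH = 7.5)
  expect_error(reaction_quotient(rx$co_sulfate, cond, sp), "CO")
})

test_that("dG is zero at constructed equilibrium", {
  f <- toy_species_file(dGf = c(A = 0, B = -10), dHf = c(A = 3, B = -8))
  toy_sp <- species_table(f)
  for (T_K in c(298.15, 310, 337.15)) {
    dG0 <- standard_gibbs(toy_reaction(), toy_sp, T_K)
    # a(B)/a(A) = exp(-dG0/RT) makes lnQ = -dG0/RT exactly
    aB <- exp(-dG0 / (8.314462618e-3 * T_K))
    cond <- fluid_conditions(T_K, c(A = 1, B = aB), pH = 7)
    e <- gibbs_energy(toy_reaction(), cond, toy_sp)
    expect_lt(abs(e$dG), 1e-9)
  }
})

test_that("per-electron yield is invariant under reaction scaling", {
  k <- 3
  base <- rx$co_sulfate
  scaled <- reaction("co_scaled", base$stoichiometry * k,
                     base$n_electrons * k, base$donor, base$acceptor)
  e1 <- gibbs_energy(base, jdfr, sp)
  e2 <- gibbs_energy(scaled, jdfr, sp)
  expect_equal(e2$dG, k * e1$dG, tolerance = 1e-9)
  expect_equal(e2$dG_per_electron, e1$dG_per_electron, tolerance = 1e-9)
})

test_that("Gibbs energies are additive over summed reactions", {
  r1 <- rx$co_sulfate
  r2 <- rx$h2_sulfate
  all_sp <- union(names(r1$stoichiometry), names(r2$stoichiometry))
  s <- stats::setNames(rep(0, length(all_sp)), all_sp)
  s[names(r1$stoichiometry)] <- s[names(r1$stoichiometry)] + r1$stoichiometry
  s[names(r2$stoichiometry)] <- s[names(r2$stoichiometry)] + r2$stoichiometry
  s <- s[s != 0]
  combined <- reaction("combined", s, r1$n_electrons + r2$n_electrons,
                       donor = "CO", acceptor = "SO4-2")
  e <- gibbs_energy(combined, jdfr, sp)
  e1 <- gibbs_energy(r1, jdfr, sp)
  e2 <- gibbs_energy(r2, jdfr, sp)
  expect_equal(e$dG, e1$dG + e2$dG, tolerance = 1e-9)
})

test_that("donor sweep matches the closed-form decrement and is monotone", {
  sw <- sweep_donor(rx$co_sulfate, jdfr, c(1e-8, 1e-6, 1e-4), sp)
  nu_d <- rx$co_sulfate$stoichiometry[["CO"]]
  closed <- nu_d * 8.314462618e-3 * 337.15 * log(1e4) / 8
  expect_equal(sw$dG_per_electron[3] - sw$dG_per_electron[1], closed,
               tolerance = 1e-6)
  expect_true(all(diff(sw$dG_per_electron) < 0))
})

test_that("a single-point sweep agrees with gibbs_energy", {
  base_co <- jdfr$concentrations[["CO"]]
  sw <- sweep_donor(rx$co_sulfate, jdfr, base_co, sp)
  e <- gibbs_energy(rx$co_sulfate, jdfr, sp)
  expect_equal(sw$dG_per_electron, e$dG_per_electron, tolerance = 1e-12)
})

test_that("sweep rejects bad grids", {
  expect_error(sweep_donor(rx$co_sulfate, jdfr, numeric(), sp), "empty")
  expect_error(sweep_donor(rx$co_sulfate, jdfr, c(1e-6, 1e-8), sp),
               "increasing")
  expect_error(sweep_donor(rx$co_sulfate, jdfr, c(-1e-6, 1e-5), sp),
               "positive")
})

test_that("CO-sulfate ranks most exergonic per electron across the sweep", {
  for (m in 10^seq(-8, -4, length.out = 9)) {
    ranking <- rank_donors(rx, jdfr, m, sp)
    expect_identical(ranking$reaction_id[1], "co_sulfate")
    expect_true(all(diff(ranking$dG_per_electron) >= 0))
  }
})

test_that("donor ranking breaks ties lexicographically", {
  base <- rx$co_sulfate
  twins <- list(
    reaction("b", base$stoichiometry, base$n_electrons, base$donor,
             base$acceptor),
    reaction("a", base$stoichiometry, base$n_electrons, base$donor,
             base$acceptor))
  ranking <- rank_donors(twins, jdfr, 1e-6, sp)
  expect_identical(ranking$reaction_id, c("a", "b"))
  one <- rank_donors(list(base), jdfr, 1e-6, sp)
  expect_identical(one$reaction_id, "co_sulfate")
})

test_that("the jdfr profile carries the field-constrained conditions", {
  expect_equal(jdfr$temperature, 337.15)
  expect_equal(jdfr$concentrations[["SO4-2"]], 0.018)
  over <- fluid_profile("jdfr", `SO4-2` = 0.028, temperature = 310)
  expect_equal(over$concentrations[["SO4-2"]], 0.028)
  expect_equal(over$temperature, 310)
  expect_error(fluid_profile("atlantis"), "jdfr")
})

test_that("fluid conditions validate their inputs", {
  expect_error(fluid_conditions(270, c(A = 1), pH = 7), "273")
  expect_error(fluid_conditions(300, c(A = 0), pH = 7), "positive")
  expect_error(fluid_conditions(300, c(A = 1), pH = 7,
                                ionic_strength = -1), ">= 0")
})
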