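# Species construction, charge scaling and pair-parameter rules.

test_that("charge scaling multiplies every site charge and preserves neutrality", {
  w <- water_tip4p2005()
  pes <- w$charge_sets$PES
  ecs <- scale_charges(pes, 0.965)
  # published TIP4P/2005 hydrogen charge times the ECS factor
  expect_equal(ecs$charges[2], 0.5564 * 0.965)
  expect_equal(ecs$charges[2], 0.53693, tolerance = 1e-4)
  # 2 q_H + q_M = 0 before and after scaling
  expect_equal(sum(pes$charges), 0)
  expect_equal(sum(ecs$charges), 0)
  # identity and order preservation
  expect_equal(scale_charges(pes, 1)$charges, pes$charges)
  expect_length(ecs$charges, length(pes$charges))
})

test_that("charge scaling is linear in the factor", {
  cs <- charge_set("PES", c(0.4, -0.3, -0.1))
  for (ab in list(c(0.5, 1.3), c(0.965, 2), c(3, 1 / 3))) {
    twice <- scale_charges(scale_charges(cs, ab[1]), ab[2])
    once <- scale_charges(cs, ab[1] * ab[2])
    expect_equal(twice$charges, once$charges)
  }
  expect_error(scale_charges(cs, 0), "positive")
  expect_error(scale_charges(cs, -1), "positive")
})

test_that("ECS salt charge sets follow valence rules and are neutral", {
  expect_equal(ecs_salt_charge_set(1)$charges, c(0.95, -0.95))
  expect_equal(ecs_salt_charge_set(2)$charges, c(1.90, -0.95, -0.95))
  expect_equal(sum(ecs_salt_charge_set(1)$charges), 0)
  expect_equal(sum(ecs_salt_charge_set(2)$charges), 0)
  expect_error(ecs_salt_charge_set(3), "unsupported")
  expect_error(ecs_salt_charge_set(1, anion_count = 2), "valence")
})

test_that("cross interactions use overrides first, Lorentz-Berthelot otherwise", {
  a <- site_spec("A", lj_epsilon = 1, lj_sigma = 0.3)
  b <- site_spec("B", lj_epsilon = 4, lj_sigma = 0.5)
  lb <- cross_interaction(a, b)
  expect_equal(lb$epsilon, 2)
  expect_equal(lb$sigma, 0.4)
  self <- cross_interaction(a, a)
  expect_equal(self$epsilon, 1)
  expect_equal(self$sigma, 0.3)
  ov <- data.frame(site_a = "A", site_b = "B", epsilon = 0.7, sigma = 0.26)
  got <- cross_interaction(a, b, ov)
  expect_equal(got$epsilon, 0.7)
  expect_equal(got$sigma, 0.26)
  # unordered lookup
  got2 <- cross_interaction(b, a, ov)
  expect_equal(got2$sigma, 0.26)
  bad <- data.frame(site_a = "A", site_b = "B", epsilon = -1, sigma = 0.3)
  expect_error(cross_interaction(a, b, bad), "non-negative")
})

test_that("species validation catches broken invariants and passes bundled models", {
  w <- water_tip4p2005()
  expect_true(validate_species(w)$pass)
  salt <- nacl_scaled_charge()
  rep <- validate_species(list(salt$cation, salt$anion), salt$group)
  expect_true(rep$pass)
  # mismatched PES/ECS site counts
  broken <- w
  broken$charge_sets$ECS <- charge_set("ECS", c(0, 0.5))
  rep2 <- validate_species(broken)
  expect_false(rep2$pass)
  expect_match(paste(rep2$messages, collapse = " "), "charges for")
  # charged "water"
  charged <- w
  charged$charge_sets$PES <- charge_set("PES", c(0.1, 0.5564, 0.5564, -1.1128))
  expect_false(validate_species(charged)$pass)
  # non-neutral fractional group
  badgroup <- fractional_group(c("Na+" = 2L, "Cl-" = 1L))
  expect_false(validate_species(list(salt$cation, salt$anion), badgroup)$pass)
})

test_that("ECS water differs from PES only in charges", {
  w <- water_tip4p2005()
  expect_identical(
    lapply(w$sites, function(s) s[c("lj_epsilon", "lj_sigma", "position")]),
    lapply(water_tip4p2005(ecs_factor = 0.9)$sites,
           function(s) s[c("lj_epsilon", "lj_sigma", "position")]))
  expect_false(isTRUE(all.equal(w$charge_sets$PES$charges,
                                w$charge_sets$ECS$charges)))
  # geometry: O-H bond length and H-O-H angle as published
  oh <- sqrt(sum((w$sites[[2]]$position - w$sites[[1]]$position)^2))
  expect_equal(oh, 0.09572, tolerance = 1e-12)
  v1 <- w$sites[[2]]$position
  v2 <- w$sites[[3]]$position
  ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  expect_equal(ang, 104.52, tolerance = 1e-10)
})
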