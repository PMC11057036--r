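# Configuration loading, fixtures, provenance and the desk-scale pipeline.

test_that("the bundled water config loads and validates", {
  ffp <- system.file("extdata", "water_ecs.yaml", package = "ecsmc")
  runp <- system.file("extdata", "run_water.yaml", package = "ecsmc")
  cfg <- load_configs(ffp, runp)
  expect_s3_class(cfg$ff, "ff_bundle")
  expect_equal(cfg$ff$species_names, "H2O")
  expect_equal(cfg$run$T, 300)
  expect_equal(cfg$run$P, 1)
  expect_equal(cfg$run$seed, 20240301)
  expect_s3_class(cfg$group, "fractional_group")
  # config charges agree with the generated species (scaling, not typing)
  w <- water_tip4p2005()
  expect_equal(cfg$ff$species[[1]]$q_ecs, w$charge_sets$ECS$charges,
               tolerance = 1e-6)
})

test_that("the bundled salt config is a neutral ECS ion pair", {
  cfg <- load_configs(system.file("extdata", "nacl_ecs.yaml",
                                  package = "ecsmc"))
  qs <- unlist(lapply(cfg$ff$species, function(s) s$q_ecs))
  expect_equal(sum(qs), 0)
  expect_equal(sort(qs), c(-0.95, 0.95))
})

test_that("invalid configurations are rejected with field-addressed messages", {
  ffp <- system.file("extdata", "water_ecs.yaml", package = "ecsmc")
  # missing seed
  tmp <- tempfile(fileext = ".yaml")
  writeLines(c("temperature: 300", "pressure: 1", "counts: {H2O: 10}"), tmp)
  expect_error(load_configs(ffp, tmp), "seed")
  # unknown unit suffix
  tmp2 <- tempfile(fileext = ".yaml")
  writeLines(c("seed: 1", "temperature: 300 Celsius", "pressure: 1",
               "counts: {H2O: 10}"), tmp2)
  expect_error(load_configs(ffp, tmp2), "unknown unit")
  # missing site field
  tmp3 <- tempfile(fileext = ".yaml")
  writeLines(c("species:",
               "  - name: X",
               "    sites:",
               "      - {name: A, sigma: 0.3, epsilon: 1.0, q_pes: 0.0}"),
             tmp3)
  expect_error(load_configs(tmp3), "q_ecs|xyz")
  expect_error(load_configs("no/such/file.yaml"), "not found")
})

test_that("fixture generation is deterministic and families are checked", {
  f1 <- make_fixture("lj_fluid", list(N = 10), seed = 5)
  f2 <- make_fixture("lj_fluid", list(N = 10), seed = 5)
  expect_identical(f1$state$com, f2$state$com)
  expect_error(make_fixture("no_such_family"), "unknown fixture")
  # expected values attached per family
  expect_true(is.finite(
    make_fixture("charge_lattice")$expected$energy_per_pair))
  expect_equal(make_fixture("two_state", list(r = 3))$expected$delta_eta,
               log(3))
})

test_that("synthetic mu tables round-trip through the linear fit", {
  fx <- make_fixture("mu_tables", list(noise = 0))
  eps <- data.frame(T = fx$table$T,
                    epsilon = fx$table$mu_ecs - fx$table$mu_pes)
  fit <- fit_epsilon_linear(eps)
  expect_equal(fit$A0, fx$expected$A0, tolerance = 1e-10)
  expect_equal(fit$A1, fx$expected$A1, tolerance = 1e-10)
  # with noise the recovery degrades gracefully
  fxn <- make_fixture("mu_tables", list(noise = 0.05), seed = 8)
  epsn <- data.frame(T = fxn$table$T,
                     epsilon = fxn$table$mu_ecs - fxn$table$mu_pes)
  fitn <- fit_epsilon_linear(epsn)
  expect_equal(fitn$A0, fxn$expected$A0, tolerance = 0.5)
})

test_that("tables carry provenance and re-runs are bitwise identical", {
  dir1 <- tempfile(); dir2 <- tempfile()
  df <- data.frame(T = c(300, 350), value = c(1.5, 1.2))
  prov <- provenance_block(inputs = list(what = "unit-test"), seed = 7)
  dir.create(dir1); dir.create(dir2)
  write_table_with_provenance(df, file.path(dir1, "t.csv"), prov)
  write_table_with_provenance(df, file.path(dir2, "t.csv"), prov)
  expect_identical(readLines(file.path(dir1, "t.csv")),
                   readLines(file.path(dir2, "t.csv")))
  expect_identical(readLines(file.path(dir1, "t.provenance.json")),
                   readLines(file.path(dir2, "t.provenance.json")))
  pj <- jsonlite::read_json(file.path(dir1, "t.provenance.json"))
  expect_equal(pj$package, "ecsmc")
  expect_equal(pj$seed, 7)
})

test_that("run outputs are written as JSON summary, CSV blocks and XYZ snapshot", {
  fx <- make_fixture("lj_fluid", list(Tstar = 1.5, rhostar = 0.2, N = 8))
  ens <- ensemble_spec(300, 1, move_weights = c(0.9, 0, 0.1, 0, 0))
  run <- run_npt(fx$ff, fx$state, ens, nsteps_equil = 2e3,
                 nsteps_prod = 1e4, nblocks = 4, seed = 55)
  dir <- tempfile()
  write_run_outputs(run, fx$ff, dir)
  expect_true(all(file.exists(file.path(
    dir, c("summary.json", "blocks.csv", "final.xyz")))))
  js <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(js$seed, 55)
  expect_equal(js$provenance$package, "ecsmc")
  blocks <- read.csv(file.path(dir, "blocks.csv"))
  expect_equal(nrow(blocks), 4)
  xyz <- readLines(file.path(dir, "final.xyz"))
  expect_equal(as.integer(xyz[1]), 8)   # one site per LJ particle
  expect_length(xyz, 2 + 8)
})

test_that("the desk-scale pipeline reproduces every property check", {
  rep <- run_reproduction_pipeline("desk", seed = 3,
                            nsteps = list(ideal_gas = 1e5))
  expect_true(all(rep$report$pass))
  expect_true(rep$all_pass)
  # the worked example: experimental-to-model saturation pressure ratio
  expect_equal(rep$psat_example$ratio, 4, tolerance = 0.35)
  expect_gt(nrow(rep$report), 8)
})

test_that("the full-scale manifest enumerates the complete campaign", {
  full <- run_reproduction_pipeline("full", seed = 1)
  man <- full$manifest
  # water mu_ex on both surfaces across the full temperature range
  muw <- man[man$stage == "mu_ex_water", ]
  expect_setequal(unique(muw$T), c(300, 350, 400, 450, 500))
  expect_setequal(unique(muw$surface), c("PES", "ECS"))
  expect_equal(nrow(muw), 10)
  # hydration for all five salts on both surfaces
  hyd <- man[man$stage == "hydration", ]
  expect_setequal(unique(hyd$system),
                  c("NaCl", "KCl", "LiCl", "MgCl2", "CaCl2"))
  expect_equal(nrow(hyd), 10)
  # NaCl coexistence at 350 K up to 6 mol/kg, activities at 298 K
  expect_setequal(man[man$stage == "coexistence_nacl", "molality"], 0:6)
  expect_equal(unique(man[man$stage == "coexistence_nacl", "T"]), 350)
  expect_setequal(man[man$stage == "activity_nacl", "molality"], 0:6)
  expect_equal(unique(man[man$stage == "activity_nacl", "T"]), 298)
  # heat of vaporization at 298 K
  expect_true(any(man$stage == "dhvap" & man$T == 298))
  # comparison targets are attached
  expect_equal(full$claims$dhvap_pes_298K, 50.2)
  expect_equal(full$claims$eps_fit_A0, 5.00)
})
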