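# A reduced objective (single short step) keeps the optimization unit tests
# fast; the full three-step protocol is exercised in the acceptance suite.
fast_objective <- function(model) {
  objective_from_model(model, amplitudes = 0.3, duration = 600)
}

test_that("a genome scores zero against its own features", {
  mod <- exemplar_model()
  obj <- fixture("fast_obj", function() fast_objective(exemplar_model()))
  sc <- score_genome(genome_bounds(mod)$value, obj, mod)
  expect_equal(sum(sc$z), 0, tolerance = 1e-10)
  # deterministic: identical on re-evaluation
  sc2 <- score_genome(genome_bounds(mod)$value, obj, mod)
  expect_identical(sc$z, sc2$z)
})

test_that("perturbing the somatic sodium conductance degrades the score", {
  mod <- exemplar_model()
  obj <- fixture("fast_obj", function() fast_objective(exemplar_model()))
  gb <- genome_bounds(mod)
  g2 <- gb$value
  i_nav <- which(gb$gene == "Nav1.6@soma")
  g2[i_nav] <- gb$hi[i_nav] # push to the upper bound (+60%)
  sc <- score_genome(g2, obj, mod)
  expect_gt(sum(sc$z), 0.5)
})

test_that("the genetic algorithm is seeded, bounded and reproducible", {
  mod <- exemplar_model()
  obj <- fixture("fast_obj", function() fast_objective(exemplar_model()))
  # n_gen = 0 returns the seeded initial population unchanged
  ga0 <- optimize_conductances(mod, obj, pop_size = 4, n_gen = 0, seed = 5,
                               seed_default = FALSE)
  gb <- genome_bounds(mod)
  expect_equal(dim(ga0$population), c(4, nrow(gb)))
  expect_true(all(t(ga0$population) >= gb$lo & t(ga0$population) <= gb$hi))
  expect_equal(max(ga0$logbook$gen), 0)
  ga0b <- optimize_conductances(mod, obj, pop_size = 4, n_gen = 0, seed = 5,
                                seed_default = FALSE)
  expect_identical(ga0$population, ga0b$population)
  expect_identical(ga0$logbook, ga0b$logbook)
})

test_that("the validation report keeps its steps independent", {
  silent <- exemplar_model()
  silent$registry$gmax[silent$registry$channel == "Nav1.6"] <- 1e-6
  rep <- validate_model(silent)
  expect_false(rep$step1$pass)
  expect_false(rep$overall)
  # steps 2 and 3 are still evaluated and reported
  expect_true(is.finite(rep$step2$sag_mv))
  expect_true(is.finite(rep$step3$cav22_block_hz))
  # overall pass iff all steps pass
  expect_equal(rep$overall,
               rep$step1$pass && rep$step2$pass && rep$step3$pass)
})

test_that("triage statistics aggregate pass fractions", {
  pass <- list(step1 = list(pass = TRUE), step2 = list(pass = TRUE),
               step3 = list(pass = TRUE), overall = TRUE)
  fail <- list(step1 = list(pass = FALSE), step2 = list(pass = TRUE),
               step3 = list(pass = TRUE), overall = FALSE)
  class(pass) <- class(fail) <- "goc_validation"
  expect_equal(triage_stats(list(pass, pass))$frac_all_steps, 1)
  expect_equal(triage_stats(list(fail, fail))$frac_all_steps, 0)
  ts <- triage_stats(list(pass, fail))
  expect_equal(ts$frac_steps_1_2, 0.5)
  expect_equal(ts$frac_all_steps, 0.5)
})

test_that("tidiers summarize fits and validations", {
  mod <- exemplar_model()
  obj <- fixture("fast_obj", function() fast_objective(exemplar_model()))
  ga <- optimize_conductances(mod, obj, pop_size = 4, n_gen = 0, seed = 1)
  expect_s3_class(tidy(ga), "tbl_df")
  expect_equal(glance(ga)$pop_size, 4)
})
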