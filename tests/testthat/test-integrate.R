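test_that("single-species dynamics match the scalar logistic closed form", {
  # one clone, one niche, no unspecific affinity: k = v * p = 100 constant,
  # so c(t) = K c0 e^(t/tau) / (K + c0 (e^(t/tau) - 1))
  cfg <- model_config(q = 1, n = 1, u_h = 0)
  c0 <- c(h1 = 1, p1 = 0)
  tr <- integrate_model(cfg, c0,
                        integration_settings(stop_at_convergence = FALSE,
                                             t_max = 60))
  K <- 100; tau <- cfg$tau
  closed <- K * exp(tr$times / tau) / (K + (exp(tr$times / tau) - 1))
  expect_equal(tr$states[, "h1"], closed, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_true(all(tr$states[, "p1"] == 0))
})

test_that("trajectories agree with an independent lsoda integration", {
  cfg <- small_config(p = 60, s_p = 0.3, u_p = 0.004, v_p = 2.5)
  c0 <- setNames(c(5, 3, 2, 1, 0, 1), c("h1","h2","h3","p1","p2","p3"))
  tr <- integrate_model(cfg, c0,
                        integration_settings(stop_at_convergence = FALSE,
                                             t_max = 80))
  sol <- deSolve::lsoda(c0, tr$times, desolve_rhs(cfg), NULL,
                        rtol = 1e-10, atol = 1e-12)
  expect_equal(max(abs(sol[, -1] - tr$states) /
                     pmax(abs(sol[, -1]), 1e-6)), 0, tolerance = 1e-5)
})

test_that("the empty system is a fixed point, converged immediately", {
  cfg <- small_config()
  tr <- integrate_model(cfg, rep(0, cfg$m))
  expect_true(tr$converged)
  expect_equal(tr$t_converged, 1)
  expect_true(all(tr$final == 0))
})

test_that("species started at zero stay exactly zero", {
  cfg <- small_config(s_p = 0.5, v_p = 4)
  c0 <- setNames(c(10, 0, 5, 2, 0, 0), c("h1","h2","h3","p1","p2","p3"))
  tr <- integrate_model(cfg, c0,
                        integration_settings(stop_at_convergence = FALSE,
                                             t_max = 200))
  expect_true(all(tr$states[, c("h2", "p2", "p3")] == 0))
  expect_true(all(tr$states >= 0))  # forward invariance of the orthant
})

test_that("the steady-state criterion leaves a small vector-field residual", {
  cfg <- model_config()
  tr <- integrate_model(cfg,
                        make_initial_state(transplant_spec(), cfg),
                        save_trajectory = FALSE)
  expect_true(tr$converged)
  resid <- max(abs(model_rhs(tr$final, cfg)))
  # relative change < 1e-6 per 1 h checkpoint at ~100 cells/clone
  expect_lt(resid, 1e-3)
})

test_that("healthy-only steady state is allocation-independent", {
  cfg <- model_config(q = 5, n = 5, u_h = 1 / 5)
  runs <- list(
    make_initial_state(transplant_spec(total_cells = 500), cfg),
    make_initial_state(transplant_spec(total_cells = 500,
                                       allocation = "multinomial",
                                       seed = 3), cfg),
    c(h1 = 400, h2 = 50, h3 = 30, h4 = 15, h5 = 5, p1 = 0, p2 = 0,
      p3 = 0, p4 = 0, p5 = 0))
  stopifnot(all(vapply(runs, function(x) all(x[1:5] > 0), logical(1))))
  finals <- lapply(runs, function(c0)
    integrate_model(cfg, c0, save_trajectory = FALSE)$final)
  target <- cfg$v_h * sum(cfg$p) / cfg$q
  for (f in finals) {
    expect_equal(unname(f[1:5]), rep(target, 5), tolerance = 1e-3)
    expect_true(all(f[6:10] == 0))
  }
})

test_that("integrate_model validates events and initial state", {
  cfg <- small_config()
  expect_error(integrate_model(cfg, rep(-1, cfg$m)), "non-negative")
  expect_error(integrate_model(cfg, rep(1, 3)), "length")
  expect_error(
    integrate_model(cfg, rep(1, cfg$m),
                    events = data.frame(time = 1.5, fraction = 0.5)),
    "multiples")
  expect_error(
    integrate_model(cfg, rep(1, cfg$m),
                    events = data.frame(time = 2, fraction = 1.2)),
    "\\[0, 1\\]")
})

test_that("physiological run reaches 1e4 cells and recovers from a 99% kill", {
  for (clonality in c("polyclonal", "monoclonal")) {
    tr <- run_physiological(clonality)
    totals <- rowSums(tr$states)
    at <- function(t) which(tr$times == t)
    # steady state before the kill and at the end (recorded state at the
    # kill time is pre-kill)
    expect_equal(totals[at(200)], 1e4, tolerance = 1e-3)
    expect_equal(totals[at(400)], 1e4, tolerance = 1e-3)
    # the kill is visible right after t = 200
    expect_lt(totals[at(201)], 0.05 * 1e4)
    # recovery to the pre-kill state, per species
    expect_equal(tr$states[at(400), ], tr$states[at(200), ],
                 tolerance = 1e-3)
    if (clonality == "polyclonal")
      expect_equal(unname(tr$states[at(400), 1:100]), rep(100, 100),
                   tolerance = 1e-3)
  }
})

test_that("a complete kill leaves the system empty", {
  tr <- run_physiological("polyclonal", config = model_config(q = 4, n = 4),
                          kill_fraction = 1, t_end = 250)
  expect_true(all(tr$states[tr$times > 200, ] == 0))
  expect_equal(sum(tr$final), 0)
})

test_that("trajectories export as tidy CSV with a manifest", {
  cfg <- small_config()
  tr <- run_physiological("polyclonal", config = cfg, t_end = 20,
                          kill_fraction = 0)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f)
  df <- as.data.frame(data.table::fread(f))
  expect_named(df, c("time", "species_index", "species_class",
                     "clone_index", "abundance"))
  expect_equal(nrow(df), length(tr$times) * cfg$m)
  # round-trip of one species' trajectory
  h2 <- df[df$species_index == 2, ]
  expect_equal(h2$abundance, unname(tr$states[, "h2"]))
  expect_equal(unique(df$species_class[df$species_index == 5]),
               "preleukemic")
  manifest <- jsonlite::read_json(sub("\\.csv$", ".manifest.json", f))
  expect_equal(manifest$config$q, cfg$q)
  expect_equal(manifest$t_end, 20)
})
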