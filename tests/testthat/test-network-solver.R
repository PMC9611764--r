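test_that("total parallel distal resistance matches hand arithmetic", {
  expect_equal(total_parallel_Rt(1e10, 1e10), 5e9)
  expect_equal(total_parallel_Rt(1e10, 1e16), 1e10, tolerance = 1e-5)
  # branch at one third of the main diameter under Murray scaling
  expect_equal(total_parallel_Rt(1e10, 2.7e11), 1e10 * 2.7e11 / 2.8e11,
               tolerance = 1e-12)
  expect_error(total_parallel_Rt(0, 1), class = "ffrtree_domain_error")
})

test_that("closed-form circuit solution matches an independent quadratic root", {
  V <- mmHg_to_Pa(90)
  m <- circuit_model(V, stenosis_model(1e9, 1e12), R1 = 1e10)
  sol <- solve_circuit_closed_form(m)
  # independent evaluation: the standard quadratic formula
  q_ref <- (-(1e9 + 1e10) + sqrt((1e9 + 1e10)^2 + 4 * 1e12 * V)) / (2 * 1e12)
  expect_equal(sol$q_stenosis, q_ref, tolerance = 1e-12)
  expect_equal(sol$FFR, 1e10 * q_ref / V, tolerance = 1e-12)
  expect_equal(sol$q_stenosis, 1.0909e-6, tolerance = 1e-4)
  expect_equal(sol$FFR, 0.909, tolerance = 1e-3)
  # equal divider: no expansion term, R(q) = C1 = R1
  eq <- solve_circuit_closed_form(
    circuit_model(V, stenosis_model(1e10, 0), R1 = 1e10))
  expect_equal(eq$FFR, 0.5, tolerance = 1e-12)
})

test_that("an upstream branch leaves FFR untouched; a downstream branch lowers it", {
  V <- mmHg_to_Pa(90)
  sten <- stenosis_model(1e9, 1e12)
  none <- solve_circuit_closed_form(circuit_model(V, sten, R1 = 1e10))
  up <- solve_circuit_closed_form(
    circuit_model(V, sten, R1 = 1e10, R2 = 2e10, "upstream"))
  down <- solve_circuit_closed_form(
    circuit_model(V, sten, R1 = 1e10, R2 = 2e10, "downstream"))
  expect_identical(up$FFR, none$FFR)
  expect_identical(up$main_outlet_flow, none$main_outlet_flow)
  expect_lt(down$FFR, none$FFR)
  # the upstream branch draws V / R2 regardless of the stenosis
  expect_equal(up$branch_flow, V / 2e10)
  expect_equal(up$inlet_flow, none$inlet_flow + V / 2e10)
  # R2 -> infinity reduces the downstream model to the no-branch model
  far <- solve_circuit_closed_form(
    circuit_model(V, sten, R1 = 1e10, R2 = 1e18, "downstream"))
  expect_equal(far$FFR, none$FFR, tolerance = 1e-7)
})

test_that("a single healthy segment obeys Ohm's law through the tree solver", {
  prof <- lumen_profile(c(0, 0.05), c(0.003, 0.003))
  R_out <- 5e9
  tree <- vessel_tree(prof, mmHg_to_Pa(90), outlet_spec(R_out))
  sol <- solve_tree(tree)
  R_seg <- poiseuille_resistance(0.05, 0.003, 0.0035)
  expect_equal(sol$inlet_flow, mmHg_to_Pa(90) / (R_out + R_seg),
               tolerance = 1e-10)
  expect_true(sol$converged)
})

test_that("solve_tree reproduces the closed-form circuits on the idealized fixtures", {
  variants <- list(model1_no_branch = "none", model2_upstream = "upstream",
                   model3_downstream = "downstream")
  for (v in names(variants)) {
    tree <- make_idealized(v)
    sol <- solve_tree(tree, neglect_cfg())
    cf <- solve_circuit_closed_form(circuit_from_fixture(tree, variants[[v]]))
    expect_equal(sol$distal_FFR, cf$FFR, tolerance = 1e-8)
    expect_equal(sol$inlet_flow, cf$inlet_flow, tolerance = 1e-8)
    expect_equal(sol$main_outlet_flow, cf$main_outlet_flow, tolerance = 1e-8)
    expect_true(sol$converged)
    expect_lt(sol$residual, 1e-10)
  }
})

test_that("flow is conserved at every junction and FFR is monotone in (0, 1]", {
  for (seed in c(3, 11)) {
    for (preset in c("patient1_like", "patient2_like")) {
      tree <- make_patient_like(synthetic_tree_config(seed, preset))
      sol <- solve_tree(tree)
      n <- length(sol$section_flows)
      expect_lt(sol$residual, 1e-10)
      expect_equal(sol$section_flows[-n] - sol$section_flows[-1],
                   sol$branch_flows, tolerance = 1e-10)
      # all outlet flows sum back to the inlet flow
      expect_equal(sum(sol$branch_flows) + sol$main_outlet_flow,
                   sol$inlet_flow, tolerance = 1e-10)
      expect_true(all(sol$node_FFR > 0 & sol$node_FFR <= 1 + 1e-12))
      expect_true(all(diff(sol$node_FFR) <= 1e-12))
    }
  }
})

test_that("shrinking the downstream branch resistance lowers FFR and raises flows", {
  sten_R2 <- c(4e10, 1e10, 4e9)
  base <- make_idealized("model3_downstream", outlet_policy = "explicit",
                         R_main = 1e10, R_branch = 1e12)
  sol0 <- solve_tree(base, neglect_cfg())
  prev <- sol0
  for (R2 in sten_R2) {
    tr <- make_idealized("model3_downstream", outlet_policy = "explicit",
                         R_main = 1e10, R_branch = R2)
    sol <- solve_tree(tr, neglect_cfg())
    expect_lt(sol$distal_FFR, prev$distal_FFR)
    expect_gt(sol$inlet_flow, prev$inlet_flow)
    expect_gt(sol$section_flows[1], prev$section_flows[1])  # stenosis flow
    prev <- sol
  }
  # upstream: FFR unchanged exactly, inlet flow up
  up_hi <- solve_tree(make_idealized("model2_upstream", "explicit",
                                     R_main = 1e10, R_branch = 4e10),
                      neglect_cfg())
  up_lo <- solve_tree(make_idealized("model2_upstream", "explicit",
                                     R_main = 1e10, R_branch = 4e9),
                      neglect_cfg())
  expect_equal(up_lo$distal_FFR, up_hi$distal_FFR, tolerance = 1e-12)
  expect_gt(up_lo$inlet_flow, up_hi$inlet_flow)
})

test_that("adding any side branch decreases the total tree resistance", {
  no_br <- make_idealized("model1_no_branch")
  for (v in c("model2_upstream", "model3_downstream")) {
    with_br <- make_idealized(v)
    r_without <- no_br$inlet_pressure_Pa / solve_tree(no_br)$inlet_flow
    r_with <- with_br$inlet_pressure_Pa / solve_tree(with_br)$inlet_flow
    expect_lt(r_with, r_without)
  }
})

test_that("distal-resistance calibration round-trips to better than 0.1%", {
  tree <- make_idealized("model3_downstream")
  truth <- tree$main_outlet$resistance_Pa_s_m3
  target <- solve_tree(tree)$distal_FFR
  est <- calibrate_distal_resistance(tree, target)
  expect_lt(abs(est - truth) / truth, 1e-3)
  # a healthy vessel with no stenosis cannot be calibrated below FFR 1
  healthy <- vessel_tree(lumen_profile(c(0, 0.075), c(0.003, 0.003)),
                         mmHg_to_Pa(90), outlet_spec(1e10))
  expect_error(calibrate_distal_resistance(healthy, 0.8, neglect_cfg()),
               class = "ffrtree_domain_error")
})

test_that("solution tables carry clinical units", {
  tree <- make_idealized("model3_downstream")
  tab <- solution_tables(solve_tree(tree))
  expect_named(tab, c("nodes", "edges"))
  expect_equal(tab$nodes$pressure_mmHg[1], 90)
  expect_equal(tab$nodes$FFR[1], 1)
  expect_equal(nrow(tab$nodes), 3)  # inlet, ostium, distal
  expect_true(all(tab$edges$flow_mL_min > 0))
})
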