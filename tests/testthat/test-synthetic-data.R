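test_that("idealized fixtures carry the canonical benchmark dimensions", {
  for (v in c("model1_no_branch", "model2_upstream", "model3_downstream")) {
    tree <- make_idealized(v)
    expect_equal(diff(range(tree$main_vessel$arc_length_m)), 0.075)
    expect_equal(unique(tree$main_vessel$diameter_m), 0.003)
    expect_equal(tree$inlet_pressure_Pa, 90 * 133.322)
    st <- tree$stenoses[[1]]
    expect_equal(st$length_m, 0.010)
    expect_equal(st$area_ratio, 0.2)
  }
  m1 <- make_idealized("model1_no_branch")
  expect_length(m1$side_branches, 0)
  m2 <- make_idealized("model2_upstream")
  m3 <- make_idealized("model3_downstream")
  expect_equal(m2$side_branches[[1]]$diameter_m, 0.0025)
  expect_equal(m2$side_branches[[1]]$angle_deg, 75)
  # branch sits 25 mm from the stenosis throat on either side
  expect_equal(m2$stenoses[[1]]$center_m - m2$side_branches[[1]]$attach_m,
               0.025)
  expect_equal(m3$side_branches[[1]]$attach_m - m3$stenoses[[1]]$center_m,
               0.025)
  # models 2 and 3 differ only in the attach position
  b2 <- m2$side_branches[[1]]; b3 <- m3$side_branches[[1]]
  b2$attach_m <- b3$attach_m
  expect_equal(b2, b3)
  expect_equal(m2$main_outlet, m3$main_outlet)
})

test_that("the throat diameter follows from the 20% area ratio", {
  tree <- make_idealized("model1_no_branch")
  d_min <- profile_diameter(tree$main_vessel, tree$stenoses[[1]]$center_m,
                            tree$stenoses)
  expect_equal(d_min, 0.003 * sqrt(0.2), tolerance = 1e-12)
  expect_equal(d_min, 1.342e-3, tolerance = 1e-3)
})

test_that("explicit outlet policy uses the supplied resistances", {
  tree <- make_idealized("model3_downstream", outlet_policy = "explicit",
                         R_main = 2e9, R_branch = 7e9)
  expect_equal(tree$main_outlet$resistance_Pa_s_m3, 2e9)
  expect_equal(tree$side_branches[[1]]$outlet$resistance_Pa_s_m3, 7e9)
  expect_error(make_idealized("model2_upstream", outlet_policy = "explicit",
                              R_main = 2e9),
               class = "ffrtree_domain_error")
})

test_that("patient-like generation is byte-reproducible given the seed", {
  cfg <- synthetic_tree_config(seed = 7, preset = "patient1_like")
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_tree(make_patient_like(cfg), f1)
  write_tree(make_patient_like(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
  f3 <- withr::local_tempfile(fileext = ".json")
  write_tree(make_patient_like(synthetic_tree_config(8, "patient1_like")), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("generated trees respect the sampling and layout constraints", {
  for (seed in c(1, 9, 31)) {
    for (preset in c("patient1_like", "patient2_like")) {
      cfg <- synthetic_tree_config(seed, preset)
      tree <- make_patient_like(cfg)
      # frame spacing exactly 36/180 mm = 0.2 mm
      expect_equal(unique(round(diff(tree$main_vessel$arc_length_m), 12)),
                   0.2e-3)
      # no sub-0.5 mm branches
      expect_true(all(vapply(tree$side_branches, `[[`, 0, "diameter_m") >=
                        0.5e-3))
      # branches clear of the lesions
      for (sb in tree$side_branches)
        for (st in tree$stenoses)
          expect_gt(abs(sb$attach_m - st$center_m), st$length_m / 2)
      # preset layout: lesion position relative to the branches
      st_c <- tree$stenoses[[1]]$center_m
      br <- vapply(tree$side_branches, `[[`, 0, "attach_m")
      if (preset == "patient1_like") expect_true(all(br < st_c))
      else expect_true(all(br > st_c))
    }
  }
})

test_that("zero noise reproduces the smooth tapered template", {
  cfg <- synthetic_tree_config(seed = 4, preset = "patient1_like",
                               area_noise_sd = 0)
  tree <- make_patient_like(cfg)
  s <- tree$main_vessel$arc_length_m
  d_expect <- 3e-3 * (1 + (0.85 - 1) * s / max(s))
  expect_equal(tree$main_vessel$diameter_m, d_expect, tolerance = 1e-12)
})

test_that("patient2-like layout suffers a larger branch effect than patient1-like", {
  # matched stenosis severity and branch count; only the layout differs
  common <- list(n_branches = 3L, severity_range = c(0.3, 0.3),
                 area_noise_sd = 0)
  c1 <- do.call(synthetic_tree_config,
                c(list(seed = 17, preset = "patient1_like"), common))
  c2 <- do.call(synthetic_tree_config,
                c(list(seed = 17, preset = "patient2_like"), common))
  d1 <- compare_with_without(make_patient_like(c1))$delta_ffr
  d2 <- compare_with_without(make_patient_like(c2))$delta_ffr
  expect_gt(d2, d1)
})

test_that("tree JSON round-trips and rejects malformed input", {
  tree <- make_patient_like(synthetic_tree_config(2, "patient2_like"))
  f <- withr::local_tempfile(fileext = ".json")
  write_tree(tree, f)
  back <- read_tree(f)
  expect_equal(back$main_vessel$arc_length_m, tree$main_vessel$arc_length_m)
  expect_equal(back$main_vessel$diameter_m, tree$main_vessel$diameter_m)
  expect_equal(back$inlet_pressure_Pa, tree$inlet_pressure_Pa)
  expect_equal(back$stenoses, tree$stenoses)
  expect_equal(back$side_branches, tree$side_branches)
  expect_equal(back$main_outlet, tree$main_outlet)
  # write-read-write is byte-stable (canonical formatting)
  f2 <- withr::local_tempfile(fileext = ".json")
  write_tree(back, f2)
  expect_identical(readLines(f), readLines(f2))

  obj <- jsonlite::read_json(f)
  obj$main_outlet <- NULL
  f3 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(obj, f3, auto_unbox = TRUE, digits = NA)
  expect_error(read_tree(f3), class = "ffrtree_validation_error")

  obj2 <- jsonlite::read_json(f)
  obj2$schema <- "ffrtree/99"
  f4 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(obj2, f4, auto_unbox = TRUE, digits = NA)
  expect_error(read_tree(f4), class = "ffrtree_schema_error")
})
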