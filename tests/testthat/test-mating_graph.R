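test_that("pairwise gap matches plane geometry in both distance modes", {
  a <- data.frame(id = "a", shell_id = "s", x_cm = 0, y_cm = 0,
                  operculum_radius_cm = 0)
  b <- data.frame(id = "b", shell_id = "s", x_cm = 3, y_cm = 4,
                  operculum_radius_cm = 0)
  expect_equal(pairwise_gap(a, b), 5.0)

  a$operculum_radius_cm <- 0.5
  b$operculum_radius_cm <- 0.5
  edge_cfg <- study_config(distance_mode = "operculum_edge")
  expect_equal(pairwise_gap(a, b, edge_cfg), 4.0)

  b$x_cm <- 0.4; b$y_cm <- 0.3   # opercula overlap: floored at zero
  expect_equal(pairwise_gap(a, b, edge_cfg), 0.0)

  b$shell_id <- "other"
  expect_error(pairwise_gap(a, b), "within a shell")
})

test_that("reach is the elongation factor times penis length", {
  expect_equal(reach_distance(data.frame(penis_length_cm = 2.77)), 5.0414)
  expect_equal(reach_distance(data.frame(penis_length_cm = 1.67)), 3.0394)
  unit <- study_config(elongation_factor = 1)
  expect_equal(reach_distance(data.frame(penis_length_cm = 2.2), unit), 2.2)
})

test_that("the three-on-a-line fixture yields exactly the brute-forced edges", {
  recs <- make_line_records()
  graph <- build_mating_graph(recs)
  expect_identical(edge_keys(graph$edges$donor_id, graph$edges$recipient_id),
                   c("A->B", "C->B"))
  oe <- oracle_edges(recs)
  expect_identical(edge_keys(graph$edges$donor_id, graph$edges$recipient_id),
                   edge_keys(oe$donor, oe$recipient))

  mgs <- compute_mgs(graph)
  expect_identical(mgs$mgs_m, c(2L, 1L, 2L))
  expect_identical(mgs$mgs_f, c(1L, 3L, 1L))
})

test_that("a focal reaching 3 neighbours while 4 reach it has MGSm 4, MGSf 5", {
  recs <- make_focal_records()
  mgs <- compute_mgs(build_mating_graph(recs))
  expect_identical(mgs$mgs_m[mgs$id == "focal"], 4L)
  expect_identical(mgs$mgs_f[mgs$id == "focal"], 5L)
  om <- oracle_mgs(recs)
  expect_identical(mgs$mgs_m, om$mgs_m)
  expect_identical(mgs$mgs_f, om$mgs_f)
})

test_that("singletons and cross-shell pairs never form edges", {
  recs <- make_line_records()
  recs$shell_id <- c("s1", "s2", "s3")  # one individual per shell
  recs$x_cm <- c(0, 1, 2)               # near, but on different shells
  graph <- build_mating_graph(recs)
  expect_identical(nrow(graph$edges), 0L)
  mgs <- compute_mgs(graph)
  expect_true(all(mgs$mgs_m == 1L & mgs$mgs_f == 1L))
})

test_that("graph and degrees equal the brute-force oracle on random instances", {
  set.seed(404)
  for (rep in 1:15) {
    recs <- random_records(n_shells = sample(1:10, 1),
                           max_per_shell = sample(2:10, 1))
    mode <- sample(c("center", "operculum_edge"), 1)
    cfg <- study_config(distance_mode = mode)
    graph <- build_mating_graph(recs, cfg)
    oe <- oracle_edges(recs, mode = mode)
    expect_identical(
      edge_keys(graph$edges$donor_id, graph$edges$recipient_id),
      edge_keys(oe$donor, oe$recipient)
    )
    mgs <- compute_mgs(graph)
    om <- oracle_mgs(recs, mode = mode)
    expect_identical(mgs$mgs_m, om$mgs_m)
    expect_identical(mgs$mgs_f, om$mgs_f)
  }
})

test_that("per shell, edges are conserved: sum(MGSm-1) = sum(MGSf-1) = |E|", {
  set.seed(405)
  for (rep in 1:10) {
    recs <- random_records(n_shells = 6, max_per_shell = 8)
    graph <- build_mating_graph(recs)
    mgs <- compute_mgs(graph)
    for (shell in unique(recs$shell_id)) {
      sub <- mgs[mgs$shell_id == shell, ]
      n_edges <- sum(graph$edges$shell_id == shell)
      expect_identical(sum(sub$mgs_m - 1L), n_edges)
      expect_identical(sum(sub$mgs_f - 1L), n_edges)
      expect_true(all(sub$mgs_m <= nrow(sub) & sub$mgs_f <= nrow(sub)))
    }
  }
})

test_that("equal penis lengths with point opercula collapse MGSm onto MGSf", {
  set.seed(406)
  for (rep in 1:8) {
    recs <- random_records(n_shells = 4, max_per_shell = 7)
    recs$penis_length_cm <- 2.5
    recs$operculum_radius_cm <- 0
    mgs <- compute_mgs(build_mating_graph(recs))
    expect_identical(mgs$mgs_m, mgs$mgs_f)
  }
})

test_that("the focal's own penis length never moves its MGSf and never shrinks its MGSm", {
  set.seed(407)
  recs <- random_records(n_shells = 3, max_per_shell = 8)
  base <- compute_mgs(build_mating_graph(recs))
  for (i in sample(nrow(recs), min(6, nrow(recs)))) {
    for (len in c(1.67, 2.77, 4.46, 8)) {
      mod <- recs
      mod$penis_length_cm[i] <- len
      mgs <- compute_mgs(build_mating_graph(mod))
      expect_identical(mgs$mgs_f[i], base$mgs_f[i])
      if (len >= recs$penis_length_cm[i]) {
        expect_gte(mgs$mgs_m[i], base$mgs_m[i])
      } else {
        expect_lte(mgs$mgs_m[i], base$mgs_m[i])
      }
    }
  }
})

test_that("deleting a shell leaves every other shell's MGS unchanged", {
  set.seed(408)
  recs <- random_records(n_shells = 6, max_per_shell = 6)
  full <- compute_mgs(build_mating_graph(recs))
  drop_shell <- sample(unique(recs$shell_id), 1)
  kept <- recs[recs$shell_id != drop_shell, ]
  part <- compute_mgs(build_mating_graph(kept))
  full_kept <- full[full$shell_id != drop_shell, ]
  expect_identical(part$mgs_m, full_kept$mgs_m)
  expect_identical(part$mgs_f, full_kept$mgs_f)
})

test_that("inclusion rules and missing organs drive exclusion as specified", {
  recs <- make_line_records()
  mgs <- compute_mgs(build_mating_graph(recs))
  flags <- apply_inclusion_filter(recs, mgs)
  expect_true(all(flags$included))  # B is isolated as male only (MGSf = 3)

  # under the either-role rule everyone on the line is isolated in one role:
  # B as male (MGSm = 1), A and C as female (MGSf = 1)
  either <- study_config(inclusion_rule = "either_role_isolated")
  flags2 <- apply_inclusion_filter(recs, mgs, either)
  expect_true(all(!flags2$included))

  far <- make_line_records()
  far$x_cm <- c(0, 100, 200)  # reaches < 100 cm: everyone fully isolated
  flags3 <- apply_inclusion_filter(far, compute_mgs(build_mating_graph(far)))
  expect_true(all(!flags3$included))
  expect_true(all(flags3$exclusion_reason == "isolated"))

  gap <- make_line_records()
  gap$ovary_weight_mg[1] <- NA  # A loses an organ but stays in the geometry
  mgs_gap <- compute_mgs(build_mating_graph(gap))
  flags4 <- apply_inclusion_filter(gap, mgs_gap)
  expect_false(flags4$included[flags4$id == "A"])
  expect_identical(flags4$exclusion_reason[flags4$id == "A"],
                   "missing_organ")
  expect_identical(mgs_gap$mgs_f, mgs$mgs_f)  # neighbours unaffected
})
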