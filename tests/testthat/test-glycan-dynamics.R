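test_that("the loose/bound threshold rule is applied exactly", {
  # designed contact counts straddle the <=2 threshold
  g2 <- make_glycan_state_trajectory(n_frames = 1, n_loose = c(U = 1),
                                     p_loose = c(U = 0), contact_loose = 2,
                                     seed = 1)
  st2 <- classify_frame(get_frame(g2$trajectory, 1), g2$topologies$U, g2$spec)
  expect_equal(st2$contacts, 2L)
  expect_equal(st2$state, "loose")

  g3 <- make_glycan_state_trajectory(n_frames = 1, n_loose = c(U = 0),
                                     p_loose = c(U = 0), contact_bound = 3,
                                     seed = 1)
  st3 <- classify_frame(get_frame(g3$trajectory, 1), g3$topologies$U, g3$spec)
  expect_equal(st3$contacts, 3L)
  expect_equal(st3$state, "bound")
})

test_that("a glycan translated far from the domain counts zero and is loose", {
  g <- make_glycan_state_trajectory(n_frames = 1, n_loose = c(U = 0),
                                    p_loose = c(U = 0), seed = 1)
  model <- get_frame(g$trajectory, 1)
  moved <- dplyr::mutate(model,
    y = ifelse(.data$chain_id == "U", .data$y - 50, .data$y))
  st <- classify_frame(moved, g$topologies$U, g$spec)
  expect_equal(st$contacts, 0L)
  expect_equal(st$state, "loose")
})

test_that("classification is invariant under whole-frame rigid motion", {
  g <- make_glycan_state_trajectory(n_frames = 6, n_loose = c(U = 3, V = 2),
                                    seed = 4)
  set.seed(17)
  for (f in 1:6) {
    model <- get_frame(g$trajectory, f)
    moved <- rigid_transform_frame(model)
    for (ch in c("U", "V")) {
      expect_identical(classify_frame(moved, g$topologies[[ch]], g$spec),
                       classify_frame(model, g$topologies[[ch]], g$spec))
    }
  }
})

test_that("raising loose_threshold never converts loose frames to bound", {
  g <- make_glycan_state_trajectory(n_frames = 20, n_loose = c(U = 8),
                                    seed = 6)
  states <- lapply(2:5, function(thr) {
    spec <- state_spec(g$spec$reference, loose_threshold = thr)
    classify_glycan_states(g$trajectory, g$topologies["U"], spec)$state
  })
  for (i in seq_along(states)[-1]) {
    was_loose <- states[[i - 1]] == "loose"
    expect_true(all(states[[i]][was_loose] == "loose"))
  }
})

test_that("unresolvable topology residues name the failing glycan index", {
  g <- make_glycan_state_trajectory(n_frames = 1, seed = 1)
  topo <- glycan_topology("U", c(1:6, 99))
  expect_error(
    classify_frame(get_frame(g$trajectory, 1), topo,
                   state_spec(g$spec$reference, probe_indices = 2:7)),
    "index 7")
})

test_that("state fractions count designed frames exactly and sum to one", {
  g <- make_glycan_state_trajectory(n_frames = 100,
                                    n_loose = c(U = 34, V = 0), seed = 3)
  fr <- state_fractions(classify_glycan_states(g$trajectory, g$topologies,
                                               g$spec))
  expect_equal(fr$f_loose[fr$chain == "U"], 0.34)
  expect_equal(fr$f_loose[fr$chain == "V"], 0)
  expect_equal(fr$f_bound + fr$f_loose, c(1, 1), tolerance = 1e-12)
})

test_that("fractions over concatenated trajectories are frame-weighted", {
  g1 <- make_glycan_state_trajectory(n_frames = 40, n_loose = c(U = 10),
                                     seed = 1)
  g2 <- make_glycan_state_trajectory(n_frames = 60, n_loose = c(U = 30),
                                     seed = 2)
  s1 <- classify_glycan_states(g1$trajectory, g1$topologies, g1$spec)
  s2 <- classify_glycan_states(g2$trajectory, g2$topologies, g2$spec)
  both <- dplyr::bind_rows(s1, dplyr::mutate(s2, frame = .data$frame + 40))
  f_all <- state_fractions(both)$f_loose
  f_wtd <- (40 * state_fractions(s1)$f_loose +
              60 * state_fractions(s2)$f_loose) / 100
  expect_equal(f_all, f_wtd, tolerance = 1e-12)
})

test_that("sampled loose fractions land within binomial error of the design", {
  p <- 0.345
  g <- make_glycan_state_trajectory(n_frames = 400, p_loose = c(U = p),
                                    seed = 12)
  fr <- state_fractions(classify_glycan_states(g$trajectory, g$topologies,
                                               g$spec))
  se <- sqrt(p * (1 - p) / 400)
  expect_lt(abs(fr$f_loose - p), 3 * se)
  # and classification agrees with the generator's own labels
  st <- classify_glycan_states(g$trajectory, g$topologies, g$spec)
  joined <- dplyr::inner_join(st, g$truth, by = c("frame", "chain"))
  expect_true(all(joined$state.x == joined$state.y))
})

test_that("accessibility: on-plane centre target is reachable", {
  geom <- accessibility_geometry(semi_major = 1.75, semi_minor = 1.0,
                                 probe_radius = 0.5)
  res <- accessibility_check(c(0, 0, 0), entrance_plane(), geom)
  expect_true(res$accessible)
  expect_false(res$blocked)
})

test_that("a probe wider than the entrance is geometrically blocked", {
  # CRD-sized probe (1.5 nm radius) vs 1.0 nm semi-minor axis: cannot pass
  geom <- accessibility_geometry(semi_major = 1.75, semi_minor = 1.0,
                                 probe_radius = 1.5)
  res <- accessibility_check(c(0, 0, -1), entrance_plane(), geom)
  expect_false(res$accessible)
  expect_true(res$blocked)
})

test_that("a target exactly contact-distance past the deepest probe surface sits on the accessibility boundary", {
  geom <- accessibility_geometry(semi_major = 1.75, semi_minor = 1.0,
                                 probe_radius = 0.5, contact_distance = 0.3)
  # deepest probe centre on the axis is the plane itself; its surface
  # reaches 0.5 nm deep; the boundary target is 0.3 nm beyond that
  depth <- geom$probe_radius + geom$contact_distance
  res <- accessibility_check(c(0, 0, -depth), entrance_plane(), geom)
  expect_true(res$accessible)
  expect_equal(res$margin, 0, tolerance = 1e-12)
  expect_equal(res$clearance, geom$contact_distance, tolerance = 1e-12)
  # one micron of extra depth tips it over
  deeper <- accessibility_check(c(0, 0, -depth - 1e-3), entrance_plane(), geom)
  expect_false(deeper$accessible)
})

test_that("off-axis targets combine depth and in-plane ellipse distance", {
  geom <- accessibility_geometry(semi_major = 1.75, semi_minor = 1.0,
                                 probe_radius = 0.5, contact_distance = 0.3)
  a <- geom$semi_major - geom$probe_radius
  # target below the plane, displaced along the major axis beyond the
  # shrunk ellipse: closest feasible centre is the shrunk-ellipse rim
  target <- c(a + 0.4, 0, -0.3)
  res <- accessibility_check(target, entrance_plane(), geom)
  want <- sqrt(0.4^2 + 0.3^2) - geom$probe_radius
  expect_equal(res$clearance, want, tolerance = 1e-6)
})
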