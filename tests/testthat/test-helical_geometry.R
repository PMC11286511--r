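test_that("screw decomposition handles pure translations and the identity", {
  p <- screw_decompose(rigid_transform(diag(3), c(0, 0, 5)))
  expect_equal(p$rise, 5)
  expect_equal(p$twist, 0)
  expect_equal(p$axis_direction, c(0, 0, 1))
  expect_error(screw_decompose(rigid_transform(diag(3), c(0, 0, 0))),
               "undefined")
})

test_that("screw decompose/recompose round-trips random transforms", {
  pts <- matrix(stats::rnorm(30 * 3, sd = 5), 30, 3)
  set.seed(42)
  for (i in 1:100) {
    t <- rigid_transform(random_rotation(), stats::rnorm(3, sd = 4))
    p <- screw_decompose(t)
    t2 <- screw_compose(p)
    expect_lt(max(abs(apply_transform(t, pts) - apply_transform(t2, pts))),
              1e-6)
    expect_gte(p$rise, 0)
    expect_true(p$twist > -180 && p$twist <= 180)
    expect_equal(sum(p$axis_direction^2), 1, tolerance = 1e-9)
  }
})

test_that("propagation applies the generating transform exactly", {
  s <- make_bundle_subunit(3, 10, 7, seed = 1)
  f1 <- propagate(s, get_preset("identity"), 1)
  expect_equal(coords(f1$structure), coords(s), ignore_attr = TRUE)

  f2 <- propagate(s, get_preset("DpHF19"), 2)
  z <- coords(f2$structure)[, 3]
  n <- n_atoms(s)
  expect_equal(mean(z[(n + 1):(2 * n)]) - mean(z[1:n]), 8.4,
               tolerance = 1e-6)

  # cumulative rotation of copy 6 is 5 * -148.9 = -744.5 == 24.5 mod 360
  f6 <- propagate(s, get_preset("DpHF19"), 6)
  xy0 <- coords(s)[, 1:2]
  xy5 <- coords(extract_chain(f6$structure, "F"))[, 1:2]
  ang <- unname(atan2(xy5[1, 2], xy5[1, 1]) - atan2(xy0[1, 2], xy0[1, 1]))
  expect_equal(helifil:::wrap_angle(ang * 180 / pi),
               helifil:::wrap_angle(5 * -148.9), tolerance = 1e-6)
  expect_error(propagate(s, get_preset("DpHF19"), 0), ">= 1")
})

test_that("helical fit recovers generating parameters from coordinates", {
  s <- make_bundle_subunit(3, 10, 7, seed = 2)
  ft <- propagate(s, rigid_transform(diag(3), c(0, 0, 5)), 10)
  p <- fit_helical_params(ft)
  expect_equal(p$rise, 5, tolerance = 1e-9)
  expect_equal(p$twist, 0, tolerance = 1e-9)

  # random generating transforms round-trip through propagate + fit
  set.seed(7)
  for (i in 1:20) {
    tw <- stats::runif(1, -170, 170)
    ri <- stats::runif(1, 2, 12)
    t <- rigid_transform(rot_z(tw), c(0, 0, ri))
    p <- fit_helical_params(propagate(s, t, 6))
    expect_equal(p$rise, ri, tolerance = 1e-6)
    expect_equal(p$twist, tw, tolerance = 1e-6)
  }
})

test_that("helical fit under coordinate noise matches an independent oracle", {
  s <- make_bundle_subunit(3, 10, 7, seed = 2)
  f <- propagate(s, get_preset("DpHF19"), 40)
  xyz <- coords(f$structure)
  noisy <- f$structure
  set.seed(11)
  noisy <- helifil:::set_coords(noisy, xyz + stats::rnorm(length(xyz), sd = 0.1))
  p <- fit_helical_params(noisy)
  expect_equal(p$rise, 8.4, tolerance = 0.05)
  expect_equal(p$twist, -148.9, tolerance = 0.5)

  # oracle: mean quaternion-method rotation angle over consecutive pairs
  subs <- helifil:::subunit_coord_list(noisy)
  angles <- vapply(seq_len(length(subs) - 1), function(i)
    quaternion_angle(subs[[i]], subs[[i + 1]]), numeric(1))
  expect_equal(abs(p$twist), mean(angles), tolerance = 0.05)
})

test_that("ring count closes helical twists at the documented tolerance", {
  expect_equal(ring_count(120), 3L)
  expect_equal(ring_count(90), 4L)
  expect_equal(ring_count(-148.9), 5L)
  # exhaustive-scan oracle for the -148.9 case
  resid <- vapply(2:24, function(n)
    abs(n * -148.9 - 360 * round(n * -148.9 / 360)), numeric(1))
  expect_equal((2:24)[which(resid < 30)[1]], 5L)
  expect_equal(resid[5 - 1], 24.5, tolerance = 1e-9)   # residual at n = 5
  expect_gt(resid[2 - 1], 30)                          # 62.2 at n = 2 fails
})

test_that("ring count is invariant to sign flips and whole turns", {
  for (tw in c(-148.9, 120, 77.3, 171)) {
    expect_equal(ring_count(-tw), ring_count(tw))
    expect_equal(ring_count(tw + 360), ring_count(tw))
    expect_equal(ring_count(tw - 720), ring_count(tw))
  }
  expect_true(is.na(ring_count(0)))
})

test_that("strand step distinguishes one- and two-start packing", {
  s <- make_bundle_subunit(3, 10, 6, seed = 1)
  dense <- propagate(s, rigid_transform(rot_z(60), c(0, 0, 4)), 8)
  expect_equal(strand_step(dense), 1L)
  # off-axis subunit with a huge rise: no copies ever touch
  at <- make_bundle_subunit(1, 8, 0, seed = 1)$atoms
  at$x <- at$x + 12
  sparse <- propagate(structure3d(at),
                      rigid_transform(rot_z(180), c(0, 0, 30)), 8)
  expect_error(strand_step(sparse), "no inter-subunit contacts")
  expect_error(strand_step(dense, contact_cutoff = 0.1), "no inter-subunit")
})

test_that("a two-strand construction yields strand step 2", {
  # flat subunit displaced from the axis; twist 180 with tall rise makes
  # copies i, i+2 stack above each other while i, i+1 sit across the axis
  s <- make_bundle_subunit(1, 8, 0, seed = 1)
  at <- s$atoms; at$x <- at$x + 12
  sub <- structure3d(at)
  f <- propagate(sub, rigid_transform(rot_z(180), c(0, 0, 6)), 8)
  expect_equal(strand_step(f), 2L)
})

test_that("antiparallel detection flags D1-style constructions only", {
  s <- make_bundle_subunit(1, 10, 0, seed = 1)
  f <- propagate(s, get_preset("DpHF19"), 6)
  res <- detect_antiparallel(f)
  expect_false(res$antiparallel)
  expect_true(all(res$signs == res$signs[1]))

  # flip every second copy by 180 degrees about x (perpendicular axis)
  at <- f$structure$atoms
  for (ch in chain_ids(f$structure)[c(2, 4, 6)]) {
    idx <- at$chain == ch
    xyz <- as.matrix(at[idx, c("x", "y", "z")])
    at[idx, c("x", "y", "z")] <- xyz %*% t(rot_axis(c(1, 0, 0), 180))
  }
  res2 <- detect_antiparallel(structure3d(at, validate = FALSE))
  expect_true(res2$antiparallel)
  expect_setequal(unique(res2$signs), c(1, -1))

  # single subunit: one sign, not antiparallel
  expect_false(detect_antiparallel(propagate(s, get_preset("DpHF19"), 1))$antiparallel)
})

test_that("strand step and antiparallel detection are rigid-motion invariant", {
  s <- make_bundle_subunit(1, 8, 0, seed = 1)
  at <- s$atoms; at$x <- at$x + 12
  f <- propagate(structure3d(at), rigid_transform(rot_z(180), c(0, 0, 6)), 8)
  set.seed(5)
  R <- random_rotation(); tr <- stats::rnorm(3, sd = 20)
  moved <- helifil:::set_coords(f$structure,
                                sweep(coords(f$structure) %*% t(R), 2, tr, "+"))
  expect_equal(strand_step(moved), strand_step(f))
  ax <- as.numeric(R %*% c(0, 0, 1))
  expect_equal(detect_antiparallel(moved, ax)$antiparallel,
               detect_antiparallel(f)$antiparallel)
})

test_that("dock sampling flags clashes and contacts like brute force", {
  one <- structure3d(data.frame(name = "CA", element = "C", x = 0, y = 0,
                                z = 0, resno = 1L, resid = "ALA", chain = "A"))
  d <- sample_docks(one, list(rise = c(8, 10), twist = c(100, 150)))
  expect_true(all(!d$clash))
  expect_true(all(d$n_contacts == 0))

  two <- structure3d(data.frame(name = c("C1", "C2"), element = "C",
                                x = c(0, 3), y = 0, z = 0, resno = 1L,
                                resid = "ALA", chain = "A"))
  d0 <- sample_docks(two, list(rise = c(0, 20), twist = 0))
  expect_true(d0$clash[d0$rise == 0])       # self-overlap at rise 0
  expect_false(d0$clash[d0$rise == 20])

  # brute-force oracle on a 5x5 grid with the 3-helix fixture
  s <- make_bundle_subunit(3, 6, 7, seed = 1)
  grid <- list(rise = seq(4, 16, length.out = 5),
               twist = seq(-170, 170, length.out = 5))
  d <- sample_docks(s, grid)
  xyz <- coords(helifil:::heavy(s))
  cen <- colMeans(xyz)
  for (r in seq_len(nrow(d))) {
    placed <- sweep(xyz, 2, cen)
    placed <- sweep(placed, 2, cen, "+")
    t <- rigid_transform(rot_z(d$twist[r]), c(0, 0, d$rise[r]))
    copies <- lapply(0:4, function(k) apply_transform(transform_power(t, k), placed))
    mind <- Inf; ncon <- 0L
    for (a in 1:4) for (b in (a + 1):5) {
      dd <- sqrt(helifil:::cross_dist2(copies[[a]], copies[[b]]))
      mind <- min(mind, min(dd))
      if (a == 1) ncon <- ncon + sum(dd <= 4.5)
    }
    expect_equal(d$clash[r], mind < 2.4)
    expect_equal(d$n_contacts[r], ncon)
    expect_equal(d$min_distance[r], mind, tolerance = 1e-9)
  }
  expect_error(sample_docks(s, list(rise = numeric(), twist = 1)), "grid")
})
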