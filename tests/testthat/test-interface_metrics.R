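carbon_at <- function(x, y = 0, z = 0, chain = "A", resno = 1L, name = "C1") {
  data.frame(name = name, element = "C", x = x, y = y, z = z,
             resno = resno, resid = "ALA", chain = chain)
}

test_that("SASA matches closed-form sphere and spherical-cap areas", {
  iso <- structure3d(carbon_at(0))
  a <- sasa(iso)
  expect_equal(sum(a), 4 * pi * (1.7 + 1.4)^2, tolerance = 0.01)

  # far-separated spheres are each isolated
  two_far <- structure3d(rbind(carbon_at(0), carbon_at(50, resno = 2L)))
  a2 <- sasa(two_far)
  expect_equal(unname(a2[1]), unname(a2[2]), tolerance = 1e-9)
  expect_equal(sum(a2), 2 * 4 * pi * 3.1^2, tolerance = 0.01)

  # overlapping equal spheres: total = 2*(4 pi R^2) - 2*cap, cap = 2 pi R h,
  # h = R - d/2 for equal radii
  d <- 4
  two <- structure3d(rbind(carbon_at(0), carbon_at(d, resno = 2L)))
  R <- 1.7 + 1.4
  analytic <- 2 * 4 * pi * R^2 - 2 * 2 * pi * R * (R - d / 2)
  expect_equal(sum(sasa(two)), analytic, tolerance = 0.01 * analytic)

  expect_error(sasa(structure3d(data.frame(
    name = "X", element = "XX", x = 0, y = 0, z = 0, resno = 1L,
    resid = "UNK", chain = "A"))), "XX")
})

test_that("SASA is invariant under rigid motion of the molecule", {
  s <- make_bundle_subunit(1, 8, 0, seed = 2)
  base <- sum(sasa(s))
  set.seed(9)
  for (i in 1:3) {
    R <- random_rotation(); tr <- stats::rnorm(3, sd = 30)
    moved <- helifil:::set_coords(s, sweep(coords(s) %*% t(R), 2, tr, "+"))
    expect_equal(sum(sasa(moved)), base, tolerance = 0.005 * base)
  }
})

test_that("interface area: zero when apart, symmetric, refinement-stable", {
  s <- make_bundle_subunit(1, 10, 0, seed = 1)
  far <- offset_pair(s, 60)
  expect_identical(interface_area(far, 1, 2), 0)

  pair <- offset_pair(s, 9)
  a_ij <- interface_area(pair, 1, 2)
  expect_gt(a_ij, 0)
  expect_identical(a_ij, interface_area(pair, 2, 1))
  # refinement oracle: doubled quadrature density within 2%
  fine <- interface_area(pair, 1, 2, n_points = 1920)
  expect_equal(a_ij, fine, tolerance = 0.02 * fine)
  # per-side convention is exactly half
  expect_equal(interface_area(pair, 1, 2, per_side = TRUE), a_ij / 2)
})

test_that("shape complementarity reproduces the planar closed form", {
  pd0 <- plane_dots(0)
  expect_equal(sc_dots(pd0$a, pd0$na, pd0$b, pd0$nb), 1, tolerance = 0.02)
  pd1 <- plane_dots(1)
  expect_equal(sc_dots(pd1$a, pd1$na, pd1$b, pd1$nb), exp(-0.5 * 1^2),
               tolerance = 0.02)
  pd2 <- plane_dots(2)
  expect_equal(sc_dots(pd2$a, pd2$na, pd2$b, pd2$nb), exp(-0.5 * 4),
               tolerance = 0.02)
})

test_that("random unmated patches score poorly", {
  set.seed(17)
  for (i in 1:20) {
    da <- matrix(stats::runif(60, 0, 5), ncol = 3)
    db <- matrix(stats::runif(60, 0, 5), ncol = 3)
    rn <- function(n) {
      m <- matrix(stats::rnorm(3 * n), ncol = 3)
      m / sqrt(rowSums(m^2))
    }
    expect_lt(sc_dots(da, rn(20), db, rn(20)), 0.3)
  }
})

test_that("structure-level Sc is symmetric, bounded, high for mated pairs", {
  s <- make_bundle_subunit(1, 10, 0, seed = 1)
  pair <- offset_pair(s, 9)
  sc <- shape_complementarity(pair, 1, 2)
  expect_true(sc >= -1 && sc <= 1)
  expect_equal(shape_complementarity(pair, 2, 1), sc)
  # helix packed against itself is reasonably complementary
  expect_gt(sc, 0.3)
  far <- offset_pair(s, 60)
  expect_error(shape_complementarity(far, 1, 2), "empty buried patch")
})

test_that("unsatisfied polar counting follows burial and partner gates", {
  # poly-alanine helix pair: backbone O(i)/N(i+4) pairs satisfy everything
  s <- make_bundle_subunit(1, 12, 0, seed = 1)
  pair <- offset_pair(s, 9)
  expect_equal(unsat_polar_count(pair, 1, 2), 0)

  # bury an asparagine OD1 between carbon shells with no polar partner
  shell <- do.call(rbind, lapply(seq_len(20), function(i) {
    ang <- 2 * pi * i / 20
    carbon_at(3.2 * cos(ang), 3.2 * sin(ang), 0, chain = "B",
              resno = as.integer(i), name = "C1")
  }))
  shell2 <- shell; shell2$z <- 2.8; shell2$resno <- 21:40
  shell3 <- shell; shell3$z <- -2.8; shell3$resno <- 41:60
  caps <- rbind(carbon_at(0, 0, 4.2, "B", 61L, "C1"),
                carbon_at(0, 0, -4.2, "B", 62L, "C1"))
  asn <- data.frame(name = "OD1", element = "O", x = 0, y = 0, z = 0,
                    resno = 1L, resid = "ASN", chain = "A")
  cage <- rbind(shell, shell2, shell3, caps)
  buried <- structure3d(rbind(asn, cage))
  expect_equal(unsat_polar_count(buried, 1, 2), 1)
  # brute force: the cage holds no polar atom at all, and every shell atom
  # sits beyond hydrogen-bond range is irrelevant -- carbons cannot satisfy
  expect_true(all(cage$element == "C"))

  # fully exposed polar residue is never counted
  lone <- structure3d(rbind(asn, carbon_at(6, chain = "B", name = "C1")))
  expect_equal(unsat_polar_count(lone, 1, 2), 0)
})

test_that("contact pseudo-energy matches a hand-countable construction", {
  # 10 residue pairs x 2 atom pairs at 4.0 A; cross pairs at 5.0 A excluded
  rows <- list()
  for (i in 1:10) {
    rows[[length(rows) + 1]] <- carbon_at(0, 0, 10 * i, "A", as.integer(i), "C1")
    rows[[length(rows) + 1]] <- carbon_at(0, 3, 10 * i, "A", as.integer(i), "C2")
    rows[[length(rows) + 1]] <- carbon_at(4, 0, 10 * i, "B", as.integer(i), "C1")
    rows[[length(rows) + 1]] <- carbon_at(4, 3, 10 * i, "B", as.integer(i), "C2")
  }
  s <- structure3d(do.call(rbind, rows))
  expect_equal(energy_gap(s, 1), -20)
  expect_equal(energy_gap(s, 2), -20)          # symmetric context

  # the per-residue-pair cap binds: 5 atoms within range on one pair -> -3
  capped <- structure3d(rbind(
    carbon_at(0, 0, 0, "A", 1L, "C1"),
    carbon_at(4, 0.0, 0, "B", 1L, "C1"), carbon_at(4, 0.5, 0, "B", 1L, "C2"),
    carbon_at(4, 1.0, 0, "B", 1L, "C3"), carbon_at(4, 1.5, 0, "B", 1L, "C4"),
    carbon_at(4, 2.0, 0, "B", 1L, "C5")))
  expect_equal(energy_gap(capped, 1), -3)

  # clashes penalize: same dock with a clash atom is strictly worse
  clash <- structure3d(rbind(carbon_at(0, 0, 0, "A", 1L, "C1"),
                             carbon_at(1.0, 0, 0, "B", 1L, "C1"),
                             carbon_at(4.0, 0, 0, "B", 1L, "C2")))
  noclash <- structure3d(rbind(carbon_at(0, 0, 0, "A", 1L, "C1"),
                               carbon_at(4.0, 0, 0, "B", 1L, "C2")))
  expect_gt(energy_gap(clash, 1), energy_gap(noclash, 1))

  # isolated subunit has zero gap
  iso <- structure3d(rbind(carbon_at(0, chain = "A"),
                           carbon_at(100, chain = "B")))
  expect_equal(energy_gap(iso, 1), 0)
})

test_that("filter pipeline equals the one-line predicate scan", {
  r <- make_design_records(1000, seed = 7)
  res <- apply_filters(r)
  keep <- r$energy_gap < -15 & r$buried_area > 700 & r$sc > 0.62 &
    r$unsat_count < 5
  expect_identical(res$survivors$design_id, r$design_id[keep])
  expect_equal(res$report$survivors, sum(keep))
  expect_equal(res$report$removed_energy_gap, sum(!(r$energy_gap < -15)))
  expect_equal(res$report$removed_buried_area, sum(!(r$buried_area > 700)))
  expect_equal(res$report$removed_sc, sum(!(r$sc > 0.62)))
  expect_equal(res$report$removed_unsat, sum(!(r$unsat_count < 5)))
})

test_that("filters use strict inequalities and report attrition per criterion", {
  base <- data.frame(design_id = sprintf("d%d", 1:4), dock_id = "k1",
                     energy_gap = -20, buried_area = 900, sc = 0.8,
                     unsat_count = 2L)
  base$energy_gap[1] <- -10       # fails energy
  base$buried_area[2] <- 600      # fails area
  base$sc[3] <- 0.5               # fails sc
  base$unsat_count[4] <- 7L       # fails unsat
  res <- apply_filters(base)
  expect_equal(nrow(res$survivors), 0)
  expect_equal(res$report$removed_energy_gap, 1)
  expect_equal(res$report$removed_buried_area, 1)
  expect_equal(res$report$removed_sc, 1)
  expect_equal(res$report$removed_unsat, 1)

  # boundary values fail under strict inequalities
  edge <- data.frame(design_id = "e", dock_id = "k", energy_gap = -15,
                     buried_area = 700, sc = 0.62, unsat_count = 5L)
  expect_equal(nrow(apply_filters(edge)$survivors), 0)
  # empty input
  e <- apply_filters(make_design_records(0))
  expect_equal(nrow(e$survivors), 0)
  expect_equal(e$report$survivors, 0)
  expect_error(apply_filters(data.frame(energy_gap = 1)), "missing column")
})

test_that("filter survivors shrink under component-wise tightening", {
  r <- make_design_records(500, seed = 11)
  base_ids <- apply_filters(r)$survivors$design_id
  tighter <- list(filter_thresholds(max_energy_gap = -18),
                  filter_thresholds(min_area = 800),
                  filter_thresholds(min_sc = 0.7),
                  filter_thresholds(max_unsat = 3))
  for (th in tighter)
    expect_true(all(apply_filters(r, th)$survivors$design_id %in% base_ids))
})

test_that("top-per-dock selection equals group-by-min brute force", {
  r <- make_design_records(1000, seed = 7)
  top <- select_top_per_dock(r)
  expect_equal(nrow(top), length(unique(r$dock_id)))
  oracle <- do.call(rbind, lapply(split(r, r$dock_id), function(g) {
    g <- g[order(g$energy_gap, g$design_id), ]
    g[1, ]
  }))
  expect_equal(top$design_id, oracle$design_id)

  one <- r[5, ]
  expect_equal(select_top_per_dock(one)$design_id, one$design_id)

  crafted <- data.frame(design_id = sprintf("d%02d", 1:15),
                        dock_id = rep(c("a", "b", "c"), each = 5),
                        energy_gap = c(5:1, 1:5, c(3, 1, 1, 4, 5)))
  top3 <- select_top_per_dock(crafted)
  expect_equal(top3$design_id, c("d05", "d06", "d12"))  # tie in dock c -> lexical
})
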