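# a linear O-H...O geometry at given donor-acceptor distance and angle
linear_hbond_system <- function(d_da = 0.28, angle = 180) {
  # donor at origin, H at 0.1 along +z; acceptor placed so the D-H...A angle
  # at H equals `angle` with |D-A| = d_da
  th <- (180 - angle) * pi / 180
  # acceptor direction from H making the requested angle with H->D (-z)
  a_dir <- c(sin(th), 0, cos(th))
  # numerically slide the H-A distance until |D-A| = d_da
  f <- function(r) {
    a <- c(5, 5, 5.1) + r * a_dir
    sqrt(sum((a - c(5, 5, 5))^2)) - d_da
  }
  r <- uniroot(f, c(0.01, d_da + 0.2))$root
  a_pos <- c(5, 5, 5.1) + r * a_dir
  particle_system(rbind(c(5, 5, 5), c(5, 5, 5.1), a_pos),
                  masses = c(16, 1, 16), box_edge = 10,
                  atom_names = c("OD", "HD", "OA"),
                  residue_ids = c(1L, 1L, 2L),
                  residue_names = c("SER", "SER", "THR"),
                  bonds = data.frame(i = 1, j = 2, kb = 1000, r0 = 0.1))
}

test_that("a prototypical linear hydrogen bond is detected", {
  hb <- detect_hbonds(linear_hbond_system(0.28, 180), donors = 1,
                      acceptors = 3)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$distance, 0.28, tolerance = 1e-6)
  expect_equal(hb$angle, 180, tolerance = 1e-6)
  expect_equal(hb$donor_residue, "SER1")
  expect_equal(hb$acceptor_residue, "THR2")
})

test_that("distance and angle cutoffs reject marginal geometries", {
  expect_equal(nrow(detect_hbonds(linear_hbond_system(0.40, 180), 1, 3)), 0L)
  expect_equal(nrow(detect_hbonds(linear_hbond_system(0.30, 120), 1, 3)), 0L)
  # just inside both criteria
  expect_equal(nrow(detect_hbonds(linear_hbond_system(0.34, 155), 1, 3)), 1L)
})

test_that("a donor without a bonded hydrogen is a configuration error", {
  sys <- particle_system(matrix(c(1, 1, 1, 1, 1, 1.3), 2, byrow = TRUE),
                         masses = c(16, 16), box_edge = 10,
                         atom_names = c("OD", "OA"))
  expect_error(detect_hbonds(sys, 1, 2), "no bonded hydrogen")
})

test_that("criteria monotonicity: wider cutoffs never remove detections", {
  for (d in c(0.27, 0.32, 0.34)) for (a in c(152, 165, 178)) {
    sys <- linear_hbond_system(d, a)
    n_tight <- nrow(detect_hbonds(sys, 1, 3, hbond_criteria(0.35, 150)))
    n_loose <- nrow(detect_hbonds(sys, 1, 3, hbond_criteria(0.40, 140)))
    expect_gte(n_loose, n_tight)
  }
})

test_that("occupancy equals a per-frame brute-force count", {
  dists <- c(0.30, 0.30, 0.40, 0.30, 0.30, 0.45, 0.30, 0.30, 0.40, 0.30)
  tr <- crafted_hbond_traj(dists)
  tab <- hbond_occupancy(tr, donors = 1, acceptors = 3)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$occupancy, 0.7)
  # oracle: frame-by-frame loop
  manual <- mean(sapply(seq_along(dists), function(f)
    nrow(detect_hbonds(system_at_frame <- thzbind:::system_at_frame(tr, f),
                       1, 3)) > 0))
  expect_equal(tab$occupancy, manual)
})

test_that("never-detected pairs are absent from the table", {
  tr <- crafted_hbond_traj(rep(0.45, 5))
  tab <- hbond_occupancy(tr, donors = 1, acceptors = 3)
  expect_equal(nrow(tab), 0L)
})

test_that("empty windows are rejected", {
  tr <- crafted_hbond_traj(rep(0.3, 5))
  expect_error(hbond_occupancy(tr, 1, 3, window = integer(0)), "empty")
  expect_error(hbond_occupancy(tr, 1, 3, window = 99), "outside")
})

test_that("stable_set applies >= semantics at the threshold", {
  tab <- structure(data.frame(id = c("a", "b"), type = "hbond",
                              donor_residue = "x", acceptor_residue = "y",
                              occupancy = c(0.9, 0.4)),
                   criteria = hbond_criteria(), window = c(1, 10),
                   class = c("contact_table", "data.frame"))
  expect_equal(stable_set(tab, 0.5), "a")
  tab$occupancy <- c(1.0, 0.4)
  expect_equal(stable_set(tab, 1.0), "a")
  expect_error(stable_set(tab, 0), "threshold")
})

test_that("hydrophobic contacts follow the distance criterion and oracle", {
  mkframe <- function(d) {
    particle_system(rbind(c(5, 5, 5), c(5, 5, 5 + d)),
                    masses = c(12, 12), box_edge = 10,
                    atom_names = c("CA1", "CB1"),
                    residue_ids = c(1L, 2L),
                    residue_names = c("LIG", "CAG"))
  }
  d_seq <- c(0.38, 0.38, 0.45, 0.38, 0.45, 0.45, 0.38, 0.45, 0.45, 0.45)
  pos <- array(0, c(10, 2, 3))
  for (f in 1:10) pos[f, , ] <- mkframe(d_seq[f])$positions
  tr <- trajectory(mkframe(0.38), seq_len(10) * 0.1, pos)
  tab <- hydrophobic_contacts(tr)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$occupancy, 0.4)   # 4 of 10 frames within 0.40 nm
  # single frames
  expect_equal(nrow(hydrophobic_contacts(
    trajectory(mkframe(0.45), 0, array(mkframe(0.45)$positions,
                                       c(1, 2, 3))))), 0L)
})

test_that("network_diff reports set differences of stable ids", {
  mktab <- function(ids, occ) structure(
    data.frame(id = ids, type = "hbond", donor_residue = "x",
               acceptor_residue = "y", occupancy = occ),
    criteria = hbond_criteria(), window = c(1, 10),
    class = c("contact_table", "data.frame"))
  before <- mktab(c("a", "b"), c(0.9, 0.8))
  after <- mktab(c("a", "b", "c", "d"), c(0.9, 0.8, 0.7, 0.6))
  nd <- network_diff(before, after)
  expect_setequal(nd$added, c("c", "d"))
  expect_length(nd$removed, 0)
  expect_setequal(nd$retained, c("a", "b"))
  # identity
  nd2 <- network_diff(before, before)
  expect_length(nd2$added, 0)
  expect_setequal(nd2$retained, c("a", "b"))
  # criteria mismatch
  odd <- mktab("a", 0.9); attr(odd, "criteria") <- hbond_criteria(d_max = 0.4)
  expect_error(network_diff(before, odd), "different criteria")
})

test_that("occupancy tables are deterministic", {
  tr <- crafted_hbond_traj(c(0.3, 0.4, 0.3, 0.3, 0.45))
  t1 <- hbond_occupancy(tr, 1, 3)
  t2 <- hbond_occupancy(tr, 1, 3)
  expect_identical(t1, t2)
})
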