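test_that("pivot-shift transform is a screw with angle s*twist and slide s*rise", {
  bb <- fixture_parent()
  pivot <- as.list(bb$helices[4, ])
  tr0 <- pivot_shift_transform(bb, pivot, 0)
  expect_equal(tr0$rotation, diag(3))
  expect_equal(tr0$translation, c(0, 0, 0))
  tr1 <- pivot_shift_transform(bb, pivot, 1)
  sd1 <- screw_decompose(tr1)
  expect_equal(sd1$angle_deg, 100, tolerance = 1 / 100)
  expect_equal(sd1$slide, 1.5, tolerance = 0.05 / 1.5)
  # the screw axis is the pivot helix axis
  ax <- fit_helix_axis(bb, pivot$chain, pivot$start, pivot$end)
  expect_equal(abs(sum(sd1$axis_dir * ax$axis_dir)), 1, tolerance = 1e-6)
  # inverse shifts compose to the identity
  trm1 <- pivot_shift_transform(bb, pivot, -1)
  comp <- compose_transform(trm1, tr1)
  expect_equal(comp$rotation, diag(3), tolerance = 1e-6)
  expect_equal(comp$translation, c(0, 0, 0), tolerance = 1e-6)
  # insufficient overlap errors
  expect_error(pivot_shift_transform(bb, pivot, 15), "overlap")
})

test_that("screw angle and slide scale linearly with the register shift", {
  bb <- fixture_parent()
  pivot <- as.list(bb$helices[4, ])
  s <- setdiff(-3:3, 0)
  sd <- lapply(s, function(si)
    screw_decompose(pivot_shift_transform(bb, pivot, si)))
  ang <- vapply(sd, `[[`, numeric(1), "angle_deg")
  sl <- vapply(sd, `[[`, numeric(1), "slide")
  # angle folds into [0, 180]: compare against the folded ideal value
  ideal <- abs(s) * 100
  ideal <- ifelse(ideal > 180, 360 - ideal, ideal)
  expect_true(all(abs(ang - ideal) < 1))
  expect_true(all(abs(sl - abs(s) * 1.5) < 0.05))
  r2 <- summary(stats::lm(sl ~ abs(s)))$r.squared
  expect_gt(r2, 0.999)
})

test_that("two-state compatibility invariants hold exactly", {
  for (states in list(fixture_states(), fixture_states_bigmove(),
                      assemble_states(fixture_parent(),
                                      hinge_spec(4, -1, "preceding_copy")))) {
    # domain 1 bitwise identical between the states
    d1x <- bb_subset(states$state_x, resno = 1:states$d1_end)
    d1y <- bb_subset(states$state_y, resno = 1:states$d1_end)
    expect_identical(d1x$atoms[, c("x", "y", "z")], d1y$atoms[, c("x", "y", "z")])
    if (states$spec$peptide_rule == "following_original") {
      # (domain 1 U peptide) superposes onto parent helices 1..p+1 with RMSD 0
      p1 <- states$helices$end[states$spec$pivot_index + 1]
      ref <- atom_coords(bb_subset(states$state_x,
                                   resno = c(1:states$d1_end,
                                             states$d2_start:p1)), "CA")
      un <- rbind(atom_coords(d1x, "CA"), atom_coords(states$peptide, "CA"))
      expect_lt(superpose(un, ref)$rmsd, 1e-9)
    } else {
      # (peptide U domain 2) superposes onto the transformed copy helices p..n
      pstart <- states$helices$start[states$spec$pivot_index]
      copy <- bb_transform(bb_subset(states$state_x,
                                     resno = pstart:max(states$state_x$residues$resno)),
                           states$transform)
      d2 <- bb_subset(states$state_y,
                      resno = states$d2_start:max(states$state_y$residues$resno))
      un <- rbind(atom_coords(states$peptide, "CA"), atom_coords(d2, "CA"))
      ref <- atom_coords(bb_subset(copy, resno = c(states$helices$start[states$spec$pivot_index]:states$helices$end[states$spec$pivot_index],
                                                   states$d2_start:max(copy$residues$resno))), "CA")
      expect_lt(superpose(un, ref)$rmsd, 1e-9)
    }
  }
})

test_that("assembly validates the pivot position and helix count", {
  bb <- fixture_parent()
  expect_error(assemble_states(bb, hinge_spec(1, 1)), "pivot_index")
  expect_error(assemble_states(bb, hinge_spec(8, 1)), "pivot_index")
  expect_error(assemble_states(ideal_helix(30), hinge_spec(2, 1)),
               "at least 4 helices")
})

test_that("the clash-free large-shift state separates domains by tens of Angstrom", {
  states <- fixture_states()
  expect_equal(states$report$clash_y, 0L)
  cax <- atom_coords(states$state_x, "CA")
  resx <- states$state_x$residues$resno
  cay <- atom_coords(states$state_y, "CA")
  resy <- states$state_y$residues$resno
  common <- intersect(resx[resx >= states$d2_start], resy)
  disp <- sqrt(rowSums((cax[match(common, resx), ] -
                          cay[match(common, resy), ])^2))
  expect_gt(max(disp), 20)
})

test_that("grid clash counting equals the brute-force all-pairs oracle", {
  brute <- function(bb, cutoff = 3.2, excl = 2) {
    a <- bb$atoms
    d <- as.matrix(stats::dist(as.matrix(a[, c("x", "y", "z")])))
    sep <- abs(outer(a$resno, a$resno, "-"))
    dc <- outer(a$chain, a$chain, "!=")
    sum(upper.tri(d) & d < cutoff & (dc | sep > excl))
  }
  # elementary construction: exactly one non-bonded pair at 2.0 A
  two <- backbone(data.frame(chain = "A", resno = c(1, 4), elety = "CA",
                             x = c(0, 2), y = 0, z = 0), validate = FALSE)
  expect_equal(clash_count(two), brute(two))
  expect_equal(clash_count(two), 1L)
  # the same pair within the bonded exclusion is not a clash
  bonded <- backbone(data.frame(chain = "A", resno = c(1, 3), elety = "CA",
                                x = c(0, 2), y = 0, z = 0), validate = FALSE)
  expect_equal(clash_count(bonded), 0L)
  # the parent fixture is clash-free by construction
  expect_equal(clash_count(fixture_parent()), 0L)
  # random clouds, grid == brute force
  set.seed(61)
  for (i in 1:100) {
    n <- 60
    cloud <- backbone(data.frame(chain = sample(c("A", "B"), n, TRUE),
                                 resno = sample(1:20, n, TRUE),
                                 elety = "CA",
                                 x = runif(n, 0, 15), y = runif(n, 0, 15),
                                 z = runif(n, 0, 15)),
                      validate = FALSE)
    expect_equal(clash_count(cloud), brute(cloud))
  }
})

test_that("contact energy reflects groove occupancy and is rigid-motion invariant", {
  states <- fixture_states()
  e <- states$report$energies
  expect_equal(contact_energy(backbone(data.frame(chain = character(0),
                                                  resno = integer(0),
                                                  elety = character(0),
                                                  x = numeric(0), y = numeric(0),
                                                  z = numeric(0)),
                                       validate = FALSE),
                              integer(0)), 0)
  # vacating the groove raises the hinge-alone energy; docking the peptide
  # lowers the complex below the empty state Y hinge
  expect_lt(e$e_x, e$e_y_hinge)
  expect_lt(e$e_complex, e$e_y_hinge)
  expect_equal(e$e_peptide, 0)
  # global rigid motion leaves all gate energies unchanged
  set.seed(71)
  tr <- random_rigid()
  moved <- states
  for (f in c("state_x", "state_y", "peptide", "complex_y"))
    moved[[f]] <- bb_transform(states[[f]], tr)
  g2 <- two_state_gate(moved)
  expect_equal(g2$energies, e)
})

test_that("the two-state gate selects the designed geometry and rejects bad shifts", {
  expect_true(fixture_states()$report$gate$pass)
  expect_true(fixture_states_bigmove()$report$gate$pass)
  # a shift that collapses the rotated domain onto domain 1 fails the gate
  bad <- assemble_states(fixture_parent(), hinge_spec(4, 1))
  expect_gt(bad$report$clash_y, 0)
  expect_false(bad$report$gate$pass_complex_lower)
  expect_false(bad$report$gate$pass)
})

test_that("label-site pairs are cross-domain, sign-filtered and ranked", {
  states <- fixture_states()
  inc <- site_pairs(states, "increase", 10)
  dec <- site_pairs(states, "decrease", 10)
  # one residue per domain: delta would be exactly 0 within a rigid domain
  expect_true(all(inc$res_i <= states$d1_end & inc$res_j >= states$d2_start))
  expect_true(all(inc$d_y > inc$d_x))
  expect_true(all(dec$d_y < dec$d_x))
  expect_true(all(diff(abs(inc$delta)) <= 1e-12))
  expect_equal(inc$delta, inc$d_y - inc$d_x)
  # the large-motion design reaches label distance changes over 20 A
  big <- site_pairs(fixture_states_bigmove(), "decrease", 1)
  expect_gte(abs(big$delta[1]), 20)
})

test_that("staple candidates are state-selective by construction", {
  states <- fixture_states()
  for (lock in c("X", "Y")) {
    st <- staple_candidates(states, lock)
    if (nrow(st) == 0) next
    din <- if (lock == "X") st$d_x else st$d_y
    dout <- if (lock == "X") st$d_y else st$d_x
    expect_true(all(din >= 3.5 & din <= 5.5))
    expect_true(all(dout > 10))
  }
  # a pair bonded in both states is never returned
  stx <- staple_candidates(states, "X")
  sty <- staple_candidates(states, "Y")
  expect_length(intersect(paste(stx$res_i, stx$res_j),
                          paste(sty$res_i, sty$res_j)), 0)
  # lock-X candidates exist on this fixture (interfaces lost in state Y)
  expect_gt(nrow(stx), 0)
})

test_that("loop feasibility follows the virtual-bond bound", {
  expect_true(loop_feasibility(10, 3))   # limit 15.2
  expect_false(loop_feasibility(20, 3))
  expect_true(loop_feasibility(0, 0))
  expect_true(loop_feasibility(0, 5))
  expect_error(loop_feasibility(-1, 3), "non-negative")
  expect_error(loop_feasibility(5, -1), "non-negative")
})
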