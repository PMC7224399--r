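test_that("SPH diabody bead/bond/angle counts follow the linker length", {
  for (N in c(1, 5, 10, 30)) {
    s <- buildSphDiabody(N, "repulsive#2")
    expect_equal(nBeads(s), N + 6 + 1)           # diabody beads + epitope
    expect_equal(nrow(bonds(s)), N + 1)          # chain + connector links
    nRestraints <- if (N >= 2) 4 else 2
    expect_equal(nrow(angles(s)), max(N - 2, 0) + nRestraints)
    expect_length(rigidGroups(s), 2)
  }
  s <- buildSphDiabody(10, "repulsive#2", tethered = FALSE)
  expect_equal(nBeads(s), 16)
})

test_that("SPH geometry: bead sizes and tangent pole placement", {
  s <- buildSphDiabody(10, "repulsive#2")
  b <- beads(s)
  expect_equal(b$diameter[b$name == "NB1"], 10)
  expect_equal(b$diameter[b$name == "P1"], 1.6)
  expect_equal(b$diameter[b$name == "CB1"], 1)
  expect_true(all(b$diameter[grepl("^L", b$name)] == 1))
  x <- startCoords(s)
  dPN <- sqrt(sum((x["P1", ] - x["NB1", ])^2))
  expect_equal(dPN, 5 + 0.8, tolerance = 1e-12)
  dCN <- sqrt(sum((x["CB1", ] - x["NB1", ])^2))
  expect_equal(dCN, 5 + 0.5, tolerance = 1e-12)
  # paratope and connector at diametrically opposite poles
  u1 <- (x["P1", ] - x["NB1", ]) / dPN
  u2 <- (x["CB1", ] - x["NB1", ]) / dCN
  expect_equal(sum(u1 * u2), -1, tolerance = 1e-12)
  # exactly one fixed epitope on the lower wall side
  expect_equal(sum(b$group == "epitope"), 1)
  expect_true(b$fixed[b$group == "epitope"])
})

test_that("wall parameter sets encode the repulsive/attractive cutoff rule", {
  ws <- wallSetTable()
  expect_setequal(ws$set, c("repulsive#1", "repulsive#2", "attractive#1",
                            "attractive#2"))
  expect_equal(ws$epsWall[ws$set == "attractive#1"], 1.5)
  expect_equal(ws$epsWall[ws$set == "attractive#2"], 2.5)
  s1 <- buildSphDiabody(5, "repulsive#1")
  b <- beads(s1)
  wl <- s1@walls$lower
  expect_equal(wl$s[b$name == "NB1"], 4.5)
  expect_equal(wl$s[b$name == "NB2"], 3.0)
  expect_equal(wl$rcut[b$name == "NB2"], 2^(1/6) * 3.0)
  sa <- buildSphDiabody(5, "attractive#2")
  wa <- sa@walls$lower
  ba <- beads(sa)
  expect_equal(wa$rcut[ba$name == "NB1"], 2.5 * 4.5)   # 11.25
  expect_equal(wa$eps[ba$name == "P1"], 2.5)
  # linker and connectors stay repulsive under attractive walls
  expect_equal(unique(wa$rcut[ba$group == "linker"]), 2^(1/6) * 0.8)
  expect_error(buildSphDiabody(5, "no-such-wall"), "wall_set")
  expect_error(buildSphDiabody(0, "repulsive#1"), "positive integer")
})

test_that("linker chain combinatorics and force constants", {
  lk <- buildLinker(10)
  expect_equal(nrow(lk$bonds), 9)
  expect_equal(nrow(lk$angles), 8)
  expect_equal(unique(lk$bonds$r0), 1)
  expect_equal(unique(lk$angles$theta0), 180)
  lk1 <- buildLinker(1)
  expect_equal(nrow(lk1$bonds), 0)
  expect_error(buildLinker(0), "positive")
  # 54 N/m at 300 K in (1/2)k convention: ~1.6e3 kT/sigma^2, and a relative
  # bond fluctuation sqrt(kT/k)/r0 of about 2 percent
  kb <- bondConstantFromSI(54)
  expect_equal(kb, 1597, tolerance = 0.001)
  expect_lt(sqrt(1 / kb), 0.03)
  expect_gt(sqrt(1 / kb), 0.02)
})

test_that("bead radii follow cube-root mass scaling and conserve volume", {
  expect_equal(assignBeadRadii(44, 44), 0.5)
  expect_equal(assignBeadRadii(8 * 44, 44), 1.0)
  m <- c(30, 100, 250, 44)
  r <- assignBeadRadii(m, 44)
  # total bead volume equals total mass in units of the reference monomer
  vol <- sum((4 / 3) * pi * r^3)
  expect_equal(vol, sum(m / 44) * (4 / 3) * pi * 0.5^3, tolerance = 1e-12)
  expect_true(all(diff(r[order(m)]) > 0))   # monotone in mass
  expect_error(assignBeadRadii(c(1, -1)), "positive")
})

test_that("SBCG map: degenerate and clustered inputs", {
  # one bead: mass-weighted centroid
  cl <- fixtureClusterCloud(rbind(c(0, 0, 0)), nPer = 30, sd = 1,
                            mass = c(rep(1, 15), rep(3, 15)), seed = 2)
  nb1 <- buildSbcgNanobody(cl$coords, cl$masses, nBeads = 1, seed = 1)
  ctr <- colSums(cl$coords * cl$masses) / sum(cl$masses)
  expect_equal(unlist(nb1$beads[1, c("x", "y", "z")]), ctr,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(nb1$beads$mass, sum(cl$masses))

  # two well-separated clusters: beads land on the k-means centroids
  cl2 <- fixtureClusterCloud(rbind(c(-8, 0, 0), c(8, 0, 0)), nPer = 60,
                             sd = 0.5, seed = 3)
  nb2 <- buildSbcgNanobody(cl2$coords, cl2$masses, nBeads = 2, seed = 4)
  km <- stats::kmeans(cl2$coords, centers = rbind(c(-8, 0, 0), c(8, 0, 0)))
  got <- as.matrix(nb2$beads[, c("x", "y", "z")])
  got <- got[order(got[, 1]), ]
  want <- km$centers[order(km$centers[, 1]), ]
  expect_equal(got, want, tolerance = 0.15, ignore_attr = TRUE)

  expect_error(buildSbcgNanobody(matrix(0, 0, 3)), "empty")
  expect_error(buildSbcgNanobody(cl2$coords, cl2$masses, nBeads = 1000),
               "exceeds")
})

test_that("SBCG map of a nanobody-like cloud conserves mass and shape", {
  cloud <- syntheticNanobodyCloud(126, seed = 5)
  nb <- buildSbcgNanobody(cloud$coords, cloud$masses, nBeads = 40, seed = 6)
  expect_equal(nrow(nb$beads), 40)
  expect_equal(sum(nb$beads$mass), sum(cloud$masses))   # exact conservation
  ctrIn <- colSums(cloud$coords * cloud$masses) / sum(cloud$masses)
  ctrOut <- colSums(as.matrix(nb$beads[, c("x", "y", "z")]) * nb$beads$mass) /
    sum(nb$beads$mass)
  expect_lt(sqrt(sum((ctrIn - ctrOut)^2)), 0.3)
  expect_gt(nrow(nb$bonds), 30)            # connected network
  # supplied chain connectivity restricts bonds to chain-adjacent domains
  conn <- cbind(seq_len(125), seq_len(125) + 1)
  nbC <- buildSbcgNanobody(cloud$coords, cloud$masses, nBeads = 10, seed = 6,
                           connectivity = conn)
  expect_true(all(nbC$bonds$i != nbC$bonds$j))
})

test_that("SBCG diabody assembles with per-bead walls and anti-rotation dihedrals", {
  sb <- buildSbcgDiabody(6, "repulsive#1", seed = 2)
  b <- beads(sb)
  expect_equal(sum(b$group == "nanobody1"), 40)
  expect_equal(nrow(dihedrals(sb)), 2)
  expect_length(rigidGroups(sb), 0)        # flexible bodies
  # SBCG nanobody beads see the wall individually with s = 0.8
  expect_equal(unique(sb@walls$lower$s[b$group == "nanobody2"]), 0.8)
  # build starts essentially strain-free
  e <- systemEnergy(sb)
  expect_lt(e[["bond"]], 1)
})
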