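test_that("residue one-hot uses the canonical alphabet and zero rows for X", {
  m <- one_hot_residue(c("A", "X", "Y", "C"))
  expect_equal(dim(m), c(4, 20))
  expect_equal(m[1, ], setNames(c(1, rep(0, 19)),
                                strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
  expect_equal(sum(m[2, ]), 0)
  expect_equal(which(m[3, ] == 1), c(Y = 20L))
  expect_equal(rowSums(m), c(1, 0, 1, 1))
})

test_that("profile and embedding blocks are sigmoid-squashed with checked widths", {
  raw <- matrix(0, 3, 20)
  expect_equal(profile_features(raw), matrix(0.5, 3, 20))
  raw[1, 1] <- -11  # PSSM minimum
  expect_equal(profile_features(raw)[1, 1], 1 / (1 + exp(11)))
  expect_lt(profile_features(raw)[1, 1], 1.7e-5)
  expect_error(profile_features(matrix(0, 3, 19)), "expected 20")
  expect_equal(dim(plm_features(matrix(0, 30, 33))), c(30, 33))
  expect_equal(plm_features(matrix(0, 2, 33))[1, 1], 0.5)
  expect_error(plm_features(matrix(0, 3, 20)), "expected 33")
  mock <- mock_feature_providers(seed = 5)
  s <- strsplit("MKTAYIAKQR", "")[[1]]
  expect_identical(mock$profile(s), mock$profile(s))
  expect_equal(dim(mock$profile(s)), c(10, 20))
  expect_equal(dim(mock$embedding(s)), c(10, 33))
  prof <- profile_features(mock$profile(s))
  expect_true(all(prof > 0 & prof < 1))
})

test_that("PSI-BLAST ASCII PSSM files parse into L x 20 raw scores", {
  f <- withr::local_tempfile(fileext = ".pssm")
  hdr <- paste(c("", "Last position-specific scoring matrix computed",
                 paste0("    ", paste(rep(c("A", "R"), 10), collapse = "  "))),
               collapse = "\n")
  rows <- vapply(1:4, function(i) {
    paste(c(sprintf("%5d %s", i, c("M", "K", "T", "A")[i]),
            sprintf("%3d", seq(-5, 14) + i),
            sprintf("%4d", rep(10, 20)), " 1.0 1.2"), collapse = " ")
  }, "")
  writeLines(c(hdr, rows), f)
  m <- read_pssm(f)
  expect_equal(dim(m), c(4, 20))
  expect_equal(m[1, 1], -4)
  expect_equal(attr(m, "sequence"), c("M", "K", "T", "A"))
})

test_that("DSSP-derived block encodes SS and accessibility bins as specified", {
  rec <- data.frame(ss8 = c("H", "E", "T", "G", "B"),
                    acc = c(0, 250, 49, 50, 95))
  b <- dssp_features(rec)
  expect_equal(ncol(b), 21)  # 3 + 8 + 2 + 8
  # code H, ACC 0: helix, ss8 hot at H, buried, first accessibility bin
  expect_equal(unname(b[1, 1:3]), c(1, 0, 0))
  expect_equal(unname(b[1, 4]), 1)
  expect_equal(unname(b[1, 12:13]), c(0, 1))
  expect_equal(unname(which(b[1, 14:21] == 1)), 1)
  # ACC 250 falls in the >210 bin; E maps to strand
  expect_equal(unname(b[2, 1:3]), c(0, 1, 0))
  expect_equal(unname(which(b[2, 14:21] == 1)), 8)
  # T is coil in 3-state; boundary ACC 50 is exposed, 49 buried
  expect_equal(unname(b[3, 1:3]), c(0, 0, 1))
  expect_equal(unname(b[3, 12:13]), c(0, 1))
  expect_equal(unname(b[4, 12:13]), c(1, 0))
  # G is helix-like, B strand-like
  expect_equal(unname(b[4, 1:3]), c(1, 0, 0))
  expect_equal(unname(b[5, 1:3]), c(0, 1, 0))
  # every one-hot sub-block has unit row sums
  expect_true(all(rowSums(b[, 1:3]) == 1))
  expect_true(all(rowSums(b[, 4:11]) == 1))
  expect_true(all(rowSums(b[, 12:13]) == 1))
  expect_true(all(rowSums(b[, 14:21]) == 1))
  # missing records fall back to coil / buried with a message
  expect_message(
    b2 <- dssp_features(data.frame(ss8 = c("H", NA), acc = c(10, NA))),
    "without DSSP")
  expect_equal(unname(b2[2, 1:3]), c(0, 0, 1))
})

test_that("local geometry recovers helix torsions and pads termini with zeros", {
  m <- make_monomer(20, "helix", seed = 3)
  lg <- local_geometry_features(m)
  expect_equal(ncol(lg), 11)
  # interior residues: recover phi/psi from the sin/cos channels within 2
  # degrees of the ideal helix values, cross-checked against bio3d
  i <- 10
  phi <- atan2(lg[i, 6], lg[i, 7]) * 180 / pi
  psi <- atan2(lg[i, 8], lg[i, 9]) * 180 / pi
  expect_lt(abs(phi - (-57)), 2)
  expect_lt(abs(psi - (-47)), 2)
  bb <- m$backbone
  phi_ref <- bio3d::torsion.xyz(as.vector(t(rbind(
    bb$C[i - 1, ], bb$N[i, ], bb$CA[i, ], bb$C[i, ]))))
  expect_lt(abs(phi - phi_ref), 1e-6)
  # residue 1: all channels requiring i-1 are exactly zero
  expect_equal(unname(lg[1, c(2, 3, 4, 5, 6, 7)]), rep(0, 6))
  # omega of an ideal trans backbone is 180 deg: sin 0, cos -1
  expect_lt(abs(lg[i, 10]), 1e-6)
  expect_lt(abs(lg[i, 11] + 1), 1e-6)
})

test_that("positional features are 1/i and clamped inverse centroid distance", {
  m <- make_monomer(8, "coil", seed = 2)
  pf <- positional_features(m)
  expect_equal(pf[, 1], 1 / (1:8))
  expect_true(all(pf[, 2] <= 1))
  set.seed(4)
  mo <- random_rigid_motion()
  m2 <- m
  m2$backbone$CA <- apply_rigid(m$backbone$CA, mo)
  expect_equal(positional_features(m2)[, 2], pf[, 2], tolerance = 1e-9)
  # single C-alpha at the centroid clamps to 1
  ca1 <- matrix(c(3, 4, 5), 1, 3)
  m1 <- protein_monomer("A", "A", list(CA = ca1),
                        data.frame(res = 1, elety = "CA",
                                   x = 3, y = 4, z = 5))
  expect_equal(positional_features(m1)[1, 2], 1)
})

test_that("orientation vectors are unit forward/reverse/CB directions", {
  # collinear chain along +x at 3.8 A spacing
  L <- 6
  ca <- cbind(3.8 * (0:(L - 1)), 0, 0)
  n <- sweep(ca, 2, c(-1.0, 1.0, 0), "+")
  cc <- sweep(ca, 2, c(1.0, 1.0, 0), "+")
  m <- protein_monomer("A", rep("A", L),
                       list(N = n, CA = ca, C = cc),
                       data.frame(res = seq_len(L), elety = "CA",
                                  x = ca[, 1], y = ca[, 2], z = ca[, 3]))
  o <- orientation_features(m)
  expect_equal(ncol(o), 9)
  for (i in 2:(L - 1)) {
    # collinear chain: reverse is the negated forward direction, and all
    # interior residues share the same local-frame representation
    expect_equal(unname(o[i, 4:6]), unname(-o[i, 1:3]))
    expect_equal(unname(o[i, 1:3]), unname(o[2, 1:3]))
    expect_equal(sum(o[i, 1:3]^2), 1)
  }
  expect_equal(unname(o[L, 1:3]), c(0, 0, 0))  # terminus padding
  norms <- sqrt(rowSums(o[, 7:9]^2))
  expect_true(all(abs(norms - 1) < 1e-6))
})

test_that("imputed glycine CB agrees with an independent tetrahedral builder", {
  m <- make_monomer(25, "mixed", seed = 13)
  for (i in c(3, 12, 20)) {
    ours <- impute_cb(m$backbone$N[i, ], m$backbone$CA[i, ],
                      m$backbone$C[i, ])
    ref <- oracle_cb(m$backbone$N[i, ], m$backbone$CA[i, ],
                     m$backbone$C[i, ])
    expect_lt(sqrt(sum((ours - ref)^2)), 1e-1)
    # direction agreement is what the feature uses
    du <- (ours - m$backbone$CA[i, ])
    ru <- (ref - m$backbone$CA[i, ])
    cosang <- sum(du * ru) / sqrt(sum(du^2) * sum(ru^2))
    expect_gt(cosang, 0.999)
  }
})

test_that("hull area feature inverts the convex hull surface area", {
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  expect_equal(convex_hull_area(cube), 6)
  m <- protein_monomer("A", "A", list(CA = matrix(cube[1, ], 1, 3)),
                       data.frame(res = 1, elety = paste0("C", 1:8),
                                  x = cube[, 1], y = cube[, 2],
                                  z = cube[, 3]))
  expect_equal(hull_area_feature(m)[1, 1], 1 / 6)
  # coplanar points are degenerate -> 0
  flat <- cbind(runif(5), runif(5), 0)
  expect_equal(convex_hull_area(flat), 0)
  # rotation invariance of the area
  set.seed(6)
  pts <- matrix(rnorm(30), 10, 3)
  a0 <- convex_hull_area(pts)
  mo <- random_rigid_motion()
  expect_lt(abs(convex_hull_area(apply_rigid(pts, mo)) - a0), 1e-9)
})

test_that("contact counts are symmetric, normalized by the chain maximum", {
  tri <- function(d) {
    ca <- rbind(c(0, 0, 0), c(d, 0, 0), c(d / 2, d * sqrt(3) / 2, 0))
    n <- sweep(ca, 2, c(-1, 0.5, 0.3), "+")
    cc <- sweep(ca, 2, c(1, 0.5, 0.3), "+")
    cb <- sweep(ca, 2, c(0, -0.5, 1), "+")
    protein_monomer("A", rep("A", 3),
                    list(N = n, CA = ca, C = cc, CB = cb),
                    data.frame(res = 1:3, elety = "CA", x = ca[, 1],
                               y = ca[, 2], z = ca[, 3]))
  }
  # pairwise CB distance 5 A: every residue contacts the other two
  expect_equal(as.vector(contact_count_feature(tri(5))), c(1, 1, 1))
  # all CB farther than 8 A: all zero
  expect_equal(as.vector(contact_count_feature(tri(50))), c(0, 0, 0))
})

test_that("assembled features have the 118 / 45 channel budget and named errors", {
  m <- make_monomer(25, "mixed", seed = 8)
  prov <- mock_feature_providers(seed = 1)
  nf <- node_features(m, prov$profile, prov$embedding)
  expect_equal(dim(nf$matrix), c(25, 118))
  structural <- c("ss3", "ss8", "rsa2", "rsa8", "local_geom", "rel_pos",
                  "orient", "hull_area", "contact_count")
  expect_equal(sum(vapply(nf$blocks[structural], ncol, 0L)), 45L)
  sequence_based <- c("aa_onehot", "pssm", "plm")
  expect_equal(sum(vapply(nf$blocks[sequence_based], ncol, 0L)), 73L)
  bad <- nf$blocks
  bad$pssm <- bad$pssm[, 1:19]
  expect_error(assemble_node_features(bad), "pssm: expected 20 columns")
  bad2 <- nf$blocks
  bad2$orient <- bad2$orient[1:10, ]
  expect_error(assemble_node_features(bad2), "orient")
  expect_error(assemble_node_features(nf$blocks[-1]), "aa_onehot")
})

test_that("structure-derived features are rigid-motion invariant", {
  m <- make_monomer(20, "mixed", seed = 17)
  base <- list(lg = local_geometry_features(m),
               pos = positional_features(m),
               orient = orientation_features(m),
               hull = hull_area_feature(m),
               cc = contact_count_feature(m))
  set.seed(23)
  for (k in 1:3) {
    mo <- random_rigid_motion(reflect = FALSE)
    m2 <- m
    for (nm in names(m$backbone)) {
      ok <- !is.na(m$backbone[[nm]][, 1])
      m2$backbone[[nm]][ok, ] <- apply_rigid(
        m$backbone[[nm]][ok, , drop = FALSE], mo)
    }
    xyz <- apply_rigid(as.matrix(m$atoms[, c("x", "y", "z")]), mo)
    m2$atoms$x <- xyz[, 1]; m2$atoms$y <- xyz[, 2]; m2$atoms$z <- xyz[, 3]
    expect_lt(max(abs(local_geometry_features(m2) - base$lg)), 1e-6)
    expect_lt(max(abs(positional_features(m2)[, 2] - base$pos[, 2])), 1e-6)
    expect_lt(max(abs(hull_area_feature(m2) - base$hull)), 1e-6)
    expect_lt(max(abs(contact_count_feature(m2) - base$cc)), 1e-6)
    # local-frame orientation vectors are invariant too
    expect_lt(max(abs(orientation_features(m2) - base$orient)), 1e-6)
  }
})
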