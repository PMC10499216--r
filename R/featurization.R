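# Residue featurization: the L x 118 node feature matrix.
#
# Channel budget (columns, in fixed block order):
#   aa_onehot 20 | pssm 20 | plm 33            -> 73 sequence channels
#   ss3 3 | ss8 8 | rsa2 2 | rsa8 8            -> 21 (DSSP-derived)
#   local_geom 11 | rel_pos 2 | orient 9       -> 22 (geometry)
#   hull_area 1 | contact_count 1              ->  2
# structural subtotal 45, grand total 118.

SS8_CODES <- c("H", "G", "I", "E", "B", "T", "S", "C")
.BLOCK_DIMS <- c(aa_onehot = 20L, pssm = 20L, plm = 33L, ss3 = 3L,
                 ss8 = 8L, rsa2 = 2L, rsa8 = 8L, local_geom = 11L,
                 rel_pos = 2L, orient = 9L, hull_area = 1L,
                 contact_count = 1L)

sigmoid <- function(x) 1 / (1 + exp(-x))

#' One-hot residue identity block (L x 20)
#'
#' Columns follow the alphabetical one-letter ordering
#' `ACDEFGHIKLMNPQRSTVWY`; nonstandard residues (`X`) give an all-zero row.
#'
#' @param sequence character vector of one-letter codes.
#' @return L x 20 binary matrix.
#' @export
one_hot_residue <- function(sequence) {
  m <- matrix(0, length(sequence), 20,
              dimnames = list(NULL, AA_ALPHABET))
  idx <- match(sequence, AA_ALPHABET)
  ok <- !is.na(idx)
  m[cbind(which(ok), idx[ok])] <- 1
  m
}

#' Sigmoid-normalized sequence profile block (L x 20)
#'
#' Squashes raw profile scores (e.g. the first 20 columns of a PSI-BLAST
#' position-specific scoring matrix) elementwise through `1/(1+exp(-v))`.
#'
#' @param raw L x 20 numeric matrix from a profile provider.
#' @return L x 20 matrix with entries in (0, 1).
#' @export
profile_features <- function(raw) {
  raw <- as.matrix(raw)
  if (ncol(raw) != 20) stop("profile: expected 20 columns, got ", ncol(raw))
  sigmoid(raw)
}

#' Sigmoid-normalized language-model embedding block (L x 33)
#'
#' @param raw L x 33 numeric matrix from an embedding provider.
#' @return L x 33 matrix with entries in (0, 1).
#' @export
plm_features <- function(raw) {
  raw <- as.matrix(raw)
  if (ncol(raw) != 33) stop("plm: expected 33 columns, got ", ncol(raw))
  sigmoid(raw)
}

#' Read a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Parses the `-out_ascii_pssm` format and returns the first 20 (log-odds)
#' columns as a raw L x 20 matrix, suitable for [profile_features()].
#'
#' @param path ASCII PSSM file.
#' @return L x 20 numeric matrix with the query sequence as an attribute.
#' @export
read_pssm <- function(path) {
  lines <- readLines(path)
  rows <- grep("^\\s*[0-9]+\\s+[A-Z]\\s", lines, value = TRUE)
  if (length(rows) == 0) stop("no PSSM rows found in ", path)
  parts <- strsplit(trimws(rows), "\\s+")
  mat <- t(vapply(parts, function(p) as.numeric(p[3:22]), numeric(20)))
  structure(mat, sequence = vapply(parts, `[`, "", 2))
}

# ---- secondary structure & accessibility ----------------------------------

#' Secondary structure and accessibility without an external DSSP binary
#'
#' Internal fallback assigning 8-state codes from backbone phi/psi torsions
#' (helical basin -> H, extended basin -> E, otherwise C) and absolute
#' accessibility by a Shrake-Rupley sphere method over the heavy atoms
#' (probe 1.4 Angstrom, 92 sphere points, element VdW radii). Adequate for
#' synthetic fixtures; supply a real `.dssp` file via [read_dssp()] when
#' available.
#'
#' @param monomer a [protein_monomer()].
#' @param n_points sphere points per atom.
#' @param probe probe radius (Angstrom).
#' @return data frame with columns `ss8` and `acc` (one row per residue).
#' @export
compute_dssp <- function(monomer, n_points = 92, probe = 1.4) {
  tor <- backbone_torsions(monomer)
  ss8 <- rep("C", length(monomer$sequence))
  helical <- !is.na(tor$phi) & !is.na(tor$psi) &
    tor$phi > -120 & tor$phi < -30 & tor$psi > -80 & tor$psi < 10
  extended <- !is.na(tor$phi) & !is.na(tor$psi) &
    tor$phi > -180 & tor$phi < -45 & (tor$psi > 90 | tor$psi < -150)
  ss8[extended] <- "E"
  ss8[helical] <- "H"
  acc <- .shrake_rupley(monomer, n_points = n_points, probe = probe)
  data.frame(ss8 = ss8, acc = acc, stringsAsFactors = FALSE)
}

.vdw_radius <- function(elety) {
  el <- substr(gsub("^[0-9]*", "", elety), 1, 1)
  r <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)[el]
  ifelse(is.na(r), 1.70, r)
}

.shrake_rupley <- function(monomer, n_points = 92, probe = 1.4) {
  at <- monomer$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rad <- .vdw_radius(at$elety) + probe
  n <- nrow(xyz)
  # golden-spiral unit sphere points
  k <- seq_len(n_points)
  phi_g <- acos(1 - 2 * (k - 0.5) / n_points)
  th <- pi * (1 + sqrt(5)) * (k - 0.5)
  sphere <- cbind(sin(phi_g) * cos(th), sin(phi_g) * sin(th), cos(phi_g))
  # anchor the sphere to the molecule's principal axes (signs fixed by
  # third moments) so the discrete sampling rotates with the structure and
  # the computed areas are rotation-invariant
  ctr <- sweep(xyz, 2, colMeans(xyz))
  ev <- eigen(crossprod(ctr), symmetric = TRUE)$vectors
  for (ax in 1:3) {
    m3 <- sum((ctr %*% ev[, ax])^3)
    if (m3 < 0) ev[, ax] <- -ev[, ax]
  }
  if (det(ev) < 0) ev[, 3] <- -ev[, 3]
  sphere <- sphere %*% t(ev)
  area <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (rad + rad[i])^2 & d2 > 1e-9)
    pts <- sweep(sphere * rad[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nb) {
      free <- free & rowSums(sweep(pts, 2, xyz[j, ])^2) > rad[j]^2
      if (!any(free)) break
    }
    area[i] <- 4 * pi * rad[i]^2 * sum(free) / n_points
  }
  as.numeric(rowsum(area, at$res)[as.character(seq_along(monomer$sequence)), 1])
}

#' Read per-residue records from a classic DSSP output file
#'
#' @param path `.dssp` file produced by the DSSP program.
#' @param chain optional chain filter.
#' @return data frame with columns `ss8` and `acc`.
#' @export
read_dssp <- function(path, chain = NULL) {
  lines <- readLines(path)
  start <- grep("^  #  RESIDUE", lines)
  if (length(start) == 0) stop("not a DSSP file: ", path)
  rec <- lines[(start + 1):length(lines)]
  rec <- rec[nchar(rec) >= 38 & substr(rec, 14, 14) != "!"]
  ch <- substr(rec, 12, 12)
  if (!is.null(chain)) rec <- rec[ch == chain]
  ss <- substr(rec, 17, 17)
  ss[!(ss %in% SS8_CODES)] <- "C"
  acc <- as.numeric(substr(rec, 35, 38))
  data.frame(ss8 = ss, acc = acc, stringsAsFactors = FALSE)
}

#' DSSP-derived feature block (L x 21)
#'
#' One-hot encodings of the 8-state code, its 3-state collapse
#' (H/G/I -> helix, E/B -> strand, T/S/C -> coil), 2-state burial at an
#' absolute accessibility cutoff of 50 (exposed when ACC >= 50), and an
#' 8-bin accessibility discretization with bins
#' \[0,30), \[30,60), ..., \[180,210), \[210,Inf).
#'
#' @param records data frame with `ss8` and `acc` columns, one row per
#'   residue ([compute_dssp()] / [read_dssp()]). Rows with `NA` are treated
#'   as coil with ACC 0 (a message is emitted).
#' @param acc_cutoff exposed/buried boundary (default 50).
#' @return L x 21 matrix: blocks ss3 (3), ss8 (8), rsa2 (2), rsa8 (8).
#' @export
dssp_features <- function(records, acc_cutoff = 50) {
  ss <- records$ss8
  acc <- records$acc
  bad <- is.na(ss) | is.na(acc)
  if (any(bad)) {
    message(sum(bad), " residue(s) without DSSP record; using C / ACC 0")
    ss[is.na(ss)] <- "C"
    acc[is.na(acc)] <- 0
  }
  L <- length(ss)
  ss8 <- matrix(0, L, 8, dimnames = list(NULL, SS8_CODES))
  ss8[cbind(seq_len(L), match(ss, SS8_CODES))] <- 1
  ss3 <- cbind(helix = ss8[, "H"] + ss8[, "G"] + ss8[, "I"],
               strand = ss8[, "E"] + ss8[, "B"],
               coil = ss8[, "T"] + ss8[, "S"] + ss8[, "C"])
  rsa2 <- cbind(exposed = as.numeric(acc >= acc_cutoff),
                buried = as.numeric(acc < acc_cutoff))
  bins <- c(seq(0, 210, by = 30), Inf)
  bin_idx <- findInterval(acc, bins, rightmost.closed = FALSE)
  rsa8 <- matrix(0, L, 8)
  rsa8[cbind(seq_len(L), pmin(bin_idx, 8))] <- 1
  cbind(ss3, ss8, rsa2, rsa8)
}

# ---- geometric blocks -----------------------------------------------------

#' Backbone torsion angles phi, psi, omega (degrees)
#'
#' `phi[i]` uses C(i-1), `psi[i]` uses N(i+1), `omega[i]` is the peptide
#' torsion preceding residue i (CA(i-1), C(i-1), N(i), CA(i)); entries
#' undefined at the termini or at missing atoms are `NA`.
#'
#' @param monomer a [protein_monomer()].
#' @return data frame with columns `phi`, `psi`, `omega`.
#' @export
backbone_torsions <- function(monomer) {
  bb <- monomer$backbone
  L <- length(monomer$sequence)
  r2d <- 180 / pi
  tors <- function(a, b, c, d) {
    if (anyNA(c(a, b, c, d))) return(NA_real_)
    dihedral_angle(a, b, c, d) * r2d
  }
  phi <- psi <- omega <- rep(NA_real_, L)
  for (i in seq_len(L)) {
    if (i > 1) {
      phi[i] <- tors(bb$C[i - 1, ], bb$N[i, ], bb$CA[i, ], bb$C[i, ])
      omega[i] <- tors(bb$CA[i - 1, ], bb$C[i - 1, ], bb$N[i, ], bb$CA[i, ])
    }
    if (i < L) {
      psi[i] <- tors(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$N[i + 1, ])
    }
  }
  data.frame(phi = phi, psi = psi, omega = omega)
}

#' Local backbone geometry block (L x 11)
#'
#' Channels: (1) cosine of the angle between the carbonyl C=O bond vectors
#' of residues i and i+1; (2-5) sine and cosine of the virtual bond angle
#' over CA(i-1), CA(i), CA(i+1) and of the virtual torsion over
#' CA(i-1)..CA(i+2); (6-11) sine and cosine of the backbone torsions phi,
#' psi and omega. Entries undefined at the termini are 0.
#'
#' @param monomer a [protein_monomer()].
#' @return L x 11 numeric matrix.
#' @export
local_geometry_features <- function(monomer) {
  bb <- monomer$backbone
  L <- length(monomer$sequence)
  out <- matrix(0, L, 11)
  co <- bb$O - bb$C  # carbonyl bond vectors
  for (i in seq_len(L)) {
    if (i < L && !anyNA(co[i, ]) && !anyNA(co[i + 1, ])) {
      out[i, 1] <- sum(unitv(co[i, ]) * unitv(co[i + 1, ]))
    }
    if (i > 1 && i < L) {
      th <- planar_angle(bb$CA[i - 1, ], bb$CA[i, ], bb$CA[i + 1, ])
      out[i, 2:3] <- c(sin(th), cos(th))
    }
    if (i > 1 && i < L - 1) {
      ta <- dihedral_angle(bb$CA[i - 1, ], bb$CA[i, ], bb$CA[i + 1, ],
                           bb$CA[i + 2, ])
      out[i, 4:5] <- c(sin(ta), cos(ta))
    }
  }
  tor <- backbone_torsions(monomer)
  d2r <- pi / 180
  for (k in 1:3) {
    ang <- tor[[k]] * d2r
    s <- ifelse(is.na(ang), 0, sin(ang))
    c_ <- ifelse(is.na(ang), 0, cos(ang))
    out[, 4 + 2 * k] <- s
    out[, 5 + 2 * k] <- c_
  }
  out
}

#' Relative positional block (L x 2)
#'
#' Column 1 is `1/i` (sequence position); column 2 is the inverse distance
#' from the monomer's C-alpha centroid to the residue's C-alpha, clamped
#' below at `eps` to bound the inverse.
#'
#' @param monomer a [protein_monomer()].
#' @param eps distance clamp in Angstrom (default 1).
#' @return L x 2 numeric matrix.
#' @export
positional_features <- function(monomer, eps = 1) {
  x <- ca_coords(monomer)
  centroid <- colMeans(x)
  d <- sqrt(rowSums(sweep(x, 2, centroid)^2))
  cbind(1 / seq_len(nrow(x)), 1 / pmax(d, eps))
}

#' Residue orientation block (L x 9)
#'
#' Three unit vectors per residue: forward CA(i+1) - CA(i), reverse
#' CA(i-1) - CA(i), and the imputed tetrahedral CB(i) - CA(i) direction
#' ([impute_cb()], used for every residue including glycine). Each vector
#' is expressed in the residue's own backbone frame (built from the
#' N-CA and C-CA bonds by Gram-Schmidt), so the block is invariant under
#' rigid motions of the whole structure while still encoding how the
#' chain and side chain are oriented relative to the local backbone.
#' A missing neighbor (chain terminus) gives a zero vector; residues
#' without N/C records fall back to global-frame vectors.
#'
#' @param monomer a [protein_monomer()].
#' @return L x 9 numeric matrix (rows of unit or zero 3-vectors).
#' @export
orientation_features <- function(monomer) {
  bb <- monomer$backbone
  L <- length(monomer$sequence)
  out <- matrix(0, L, 9)
  for (i in seq_len(L)) {
    frame <- diag(3)
    has_frame <- !anyNA(bb$N[i, ]) && !anyNA(bb$C[i, ])
    if (has_frame) {
      e1 <- unitv(bb$N[i, ] - bb$CA[i, ])
      v <- bb$C[i, ] - bb$CA[i, ]
      e2 <- unitv(v - sum(v * e1) * e1)
      frame <- rbind(e1, e2, vcross(e1, e2))
    }
    if (i < L) {
      out[i, 1:3] <- frame %*% unitv(bb$CA[i + 1, ] - bb$CA[i, ])
    }
    if (i > 1) {
      out[i, 4:6] <- frame %*% unitv(bb$CA[i - 1, ] - bb$CA[i, ])
    }
    if (has_frame) {
      cb <- impute_cb(bb$N[i, ], bb$CA[i, ], bb$C[i, ])
      out[i, 7:9] <- frame %*% unitv(cb - bb$CA[i, ])
    }
  }
  out
}

#' Inverse convex-hull surface area block (L x 1)
#'
#' Each residue is viewed as the convex hull of its heavy atoms; the
#' feature is the inverse of the hull's surface area, or 0 when the hull
#' is degenerate (fewer than 4 non-coplanar atoms).
#'
#' @param monomer a [protein_monomer()].
#' @return L x 1 numeric matrix.
#' @export
hull_area_feature <- function(monomer) {
  vals <- vapply(seq_along(monomer$sequence), function(r) {
    pts <- as.matrix(
      monomer$atoms[monomer$atoms$res == r, c("x", "y", "z"), drop = FALSE])
    a <- convex_hull_area(pts)
    if (a > 0) 1 / a else 0
  }, numeric(1))
  matrix(vals, ncol = 1)
}

#' Normalized C-beta contact count block (L x 1)
#'
#' Counts, for each residue, the other residues whose C-beta atom
#' (imputed for glycine) lies within `cb_cutoff`, and divides by the
#' chain's maximum count (0 when no contacts exist anywhere).
#'
#' @param monomer a [protein_monomer()].
#' @param cb_cutoff contact cutoff in Angstrom (default 8).
#' @return L x 1 numeric matrix with values in \[0, 1\].
#' @export
contact_count_feature <- function(monomer, cb_cutoff = 8) {
  bb <- monomer$backbone
  L <- length(monomer$sequence)
  cb <- bb$CB
  for (i in seq_len(L)) {
    if (anyNA(cb[i, ]) && !anyNA(bb$N[i, ]) && !anyNA(bb$C[i, ])) {
      cb[i, ] <- impute_cb(bb$N[i, ], bb$CA[i, ], bb$C[i, ])
    }
  }
  d <- as.matrix(stats::dist(cb))
  counts <- rowSums(d <= cb_cutoff, na.rm = TRUE) - 1L
  counts[counts < 0] <- 0
  mx <- max(counts)
  matrix(if (mx > 0) counts / mx else counts * 0, ncol = 1)
}

#' Assemble named blocks into the L x 118 node feature matrix
#'
#' @param blocks named list with entries `aa_onehot`, `pssm`, `plm`, `ss3`,
#'   `ss8`, `rsa2`, `rsa8`, `local_geom`, `rel_pos`, `orient`, `hull_area`,
#'   `contact_count`, each with L rows and the fixed column count.
#' @return object of class `node_feature_matrix` with fields `blocks` and
#'   `matrix` (L x 118).
#' @export
assemble_node_features <- function(blocks) {
  missing_ <- setdiff(names(.BLOCK_DIMS), names(blocks))
  if (length(missing_) > 0) {
    stop("missing feature block(s): ", paste(missing_, collapse = ", "))
  }
  L <- nrow(as.matrix(blocks[[names(.BLOCK_DIMS)[1]]]))
  for (nm in names(.BLOCK_DIMS)) {
    b <- as.matrix(blocks[[nm]])
    if (ncol(b) != .BLOCK_DIMS[[nm]]) {
      stop(nm, ": expected ", .BLOCK_DIMS[[nm]], " columns, got ", ncol(b))
    }
    if (nrow(b) != L) {
      stop(nm, ": expected ", L, " rows, got ", nrow(b))
    }
  }
  mat <- do.call(cbind, lapply(names(.BLOCK_DIMS),
                               function(nm) as.matrix(blocks[[nm]])))
  structure(list(blocks = blocks[names(.BLOCK_DIMS)], matrix = mat),
            class = "node_feature_matrix")
}

#' @export
print.node_feature_matrix <- function(x, ...) {
  cat(sprintf("<node_feature_matrix> %d residues x %d channels\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Full 118-channel featurization of a monomer
#'
#' Convenience wrapper computing every block: residue one-hot, sigmoid
#' profile, sigmoid embedding, secondary structure / accessibility
#' one-hots, local geometry, relative position, orientation vectors,
#' inverse hull area and normalized contact count.
#'
#' @param monomer a [protein_monomer()].
#' @param profile_provider function `sequence -> L x 20` raw profile.
#' @param embedding_provider function `sequence -> L x 33` raw embedding.
#' @param dssp optional precomputed data frame (`ss8`, `acc`); computed
#'   internally via [compute_dssp()] when `NULL`.
#' @param acc_cutoff,cb_cutoff,centroid_eps tunables of the respective
#'   blocks.
#' @return a `node_feature_matrix` (L x 118).
#' @export
node_features <- function(monomer, profile_provider, embedding_provider,
                          dssp = NULL, acc_cutoff = 50, cb_cutoff = 8,
                          centroid_eps = 1) {
  seqv <- monomer$sequence
  raw_prof <- profile_provider(seqv)
  raw_plm <- embedding_provider(seqv)
  if (nrow(as.matrix(raw_prof)) != length(seqv)) {
    stop("profile provider returned ", nrow(as.matrix(raw_prof)),
         " rows for a length-", length(seqv), " sequence")
  }
  if (nrow(as.matrix(raw_plm)) != length(seqv)) {
    stop("embedding provider returned ", nrow(as.matrix(raw_plm)),
         " rows for a length-", length(seqv), " sequence")
  }
  if (is.null(dssp)) dssp <- compute_dssp(monomer)
  d21 <- dssp_features(dssp, acc_cutoff = acc_cutoff)
  assemble_node_features(list(
    aa_onehot = one_hot_residue(seqv),
    pssm = profile_features(raw_prof),
    plm = plm_features(raw_plm),
    ss3 = d21[, 1:3, drop = FALSE],
    ss8 = d21[, 4:11, drop = FALSE],
    rsa2 = d21[, 12:13, drop = FALSE],
    rsa8 = d21[, 14:21, drop = FALSE],
    local_geom = local_geometry_features(monomer),
    rel_pos = positional_features(monomer, eps = centroid_eps),
    orient = orientation_features(monomer),
    hull_area = hull_area_feature(monomer),
    contact_count = contact_count_feature(monomer, cb_cutoff = cb_cutoff)
  ))
}
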