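# Desk-scale synthetic fixtures: ideal backbones built from internal
# coordinates, posed two-chain complexes with geometric interface labels,
# and deterministic mock providers for profile / embedding features.
#
# The planted labels (any receptor heavy atom within `label_cutoff` of any
# ligand heavy atom) are a stand-in geometry for testing the pipeline; they
# are NOT the labeling convention of any published interface benchmark.

# ideal backbone internal coordinates (Angstrom / degrees)
.BOND <- list(n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231)
.ANG <- list(n_ca_c = 111.0, ca_c_n = 116.2, c_n_ca = 121.7)

#' Generate a synthetic protein monomer
#'
#' Builds an all-backbone (N, CA, C, O, and CB for non-glycine) chain from
#' ideal bond lengths and angles by sequential natural-extension (NeRF)
#' placement, with backbone torsions set by `style`:
#' \describe{
#'   \item{helix}{ideal alpha-helix, phi = -57, psi = -47 (rise about
#'     1.5 Angstrom, about 100 degrees per residue, radius about 2.3).}
#'   \item{coil}{perturbed extended chain, phi/psi jittered around the
#'     polyproline/beta basin.}
#'   \item{mixed}{random alternation of helical and coil segments.}
#' }
#' The sequence is drawn uniformly from the 20 standard residues.
#'
#' @param L chain length (>= 3).
#' @param style `"helix"`, `"coil"` or `"mixed"`.
#' @param seed integer seed; same seed reproduces coordinates and sequence.
#' @param chain_id chain identifier for the generated monomer.
#' @return a [protein_monomer()].
#' @export
make_monomer <- function(L, style = c("helix", "coil", "mixed"), seed = 1,
                         chain_id = "A") {
  style <- match.arg(style)
  if (L < 3) stop("L must be >= 3")
  rng <- local({ set.seed(seed); NULL })
  set.seed(seed)
  sequence <- sample(AA_ALPHABET, L, replace = TRUE)
  tor <- .style_torsions(L, style)
  bb <- .build_backbone(L, tor$phi, tor$psi)
  cb <- t(vapply(seq_len(L), function(i) {
    impute_cb(bb$N[i, ], bb$CA[i, ], bb$C[i, ])
  }, numeric(3)))
  cb[sequence == "G", ] <- NA_real_
  atoms <- do.call(rbind, lapply(seq_len(L), function(i) {
    names <- c("N", "CA", "C", "O")
    xyz <- rbind(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$O[i, ])
    if (sequence[i] != "G") {
      names <- c(names, "CB")
      xyz <- rbind(xyz, cb[i, ])
    }
    data.frame(res = i, elety = names, x = xyz[, 1], y = xyz[, 2],
               z = xyz[, 3], stringsAsFactors = FALSE)
  }))
  protein_monomer(chain_id, sequence,
                  backbone = list(N = bb$N, CA = bb$CA, C = bb$C, O = bb$O,
                                  CB = cb),
                  atoms = atoms)
}

.style_torsions <- function(L, style) {
  helix <- function(n) list(phi = rep(-57, n), psi = rep(-47, n))
  coil <- function(n) list(phi = stats::runif(n, -150, -60),
                           psi = stats::runif(n, 100, 170))
  if (style == "helix") return(helix(L))
  if (style == "coil") return(coil(L))
  phi <- numeric(0); psi <- numeric(0)
  while (length(phi) < L) {
    seg <- sample(4:10, 1)
    part <- if (stats::runif(1) < 0.5) helix(seg) else coil(seg)
    phi <- c(phi, part$phi); psi <- c(psi, part$psi)
  }
  list(phi = phi[1:L], psi = psi[1:L])
}

# sequential NeRF chain build; torsions in degrees
.build_backbone <- function(L, phi, psi, omega = rep(180, L)) {
  d2r <- pi / 180
  N <- CA <- C <- O <- matrix(NA_real_, L, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(.BOND$n_ca, 0, 0)
  a <- .ANG$n_ca_c * d2r
  C[1, ] <- CA[1, ] + .BOND$ca_c * c(-cos(a), sin(a), 0)
  for (i in seq_len(L - 1)) {
    N[i + 1, ] <- nerf_place(N[i, ], CA[i, ], C[i, ], .BOND$c_n,
                             .ANG$ca_c_n * d2r, psi[i] * d2r)
    CA[i + 1, ] <- nerf_place(CA[i, ], C[i, ], N[i + 1, ], .BOND$n_ca,
                              .ANG$c_n_ca * d2r, omega[i] * d2r)
    C[i + 1, ] <- nerf_place(C[i, ], N[i + 1, ], CA[i + 1, ], .BOND$ca_c,
                             .ANG$n_ca_c * d2r, phi[i + 1] * d2r)
  }
  # carbonyl oxygens: in the peptide plane, anti to the next amide N
  nv <- rbind(N[-1, , drop = FALSE],
              nerf_place(N[L, ], CA[L, ], C[L, ], .BOND$c_n,
                         .ANG$ca_c_n * d2r, psi[L] * d2r))
  for (i in seq_len(L)) {
    O[i, ] <- C[i, ] + .BOND$c_o *
      unitv(unitv(C[i, ] - CA[i, ]) + unitv(C[i, ] - nv[i, ]))
  }
  list(N = N, CA = CA, C = C, O = O)
}

#' Generate a posed two-chain complex with planted interface labels
#'
#' Builds a receptor and a ligand monomer, rotates the ligand randomly and
#' translates it along the receptor's centroid-to-N-terminus direction
#' until the closest heavy-atom distance between the chains is
#' approximately `gap`. Receptor residues with any heavy atom within
#' `label_cutoff` of any ligand heavy atom are labeled as interface (1),
#' the rest 0.
#'
#' The approach direction is deliberately a deterministic function of the
#' receptor's own geometry (the ligand docks onto the surface patch around
#' the N-terminal end) so that the planted labels are recoverable from
#' partner-independent receptor features; with a uniformly random approach
#' direction no monomer-only predictor could identify the interface side.
#'
#' @param L_receptor,L_ligand chain lengths (>= 3).
#' @param gap target closest approach between the chains (Angstrom).
#' @param label_cutoff heavy-atom distance defining an interface residue.
#' @param seed integer seed.
#' @param style backbone style passed to [make_monomer()].
#' @return object of class `synthetic_complex` with fields `receptor`,
#'   `ligand`, `labels` (0/1 per receptor residue) and `rng_seed`.
#' @export
make_labeled_complex <- function(L_receptor, L_ligand, gap = 5,
                                 label_cutoff = 8, seed = 1,
                                 style = "mixed") {
  stopifnot(L_receptor >= 3, L_ligand >= 3)
  for (attempt in 1:5) {
    sub <- seed + 1000L * (attempt - 1L)
    receptor <- make_monomer(L_receptor, style, seed = sub, chain_id = "A")
    ligand <- make_monomer(L_ligand, style, seed = sub + 500L,
                           chain_id = "B")
    set.seed(sub + 7L)
    motion <- random_rigid_motion()
    rca <- ca_coords(receptor)
    u <- unitv(rca[1, ] - colMeans(rca))
    ra <- as.matrix(receptor$atoms[, c("x", "y", "z")])
    la0 <- apply_rigid(as.matrix(ligand$atoms[, c("x", "y", "z")]), motion)
    # center the ligand on the approach axis above the docking site,
    # then pull it in along u until the closest approach reaches the gap
    r_lig <- max(sqrt(rowSums(sweep(la0, 2, colMeans(la0))^2)))
    target <- rca[1, ] + (r_lig + gap + 5) * u
    la <- sweep(la0, 2, target - colMeans(la0), "+")
    for (it in 1:8) {
      dmin <- .min_cross_dist(ra, la)
      if (abs(dmin - gap) < 0.05) break
      la <- sweep(la, 2, (dmin - gap) * u, "-")
    }
    ligand <- .set_atom_coords(ligand, la)
    dres <- .residue_min_dist(receptor, la)
    labels <- as.integer(dres <= label_cutoff)
    if (sum(labels) > 0 && sum(labels) < L_receptor) {
      return(structure(list(receptor = receptor, ligand = ligand,
                            labels = labels, rng_seed = seed),
                       class = "synthetic_complex"))
    }
    gap <- max(gap * 0.6, 1)
  }
  stop("failed to produce a labeled interface in 5 attempts ",
       "(chains too far apart for the label cutoff?)")
}

.min_cross_dist <- function(a, b) {
  # min over pairs; block to keep memory bounded
  m <- Inf
  step <- 2000
  for (s in seq(1, nrow(a), by = step)) {
    blk <- a[s:min(s + step - 1, nrow(a)), , drop = FALSE]
    d2 <- outer(rowSums(blk^2), rowSums(b^2), "+") - 2 * blk %*% t(b)
    m <- min(m, min(d2))
  }
  sqrt(max(m, 0))
}

.residue_min_dist <- function(monomer, other_xyz) {
  vapply(seq_along(monomer$sequence), function(r) {
    ra <- as.matrix(
      monomer$atoms[monomer$atoms$res == r, c("x", "y", "z"), drop = FALSE])
    d2 <- outer(rowSums(ra^2), rowSums(other_xyz^2), "+") -
      2 * ra %*% t(other_xyz)
    sqrt(max(min(d2), 0))
  }, numeric(1))
}

.set_atom_coords <- function(monomer, xyz) {
  monomer$atoms$x <- xyz[, 1]; monomer$atoms$y <- xyz[, 2]
  monomer$atoms$z <- xyz[, 3]
  for (nm in names(monomer$backbone)) {
    sel <- monomer$atoms$elety == nm
    rows <- monomer$atoms$res[sel]
    monomer$backbone[[nm]][rows, ] <- xyz[sel, , drop = FALSE]
  }
  monomer
}

#' @export
print.synthetic_complex <- function(x, ...) {
  cat(sprintf(
    "<synthetic_complex> receptor %d aa, ligand %d aa, %d interface residues\n",
    length(x$receptor$sequence), length(x$ligand$sequence), sum(x$labels)))
  invisible(x)
}

#' Deterministic mock profile and embedding providers
#'
#' Returns stand-ins for the PSI-BLAST profile and protein language-model
#' embedding providers: pseudo-random L x 20 and L x 33 matrices with
#' values in \[-10, 10\], keyed by `(seed, sequence)` so the same sequence
#' always receives the same matrices and different sequences differ.
#'
#' @param seed integer seed.
#' @return list with functions `profile(sequence)` and
#'   `embedding(sequence)`.
#' @export
mock_feature_providers <- function(seed = 1) {
  keyed <- function(sequence, ncol_, salt) {
    codes <- utf8ToInt(paste(sequence, collapse = ""))
    key <- sum(codes * seq_along(codes)) %% 1000003L
    set.seed((seed * 2017L + salt * 8191L + key) %% .Machine$integer.max)
    matrix(stats::runif(length(sequence) * ncol_, -10, 10),
           nrow = length(sequence), ncol = ncol_)
  }
  list(
    profile = function(sequence) keyed(sequence, 20L, salt = 1L),
    embedding = function(sequence) keyed(sequence, 33L, salt = 2L)
  )
}

#' Generate an end-to-end labeled training set
#'
#' Builds `n_complexes` synthetic complexes, parses each receptor into the
#' residue graph, featurizes it with mock providers and the internal
#' secondary-structure/accessibility routine, and attaches the planted
#' interface labels. Regenerates (with shifted seed) until the pooled
#' positive fraction lies in \[0.05, 0.40\], mimicking the class imbalance
#' of real interface data.
#'
#' @param n_complexes number of complexes (>= 1).
#' @param sizes integer vector of receptor lengths to sample from.
#' @param seed integer seed.
#' @param ligand_frac ligand length as a fraction of receptor length.
#' @return list of labeled graphs; each element has `graph`
#'   (a `residue_graph`), `features` (a `node_feature_matrix`), `labels`
#'   and `monomer`.
#' @export
generate_dataset <- function(n_complexes, sizes = 30:45, seed = 1,
                             ligand_frac = 0.25) {
  stopifnot(n_complexes >= 1)
  for (round in 1:10) {
    base <- seed + 100000L * (round - 1L)
    set.seed(base)
    Ls <- sample(sizes, n_complexes, replace = TRUE)
    out <- vector("list", n_complexes)
    for (k in seq_len(n_complexes)) {
      cx <- make_labeled_complex(
        Ls[k], max(3L, round(Ls[k] * ligand_frac)),
        seed = base + k, style = "mixed")
      prov <- mock_feature_providers(seed = base + k)
      feats <- node_features(cx$receptor, prov$profile, prov$embedding)
      out[[k]] <- list(graph = build_residue_graph(cx$receptor),
                       features = feats,
                       labels = cx$labels,
                       monomer = cx$receptor)
    }
    pos <- sum(vapply(out, function(g) sum(g$labels), numeric(1)))
    tot <- sum(vapply(out, function(g) length(g$labels), numeric(1)))
    frac <- pos / tot
    if (frac >= 0.05 && frac <= 0.40) return(out)
  }
  stop("could not reach a pooled positive fraction in [0.05, 0.40]")
}
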