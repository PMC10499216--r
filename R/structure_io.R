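# Structure parsing and residue-graph construction.
#
# A parsed chain is held as a "protein_monomer": the one-letter sequence,
# sequential residue indices 1..L (author numbering collapsed), per-residue
# backbone coordinate matrices and the full heavy-atom table. The residue
# interaction graph connects pairs whose C-alpha atoms lie within a distance
# cutoff and whose sequence separation is at least a minimum, the convention
# used throughout for partner-independent interface prediction.

AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M", SEC = "U", PYL = "O"
)

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Construct a protein monomer object
#'
#' Low-level constructor used by [parse_structure()] and the synthetic
#' backbone generator. Residues are renumbered sequentially 1..L.
#'
#' @param chain_id single chain identifier.
#' @param sequence character vector of one-letter codes (length L).
#' @param backbone named list of L x 3 matrices (`N`, `CA`, `C`, `O`, `CB`),
#'   rows `NA` where the atom is absent. `CA` must be complete.
#' @param atoms data frame of all heavy atoms with columns
#'   `res` (1..L), `elety`, `x`, `y`, `z`.
#' @return object of class `protein_monomer`.
#' @export
protein_monomer <- function(chain_id, sequence, backbone, atoms) {
  L <- length(sequence)
  stopifnot(L >= 1)
  for (nm in c("N", "CA", "C", "O", "CB")) {
    if (is.null(backbone[[nm]])) {
      backbone[[nm]] <- matrix(NA_real_, L, 3)
    }
    stopifnot(nrow(backbone[[nm]]) == L, ncol(backbone[[nm]]) == 3)
  }
  if (anyNA(backbone$CA)) {
    stop("every residue must have a CA coordinate")
  }
  structure(
    list(chain_id = chain_id,
         sequence = sequence,
         residue_index = seq_len(L),
         backbone = backbone,
         atoms = atoms),
    class = "protein_monomer"
  )
}

#' @export
print.protein_monomer <- function(x, ...) {
  cat(sprintf("<protein_monomer> chain %s, %d residues\n",
              x$chain_id, length(x$sequence)))
  cat("  sequence: ",
      paste(utils::head(x$sequence, 40), collapse = ""),
      if (length(x$sequence) > 40) "..." else "", "\n", sep = "")
  invisible(x)
}

#' C-alpha coordinate matrix of a monomer
#' @param monomer a `protein_monomer`.
#' @return L x 3 numeric matrix (Angstrom).
#' @export
ca_coords <- function(monomer) monomer$backbone$CA

#' Parse a single chain from a PDB or mmCIF file
#'
#' Reads ATOM records for one chain, resolves alternate locations by
#' occupancy (ties broken by altloc letter), excludes heteroatoms, waters
#' and hydrogens, drops residues lacking a C-alpha record (with a warning)
#' and renumbers the remainder sequentially 1..L.
#'
#' @param path PDB (`.pdb`, `.ent`) or mmCIF (`.cif`, `.mmcif`) file.
#' @param chain chain identifier; defaults to the first chain in the file.
#' @return a [protein_monomer()].
#' @export
parse_structure <- function(path, chain = NULL) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext %in% c("cif", "mmcif")) {
    bio3d::read.cif(path, verbose = FALSE)
  } else {
    bio3d::read.pdb(path, verbose = FALSE)
  }
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (is.null(chain)) chain <- at$chain[1]
  at <- at[at$chain %in% chain, , drop = FALSE]
  if (nrow(at) == 0) stop("chain '", chain, "' not found in ", path)
  # exclude hydrogens and waters
  elem <- if (!is.null(at$elesy) && !all(is.na(at$elesy))) {
    toupper(trimws(at$elesy))
  } else {
    substr(gsub("^[0-9]*", "", trimws(at$elety)), 1, 1)
  }
  at <- at[!(elem %in% c("H", "D")) & !(at$resid %in% c("HOH", "WAT")), ,
           drop = FALSE]
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  rkey <- paste(at$resno, at$insert, sep = "_")
  rlev <- unique(rkey)  # file order
  # altloc resolution: within (residue, atom name) keep max occupancy,
  # ties by altloc letter
  o <- if (is.null(at$o)) rep(1, nrow(at)) else ifelse(is.na(at$o), 1, at$o)
  ord <- order(match(rkey, rlev), at$elety, -o, at$alt)
  at <- at[ord, , drop = FALSE]
  keep <- !duplicated(paste(rkey[ord], at$elety, sep = "|"))
  at <- at[keep, , drop = FALSE]
  rkey <- paste(at$resno, at$insert, sep = "_")

  seqs <- character(0); bbN <- bbCA <- bbC <- bbO <- bbCB <- NULL
  rows <- list(); dropped <- character(0)
  for (rk in rlev) {
    sub <- at[rkey == rk, , drop = FALSE]
    if (!("CA" %in% sub$elety)) {
      dropped <- c(dropped, rk)
      next
    }
    getxyz <- function(name) {
      i <- match(name, sub$elety)
      if (is.na(i)) rep(NA_real_, 3) else as.numeric(sub[i, c("x", "y", "z")])
    }
    aa <- unname(AA3TO1[sub$resid[1]])
    seqs <- c(seqs, ifelse(is.na(aa), "X", aa))
    bbN <- rbind(bbN, getxyz("N")); bbCA <- rbind(bbCA, getxyz("CA"))
    bbC <- rbind(bbC, getxyz("C")); bbO <- rbind(bbO, getxyz("O"))
    bbCB <- rbind(bbCB, getxyz("CB"))
    rows[[length(rows) + 1]] <- data.frame(
      res = length(seqs), elety = sub$elety,
      x = sub$x, y = sub$y, z = sub$z, stringsAsFactors = FALSE)
  }
  if (length(dropped) > 0) {
    warning(length(dropped), " residue(s) without CA dropped: ",
            paste(dropped, collapse = ", "))
  }
  if (length(seqs) == 0) stop("no residues with CA records in chain ", chain)
  resno <- suppressWarnings(as.integer(sub("_.*", "", setdiff(rlev, dropped))))
  if (!anyNA(resno) && any(diff(resno) > 1)) {
    warning("chain breaks (author numbering gaps) after residue(s): ",
            paste(resno[which(diff(resno) > 1)], collapse = ", "),
            "; residues renumbered sequentially")
  }
  protein_monomer(
    chain_id = chain, sequence = seqs,
    backbone = list(N = bbN, CA = bbCA, C = bbC, O = bbO, CB = bbCB),
    atoms = do.call(rbind, rows)
  )
}

#' Edge feature: log sequence separation over spatial distance
#'
#' The per-edge scalar couples how far apart two residues are along the
#' chain with how close they are in space:
#' `a_ij = log(|i - j|) / ||x_i - x_j||`. Natural logarithm by default.
#'
#' @param i,j 1-based residue indices, `|i - j| >= 2`.
#' @param xi,xj C-alpha coordinates (length-3, Angstrom).
#' @param log_base logarithm base (default `exp(1)`).
#' @return positive scalar, symmetric in (i, j).
#' @export
edge_feature <- function(i, j, xi, xj, log_base = exp(1)) {
  sep <- abs(i - j)
  if (sep < 2) stop("edge_feature requires |i - j| >= 2")
  d <- vnorm(xi - xj)
  if (d <= 0) stop("coincident C-alpha atoms (zero distance) for pair ",
                   i, ",", j)
  log(sep, base = log_base) / d
}

#' Build the residue interaction graph of a monomer
#'
#' Connects residue pairs whose C-alpha Euclidean distance is at most
#' `cutoff` (inclusive) and whose sequence separation `|i - j|` is at least
#' `min_sep` (inclusive). Edges are stored in both directions for message
#' passing, with identical edge features.
#'
#' @param monomer a [protein_monomer()].
#' @param cutoff C-alpha distance cutoff in Angstrom (default 14).
#' @param min_sep minimum sequence separation in residues (default 6).
#' @param log_base base of the logarithm in [edge_feature()].
#' @return object of class `residue_graph` with fields `n_nodes`,
#'   `edges` (E x 2 integer matrix, both directions), `edge_attr`
#'   (length E), and `x` (L x 3 C-alpha coordinates).
#' @export
build_residue_graph <- function(monomer, cutoff = 14, min_sep = 6,
                                log_base = exp(1)) {
  x <- ca_coords(monomer)
  L <- nrow(x)
  d <- as.matrix(stats::dist(x))
  sep <- abs(outer(seq_len(L), seq_len(L), "-"))
  adj <- d <= cutoff & sep >= min_sep
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  if (nrow(idx) > 0) {
    attr_ <- log(sep[idx], base = log_base) / d[idx]
    edges <- rbind(idx, idx[, c(2, 1), drop = FALSE])
    edge_attr <- c(attr_, attr_)
  } else {
    edges <- matrix(integer(0), 0, 2)
    edge_attr <- numeric(0)
  }
  dimnames(edges) <- list(NULL, c("i", "j"))
  structure(
    list(n_nodes = L, edges = edges, edge_attr = edge_attr, x = x),
    class = "residue_graph"
  )
}

#' @export
print.residue_graph <- function(x, ...) {
  cat(sprintf("<residue_graph> %d nodes, %d undirected edges\n",
              x$n_nodes, nrow(x$edges) / 2))
  invisible(x)
}

#' Write a monomer as a single-model PDB file
#'
#' Emits standard fixed-width ATOM records (N, CA, C, O, CB where present)
#' plus any additional heavy atoms recorded for each residue.
#'
#' @param monomer a [protein_monomer()].
#' @param path output file.
#' @param chain chain identifier to write (defaults to the monomer's).
#' @return `path`, invisibly.
#' @export
write_pdb <- function(monomer, path, chain = monomer$chain_id) {
  aa13 <- names(AA3TO1)[match(monomer$sequence, AA3TO1)]
  aa13[is.na(aa13)] <- "UNK"
  lines <- character(0)
  serial <- 0
  for (r in seq_along(monomer$sequence)) {
    sub <- monomer$atoms[monomer$atoms$res == r, , drop = FALSE]
    for (k in seq_len(nrow(sub))) {
      serial <- serial + 1
      name <- sub$elety[k]
      # PDB atom-name column convention: element right-justified in 14-15
      fname <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
      lines <- c(lines, sprintf(
        "ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, fname, aa13[r], substr(chain, 1, 1), r,
        sub$x[k], sub$y[k], sub$z[k], 1.00, 0.00,
        substr(name, 1, 1)))
    }
  }
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}
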